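# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own matrix algebra:
# the Jaccard oracle works by set arithmetic on the raw edge list, the
# clustering oracle recomputes every linkage value from scratch from the
# original distances at every agglomeration step.

edge_df <- function(mirna, gene) {
  data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
}

# Random bipartite edge list; every miRNA gets at least one edge.
random_edges <- function(n_mirnas, n_genes, p = 0.3, seed = 1) {
  set.seed(seed)
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  genes <- sprintf("g%02d", seq_len(n_genes))
  rows <- lapply(mirnas, function(m) {
    hit <- genes[runif(n_genes) < p]
    if (!length(hit)) hit <- sample(genes, 1)
    edge_df(rep(m, length(hit)), hit)
  })
  do.call(rbind, rows)
}

# Pairwise Jaccard distances straight from the edge list, by set arithmetic.
oracle_jaccard <- function(edges) {
  sets <- split(edges$gene, edges$mirna)
  sets <- sets[order(names(sets))]
  ids <- names(sets)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- unique(sets[[i]]); b <- unique(sets[[j]])
      D[i, j] <- 1 - length(intersect(a, b)) / length(union(a, b))
    }
  }
  D
}

# Naive O(n^3) agglomerative clustering: at each step every candidate
# linkage value is recomputed from the ORIGINAL distance matrix over all
# cross-cluster leaf pairs (no Lance-Williams updates). Same lexicographic
# tie rule as the package. Returns the merge heights in order.
oracle_linkage_heights <- function(D, linkage) {
  labels <- rownames(D)
  clusters <- lapply(seq_len(nrow(D)), identity)
  heights <- numeric(0)
  link_val <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    switch(linkage,
           complete = max(vals),
           single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- link_val(clusters[[i]], clusters[[j]])
        key <- paste(sort(labels[c(clusters[[i]], clusters[[j]])]),
                     collapse = "\r")
        if (d < best_d - 1e-12 ||
            (d <= best_d + 1e-12 && (is.null(best_key) || key < best_key))) {
          best <- c(i, j); best_d <- min(best_d, d); best_key <- key
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Number of ordered triples (i, j, k) violating D[i,j] <= D[i,k] + D[k,j].
count_triangle_violations <- function(D, tol = 1e-12) {
  n <- nrow(D)
  bad <- 0L
  for (k in seq_len(n)) {
    relayed <- outer(D[, k], D[k, ], "+")
    bad <- bad + sum(D > relayed + tol)
  }
  bad
}

# Partitions equal up to cluster relabeling.
identical_partitions_test <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Write a quick edge-list / gene-list pair to temp files.
write_tmp_edges <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
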