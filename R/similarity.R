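#' Jaccard distance between two target sets
#'
#' \deqn{D_{ij} = 1 - |t_i \cap t_j| / |t_i \cup t_j|}{D = 1 - |A n B|/|A u B|}
#' — the proportion of genes not shared between the two miRNAs' target
#' sets, relative to all genes either targets. 0 means identical target
#' sets, 1 means disjoint. Only mutual presence of targets counts, so two
#' miRNAs with large but non-overlapping target lists are maximally
#' distant (unlike simple-matching-style coefficients, which would call
#' them similar on the strength of genes neither targets).
#'
#' @param ti,tj Character vectors (or sets) of target gene identifiers;
#'   both must be nonempty.
#' @return The Jaccard distance, a number in [0, 1].
#' @examples
#' jaccard_distance(c("A", "B", "C"), c("B", "C", "D")) # 0.5
#' @export
jaccard_distance <- function(ti, tj) {
  ti <- unique(as.character(ti))
  tj <- unique(as.character(tj))
  if (length(ti) == 0L && length(tj) == 0L) {
    stop("Jaccard distance is undefined for two empty target sets",
         call. = FALSE)
  }
  1 - length(intersect(ti, tj)) / length(union(ti, tj))
}

#' Pairwise Jaccard distance matrix over miRNA target sets
#'
#' Computes all pairwise distances from the adjacency matrix's column
#' supports. miRNAs with an empty target column (possible after a strict
#' intersection with the DE universe) are removed with a warning before
#' the computation, since the distance is undefined for empty sets.
#'
#' @param adj A \code{"mirna_adjacency"} matrix from [build_adjacency()].
#' @return A symmetric numeric matrix with zero diagonal, miRNA identifiers
#'   as dimnames, entries in [0, 1].
#' @export
jaccard_matrix <- function(adj) {
  stopifnot(is.matrix(adj))
  m <- unclass(adj)
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " miRNA(s) with no targets: ",
            paste(colnames(m)[empty], collapse = ", "), call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) < 2L) {
    stop("nothing to cluster: fewer than 2 miRNAs with targets",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  inter <- crossprod(m)                       # |ti n tj|
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter      # |ti u tj|
  D <- 1 - inter / un
  diag(D) <- 0
  D
}

#' Hierarchical clustering of miRNAs by target-set distance
#'
#' Agglomerative clustering over a Jaccard distance matrix. Inter-cluster
#' distance is defined by the linkage: \code{complete} (maximum pairwise
#' distance, the default), \code{average} (UPGMA mean), or \code{single}
#' (minimum). When two candidate merges are exactly tied on linkage value,
#' the pair whose concatenated sorted leaf names sort first lexicographically
#' is merged, so the tree is deterministic and independent of input order.
#'
#' @param D Symmetric distance matrix with miRNA identifiers as dimnames
#'   (e.g. from [jaccard_matrix()]); all entries must be finite.
#' @param linkage One of \code{"complete"}, \code{"average"},
#'   \code{"single"}.
#' @return An object of class \code{"hclust"} (so \code{plot()},
#'   \code{stats::cutree()}, \code{ape::as.phylo()} all apply), with
#'   \code{$labels} the miRNA identifiers.
#' @export
cluster_mirnas <- function(D, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 2L) stop("nothing to cluster: need >= 2 miRNAs", call. = FALSE)
  if (any(!is.finite(D))) {
    stop("non-finite entries in distance matrix", call. = FALSE)
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(D)))
  n <- nrow(D)
  # active clusters: id (<0 leaf, >0 merge row), members (leaf indices), size
  work <- matrix(as.numeric(D), n, n)
  ids <- -seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  tie_key <- function(i, j) {
    paste(sort(labels[c(members[[i]], members[[j]])]), collapse = "\r")
  }
  for (step in seq_len(n - 1L)) {
    k <- length(ids)
    dmin <- Inf
    best <- c(NA_integer_, NA_integer_)
    best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        d <- work[i, j]
        if (d < dmin - 1e-12) {
          dmin <- d; best <- c(i, j); best_key <- NULL
        } else if (d <= dmin + 1e-12) {
          if (is.null(best_key)) best_key <- tie_key(best[1L], best[2L])
          key <- tie_key(i, j)
          if (key < best_key) {
            dmin <- min(dmin, d); best <- c(i, j); best_key <- key
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- work[i, j]
    # Lance-Williams update of distances to the merged cluster
    rest <- setdiff(seq_len(k), c(i, j))
    newd <- switch(linkage,
      complete = pmax(work[i, rest], work[j, rest]),
      single   = pmin(work[i, rest], work[j, rest]),
      average  = (sizes[i] * work[i, rest] + sizes[j] * work[j, rest]) /
                 (sizes[i] + sizes[j])
    )
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- step
    work[i, rest] <- newd
    work[rest, i] <- newd
    work <- work[-j, -j, drop = FALSE]
    ids <- ids[-j]; members[j] <- NULL; sizes <- sizes[-j]
  }
  out <- list(merge = merge, height = height,
              order = tree_leaf_order(merge),
              labels = labels, method = linkage,
              dist.method = "jaccard",
              call = match.call())
  class(out) <- "hclust"
  out
}

# Left-to-right leaf traversal of an hclust merge matrix.
tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Export a cluster tree as a Newick string or file
#'
#' Converts the merge tree to a rooted phylogram with branch lengths
#' derived from merge heights (each merge height is split at its midpoint,
#' so two leaves merged at height h sit at depth h/2 each) and writes
#' standard Newick.
#'
#' @param tree An \code{"hclust"} object from [cluster_mirnas()].
#' @param path Optional output file; when \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Write a distance matrix as a square table
#'
#' miRNA identifiers appear as both the header row and the first column.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "csv")) {
  df <- data.frame(mirna = rownames(D), as.data.frame(D),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_output_table(df, path, format)
}
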