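#' Simulate a bipartite miRNA-target network with planted structure
#'
#' Generates a synthetic interaction edge list shaped like the networks the
#' method is built for: optional planted hub genes (targeted by many
#' miRNAs, emulating convergently regulated key genes) and optional planted
#' miRNA clusters (groups sharing a common core of targets, emulating
#' cooperative miRNAs). All sampling is driven by a single integer seed and
#' the global RNG state is left untouched.
#'
#' With \code{n_clusters >= 1}, the miRNAs are split evenly into clusters;
#' each miRNA targets its cluster's shared core (a fraction
#' \code{within_cluster_overlap} of its target budget) plus private genes
#' drawn from a cluster-specific pool, so target sets overlap within a
#' cluster and are disjoint between clusters. With \code{n_clusters = 0},
#' edges are sampled uniformly (Bernoulli at \code{edge_density}) with no
#' planted structure. Every miRNA is guaranteed at least one target.
#'
#' @param n_mirnas,n_genes Numbers of miRNAs and of candidate target genes.
#' @param edge_density Expected fraction of the gene pool each miRNA
#'   targets, in (0, 1].
#' @param n_hub_genes,hub_degree Number of planted hub genes and the number
#'   of distinct miRNAs targeting each; \code{hub_degree} cannot exceed
#'   \code{n_mirnas}. Zero hubs by default.
#' @param n_clusters Number of planted miRNA clusters (0 = uniform network).
#' @param within_cluster_overlap Fraction in [0, 1] of each miRNA's target
#'   budget devoted to its cluster's shared core.
#' @param decoy_frac Fraction of additional never-targeted genes appended to
#'   the DE list, so G exceeds T as in real experiments.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A list with \code{interactions} (an \code{"interaction_table"}),
#'   \code{de_genes} (character), \code{clusters} (named integer vector of
#'   planted memberships, or \code{NULL}), \code{hub_genes} (character) and
#'   \code{spec} (the arguments, for sidecar serialization).
#' @examples
#' net <- simulate_network(n_mirnas = 8, n_genes = 60, n_clusters = 2,
#'                         within_cluster_overlap = 0.9, seed = 42)
#' nrow(net$interactions)
#' @export
simulate_network <- function(n_mirnas = 14, n_genes = 1000,
                             edge_density = 0.25,
                             n_hub_genes = 0, hub_degree = n_mirnas,
                             n_clusters = 0, within_cluster_overlap = 0.5,
                             decoy_frac = 0.3, seed = 1L) {
  stopifnot(n_mirnas >= 1, n_genes >= 1,
            edge_density > 0, edge_density <= 1,
            n_hub_genes >= 0, n_clusters >= 0,
            within_cluster_overlap >= 0, within_cluster_overlap <= 1,
            decoy_frac >= 0)
  if (n_hub_genes > 0 && hub_degree > n_mirnas) {
    stop("infeasible: hub_degree (", hub_degree,
         ") exceeds n_mirnas (", n_mirnas, ")", call. = FALSE)
  }
  if (n_hub_genes + 1 > n_genes) {
    stop("infeasible: more hub genes than genes", call. = FALSE)
  }
  spec <- list(n_mirnas = n_mirnas, n_genes = n_genes,
               edge_density = edge_density, n_hub_genes = n_hub_genes,
               hub_degree = hub_degree, n_clusters = n_clusters,
               within_cluster_overlap = within_cluster_overlap,
               decoy_frac = decoy_frac, seed = seed)
  mirnas <- sprintf("mir-%02d", seq_len(n_mirnas))
  genes <- sprintf("G%04d", seq_len(n_genes))
  edges <- with_local_seed(seed, {
    budget <- max(1L, round(edge_density * n_genes))
    el <- list()
    clusters <- NULL
    if (n_clusters >= 1L) {
      clusters <- rep(seq_len(n_clusters), length.out = n_mirnas)
      names(clusters) <- mirnas
      core_size <- round(within_cluster_overlap * budget)
      pools <- split(sample(genes), rep(seq_len(n_clusters),
                                        length.out = n_genes))
      for (cl in seq_len(n_clusters)) {
        pool <- pools[[cl]]
        core <- pool[seq_len(min(core_size, length(pool)))]
        private_pool <- setdiff(pool, core)
        for (mir in mirnas[clusters == cl]) {
          n_priv <- min(budget - length(core), length(private_pool))
          priv <- if (n_priv > 0) sample(private_pool, n_priv) else character()
          tgts <- c(core, priv)
          if (length(tgts) == 0L) tgts <- sample(pool, 1L)
          el[[mir]] <- tgts
        }
      }
    } else {
      for (mir in mirnas) {
        hit <- genes[stats::runif(n_genes) < edge_density]
        if (length(hit) == 0L) hit <- sample(genes, 1L)
        el[[mir]] <- hit
      }
    }
    hub_genes <- character()
    if (n_hub_genes > 0L) {
      targeted <- unique(unlist(el, use.names = FALSE))
      candidates <- setdiff(genes, targeted)
      if (length(candidates) < n_hub_genes) candidates <- genes
      hub_genes <- sample(candidates, n_hub_genes)
      for (hg in hub_genes) {
        for (mir in sample(mirnas, hub_degree)) {
          el[[mir]] <- union(el[[mir]], hg)
        }
      }
    }
    df <- data.frame(
      mirna = rep(names(el), lengths(el)),
      gene = unlist(el, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    targeted <- unique(df$gene)
    n_decoys <- round(decoy_frac * length(targeted))
    untargeted <- setdiff(genes, targeted)
    if (length(untargeted) < n_decoys) {
      untargeted <- c(untargeted,
                      sprintf("DECOY%04d", seq_len(n_decoys)))
    }
    decoys <- if (n_decoys > 0) sample(untargeted, n_decoys) else character()
    list(df = df, de = c(targeted, decoys), clusters = clusters,
         hub_genes = hub_genes)
  })
  list(interactions = as_interaction_table(edges$df),
       de_genes = sort(edges$de),
       clusters = edges$clusters,
       hub_genes = edges$hub_genes,
       spec = spec)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write a simulated network to disk in the pipeline's input formats
#'
#' Emits the two-column tab-separated edge list, the one-column DE gene
#' list, and a sidecar JSON recording the generator arguments so the
#' artifact is self-describing.
#'
#' @param net A network from [simulate_network()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_network <- function(net, dir, prefix = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    interactions = file.path(dir, paste0(prefix, "_interactions.tsv")),
    de_genes = file.path(dir, paste0(prefix, "_de_genes.txt")),
    spec = file.path(dir, paste0(prefix, "_spec.json"))
  )
  write_interactions(net$interactions, paths[["interactions"]])
  writeLines(net$de_genes, paths[["de_genes"]])
  jsonlite::write_json(net$spec, paths[["spec"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Check whether the pipeline recovers planted network structure
#'
#' Given a simulated network and the map fitted on it, reports (a) whether
#' the planted hub genes occupy the top ranks of the gene-centrality table
#' and (b) whether cutting the cluster tree at the widest gap between
#' consecutive merge heights recovers the planted miRNA partition exactly
#' (up to cluster relabeling).
#'
#' @param net A network from [simulate_network()] with planted structure.
#' @param map A \code{"mirmap"} fitted on \code{net}'s inputs.
#' @return A list: \code{hubs_recovered}, \code{hub_ranks},
#'   \code{clusters_recovered}, \code{k_found}, \code{height_gap}, and
#'   \code{note} (set to \code{"no separation"} when there is no usable gap
#'   or no planted structure, in which case \code{clusters_recovered} is
#'   \code{NA}).
#' @export
recover_planted_structure <- function(net, map) {
  stopifnot(inherits(map, "mirmap"))
  res <- list(hubs_recovered = NA, hub_ranks = integer(),
              clusters_recovered = NA, k_found = NA_integer_,
              height_gap = NA_real_, note = "")
  if (length(net$hub_genes) > 0L) {
    ranks <- match(net$hub_genes, map$gene_centrality$gene)
    res$hub_ranks <- ranks
    res$hubs_recovered <- all(!is.na(ranks)) &&
      all(ranks <= length(net$hub_genes))
  }
  if (!is.null(net$clusters) && length(unique(net$clusters)) >= 2L &&
      !is.null(map$tree)) {
    h <- sort(map$tree$height)
    gaps <- diff(h)
    if (length(gaps) == 0L || max(gaps) < 0.1) {
      res$note <- "no separation"
      return(res)
    }
    g <- which.max(gaps)
    cut_h <- (h[g] + h[g + 1L]) / 2
    found <- stats::cutree(map$tree, h = cut_h)
    res$k_found <- length(unique(found))
    res$height_gap <- max(gaps)
    planted <- net$clusters[names(found)]
    res$clusters_recovered <- identical_partitions(found, planted)
  } else {
    res$note <- "no separation"
  }
  res
}

# TRUE iff two cluster labelings induce the same partition.
identical_partitions <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
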