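#' Build a miRNA-mRNA network map
#'
#' The package's central constructor: from an edge list of predicted
#' miRNA-gene interactions (and an optional universe of differentially
#' expressed genes) it assembles the binary adjacency matrix, per-gene
#' degrees of centrality, the per-miRNA impact table, the pairwise Jaccard
#' distance matrix over target sets, and the hierarchical clustering of
#' miRNAs, in one classed object.
#'
#' The analysis is intended for one sign-stratum per run (e.g. upregulated
#' miRNAs against downregulated genes); run it twice for the two canonical
#' strata of an inverse-correlation design.
#'
#' @param interactions A two-column data frame (miRNA, gene), an
#'   \code{"interaction_table"}, or a file path understood by
#'   [read_interactions()].
#' @param de_genes Optional character vector of DE genes or a file path for
#'   [read_de_genes()]. When absent, G falls back to T (the number of
#'   targeted genes) and the DE-percentage column is flagged as derived.
#' @param mirna_list Optional character vector of all DE miRNAs, so that
#'   miRNAs with no surviving target edge are still reported (with zero
#'   impact) instead of silently disappearing from the outputs.
#' @param policy Intersection policy for genes outside the DE universe:
#'   \code{"warn"} keeps them, \code{"strict"} drops their edges (see
#'   [validate_universe()]).
#' @param linkage Clustering linkage passed to [cluster_mirnas()].
#' @param id_case Identifier case policy (see [read_interactions()]).
#' @return An object of class \code{"mirmap"}: a list with components
#'   \code{interactions}, \code{de_genes}, \code{adjacency}, \code{impact},
#'   \code{gene_centrality}, \code{distance}, \code{tree},
#'   \code{validation}, and \code{params}. If fewer than two miRNAs carry
#'   targets, \code{distance} and \code{tree} are \code{NULL}.
#' @examples
#' net <- simulate_network(n_mirnas = 6, n_genes = 40, seed = 1)
#' m <- mirmap(net$interactions, net$de_genes)
#' m
#' head(impact_table(m))
#' @export
mirmap <- function(interactions, de_genes = NULL, mirna_list = NULL,
                   policy = c("warn", "strict"),
                   linkage = c("complete", "average", "single"),
                   id_case = c("preserve", "upper")) {
  policy <- match.arg(policy)
  linkage <- match.arg(linkage)
  id_case <- match.arg(id_case)
  if (is.character(interactions) && length(interactions) == 1L) {
    interactions <- read_interactions(interactions, id_case = id_case)
  } else {
    interactions <- as_interaction_table(interactions, id_case = id_case)
  }
  if (is.character(de_genes) && length(de_genes) == 1L &&
      file.exists(de_genes)) {
    de_genes <- read_de_genes(de_genes, id_case = id_case)
  }
  if (!is.null(de_genes)) {
    de_genes <- unique(as.character(de_genes))
    if (id_case == "upper") de_genes <- toupper(de_genes)
  }
  val <- validate_universe(interactions, de_genes, policy = policy)
  adj <- build_adjacency(val$interactions)
  imp <- compute_impact(adj, de_genes = de_genes, extra_mirnas = mirna_list)
  D <- NULL
  tree <- NULL
  if (ncol(adj) >= 2L) {
    D <- jaccard_matrix(adj)
    tree <- cluster_mirnas(D, linkage = linkage)
  }
  structure(list(
    interactions = val$interactions,
    de_genes = de_genes,
    adjacency = adj,
    impact = imp,
    gene_centrality = rank_genes_by_centrality(adj),
    distance = D,
    tree = tree,
    validation = val[c("extra_target_genes", "untargeted_de_genes",
                       "n_dropped_edges", "policy")],
    params = list(policy = policy, linkage = linkage, id_case = id_case)
  ), class = "mirmap")
}

#' @export
print.mirmap <- function(x, ...) {
  cat("miRNA-mRNA network map\n")
  cat("  edges:   ", nrow(x$interactions), "\n")
  cat("  miRNAs:  ", ncol(x$adjacency), "\n")
  cat("  genes:   ", nrow(x$adjacency), " targeted (T = ",
      attr(x$impact, "T"), ", G = ", attr(x$impact, "G"),
      if (isTRUE(attr(x$impact, "g_is_fallback"))) ", G fallback = T", ")\n",
      sep = "")
  cat("  linkage: ", x$params$linkage, "\n")
  top <- x$gene_centrality[1L, ]
  cat("  top gene centrality: ", top$gene, " (", top$degree, " miRNAs)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mirmap <- function(object, ...) {
  imp <- object$impact
  out <- list(
    n_edges = nrow(object$interactions),
    n_mirnas = ncol(object$adjacency),
    n_genes = nrow(object$adjacency),
    T = attr(imp, "T"),
    G = attr(imp, "G"),
    g_is_fallback = attr(imp, "g_is_fallback"),
    top_mirnas = utils::head(imp, 5L),
    top_genes = utils::head(object$gene_centrality, 5L),
    zero_impact_mirnas = attr(imp, "zero_impact_mirnas"),
    validation = object$validation
  )
  class(out) <- "summary.mirmap"
  out
}

#' @export
print.summary.mirmap <- function(x, ...) {
  cat("miRNA-mRNA network map:", x$n_edges, "edges,", x$n_mirnas,
      "miRNAs,", x$n_genes, "targeted genes\n")
  cat("T =", x$T, " G =", x$G,
      if (isTRUE(x$g_is_fallback)) "(fallback G = T)\n" else "\n")
  cat("\nTop miRNAs by impact:\n")
  print.data.frame(as.data.frame(x$top_mirnas), row.names = FALSE)
  cat("\nTop genes by degree of centrality:\n")
  print.data.frame(x$top_genes, row.names = FALSE)
  if (length(x$zero_impact_mirnas)) {
    cat("\nmiRNAs with zero impact:",
        paste(x$zero_impact_mirnas, collapse = ", "), "\n")
  }
  if (x$validation$n_dropped_edges > 0L) {
    cat("\nEdges dropped by DE-universe intersection:",
        x$validation$n_dropped_edges, "\n")
  }
  invisible(x)
}

#' Plot method for mirmap objects
#'
#' @param x A \code{"mirmap"} object.
#' @param type Which of the three canonical plots to draw.
#' @param ... Passed on to [plot_impact_barplot()], [plot_dendrogram()] or
#'   [plot_identity()].
#' @return The underlying plot function's value, invisibly.
#' @export
plot.mirmap <- function(x, type = c("barplot", "dendrogram", "identity"),
                        ...) {
  type <- match.arg(type)
  switch(type,
    barplot = plot_impact_barplot(x$impact, ...),
    dendrogram = {
      if (is.null(x$tree)) stop("no cluster tree (fewer than 2 miRNAs)",
                                call. = FALSE)
      plot_dendrogram(x$tree, ...)
    },
    identity = {
      if (is.null(x$tree)) stop("no cluster tree (fewer than 2 miRNAs)",
                                call. = FALSE)
      plot_identity(x$distance, x$tree, ...)
    }
  )
}

#' Accessors for mirmap components
#'
#' @param x A \code{"mirmap"} object.
#' @return \code{adjacency_matrix()} the binary gene-by-miRNA matrix;
#'   \code{impact_table()} the per-miRNA impact table;
#'   \code{jaccard_distances()} the pairwise distance matrix;
#'   \code{cluster_tree()} the \code{"hclust"} tree;
#'   \code{gene_centrality()} the ranked gene-degree table.
#' @name mirmap-accessors
NULL

#' @rdname mirmap-accessors
#' @export
adjacency_matrix <- function(x) { stopifnot(inherits(x, "mirmap")); x$adjacency }

#' @rdname mirmap-accessors
#' @export
impact_table <- function(x) { stopifnot(inherits(x, "mirmap")); x$impact }

#' @rdname mirmap-accessors
#' @export
jaccard_distances <- function(x) { stopifnot(inherits(x, "mirmap")); x$distance }

#' @rdname mirmap-accessors
#' @export
cluster_tree <- function(x) { stopifnot(inherits(x, "mirmap")); x$tree }

#' @rdname mirmap-accessors
#' @export
gene_centrality <- function(x) { stopifnot(inherits(x, "mirmap")); x$gene_centrality }
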