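#' Build the binary gene-by-miRNA adjacency matrix
#'
#' Converts the canonical edge list into a dense binary incidence matrix
#' with genes as rows and miRNAs as columns; cell (g, m) is 1 when miRNA m
#' is predicted to target gene g. The row sums are the genes' degrees of
#' centrality (how many miRNAs converge on each gene) and the column sums
#' are the miRNAs' out-degrees (their target counts, t).
#'
#' Rows are ordered by decreasing degree of centrality, columns by
#' decreasing target count; ties are broken lexicographically by identifier
#' so the layout is deterministic and independent of input edge order.
#'
#' @param interactions An \code{"interaction_table"} data frame (columns
#'   \code{mirna}, \code{gene}) with at least one edge.
#' @return An integer matrix with \code{dimnames} (genes, miRNAs), classed
#'   \code{"mirna_adjacency"}. The gene degree sums are available via
#'   \code{rowSums()}; [rank_genes_by_centrality()] returns them as a table.
#' @examples
#' tab <- as_interaction_table(data.frame(
#'   mirna = c("m1", "m1", "m2"), gene = c("gA", "gB", "gA")))
#' build_adjacency(tab)
#' @export
build_adjacency <- function(interactions) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) == 0L) {
    stop("cannot build adjacency from an empty interaction table",
         call. = FALSE)
  }
  genes <- sort(unique(interactions$gene))
  mirnas <- sort(unique(interactions$mirna))
  m <- matrix(0L, nrow = length(genes), ncol = length(mirnas),
              dimnames = list(genes, mirnas))
  m[cbind(match(interactions$gene, genes),
          match(interactions$mirna, mirnas))] <- 1L
  # presentation order: heavy rows/columns first, names break ties
  rs <- rowSums(m)
  cs <- colSums(m)
  m <- m[order(-rs, genes), order(-cs, mirnas), drop = FALSE]
  class(m) <- c("mirna_adjacency", class(m))
  m
}

#' Rank genes by degree of centrality
#'
#' Orders genes by the number of distinct miRNAs targeting them. The gene at
#' the top of this ranking is the network's most convergently regulated gene
#' and a candidate key gene of the system.
#'
#' @param adj A \code{"mirna_adjacency"} matrix from [build_adjacency()].
#' @return A data frame with columns \code{gene} and \code{degree}, sorted by
#'   decreasing degree, ties broken lexicographically by gene identifier.
#' @export
rank_genes_by_centrality <- function(adj) {
  stopifnot(is.matrix(adj))
  deg <- rowSums(adj)
  ord <- order(-deg, names(deg))
  data.frame(gene = names(deg)[ord], degree = as.integer(deg[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert an adjacency matrix back to an edge list
#'
#' @param adj A \code{"mirna_adjacency"} matrix.
#' @return An \code{"interaction_table"} data frame.
#' @export
adjacency_to_edges <- function(adj) {
  idx <- which(adj == 1L, arr.ind = TRUE)
  as_interaction_table(data.frame(
    mirna = colnames(adj)[idx[, "col"]],
    gene  = rownames(adj)[idx[, "row"]],
    stringsAsFactors = FALSE
  ))
}

#' Write the adjacency matrix with a final "Sums" column
#'
#' The layout mirrors the tabular output users inspect: first column the
#' gene identifier, one 0/1 column per miRNA, and a final \code{Sums}
#' column holding each gene's degree of centrality.
#'
#' @param adj A \code{"mirna_adjacency"} matrix.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_adjacency <- function(adj, path, format = c("tsv", "csv")) {
  df <- data.frame(gene = rownames(adj), as.data.frame(unclass(adj)),
                   Sums = as.integer(rowSums(adj)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_output_table(df, path, format)
}
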