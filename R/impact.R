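#' Per-miRNA impact on the regulated transcriptome
#'
#' For each miRNA m with t predicted targets in the network, two
#' proportions are computed and expressed as percentages:
#' \deqn{100 \cdot t / T}{100 * t / T} the share of all targeted genes that
#' m regulates (T is the number of distinct genes hit by at least one
#' miRNA), and \deqn{100 \cdot t / G}{100 * t / G} the share of the whole
#' DE-gene universe that m regulates (G is the number of DE genes). The
#' first measures the miRNA's centrality within the network; the second its
#' overall impact on the experiment's differential expression. When no DE
#' list is supplied, G falls back to T and the two columns coincide; the
#' returned table is flagged accordingly.
#'
#' @param adj A \code{"mirna_adjacency"} matrix from [build_adjacency()].
#' @param de_genes Optional character vector of DE genes; its length is G.
#' @param extra_mirnas Optional character vector of miRNA identifiers that
#'   carry no surviving edge (e.g. DE miRNAs with no DE target); they are
#'   reported separately with t = 0 rather than inserted into the table.
#' @return A data frame of class \code{"impact_table"} with columns
#'   \code{mirna}, \code{t}, \code{pct_of_targets}, \code{pct_of_de_genes},
#'   sorted by decreasing t (ties by miRNA identifier); percentages are kept
#'   at full precision. Attributes: \code{T}, \code{G}, \code{g_is_fallback}
#'   (TRUE when G defaulted to T), and \code{zero_impact_mirnas}.
#' @examples
#' tab <- as_interaction_table(data.frame(
#'   mirna = c("m1", "m1", "m2"), gene = c("gA", "gB", "gA")))
#' compute_impact(build_adjacency(tab))
#' @export
compute_impact <- function(adj, de_genes = NULL, extra_mirnas = NULL) {
  stopifnot(is.matrix(adj))
  T_total <- sum(rowSums(adj) >= 1L)
  if (T_total == 0L) {
    stop("no targeted genes: adjacency matrix is empty", call. = FALSE)
  }
  g_is_fallback <- is.null(de_genes)
  G_total <- if (g_is_fallback) T_total else length(unique(as.character(de_genes)))
  t <- colSums(adj)
  ord <- order(-t, colnames(adj))
  res <- data.frame(
    mirna = colnames(adj)[ord],
    t = as.integer(t[ord]),
    pct_of_targets = 100 * t[ord] / T_total,
    pct_of_de_genes = 100 * t[ord] / G_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  zero <- sort(setdiff(as.character(extra_mirnas), res$mirna))
  class(res) <- c("impact_table", "data.frame")
  attr(res, "T") <- as.integer(T_total)
  attr(res, "G") <- as.integer(G_total)
  attr(res, "g_is_fallback") <- g_is_fallback
  attr(res, "zero_impact_mirnas") <- zero
  res
}

#' Format an impact table for display
#'
#' Rounds the percentage columns to a fixed number of decimals (round half
#' to even, as in base \code{round()}) for printing or writing; the
#' underlying table keeps full precision.
#'
#' @param impact An \code{"impact_table"} from [compute_impact()].
#' @param decimals Number of decimal places (default 1, matching the usual
#'   tabular rendering).
#' @return A data frame with columns \code{miRNA},
#'   \code{Predicted_Genes_Found}, \code{Percentage_of_Targets},
#'   \code{Percentage_of_DE_Genes}; percentages are formatted strings.
#' @export
render_impact_table <- function(impact, decimals = 1L) {
  stopifnot(inherits(impact, "impact_table"))
  fmt <- function(x) {
    formatC(round(x, decimals), format = "f", digits = decimals)
  }
  data.frame(
    miRNA = impact$mirna,
    Predicted_Genes_Found = impact$t,
    Percentage_of_Targets = fmt(impact$pct_of_targets),
    Percentage_of_DE_Genes = fmt(impact$pct_of_de_genes),
    stringsAsFactors = FALSE
  )
}

#' Write the impact table
#'
#' @inheritParams render_impact_table
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_impact <- function(impact, path, format = c("tsv", "csv"),
                         decimals = 1L) {
  df <- render_impact_table(impact, decimals)
  if (isTRUE(attr(impact, "g_is_fallback"))) {
    names(df)[names(df) == "Percentage_of_DE_Genes"] <-
      "Percentage_of_DE_Genes(derived:G=T)"
  }
  write_output_table(df, path, format)
}

#' @export
print.impact_table <- function(x, decimals = 1L, ...) {
  cat("miRNA impact table: T =", attr(x, "T"), "targeted genes, G =",
      attr(x, "G"),
      if (isTRUE(attr(x, "g_is_fallback"))) "DE genes (fallback G = T)\n"
      else "DE genes\n")
  print.data.frame(render_impact_table(x, decimals), row.names = FALSE, ...)
  zi <- attr(x, "zero_impact_mirnas")
  if (length(zi)) {
    cat("miRNAs with no impact (t = 0):", paste(zi, collapse = ", "), "\n")
  }
  invisible(x)
}
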