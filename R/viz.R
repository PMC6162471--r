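#' Open a graphics device for a plot file
#'
#' @param path Output file.
#' @param format One of \code{"png"}, \code{"svg"}, \code{"pdf"}.
#' @param width,height Device size in inches.
#' @param dpi Resolution for raster output.
#' @noRd
open_plot_device <- function(path, format = c("pdf", "png", "svg"),
                             width = 9, height = 6, dpi = 150) {
  format <- match.arg(format)
  switch(format,
    pdf = grDevices::pdf(path, width = width, height = height),
    png = grDevices::png(path, width = width * dpi, height = height * dpi,
                         res = dpi),
    svg = grDevices::svg(path, width = width, height = height)
  )
}

#' Barplot of per-miRNA impact
#'
#' Grouped bars per miRNA, ordered from the largest to the smallest number
#' of impacted genes: the percentage of all targeted genes in red, the
#' percentage of all DE genes in blue.
#'
#' @param impact An \code{"impact_table"} from [compute_impact()].
#' @param path Optional output file; when \code{NULL}, draws on the current
#'   device.
#' @param format Output format, \code{"pdf"}, \code{"png"} or \code{"svg"}.
#' @param width,height,dpi Device geometry.
#' @return The output path (or \code{NULL} when drawn on screen), invisibly.
#' @export
plot_impact_barplot <- function(impact, path = NULL,
                                format = c("pdf", "png", "svg"),
                                width = 9, height = 6, dpi = 150) {
  stopifnot(inherits(impact, "impact_table"), nrow(impact) >= 1L)
  if (!is.null(path)) {
    open_plot_device(path, format, width, height, dpi)
    on.exit(grDevices::dev.off())
  }
  h <- t(as.matrix(impact[, c("pct_of_targets", "pct_of_de_genes")]))
  colnames(h) <- impact$mirna
  op <- graphics::par(mar = c(9, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::barplot(h, beside = TRUE, col = c("red", "blue"),
                    las = 2, ylab = "Impacted genes (%)",
                    main = "miRNA impact on gene expression",
                    cex.names = 0.8)
  graphics::legend("topright", fill = c("red", "blue"), bty = "n",
                   legend = c("% of targeted genes", "% of DE genes"))
  invisible(path)
}

#' Dendrogram of miRNA target-set similarity
#'
#' @param tree An \code{"hclust"} object from [cluster_mirnas()].
#' @inheritParams plot_impact_barplot
#' @return The output path, invisibly.
#' @export
plot_dendrogram <- function(tree, path = NULL,
                            format = c("pdf", "png", "svg"),
                            width = 9, height = 6, dpi = 150) {
  stopifnot(inherits(tree, "hclust"))
  if (!is.null(path)) {
    open_plot_device(path, format, width, height, dpi)
    on.exit(grDevices::dev.off())
  }
  plot(stats::as.dendrogram(tree), ylab = "Jaccard distance",
       main = "miRNA clustering by shared targets")
  invisible(path)
}

#' Identity heatmap of miRNA similarity
#'
#' Renders Jaccard similarity (1 - distance), so the diagonal is identically
#' 1, with rows and columns ordered by the cluster tree's leaf order. The
#' distance matrix itself is what the pipeline writes to disk; the heatmap
#' shows similarity because "identity" reads most naturally as 1 on the
#' diagonal.
#'
#' @param D Symmetric Jaccard distance matrix (see [jaccard_matrix()]).
#' @param tree An \code{"hclust"} over exactly the same miRNA set.
#' @inheritParams plot_impact_barplot
#' @return The output path, invisibly.
#' @export
plot_identity <- function(D, tree, path = NULL,
                          format = c("pdf", "png", "svg"),
                          width = 8, height = 8, dpi = 150) {
  stopifnot(is.matrix(D), inherits(tree, "hclust"))
  if (!setequal(rownames(D), tree$labels)) {
    stop("distance matrix and cluster tree cover different miRNA sets",
         call. = FALSE)
  }
  if (!is.null(path)) {
    open_plot_device(path, format, width, height, dpi)
    on.exit(grDevices::dev.off())
  }
  ord <- tree$labels[tree$order]
  S <- 1 - D[ord, ord]
  n <- nrow(S)
  op <- graphics::par(mar = c(8, 8, 3, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  pal <- grDevices::colorRampPalette(c("white", "steelblue", "darkblue"))(64)
  # image() draws row 1 at the bottom; flip so the heatmap reads top-down
  graphics::image(seq_len(n), seq_len(n), t(S[n:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "",
                  main = "miRNA identity (Jaccard similarity)")
  graphics::axis(1, at = seq_len(n), labels = ord, las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(ord), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(path)
}
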