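#' Run the full analysis and write all outputs
#'
#' One-call orchestration: reads the two input files, fits the network map,
#' and writes the five canonical outputs (adjacency matrix, impact table,
#' impact barplot, identity heatmap, dendrogram) plus the distance matrix,
#' the Newick tree, and a JSON manifest recording input digests, parameters
#' and the key counts (edges, T, G).
#'
#' @param interactions Path to the two-column edge-list file.
#' @param de_genes Optional path to the one-column DE gene list.
#' @param out_dir Output directory, created if absent.
#' @param prefix Filename prefix for every output.
#' @param policy,linkage,id_case,mirna_list Passed to [mirmap()].
#' @param decimals Display decimals for the written impact table.
#' @param plot_format \code{"pdf"}, \code{"png"} or \code{"svg"}.
#' @param table_format \code{"tsv"} or \code{"csv"}.
#' @param force Overwrite existing output files; without it an existing
#'   output aborts the run.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_mirmap <- function(interactions, de_genes = NULL, out_dir = ".",
                       prefix = "mirmap",
                       policy = c("warn", "strict"),
                       linkage = c("complete", "average", "single"),
                       id_case = c("preserve", "upper"),
                       mirna_list = NULL, decimals = 1L,
                       plot_format = c("pdf", "png", "svg"),
                       table_format = c("tsv", "csv"),
                       force = FALSE, quiet = FALSE) {
  plot_format <- match.arg(plot_format)
  table_format <- match.arg(table_format)
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ext <- table_format
  paths <- c(
    adjacency = paste0(prefix, "_adjacency.", ext),
    impact = paste0(prefix, "_impact.", ext),
    barplot = paste0(prefix, "_barplot.", plot_format),
    identity = paste0(prefix, "_identity.", plot_format),
    dendrogram = paste0(prefix, "_dendrogram.", plot_format),
    distance = paste0(prefix, "_distance.", ext),
    tree = paste0(prefix, "_tree.nwk"),
    manifest = paste0(prefix, "_manifest.json")
  )
  paths <- vapply(paths, function(p) file.path(out_dir, p), "")
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force) {
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  say("reading inputs")
  map <- mirmap(interactions, de_genes = de_genes, mirna_list = mirna_list,
                policy = policy, linkage = linkage, id_case = id_case)
  say("writing adjacency matrix (", nrow(map$adjacency), " genes x ",
      ncol(map$adjacency), " miRNAs)")
  write_adjacency(map$adjacency, paths[["adjacency"]], table_format)
  write_impact(map$impact, paths[["impact"]], table_format, decimals)
  say("writing plots")
  plot_impact_barplot(map$impact, paths[["barplot"]], plot_format)
  if (is.null(map$tree)) {
    stop("nothing to cluster: fewer than 2 miRNAs with targets",
         call. = FALSE)
  }
  plot_identity(map$distance, map$tree, paths[["identity"]], plot_format)
  plot_dendrogram(map$tree, paths[["dendrogram"]], plot_format)
  write_distance_matrix(map$distance, paths[["distance"]], table_format)
  export_newick(map$tree, paths[["tree"]])
  digests <- tools::md5sum(c(interactions,
                             if (!is.null(de_genes) &&
                                 is.character(de_genes) &&
                                 length(de_genes) == 1L &&
                                 file.exists(de_genes)) de_genes))
  manifest <- list(
    inputs = as.list(digests),
    parameters = list(policy = map$params$policy,
                      linkage = map$params$linkage,
                      id_case = map$params$id_case,
                      decimals = decimals,
                      plot_format = plot_format),
    counts = list(n_edges = nrow(map$interactions),
                  n_mirnas = ncol(map$adjacency),
                  n_genes_targeted = nrow(map$adjacency),
                  T = attr(map$impact, "T"),
                  G = attr(map$impact, "G"),
                  g_is_fallback = attr(map$impact, "g_is_fallback")),
    warnings = list(
      dropped_edges = map$validation$n_dropped_edges,
      extra_target_genes = map$validation$extra_target_genes,
      zero_impact_mirnas = attr(map$impact, "zero_impact_mirnas")),
    leaf_order = map$tree$labels[map$tree$order],
    outputs = as.list(basename(paths))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  say("done: ", length(paths), " files in ", out_dir)
  invisible(manifest)
}
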