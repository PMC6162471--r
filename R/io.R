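#' Read a miRNA-gene interaction edge list
#'
#' Reads a headerless, delimited text file with one miRNA-gene pair per row
#' (miRNA identifier in the first column, gene identifier in the second).
#' Blank lines are skipped, surrounding whitespace is trimmed, and duplicate
#' pairs are collapsed so that the edge set is binary; the number of
#' duplicates removed is reported as a message.
#'
#' @param path Path to the edge-list file.
#' @param id_case Identifier case policy: \code{"preserve"} keeps identifiers
#'   as written (HUGO gene symbols are conventionally case-sensitive);
#'   \code{"upper"} upper-cases everything, useful for messy inputs.
#' @param delimiter Field delimiter, tab by default.
#' @return A data frame of class \code{"interaction_table"} with character
#'   columns \code{mirna} and \code{gene}, one row per unique edge in
#'   first-seen order. The source path is kept in attribute \code{"source"}.
#' @seealso [read_de_genes()], [as_interaction_table()]
#' @examples
#' tf <- tempfile()
#' writeLines(c("hsa-miR-107\tN4BP1", "hsa-let-7e-5p\tFNDC3A"), tf)
#' read_interactions(tf)
#' @export
read_interactions <- function(path, id_case = c("preserve", "upper"),
                              delimiter = "\t") {
  id_case <- match.arg(id_case)
  if (!file.exists(path)) {
    stop("interaction file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0L) {
    stop("no interactions: file '", path, "' is empty", call. = FALSE)
  }
  fields <- strsplit(lines[keep], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- keep[which(nf < 2L)[1L]]
    stop("line ", bad, " of '", path, "' has fewer than 2 fields",
         call. = FALSE)
  }
  if (any(nf > 2L)) {
    warning(sum(nf > 2L), " line(s) with more than 2 fields; extra fields ignored",
            call. = FALSE)
  }
  edges <- data.frame(
    mirna = trimws(vapply(fields, `[[`, "", 1L)),
    gene  = trimws(vapply(fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  out <- as_interaction_table(edges, id_case = id_case)
  attr(out, "source") <- path
  out
}

#' Canonicalize an edge data frame into an interaction table
#'
#' Applies the identifier case policy, rejects empty identifiers and
#' collapses duplicate (miRNA, gene) pairs, preserving first-seen order.
#'
#' @param edges A two-column data frame (miRNA, gene) or anything coercible.
#' @inheritParams read_interactions
#' @return An \code{"interaction_table"} data frame (columns \code{mirna},
#'   \code{gene}).
#' @export
as_interaction_table <- function(edges, id_case = c("preserve", "upper")) {
  id_case <- match.arg(id_case)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns", call. = FALSE)
  edges <- data.frame(mirna = trimws(as.character(edges[[1L]])),
                      gene  = trimws(as.character(edges[[2L]])),
                      stringsAsFactors = FALSE)
  if (id_case == "upper") {
    edges$mirna <- toupper(edges$mirna)
    edges$gene <- toupper(edges$gene)
  }
  if (any(!nzchar(edges$mirna)) || any(!nzchar(edges$gene))) {
    stop("empty miRNA or gene identifier in interaction table", call. = FALSE)
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    message(sum(dup), " duplicate interaction(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  class(edges) <- c("interaction_table", "data.frame")
  edges
}

#' Read a list of differentially expressed genes
#'
#' Reads a one-column, headerless text file with one gene symbol per line.
#' This is the optional second input: it defines G, the size of the DE-gene
#' universe against which per-miRNA impact is expressed.
#'
#' @inheritParams read_interactions
#' @return A character vector of unique gene identifiers, classed
#'   \code{"de_gene_list"}; \code{length()} of the result is G.
#' @examples
#' tf <- tempfile()
#' writeLines(c("IFI16", "COL5A2", "GJA1"), tf)
#' read_de_genes(tf)
#' @export
read_de_genes <- function(path, id_case = c("preserve", "upper")) {
  id_case <- match.arg(id_case)
  if (!file.exists(path)) {
    stop("DE gene list not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  genes <- lines[nzchar(lines)]
  if (length(genes) == 0L) {
    stop("empty DE gene list: ", path, call. = FALSE)
  }
  if (id_case == "upper") genes <- toupper(genes)
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)), " duplicate DE gene(s) collapsed",
            call. = FALSE)
    genes <- unique(genes)
  }
  class(genes) <- "de_gene_list"
  genes
}

#' Reconcile the interaction table against the DE gene universe
#'
#' Target genes are expected to be a subset of the DE genes (interaction
#' lists pulled straight from prediction repositories must be intersected
#' with the experiment's DE genes). This reports genes on either side of
#' that intersection and, under \code{policy = "strict"}, drops edges whose
#' target gene is absent from the DE list.
#'
#' @param interactions An \code{"interaction_table"} (see
#'   [read_interactions()]).
#' @param de_genes Character vector of DE genes, or \code{NULL} to skip the
#'   check (everything is then kept).
#' @param policy \code{"strict"} drops out-of-universe edges (the
#'   intersection rule); \code{"warn"} keeps them but flags the genes.
#' @return A list with elements \code{interactions} (the possibly filtered
#'   table), \code{extra_target_genes} (targets absent from the DE list),
#'   \code{untargeted_de_genes} (DE genes never targeted),
#'   \code{n_dropped_edges} and \code{policy}.
#' @export
validate_universe <- function(interactions, de_genes = NULL,
                              policy = c("warn", "strict")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(interactions))
  if (is.null(de_genes)) {
    return(list(interactions = interactions, extra_target_genes = character(),
                untargeted_de_genes = character(), n_dropped_edges = 0L,
                policy = policy))
  }
  de_genes <- as.character(de_genes)
  outside <- !(interactions$gene %in% de_genes)
  extra <- unique(interactions$gene[outside])
  untargeted <- setdiff(de_genes, interactions$gene)
  dropped <- 0L
  if (policy == "strict" && any(outside)) {
    dropped <- sum(outside)
    warning("dropping ", dropped, " edge(s) to ", length(extra),
            " gene(s) outside the DE universe", call. = FALSE)
    interactions <- interactions[!outside, , drop = FALSE]
    rownames(interactions) <- NULL
    if (nrow(interactions) == 0L) {
      stop("no edges survive the DE-universe intersection", call. = FALSE)
    }
  } else if (any(outside)) {
    warning(length(extra), " target gene(s) absent from the DE list (kept; ",
            "use policy = \"strict\" to drop them)", call. = FALSE)
  }
  list(interactions = interactions, extra_target_genes = extra,
       untargeted_de_genes = untargeted, n_dropped_edges = dropped,
       policy = policy)
}

#' Write an interaction table back to disk
#'
#' Inverse of [read_interactions()]: headerless, two columns, tab-separated.
#'
#' @inheritParams validate_universe
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_interactions <- function(interactions, path, delimiter = "\t") {
  utils::write.table(interactions[, c("mirna", "gene")], path,
                     sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared writer for output tables: TSV (default) or CSV, always with header.
write_output_table <- function(df, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
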