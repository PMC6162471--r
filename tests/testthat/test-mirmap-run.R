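make_inputs <- function(dir = tempfile(), seed = 4) {
  net <- simulate_network(n_mirnas = 6, n_genes = 40, edge_density = 0.25,
                          n_clusters = 2, within_cluster_overlap = 0.7,
                          decoy_frac = 0.2, seed = seed)
  paths <- write_network(net, dir)
  list(net = net, paths = paths, dir = dir)
}

test_that("mirmap assembles a coherent object from files or frames", {
  x <- make_inputs()
  m <- mirmap(x$paths[["interactions"]], x$paths[["de_genes"]])
  expect_s3_class(m, "mirmap")
  expect_identical(sort(colnames(m$adjacency)), sort(unique(m$interactions$mirna)))
  expect_equal(attr(m$impact, "T"), nrow(m$adjacency))
  expect_equal(sum(m$impact$t), sum(m$adjacency))
  expect_setequal(rownames(m$distance), colnames(m$adjacency))
  expect_setequal(m$tree$labels, colnames(m$adjacency))
  # same result from in-memory inputs
  m2 <- mirmap(x$net$interactions, x$net$de_genes)
  expect_equal(m2$impact, m$impact)
  expect_output(print(m), "miRNA-mRNA network map")
  expect_output(print(summary(m)), "Top miRNAs by impact")
})

test_that("plot methods write non-empty files in each supported format", {
  x <- make_inputs()
  m <- mirmap(x$net$interactions, x$net$de_genes)
  for (type in c("barplot", "dendrogram", "identity")) {
    tf <- tempfile(fileext = ".pdf")
    plot(m, type = type, path = tf, format = "pdf")
    expect_true(file.exists(tf))
    expect_gt(file.size(tf), 0)
  }
  tf <- tempfile(fileext = ".svg")
  plot_impact_barplot(m$impact, tf, format = "svg")
  expect_gt(file.size(tf), 0)
  # single-miRNA impact table still plots
  one <- m$impact[1, , drop = FALSE]
  class(one) <- class(m$impact)
  tf1 <- tempfile(fileext = ".pdf")
  plot_impact_barplot(one, tf1)
  expect_gt(file.size(tf1), 0)
  # mismatched miRNA sets are rejected
  expect_error(plot_identity(m$distance[-1, -1], m$tree,
                             tempfile(fileext = ".pdf")),
               "different miRNA sets")
})

test_that("run_mirmap writes the full output set with a faithful manifest", {
  x <- make_inputs()
  out <- tempfile()
  manifest <- run_mirmap(x$paths[["interactions"]], x$paths[["de_genes"]],
                         out_dir = out, quiet = TRUE)
  files <- list.files(out)
  expect_length(files, 8)
  expect_setequal(tools::file_ext(files),
                  c("tsv", "pdf", "nwk", "json"))
  # manifest counts agree with the written tables
  imp <- read.delim(file.path(out, "mirmap_impact.tsv"))
  expect_equal(manifest$counts$n_mirnas, nrow(imp))
  adj <- read.delim(file.path(out, "mirmap_adjacency.tsv"),
                    check.names = FALSE)
  expect_equal(manifest$counts$T, nrow(adj))
  expect_equal(manifest$counts$n_edges, sum(adj$Sums))
  expect_equal(manifest$counts$G, length(x$net$de_genes))
  on_disk <- jsonlite::read_json(file.path(out, "mirmap_manifest.json"))
  expect_equal(on_disk$counts$n_edges, manifest$counts$n_edges)

  # a second run without force refuses to overwrite
  expect_error(run_mirmap(x$paths[["interactions"]], x$paths[["de_genes"]],
                          out_dir = out, quiet = TRUE),
               "already exist")

  # rerunning with force reproduces tabular outputs byte for byte
  before <- tools::md5sum(file.path(out, c("mirmap_adjacency.tsv",
                                           "mirmap_impact.tsv",
                                           "mirmap_distance.tsv",
                                           "mirmap_tree.nwk")))
  run_mirmap(x$paths[["interactions"]], x$paths[["de_genes"]],
             out_dir = out, force = TRUE, quiet = TRUE)
  after <- tools::md5sum(names(before))
  expect_identical(before, after)
})

test_that("strict policy aborts cleanly when the DE universe kills all edges", {
  dir <- tempfile(); dir.create(dir)
  ints <- file.path(dir, "edges.tsv")
  writeLines(c("m1\tgA", "m2\tgB"), ints)
  de <- file.path(dir, "de.txt")
  writeLines("unrelated_gene", de)
  out <- file.path(dir, "out")
  expect_error(
    suppressWarnings(run_mirmap(ints, de, out_dir = out, policy = "strict",
                                quiet = TRUE)),
    "no edges survive")
  # no partial plot outputs left behind
  expect_false(any(grepl("pdf$", list.files(out))))
})
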