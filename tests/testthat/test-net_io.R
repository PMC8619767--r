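write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("edge tables parse, collapse duplicates, and convert dialects", {
  f <- write_lines_tmp(c("A\tB\t0.5", "B\tC\t0.7", "C\tD\t0.9"))
  net <- read_edge_table(f, dialect = "unit")
  expect_equal(n_edges(net), 3)
  expect_equal(net$edges$confidence, c(0.5, 0.7, 0.9))

  # duplicate unordered pair keeps the max confidence
  f <- write_lines_tmp(c("A\tB\t0.5", "B\tA\t0.7"))
  net <- read_edge_table(f, dialect = "unit")
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$confidence, 0.7)

  # STRING dialect: 0-1000 scores divided by 1000
  f <- write_lines_tmp("ALB VWF 400")
  net <- read_edge_table(f, dialect = "string1000")
  expect_equal(net$edges$confidence, 0.400)
  expect_setequal(net$nodes, c("ALB", "VWF"))

  # header auto-detected by non-numeric third field
  f <- write_lines_tmp(c("node_a\tnode_b\tscore", "A\tB\t0.5"))
  expect_equal(n_edges(read_edge_table(f, "unit")), 1)
})

test_that("edge-table validation rejects malformed and out-of-range rows", {
  f <- write_lines_tmp(c("A\tB\t0.5", "A\tB"))
  expect_error(read_edge_table(f, "unit"), "line 2")
  f <- write_lines_tmp(c("A\tB\t0.5", "B\tC\tnope"))
  expect_error(read_edge_table(f, "unit"), "line 2.*non-numeric")
  f <- write_lines_tmp("A\tB\t1.5")
  expect_error(read_edge_table(f, "unit"), "\\[0, 1\\]")
  f <- write_lines_tmp("A\tB\t1500")
  expect_error(read_edge_table(f, "string1000"), "\\[0, 1000\\]")
  f <- write_lines_tmp(c("A\tA\t0.5", "A\tB\t0.6"))
  expect_warning(net <- read_edge_table(f, "unit"), "self-loop")
  expect_equal(n_edges(net), 1)
})

test_that("GMT collections parse and validate", {
  f <- write_lines_tmp(c("T1\tfirst term\tA\tB\tC", "T2\tsecond term\tb\tD"))
  coll <- read_gmt(f, universe_size = 100)
  expect_length(coll$terms, 2)
  expect_equal(coll$terms$T2$genes, c("B", "D"))  # case-normalized
  expect_equal(coll$universe_size, 100L)

  f <- write_lines_tmp(c("T1\tx\tA", "T1\ty\tB"))
  expect_error(read_gmt(f, 10), "duplicate term_id: T1")
  f <- write_lines_tmp("T1\tonly-description")
  expect_error(read_gmt(f, 10), "line 1")
  f <- write_lines_tmp(character(0))
  expect_warning(coll <- read_gmt(f, 10), "empty")
  expect_length(coll$terms, 0)
  f <- write_lines_tmp("T1\tx\tA\tB\tC")
  expect_error(read_gmt(f, 2), "universe_size")
})

test_that("seed lists normalize, deduplicate, and apply aliases", {
  dep <- read_seed_list(system.file("extdata", "seeds_dep15.txt",
                                    package = "seednet"))
  expect_length(dep$members, 15)
  expect_true(all(c("SERPINC1", "VWF", "IL6", "SELE") %in% dep$members))

  f <- write_lines_tmp(c("ALB", "alb  ", "# comment", ""))
  expect_warning(s <- read_seed_list(f), "duplicate")
  expect_equal(s$members, "ALB")

  expect_error(read_seed_list(write_lines_tmp(c("# nothing", ""))), "no identifiers")
})

test_that("the combined DEP+gene fixture merges to 24 members via the alias table", {
  aliases <- system.file("extdata", "id_aliases.tsv", package = "seednet")
  combined <- suppressWarnings(read_seed_list(
    system.file("extdata", "seeds_dep_gene.txt", package = "seednet"),
    aliases = aliases))
  expect_length(combined$members, 24)
  expect_true("FGB" %in% combined$members)
  expect_false("FBG" %in% combined$members)
})

test_that("reports round-trip losslessly", {
  net <- pn(rbind(c("A", "B"), c("B", "C"), c("A", "C")), c(0.5, 0.6, 0.7))
  topo <- topology_report(net)
  f <- tempfile(fileext = ".json")
  write_report(topo, f, "json")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$density, topo$density)
  expect_equal(back$char_path_length, topo$char_path_length)
  expect_equal(back$degree$B, 2)

  cl <- make_clustering(c(A = 1L, B = 1L, C = 2L))
  f <- tempfile(fileext = ".tsv")
  write_report(cl, f, "tsv")
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(tab$node, c("A", "B", "C"))
  expect_equal(tab$cluster_id, c(1, 1, 2))

  # GMT write -> read is the identity
  coll <- gene_set_collection(
    list(list(term_id = "T1", description = "d1", genes = c("A", "B", "C")),
         list(term_id = "T2", description = "d2", genes = c("B", "D"))),
    universe_size = 50)
  f <- tempfile(fileext = ".gmt")
  write_gmt(coll, f)
  again <- read_gmt(f, universe_size = 50)
  expect_equal(lapply(again$terms, `[[`, "genes"),
               lapply(coll$terms, `[[`, "genes"))
})

test_that("enrichment tables are written sorted by p ascending", {
  coll <- gene_set_collection(
    list(list(term_id = "BROAD", description = "d", genes = sprintf("G%02d", 1:40)),
         list(term_id = "TIGHT", description = "d", genes = sprintf("G%02d", 1:5))),
    universe_size = 100)
  res <- ora(sprintf("G%02d", 1:5), coll, min_overlap = 3)
  f <- tempfile(fileext = ".tsv")
  write_report(res, f, "tsv")
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_false(is.unsorted(tab$p))
})
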