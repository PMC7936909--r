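test_that("packaged reference tables have the printed shapes and contents", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 81)
  expect_equal(sum(t1$whitelisted), 11)
  expect_equal(sum(is.na(t1$ob) & is.na(t1$dl)), 10)
  expect_true(all(is.na(t1$ob) == (t1$source == "animal_db")))
  expect_true(all(t1$herbs != ""))
  expect_true(all(is.na(t1$dl) | (t1$dl >= 0 & t1$dl <= 1)))

  t2 <- load_fixture("table2")
  expect_equal(nrow(t2), 74)
  expect_equal(sum(t2$herb != "Target"), 35)
  expect_equal(sum(t2$herb == "Target"), 39)
  # scientific notation in the printed betweenness column parses as numeric
  expect_equal(t2$betweenness[t2$node == "8-Debenzoylpaeonidanin"], 1.33e-2)

  expect_equal(nrow(load_fixture("table3")), 3)
  expect_equal(nrow(load_fixture("table4")), 33)

  t5 <- load_fixture("table5")
  expect_equal(sum(t5$kind == "hc" & t5$node1 == "CS"), 20)
  expect_equal(sum(t5$kind == "hc" & t5$node1 == "DaH"), 10)
  expect_equal(sum(t5$kind == "ct" & t5$node2 == "PTAFR"), 14)
  expect_equal(sum(t5$kind == "ct" & t5$node2 == "CASP3"), 8)

  v14 <- load_fixture("verified14")
  expect_setequal(v14, c("PTEN", "CTH", "PTGS2", "PTAFR", "FOS", "NOS1",
                         "NOS2", "PGR", "MMP3", "PON1", "NEDD4", "ACADSB",
                         "KL", "CASP3"))
  expect_length(load_fixture("mapk11"), 11)
  expect_error(load_fixture("table9"))
})

test_that("tabular readers canonicalize, preserve order, and flag schema errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "cpd1\tptafr", "cpd2\t Casp3 ", "cpd1\tPTAFR"), tmp)
  ed <- read_edge_table(tmp, kind = "compound_target")
  expect_equal(ed$target, c("PTAFR", "CASP3"))  # uppercased, deduplicated
  expect_equal(ed$source, c("cpd1", "cpd2"))    # compound case preserved

  writeLines("source\ttarget", tmp)
  expect_equal(nrow(read_edge_table(tmp, "ppi")), 0)

  writeLines(c("source\tweight", "a\t1"), tmp)
  expect_error(read_edge_table(tmp, "ppi"), "target")

  writeLines(c("source\ttarget\tweight", "a\tb\toops"), tmp)
  expect_error(read_edge_table(tmp, "ppi"), "row 1")
})

test_that("edge canonicalization drops self-edges, is idempotent, and treats PPI pairs as unordered", {
  ed <- data.frame(source = c("B", "A", "A", "A"),
                   target = c("A", "B", "A", "C"),
                   kind = "ppi", stringsAsFactors = FALSE)
  out <- canonicalize_edges(ed)
  expect_equal(nrow(out), 2)  # B-A == A-B, self-edge dropped
  expect_identical(canonicalize_edges(out), out)
  expect_identical(canonicalize_symbols(canonicalize_symbols(" ptafr ")),
                   canonicalize_symbols(" ptafr "))
})

test_that("network writers round-trip nodes, edges and attributes", {
  path3 <- layered_graph(
    data.frame(id = c("a", "b", "c"), layer = c("compound", "target", "target")),
    data.frame(from = c("a", "b"), to = c("b", "c"), kind = c("ct", "ppi"))
  )
  ed <- fixture_hctp_edges()
  hctp <- assemble_hctp(ed$hc, ed$ct, ed$tp, load_fixture("verified14"),
                        c("MAPK signaling pathway", "Calcium signaling pathway"))
  empty <- layered_graph(data.frame(id = character(), layer = character()),
                         data.frame(from = character(), to = character(),
                                    kind = character()))
  graph_fingerprint <- function(g) {
    nodes <- data.frame(id = igraph::V(g)$name, layer = igraph::V(g)$layer)
    nodes <- nodes[order(nodes$id), ]
    e <- igraph::as_data_frame(g, "edges")
    if (!"kind" %in% names(e)) e$kind <- character(nrow(e))
    e <- e[, c("from", "to", "kind")]
    a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
    e <- data.frame(a = a, b = b, kind = e$kind)
    e <- e[order(e$a, e$b, e$kind), ]
    list(nodes = nodes, edges = e)
  }
  for (g in list(path3, hctp, empty)) {
    for (fmt in c("sif", "graphml", "json")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_network(g, f, fmt)
      back <- read_network(f, fmt)
      expect_equal(graph_fingerprint(back), graph_fingerprint(g),
                   ignore_attr = TRUE)
    }
  }
  # SIF encodes one interaction line per edge
  f <- withr::local_tempfile(fileext = ".sif")
  write_network(path3, f, "sif")
  expect_length(readLines(f), 2)
  expect_error(write_network(path3, f, "dot"))
})

test_that("GMT reading/writing round-trips and validates", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("hsa04010\tMAPK signaling pathway\tFOS\tcasp3\tFOS",
               "hsa04020\tCalcium signaling pathway\tPTAFR\tNOS1"), f)
  sets <- read_gmt(f)
  expect_equal(sets$hsa04010$genes, c("FOS", "CASP3"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  expect_identical(read_gmt(f2), sets)
  writeLines("broken\tonly-two-fields", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("count matrices read, validate groups, and reject bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "actb\t10\t20", "GAPDH\t0\t5"), f)
  cm <- read_count_matrix(f, groups = c(s1 = "A", s2 = "B"))
  expect_equal(rownames(cm$counts), c("ACTB", "GAPDH"))
  expect_equal(unname(cm$groups), c("A", "B"))
  writeLines(c("gene\ts1", "a\t-1"), f)
  expect_error(read_count_matrix(f), "non-negative")
  writeLines(c("gene\ts1", "a\tx"), f)
  expect_error(read_count_matrix(f), "s1")
})
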