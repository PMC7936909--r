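test_that("hypergeometric upper tail matches exhaustive draw enumeration", {
  expect_equal(hypergeom_upper(0, 3, 3, 10), 1)
  expect_equal(hypergeom_upper(2, 3, 3, 10), 11 / 60, tolerance = 1e-12)
  expect_equal(hypergeom_upper(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)

  # full grid over small universes
  for (N in c(6, 9, 12)) {
    for (K in c(2, floor(N / 2), N - 1)) {
      for (n in c(2, floor(N / 2))) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper(k, K, n, N), enum_hyper_upper(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # point masses sum to one
  for (N in c(8, 12)) {
    K <- 5; n <- 4
    pmf <- vapply(0:min(K, n), function(k) {
      hypergeom_upper(k, K, n, N) -
        if (k < min(K, n)) hypergeom_upper(k + 1, K, n, N) else 0
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
  expect_error(hypergeom_upper(5, 3, 3, 10), "invalid")
})

test_that("one-sided Fisher test is the hypergeometric upper tail", {
  expect_equal(fisher_exact_greater(2, 1, 1, 2), 0.5, tolerance = 1e-12)
  expect_equal(fisher_exact_greater(0, 3, 5, 7), 1)
  set.seed(3)
  for (i in 1:200) {
    cells <- rpois(4, 4)
    p <- fisher_exact_greater(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, hypergeom_upper(cells[1], cells[1] + cells[2],
                                    cells[1] + cells[3], sum(cells)),
                 tolerance = 1e-12)
    if (sum(cells) > 0) {
      ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                                alternative = "greater")$p.value
      expect_equal(p, ref, tolerance = 1e-9)
    }
  }
  expect_error(fisher_exact_greater(-1, 1, 1, 1))
})

test_that("BH adjustment is step-up, order-invariant, and respects m", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), 3), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04, 1), 0.04)
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^2
    m <- length(p) + sample(0:10, 1)
    adj <- bh_adjust(p, m)
    expect_equal(adj, stepup_bh(p, m), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm], m), adj[perm], tolerance = 1e-12)
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # equal p-values share an adjusted value
    p2 <- c(p, p[1])
    adj2 <- bh_adjust(p2, length(p2))
    expect_equal(adj2[1], adj2[length(p2)])
  }
})

test_that("over-representation analysis counts within the annotated universe", {
  ann <- list(
    T1 = list(name = "term one", genes = c("A", "B", "C", "D")),
    T2 = list(name = "term two", genes = c("C", "D", "E", "F", "G", "H"))
  )
  # single annotated input gene in a single term: m = 1 identity
  res <- run_ora("A", ann)
  expect_equal(nrow(res), 1)
  expect_equal(res$k, 1)
  expect_equal(res$K, 4)
  expect_equal(res$n, 1)
  expect_equal(res$N, 8)
  expect_equal(res$p, 4 / 8)
  expect_equal(res$p_adj, res$p)

  # unannotated input genes fall out of n
  res2 <- run_ora(c("A", "B", "ZZZ"), ann)
  expect_true(all(res2$n == 2))
  expect_warning(run_ora("ZZZ", ann), "annotated")

  # a strongly planted term ranks first
  cfg <- synth_config(seed = 21)
  world <- gen_annotation(cfg, planted = sprintf("T%04d", 1:40))
  res3 <- run_ora(sprintf("T%04d", 1:40), world$annotation)
  expect_equal(res3$term_id[1], "PLANTED")
  expect_true(res3$reserved[1])
})

test_that("ORA p-values are approximately uniform under null annotation", {
  set.seed(17)
  universe <- sprintf("G%04d", 1:2000)
  ann <- lapply(1:200, function(i) {
    list(name = paste("null term", i), genes = sample(universe, sample(100:400, 1)))
  })
  names(ann) <- sprintf("N%03d", 1:200)
  res <- run_ora(sample(universe, 200), ann)
  expect_gt(nrow(res), 150)
  frac <- mean(res$p <= 0.05)
  expect_lt(frac, 0.09)
  expect_gt(frac, 0.01)
})

test_that("GO level classification counts genes per term with top-n truncation", {
  ann <- data.frame(
    term_id = rep(sprintf("GO%02d", 1:25), each = 2),
    term_name = rep(sprintf("term %02d", 1:25), each = 2),
    namespace = "BP", level = 2L,
    gene = c(rbind(sprintf("g%02d", 1:25), "SHARED")),
    stringsAsFactors = FALSE
  )
  res <- classify_go(c(sprintf("g%02d", 1:25), "shared"), ann, level = 2)
  expect_equal(nrow(res), 20)             # top-20 rule
  expect_true(all(res$gene_count == 2))   # shared gene counted in every term
  expect_equal(res$term_id, sprintf("GO%02d", 1:20))  # count ties -> id order
  expect_warning(empty <- classify_go("g01", ann, level = 5), "level")
  expect_equal(nrow(empty), 0)
})

test_that("pathway intersection matches by id, then by normalized name", {
  a <- data.frame(term_id = c("hsa04010", "hsa04020"),
                  term_name = c("MAPK signaling pathway", "Calcium signaling pathway"))
  b <- data.frame(term_id = c("hsa04020", "hsa04024"),
                  term_name = c("Calcium signaling pathway", "cAMP signaling pathway"))
  m <- intersect_pathways(a, b)
  expect_equal(m$term_id_a, "hsa04020")
  expect_equal(m$matched_by, "id")

  a2 <- data.frame(term_name = "MAPK  Signaling Pathway")
  b2 <- data.frame(term_name = "mapk signaling pathway")
  expect_equal(intersect_pathways(a2, b2)$matched_by, "name")
  expect_equal(nrow(intersect_pathways(a[0, ], b)), 0)
})
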