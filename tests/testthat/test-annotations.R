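test_that("GMT and two-column TSV annotation files parse to the same catalog", {
  gmt <- c("GO:1\tfirst term\tA\tB\tC",
           "GO:2\tsecond term\tA\tD")
  cat_gmt <- read_annotations(gmt, format = "gmt")
  expect_setequal(cat_gmt$sets[["GO:1"]], c("A", "B", "C"))
  expect_equal(unname(cat_gmt$term_names[["GO:2"]]), "second term")
  expect_equal(n_associations(cat_gmt), 5L)
  expect_equal(unname(protein_counts(cat_gmt)["A"]), 2L)

  tsv <- c("GO:1\tA", "GO:1\tB", "GO:1\tC", "GO:1\tA", "GO:2\tA", "GO:2\tD")
  cat_tsv <- read_annotations(tsv, format = "tsv")
  expect_equal(lapply(cat_tsv$sets, sort), lapply(cat_gmt$sets, sort))

  expect_error(read_annotations(c("GO:1\tA", "orphan"), format = "tsv"),
               "line 2")
  expect_error(read_annotations(c("GO:1\tdesc\tA", "GO:1\tdesc\tB"),
                                format = "gmt"),
               "duplicate")
})

test_that("term filtering enforces size, coverage, and effective-size bounds", {
  vertices <- sprintf("P%02d", 1:50)
  sets <- list(
    ok = vertices[1:10],
    tiny = vertices[1:2],                       # |S| = 2 < 3
    low_cov = c(vertices[1], paste0("X", 1:3)), # coverage 1/4 < 0.5
    eff_small = c(vertices[1:2], "X9", "X10"),  # coverage 0.5 but only 2 in net
    big = paste0("Y", 1:1001)                   # |S| = 1001 > 1000
  )
  catalog <- annotation_catalog(sets)
  kept <- filter_annotations(catalog, vertices)
  expect_equal(names(kept$sets), "ok")

  # a term of size 1001 is dropped purely by the upper bound
  big_net <- c(vertices, paste0("Y", 1:1001))
  kept2 <- filter_annotations(catalog, big_net, max_size = 1000)
  expect_false("big" %in% names(kept2$sets))
  kept3 <- filter_annotations(catalog, big_net, max_size = 1001)
  expect_true("big" %in% names(kept3$sets))
})

test_that("coverage tightening never adds terms (monotonicity)", {
  set.seed(11)
  vertices <- sprintf("P%02d", 1:30)
  universe <- c(vertices, sprintf("X%02d", 1:30))
  catalog <- random_catalog(40, universe, size_range = c(3, 12))
  coverages <- c(0.2, 0.4, 0.6, 0.8, 1)
  kept <- lapply(coverages, function(cv) {
    names(filter_annotations(catalog, vertices, min_coverage = cv)$sets)
  })
  for (i in seq_along(kept)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("shuffling preserves both bipartite marginals exactly", {
  set.seed(23)
  catalog <- random_catalog(50, sprintf("P%03d", 1:120))
  before <- catalog_marginals(catalog)
  shuf <- shuffle_annotations(catalog, n_swaps = 10000)
  after <- catalog_marginals(shuf)
  expect_identical(after$sizes, before$sizes)
  expect_identical(after$counts[names(before$counts)], before$counts)
  expect_true(shuf$shuffled)
  # the shuffle actually moved associations around
  moved <- vapply(names(catalog$sets),
                  function(id) !setequal(catalog$sets[[id]], shuf$sets[[id]]),
                  NA)
  expect_gt(mean(moved), 0.5)
})

test_that("shuffling is reproducible under a seed and honours n_swaps = 0", {
  set.seed(5)
  catalog <- random_catalog(20, sprintf("P%03d", 1:60))
  expect_identical(shuffle_annotations(catalog, n_swaps = 0)$sets, catalog$sets)

  set.seed(99); a <- shuffle_annotations(catalog, n_swaps = 5000)
  set.seed(99); b <- shuffle_annotations(catalog, n_swaps = 5000)
  expect_identical(a$sets, b$sets)
})

test_that("a single swap attempt either leaves the catalog intact or swaps legally", {
  catalog <- annotation_catalog(list(`GO:1` = "A", `GO:2` = "B"))
  for (s in 1:12) {
    set.seed(s)
    out <- shuffle_annotations(catalog, n_swaps = 1)
    expect_true(identical(out$sets, catalog$sets) ||
                  identical(lapply(out$sets, sort),
                            list(`GO:1` = "B", `GO:2` = "A")))
  }
  # across seeds both outcomes occur: the only legal swap exchanges A and B
  outcomes <- vapply(1:12, function(s) {
    set.seed(s)
    identical(shuffle_annotations(catalog, n_swaps = 1)$sets[["GO:1"]], "B")
  }, NA)
  expect_true(any(outcomes))

  tiny <- annotation_catalog(list(`GO:1` = "A"))
  expect_warning(out <- shuffle_annotations(tiny, n_swaps = 10), "fewer than 2")
  expect_identical(out$sets, tiny$sets)
})

test_that("swaps never place a protein twice in the same term", {
  set.seed(31)
  catalog <- random_catalog(30, sprintf("P%02d", 1:40), size_range = c(3, 8))
  shuf <- shuffle_annotations(catalog, n_swaps = 20000)
  expect_true(all(vapply(shuf$sets, anyDuplicated, 0L) == 0L))
})
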