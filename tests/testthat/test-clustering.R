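test_that("all-pairs distances are exact on hand-checkable graphs", {
  tri <- unit_graph(cbind(c("A", "B", "C"), c("B", "C", "A")))
  d <- all_pairs_distances(tri)
  expect_equal(unname(d[upper.tri(d)]), c(1, 1, 1))
  expect_equal(unname(diag(d)), c(0, 0, 0))

  path <- igraph::graph_from_edgelist(cbind(c("A", "B"), c("B", "C")),
                                      directed = FALSE)
  igraph::E(path)$weight <- c(0.5, 0.25)
  d <- all_pairs_distances(path)
  expect_equal(d["A", "C"], 0.75)

  disc <- unit_graph(cbind(c("A", "C"), c("B", "D")))
  expect_error(all_pairs_distances(disc), "disconnected")
})

test_that("distances match an independent Bellman-Ford oracle on a random graph", {
  set.seed(13)
  g <- random_connected_graph(30)
  expect_equal(all_pairs_distances(g), bellman_ford_all_pairs(g),
               tolerance = 1e-9)
})

test_that("TPD sums each unordered pair once", {
  g <- unit_graph(cbind(c("A", "B", "C"), c("B", "C", "A")))
  d <- all_pairs_distances(g)
  expect_equal(tpd(d, c("A", "B")), 1)
  expect_equal(tpd(d, c("A", "B", "C")), 3)
  expect_error(tpd(d, "A"), "at least 2")
  expect_error(tpd(d, c("A", "Z")), "Z")

  # complete unit-weight graph: TPD of all n vertices is n(n-1)/2
  n <- 7
  kn <- igraph::make_full_graph(n)
  igraph::V(kn)$name <- paste0("K", 1:n)
  igraph::E(kn)$weight <- 1
  dk <- all_pairs_distances(kn)
  expect_equal(tpd(dk, igraph::V(kn)$name), n * (n - 1) / 2)
})

test_that("TPD on an all-ones weighting is an integer hop-count sum", {
  set.seed(3)
  g <- random_connected_graph(25)
  igraph::E(g)$weight <- 1
  d <- all_pairs_distances(g)
  for (k in 1:10) {
    s <- sample(igraph::V(g)$name, 6)
    expect_equal(tpd(d, s) %% 1, 0)
  }
})

test_that("uniform null moments match exhaustive enumeration on a 5-vertex fixture", {
  # triangle A-B-C plus path C-D-E
  g <- unit_graph(cbind(c("A", "B", "C", "C", "D"),
                        c("B", "C", "A", "D", "E")))
  d <- all_pairs_distances(g)
  combos <- utils::combn(rownames(d), 3)
  exact <- apply(combos, 2, function(s) tpd(d, s))
  exact_sd <- sqrt(mean((exact - mean(exact))^2))  # population sd over subsets
  set.seed(101)
  nm <- build_null_model(d, rownames(d), sizes = 3, n_samples = 2e4)
  se <- exact_sd / sqrt(2e4)
  expect_lt(abs(nm$mean - mean(exact)), 3 * se)
  expect_equal(nm$sd, exact_sd, tolerance = 0.05)
})

test_that("degenerate null (size = pool) has zero sd and the exact TPD mean", {
  g <- unit_graph(cbind(c("A", "B", "C"), c("B", "C", "A")))
  d <- all_pairs_distances(g)
  nm <- build_null_model(d, rownames(d), sizes = 3, n_samples = 100)
  expect_equal(nm$sd, 0)
  expect_equal(nm$mean, tpd(d, rownames(d)))
  expect_error(build_null_model(d, rownames(d), sizes = 4, n_samples = 10),
               "exceeds")
  expect_error(build_null_model(d, rownames(d), sizes = 3, n_samples = 1),
               "n_samples")
})

test_that("annotation-weighted sampling includes heavy proteins at the analytic rate", {
  # star around H; distances identify membership of H in a sampled pair:
  # d(H, leaf) = 1, d(leaf, leaf) = 2, so TPD(pair) = 1 iff H is drawn.
  g <- unit_graph(cbind("H", paste0("L", 1:4)))
  d <- all_pairs_distances(g)
  w <- c(H = 10, L1 = 1, L2 = 1, L3 = 1, L4 = 1)
  # analytic inclusion probability of H in a sequential no-replacement pair:
  # P(first) + sum over leaves P(leaf first) P(H second)
  p_inc <- 10 / 14 + 4 * (1 / 14) * (10 / 13)
  set.seed(77)
  nm <- build_null_model(d, names(w), sizes = 2, n_samples = 1e5,
                         weights = w, keep_samples = TRUE)
  freq <- mean(attr(nm, "samples")[[1]] == 1)
  se <- sqrt(p_inc * (1 - p_inc) / 1e5)
  expect_lt(abs(freq - p_inc), 3 * se)
  expect_equal(nm$mode, "weighted")
  expect_error(build_null_model(d, names(w), sizes = 2, n_samples = 10,
                                weights = c(H = 1)),
               "sampling weight")
})

test_that("null models are bit-reproducible under a seed and monotone in size", {
  set.seed(19)
  g <- random_connected_graph(40)
  d <- all_pairs_distances(g)
  set.seed(7); a <- build_null_model(d, rownames(d), sizes = c(3, 5, 8),
                                     n_samples = 2000)
  set.seed(7); b <- build_null_model(d, rownames(d), sizes = c(3, 5, 8),
                                     n_samples = 2000)
  expect_identical(a, b)
  expect_true(all(diff(a$mean) > 0))
})

test_that("clustering p-values follow the lower-tail normal with the sd = 0 convention", {
  expect_equal(clustering_pvalue(10, 10, 2), 0.5)
  expect_equal(clustering_pvalue(10 - 1.959964 * 2, 10, 2), 0.025,
               tolerance = 1e-6)
  expect_equal(clustering_pvalue(11, 10, 0), 1)
  expect_equal(clustering_pvalue(10, 10, 0), 1)
  expect_equal(clustering_pvalue(9, 10, 0), .Machine$double.xmin)
  expect_error(clustering_pvalue(1, 0, -1), "sigma")
  # vectorizes over observations and is monotone at fixed moments
  p <- clustering_pvalue(seq(0, 20, by = 0.5), 10, 2)
  expect_length(p, 41)
  expect_true(all(diff(p) >= 0))
  expect_equal(clustering_pvalue(c(5, 15), c(10, 10), c(2, 0)),
               c(stats::pnorm(5, 10, 2), 1))
})

test_that("term scores are deterministic and minimal for the closest triple", {
  set.seed(29)
  g <- random_connected_graph(20)
  d <- all_pairs_distances(g)
  vn <- rownames(d)
  combos <- utils::combn(vn, 3)
  tpds <- apply(combos, 2, function(s) tpd(d, s))
  best <- combos[, which.min(tpds)]

  catalog <- annotation_catalog(list(best = best, twin = best,
                                     other = vn[1:5]))
  set.seed(1)
  nm <- build_null_model(d, vn, sizes = c(3, 5), n_samples = 2000)
  sc <- score_terms(d, catalog, nm)
  expect_equal(sc$tpd[sc$term_id == "best"], min(tpds))
  expect_equal(sc$p_value[sc$term_id == "best"],
               sc$p_value[sc$term_id == "twin"])
  expect_equal(sc$tpd[sc$term_id == "best"],
               min(apply(utils::combn(vn, 3), 2, function(s) tpd(d, s))))

  nm3 <- build_null_model(d, vn, sizes = 3, n_samples = 2000)
  expect_error(score_terms(d, catalog, nm3), "other")
})

test_that("null-model caches round-trip through TSV with key checking", {
  set.seed(3)
  g <- random_connected_graph(15)
  d <- all_pairs_distances(g)
  nm <- build_null_model(d, rownames(d), sizes = c(3, 4), n_samples = 500)
  key <- network_digest(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_null_model(nm, path, key = key)
  back <- read_null_model(path, key = key)
  expect_equal(as.data.frame(back), as.data.frame(nm), tolerance = 1e-12)
  expect_error(read_null_model(path, key = "deadbeef"), "mismatch")
})
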