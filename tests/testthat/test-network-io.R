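biogrid_lines <- function(rows) {
  header <- paste("#ID A", "ID B", "Official Symbol Interactor A",
                  "Official Symbol Interactor B", "Organism Interactor A",
                  "Organism Interactor B", "Experimental System Type",
                  sep = "\t")
  c(header, vapply(rows, function(r) paste(r, collapse = "\t"), ""))
}

test_that("BioGRID parser keeps same-taxon rows and drops the rest", {
  lines <- biogrid_lines(list(
    c("1", "2", "TP53", "MDM2", "9606", "9606", "physical"),
    c("3", "4", "BRCA1", "BARD1", "9606", "9606", "genetic"),
    c("5", "6", "TP53", "CDC28", "9606", "559292", "physical")))
  rec <- read_biogrid(lines, taxon = 9606)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$protein_a, c("TP53", "BRCA1"))
  expect_true(all(is.na(rec$score)))

  expect_equal(nrow(read_biogrid(lines, taxon = 559292)), 0L)
  expect_equal(nrow(read_biogrid(lines, taxon = 9606, physical_only = TRUE)), 1L)
  expect_equal(nrow(read_biogrid(biogrid_lines(list()), taxon = 9606)), 0L)
})

test_that("BioGRID parser reports missing columns by name", {
  bad <- c("colA\tcolB", "x\ty")
  expect_error(read_biogrid(bad), "Official Symbol Interactor A")
  no_org <- c("Official Symbol Interactor A\tOfficial Symbol Interactor B",
              "TP53\tMDM2")
  expect_error(read_biogrid(no_org), "Organism Interactor A")
})

test_that("STRING parser applies the combined-score cutoff strictly", {
  lines <- c("protein1 protein2 combined_score",
             "ENSP1 ENSP2 401",
             "ENSP1 ENSP3 400",
             "ENSP2 ENSP3 999")
  rec <- read_string(lines, min_score = 400)
  expect_equal(nrow(rec), 2L)
  expect_false(any(rec$protein_b == "ENSP3" & rec$protein_a == "ENSP1"))
  expect_equal(nrow(read_string(lines, min_score = 400, inclusive = TRUE)), 3L)
  expect_equal(nrow(read_string(character(0))), 0L)
  expect_error(read_string(c("protein1 protein2 combined_score",
                             "ENSP1 ENSP2 0.87")),
               "line 2")
})

test_that("network build collapses duplicates, drops self-loops, takes the LCC", {
  rec <- data.frame(protein_a = c("A", "B", "A"),
                    protein_b = c("B", "A", "A"))
  g <- build_network(rec, hub_cutoff = 1000)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)

  rec <- data.frame(protein_a = c("A", "B", "C", "D"),
                    protein_b = c("B", "C", "A", "E"))
  g <- build_network(rec)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 3L)
})

test_that("hub removal re-establishes connectivity", {
  # star H with 5 leaves: removing H isolates every leaf -> nothing remains
  star <- data.frame(protein_a = "H", protein_b = paste0("L", 1:5))
  expect_error(build_network(star, hub_cutoff = 5), "no network remains")

  # same star plus an edge between two leaves: that edge is the surviving LCC
  star2 <- rbind(star, data.frame(protein_a = "L1", protein_b = "L2"))
  g <- build_network(star2, hub_cutoff = 5)
  expect_setequal(igraph::V(g)$name, c("L1", "L2"))
  expect_true(igraph::is_connected(g))
})

test_that("built networks satisfy their invariants and rebuilding is idempotent", {
  set.seed(41)
  for (rep in 1:5) {
    el <- cbind(sample(LETTERS[1:15], 40, TRUE), sample(LETTERS[1:15], 40, TRUE))
    rec <- data.frame(protein_a = el[, 1], protein_b = el[, 2])
    rec <- rec[rec$protein_a != rec$protein_b | seq_len(nrow(rec)) %% 2 == 0, ]
    g <- build_network(rec, hub_cutoff = 8)
    expect_true(igraph::is_simple(g))
    expect_true(igraph::is_connected(g))
    expect_lt(max(igraph::degree(g)), 8)
    counts <- g$stage_counts
    expect_true(all(diff(counts$vertices) <= 0))
    expect_true(all(diff(counts$edges) <= 0))

    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    g2 <- build_network(data.frame(protein_a = ends[, 1], protein_b = ends[, 2]),
                        hub_cutoff = 8)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
  }
})
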