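#' Specification for a synthetic benchmark dataset
#'
#' Describes a synthetic PPI network, annotation catalog, and two-condition
#' expression table with planted "signal" terms: connected modules whose
#' proteins are differentially expressed by a known effect size. The defaults
#' generate a desk-scale analogue of a quantitative proteomics study on a
#' scale-free interactome: 200 proteins, 50 annotation terms, one
#' 10-protein dysregulated module with a 4-fold expression change, and
#' 10\% log-normal biological noise around no-change for the background.
#'
#' @param n_vertices Number of proteins in the network. Default 200.
#' @param attachment Edges per vertex: preferential-attachment edges added
#'   per new vertex (\code{topology = "pa"}), or the factor multiplying
#'   \code{n_vertices} to give the total edge count (\code{topology =
#'   "gnm"}). Default 2.
#' @param topology \code{"pa"} (default): scale-free-like preferential
#'   attachment, emulating the heavy-tailed degree distribution of PPI
#'   networks. \code{"gnm"}: homogeneous Erdos-Renyi (largest connected
#'   component, so the vertex count comes out slightly below
#'   \code{n_vertices}). At desk scale the homogeneous topology is the one
#'   that reproduces the tail regime of a full-size PPI network, where the
#'   largest hub enters only a negligible fraction of random protein sets;
#'   a 200-vertex preferential-attachment hub sits in nearly half of them.
#' @param n_terms Number of annotation terms (including signal terms).
#'   Default 50.
#' @param term_size_range Bounds (min, max) of the uniform term-size
#'   distribution for background terms. Default c(3, 20).
#' @param module_size Number of proteins annotated by each planted signal
#'   term. Default 10.
#' @param region_scale Each signal term's proteins are drawn from a connected
#'   dysregulated region of \code{region_scale * module_size} proteins (the
#'   "pathway"), of which the term annotates a hop-spread subset of
#'   \code{module_size}. With \code{region_scale = 1} the term annotates the
#'   whole region and is compact in hop distance as well. Default 3.
#' @param effect Fold-change applied to all region proteins (numerator over
#'   denominator condition); must be positive and is 1 for a null fixture
#'   with no planted signal. Default 4.
#' @param noise_sd Standard deviation of per-sample log-normal noise on
#'   expression values. Default 0.1.
#' @param n_signal Number of planted signal terms. Default 1; 0 gives a
#'   fully null fixture.
#' @param samples_per_condition Replicates per condition. Default 3.
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_vertices = 200, attachment = 2, n_terms = 50,
                           term_size_range = c(3, 20), module_size = 10,
                           region_scale = 3, effect = 4, noise_sd = 0.1,
                           n_signal = 1, samples_per_condition = 3,
                           topology = c("pa", "gnm"), seed = 1) {
  topology <- match.arg(topology)
  spec <- list(n_vertices = n_vertices, attachment = attachment,
               topology = topology,
               n_terms = n_terms, term_size_range = term_size_range,
               module_size = module_size, region_scale = region_scale,
               effect = effect, noise_sd = noise_sd, n_signal = n_signal,
               samples_per_condition = samples_per_condition, seed = seed)
  stopifnot(effect > 0, noise_sd >= 0, n_terms >= n_signal,
            region_scale >= 1,
            term_size_range[1] >= 2, term_size_range[2] >= term_size_range[1])
  if (ceiling(module_size * region_scale) > n_vertices) {
    stop("infeasible spec: module region larger than the network")
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic benchmark dataset
#'
#' Builds a connected scale-free-like PPI network
#' (preferential attachment), an annotation catalog of random protein sets,
#' and a two-condition expression table. Each planted signal emulates a
#' dysregulated pathway: a connected region of the network is grown by
#' breadth-first expansion from a random seed protein and all its proteins
#' receive expression values whose condition ratio centres on \code{effect};
#' the signal term annotates a hop-spread subset of the region
#' (farthest-point selection), so the term's proteins are linked by short
#' dysregulated paths without being compact in plain hop distance — the
#' configuration the expression-weighted analysis exists to detect. All
#' other proteins centre on a ratio of 1 with log-normal noise
#' \code{noise_sd}. Output is deterministic given \code{spec$seed}.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class \code{synthetic_fixture}: \code{network} (igraph),
#'   \code{expression} (\code{expression_table}), \code{catalog}
#'   (\code{annotation_catalog}), \code{signal_terms} (character vector of
#'   planted term IDs), \code{regions} (list of the dysregulated protein
#'   regions), and \code{conditions} (the two condition labels, numerator
#'   first).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- if (identical(spec$topology, "gnm")) {
    .largest_component(igraph::sample_gnm(spec$n_vertices,
                                          spec$attachment * spec$n_vertices))
  } else {
    igraph::sample_pa(spec$n_vertices, power = 1, m = spec$attachment,
                      directed = FALSE)
  }
  igraph::V(g)$name <- sprintf("P%04d", seq_len(igraph::vcount(g)))
  vnames <- igraph::V(g)$name

  region_size <- ceiling(spec$module_size * spec$region_scale)
  hops <- if (spec$n_signal > 0 && region_size > spec$module_size) {
    igraph::distances(g)
  } else NULL
  module_of <- vector("list", spec$n_signal)
  sets <- vector("list", spec$n_terms)
  names(sets) <- sprintf("T%03d", seq_len(spec$n_terms))
  for (i in seq_len(spec$n_signal)) {
    module_of[[i]] <- .grow_module(g, region_size)
    sets[[i]] <- .spread_subset(module_of[[i]], spec$module_size, hops)
  }
  for (i in seq_len(spec$n_terms - spec$n_signal) + spec$n_signal) {
    size <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]), 1L)
    sets[[i]] <- sample(vnames, size)
  }
  catalog <- annotation_catalog(sets)

  module_proteins <- unique(unlist(module_of))
  k <- spec$samples_per_condition
  nv <- length(vnames)
  baseline <- stats::rlnorm(nv, meanlog = 10, sdlog = 1)
  names(baseline) <- vnames
  target <- rep(1, nv)
  names(target) <- vnames
  target[module_proteins] <- spec$effect
  noise <- function(n) if (spec$noise_sd == 0) rep(1, n)
                       else stats::rlnorm(n, 0, spec$noise_sd)
  vals_a <- baseline * target * matrix(noise(nv * k), nv, k)
  vals_b <- baseline * matrix(noise(nv * k), nv, k)
  values <- cbind(vals_a, vals_b)
  rownames(values) <- vnames
  colnames(values) <- c(sprintf("case_%d", seq_len(k)),
                        sprintf("control_%d", seq_len(k)))
  expr <- expression_table(values, rep(c("case", "control"), each = k))

  structure(list(network = g, expression = expr, catalog = catalog,
                 signal_terms = names(sets)[seq_len(spec$n_signal)],
                 regions = module_of,
                 conditions = c("case", "control"), spec = spec),
            class = "synthetic_fixture")
}

# Farthest-point subset: greedily pick region members maximizing the minimum
# hop distance to those already picked, so the term is spread across the
# region rather than forming a compact ball.
.spread_subset <- function(region, size, hops) {
  if (is.null(hops) || size >= length(region)) return(region[seq_len(size)])
  sel <- region[[1L]]
  while (length(sel) < size) {
    cand <- setdiff(region, sel)
    nearest <- apply(hops[cand, sel, drop = FALSE], 1L, min)
    sel <- c(sel, cand[[which.max(nearest)]])
  }
  sel
}

# Connected region: breadth-first expansion from a random seed vertex,
# visiting each frontier in random order so repeated draws differ.
.grow_module <- function(g, size) {
  vnames <- igraph::V(g)$name
  start <- sample(vnames, 1L)
  chosen <- start
  frontier <- setdiff(names(igraph::neighbors(g, start)), chosen)
  while (length(chosen) < size) {
    if (length(frontier) == 0L) stop("module growth exhausted the component")
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    chosen <- c(chosen, nxt)
    frontier <- setdiff(unique(c(frontier,
                                 names(igraph::neighbors(g, nxt)))), chosen)
    frontier <- setdiff(frontier, nxt)
  }
  chosen
}

#' Write a synthetic fixture in the pipeline's input formats
#'
#' Serializes the fixture as the same files the real pipeline reads: a
#' BioGRID-style tab-delimited interaction file, an expression TSV plus a
#' sample-to-condition map, and a GMT annotation file. The fixture thereby
#' doubles as format documentation.
#'
#' @param fixture A \code{synthetic_fixture} from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @param taxon Taxon ID written into the interaction file. Default 9606.
#' @return Named character vector of the written paths (\code{network},
#'   \code{expression}, \code{conditions}, \code{annotations}).
#' @export
write_fixture <- function(fixture, dir, taxon = 9606) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             annotations = file.path(dir, "annotations.gmt"))

  ends <- igraph::ends(fixture$network, igraph::E(fixture$network), names = TRUE)
  net <- data.frame(`Official Symbol Interactor A` = ends[, 1L],
                    `Official Symbol Interactor B` = ends[, 2L],
                    `Organism Interactor A` = taxon,
                    `Organism Interactor B` = taxon,
                    check.names = FALSE)
  utils::write.table(net, paths[["network"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expr <- data.frame(protein = rownames(fixture$expression$values),
                     fixture$expression$values, check.names = FALSE)
  utils::write.table(expr, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(fixture$expression$values),
               condition = fixture$expression$conditions),
    paths[["conditions"]], sep = "\t", quote = FALSE, row.names = FALSE)

  gmt <- vapply(names(fixture$catalog$sets), function(id) {
    paste(c(id, unname(fixture$catalog$term_names[[id]]),
            fixture$catalog$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(gmt, paths[["annotations"]])
  paths
}
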