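# Independent all-pairs shortest-path oracle: one Bellman-Ford relaxation
# sweep per source over the raw edge list. Deliberately avoids igraph so it
# can serve as a cross-check for all_pairs_distances().
bellman_ford_all_pairs <- function(graph) {
  vn <- igraph::V(graph)$name
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  w <- igraph::E(graph)$weight
  n <- length(vn)
  D <- matrix(Inf, n, n, dimnames = list(vn, vn))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    for (iter in seq_len(n - 1L)) {
      changed <- FALSE
      for (e in seq_len(nrow(ends))) {
        a <- ends[e, 1L]; b <- ends[e, 2L]
        if (dist[a] + w[e] < dist[b]) { dist[b] <- dist[a] + w[e]; changed <- TRUE }
        if (dist[b] + w[e] < dist[a]) { dist[a] <- dist[b] + w[e]; changed <- TRUE }
      }
      if (!changed) break
    }
    D[s, ] <- dist
  }
  D
}

# Random connected graph with weights in (0, 1]: random spanning tree plus
# extra random edges. Uses the caller's RNG state.
random_connected_graph <- function(n, extra = n) {
  vn <- sprintf("V%02d", seq_len(n))
  tree <- cbind(vn[vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L)], vn[2:n])
  more <- cbind(sample(vn, extra, replace = TRUE), sample(vn, extra, replace = TRUE))
  el <- rbind(tree, more)
  el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.05, 1)
  g
}

# Small unit-weight graph from an edge list given as a 2-column matrix.
unit_graph <- function(edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}

# Catalog of random protein sets over a protein universe.
random_catalog <- function(n_terms, proteins, size_range = c(3, 10)) {
  sets <- lapply(seq_len(n_terms), function(i) {
    sample(proteins, sample(seq(size_range[1], size_range[2]), 1L))
  })
  names(sets) <- sprintf("GO:%04d", seq_len(n_terms))
  annotation_catalog(sets)
}

# Bipartite marginals of a catalog: per-term sizes and per-protein counts.
catalog_marginals <- function(catalog) {
  list(sizes = lengths(catalog$sets),
       counts = protein_counts(catalog))
}
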