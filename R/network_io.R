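#' Parse a BioGRID tab-delimited interaction file
#'
#' Reads a BioGRID tab2/tab3 release file and returns one interaction record
#' per row in which both interactors belong to the requested organism.
#' Identifiers are taken from the "Official Symbol" columns.
#'
#' @param file Path to a BioGRID tab-delimited file, or a character vector of
#'   lines (header included).
#' @param taxon NCBI taxonomy identifier; only rows where both interactors
#'   have this taxon are kept. Default 9606 (human).
#' @param physical_only If \code{TRUE} and an "Experimental System Type"
#'   column is present, keep only rows typed "physical". Default \code{FALSE}:
#'   all interaction rows for the taxon are used.
#' @return A data frame of interaction records with columns
#'   \code{protein_a}, \code{protein_b} (character) and \code{score}
#'   (numeric, all \code{NA}: BioGRID carries no confidence score).
#' @seealso [read_string()], [build_network()]
#' @export
read_biogrid <- function(file, taxon = 9606, physical_only = FALSE) {
  lines <- .read_lines_arg(file)
  if (length(lines) == 0L) stop("empty BioGRID file: no header row", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- sub("^#", "", trimws(header))
  col <- function(patterns, what) {
    for (p in patterns) {
      i <- which(tolower(header) == tolower(p))
      if (length(i)) return(i[[1L]])
    }
    stop("BioGRID format error: missing required column '", what, "'", call. = FALSE)
  }
  ia <- col(c("Official Symbol Interactor A"), "Official Symbol Interactor A")
  ib <- col(c("Official Symbol Interactor B"), "Official Symbol Interactor B")
  oa <- col(c("Organism Interactor A", "Organism ID Interactor A"),
            "Organism Interactor A")
  ob <- col(c("Organism Interactor B", "Organism ID Interactor B"),
            "Organism Interactor B")
  et <- {
    i <- which(tolower(header) == tolower("Experimental System Type"))
    if (length(i)) i[[1L]] else NA_integer_
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(.interaction_records(character(), character()))

  fields <- strsplit(body, "\t", fixed = TRUE)
  need <- max(ia, ib, oa, ob, et, na.rm = TRUE)
  short <- vapply(fields, length, 0L) < need
  if (any(short)) {
    stop("BioGRID format error: line ", which(short)[[1L]] + 1L,
         " has too few columns", call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  keep <- suppressWarnings(as.integer(get(oa))) == taxon &
          suppressWarnings(as.integer(get(ob))) == taxon
  keep[is.na(keep)] <- FALSE
  if (physical_only && !is.na(et)) {
    keep <- keep & tolower(get(et)) == "physical"
  }
  .interaction_records(get(ia)[keep], get(ib)[keep])
}

#' Parse a STRING protein-links file
#'
#' Reads STRING's \code{protein.links} format (columns \code{protein1},
#' \code{protein2}, \code{combined_score} on STRING's 0--1000 integer scale)
#' and keeps interactions above a confidence cutoff. Identifiers are passed
#' through unchanged; map ENSP identifiers to gene symbols upstream if the
#' expression table uses symbols.
#'
#' @param file Path to a STRING protein-links file, or a character vector of
#'   lines (header included). Fields may be space- or tab-separated.
#' @param min_score Confidence cutoff on the 0--1000 scale. Default 400
#'   (medium confidence, score above 0.4).
#' @param inclusive If \code{TRUE}, keep scores \code{>= min_score} instead of
#'   the default strict \code{>}.
#' @return A data frame of interaction records (\code{protein_a},
#'   \code{protein_b}, \code{score}).
#' @export
read_string <- function(file, min_score = 400, inclusive = FALSE) {
  lines <- .read_lines_arg(file)
  if (length(lines) == 0L) return(.interaction_records(character(), character()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  head1 <- tolower(fields[[1L]])
  has_header <- any(head1 %in% c("protein1", "combined_score"))
  if (has_header) fields <- fields[-1L]
  fields <- fields[vapply(fields, function(f) length(f) > 0L && nzchar(f[[1L]]), NA)]
  if (length(fields) == 0L) return(.interaction_records(character(), character()))
  bad <- vapply(fields, length, 0L) < 3L
  if (any(bad)) {
    stop("STRING format error: line ", which(bad)[[1L]] + has_header,
         " has fewer than 3 fields", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(score) || any(score != floor(score))) {
    bad <- which(is.na(score) | score != floor(score))[[1L]]
    stop("STRING format error: non-integer combined_score on line ",
         bad + has_header, call. = FALSE)
  }
  keep <- if (inclusive) score >= min_score else score > min_score
  .interaction_records(vapply(fields, `[[`, "", 1L)[keep],
                       vapply(fields, `[[`, "", 2L)[keep],
                       score[keep])
}

.interaction_records <- function(a, b, score = rep(NA_real_, length(a))) {
  data.frame(protein_a = as.character(a), protein_b = as.character(b),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

.read_lines_arg <- function(file) {
  if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Build the filtered PPI network
#'
#' Assembles interaction records into a simple undirected graph and applies
#' the standard filters: self-loops and duplicate edges are collapsed, the
#' graph is restricted to its largest connected component (LCC), hub proteins
#' interacting with \code{hub_cutoff} or more partners are removed, and the
#' LCC is re-taken so that the result is connected (every pairwise
#' shortest-path distance downstream must be finite).
#'
#' @param records Data frame of interaction records, e.g. from
#'   [read_biogrid()] or [read_string()], or any data frame whose first two
#'   columns are protein identifiers.
#' @param hub_cutoff Remove vertices of degree \code{>= hub_cutoff} (keep
#'   proteins interacting with fewer than \code{hub_cutoff} others,
#'   degree computed on the post-LCC graph). Default 1000.
#' @param retake_lcc Re-take the largest connected component after hub
#'   removal (default \code{TRUE}). Set \code{FALSE} to stop after the hub
#'   filter; the result may then be disconnected and unusable for distance
#'   computations.
#' @param verbose Log vertex/edge counts after each filter stage.
#' @return An \pkg{igraph} undirected graph whose vertex names are protein
#'   identifiers, with attribute \code{stage_counts}: a data frame of
#'   vertex/edge counts per filter stage.
#' @export
build_network <- function(records, hub_cutoff = 1000, retake_lcc = TRUE,
                          verbose = FALSE) {
  stopifnot(is.data.frame(records), ncol(records) >= 2L)
  if (nrow(records) == 0L) stop("no network remains: no interaction records", call. = FALSE)
  a <- trimws(as.character(records[[1L]]))
  b <- trimws(as.character(records[[2L]]))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("no network remains: empty protein identifier", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  counts <- data.frame(stage = "simple", vertices = igraph::vcount(g),
                       edges = igraph::ecount(g))
  g <- .largest_component(g)
  counts <- rbind(counts, data.frame(stage = "lcc", vertices = igraph::vcount(g),
                                     edges = igraph::ecount(g)))
  hubs <- igraph::V(g)[igraph::degree(g) >= hub_cutoff]
  g <- igraph::delete_vertices(g, hubs)
  counts <- rbind(counts, data.frame(stage = "hub_filter",
                                     vertices = igraph::vcount(g),
                                     edges = igraph::ecount(g)))
  if (retake_lcc && igraph::vcount(g) > 0L) {
    g <- .largest_component(g)
    counts <- rbind(counts, data.frame(stage = "relcc",
                                       vertices = igraph::vcount(g),
                                       edges = igraph::ecount(g)))
  }
  if (igraph::ecount(g) == 0L) stop("no network remains after filtering", call. = FALSE)
  if (verbose) {
    for (i in seq_len(nrow(counts))) {
      message(sprintf("  [%s] %d proteins, %d interactions",
                      counts$stage[i], counts$vertices[i], counts$edges[i]))
    }
  }
  g$stage_counts <- counts
  g
}

.largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}
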