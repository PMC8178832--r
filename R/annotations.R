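#' Construct an annotation catalog
#'
#' A catalog maps each functional annotation (e.g. a propagated GO term) to
#' its set of annotated proteins. Protein sets are deduplicated; empty terms
#' are dropped.
#'
#' @param sets Named list of character vectors: term ID -> protein
#'   identifiers.
#' @param term_names Optional named character vector of human-readable term
#'   names (defaults to the IDs).
#' @param namespace Optional named character vector of ontology namespaces
#'   (BP/MF/CC), carried through to results.
#' @param shuffled Internal flag marking a shuffled catalog.
#' @return An object of class \code{annotation_catalog}.
#' @export
annotation_catalog <- function(sets, term_names = NULL, namespace = NULL,
                               shuffled = FALSE) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  keep <- vapply(sets, length, 0L) > 0L
  sets <- sets[keep]
  ids <- names(sets)
  tn <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(term_names)) tn[intersect(ids, names(term_names))] <-
      term_names[intersect(ids, names(term_names))]
  tn[is.na(tn)] <- ids[is.na(tn)]
  ns <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(namespace)) ns[intersect(ids, names(namespace))] <-
      namespace[intersect(ids, names(namespace))]
  structure(list(sets = sets, term_names = tn, namespace = ns,
                 shuffled = isTRUE(shuffled)),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("Annotation catalog%s: %d terms, %d proteins, %d associations\n",
              if (x$shuffled) " (shuffled)" else "",
              length(x$sets), length(unique(unlist(x$sets, use.names = FALSE))),
              sum(sizes)))
  if (length(sizes)) {
    cat(sprintf("  term sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' @export
length.annotation_catalog <- function(x) length(x$sets)

#' Total number of term-protein associations
#' @param catalog An \code{annotation_catalog}.
#' @return Integer: the sum of term set sizes.
#' @export
n_associations <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  sum(lengths(catalog$sets))
}

#' Per-protein annotation counts
#'
#' Number of catalog terms annotating each protein; used as sampling weights
#' by the annotation-weighted Monte-Carlo null model.
#'
#' @param catalog An \code{annotation_catalog}.
#' @return Named integer vector: protein -> number of annotating terms.
#' @export
protein_counts <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  tab <- table(unlist(catalog$sets, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a protein annotation file (GMT or two-column TSV)
#'
#' GMT lines are \code{term <TAB> description <TAB> protein...}; TSV rows are
#' \code{term <TAB> protein} with an optional third namespace column.
#' Annotations are expected to be pre-propagated up the ontology (every
#' protein annotated by a term is also annotated by the term's ancestors).
#' Duplicate (term, protein) pairs are collapsed silently.
#'
#' @param file Path to the annotation file, or a character vector of lines.
#' @param format \code{"auto"} (default: GMT if any line has >= 3 fields and
#'   field 3 does not look like a namespace tag), \code{"gmt"}, or
#'   \code{"tsv"}.
#' @return An \code{annotation_catalog}.
#' @export
read_annotations <- function(file, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  lines <- .read_lines_arg(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty annotation file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (format == "auto") {
    third <- unique(toupper(unlist(lapply(fields[nf >= 3L], `[[`, 3L))))
    format <- if (all(nf <= 3L) &&
                  (all(nf == 2L) || all(third %in% c("BP", "MF", "CC"))))
      "tsv" else "gmt"
  }
  if (format == "gmt") {
    bad <- which(nf < 3L)
    if (length(bad)) {
      stop("annotation format error: GMT line ", bad[[1L]],
           " has fewer than 3 fields", call. = FALSE)
    }
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids)) {
      stop("annotation format error: duplicate GMT term '",
           ids[duplicated(ids)][[1L]], "'", call. = FALSE)
    }
    sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
    tn <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
    annotation_catalog(sets, term_names = tn)
  } else {
    bad <- which(nf < 2L)
    if (length(bad)) {
      stop("annotation format error: TSV line ", bad[[1L]],
           " has fewer than 2 fields", call. = FALSE)
    }
    term <- vapply(fields, `[[`, "", 1L)
    prot <- vapply(fields, `[[`, "", 2L)
    ns <- NULL
    if (all(nf >= 3L)) {
      ns3 <- vapply(fields, `[[`, "", 3L)
      ns <- stats::setNames(ns3, term)[!duplicated(term)]
    }
    annotation_catalog(split(prot, term), namespace = ns)
  }
}

#' Filter annotation terms against a PPI network
#'
#' Keeps a term when (i) its total protein set size is within
#' \code{[min_size, max_size]}, (ii) at least \code{min_coverage} of its
#' proteins are present in the network, and (iii) its effective set (the
#' proteins present in the network, the set actually scored) still has at
#' least \code{min_size} members. The bounds exclude tiny terms with no
#' stable clustering signal and very general terms of little biological
#' interest.
#'
#' @param catalog An \code{annotation_catalog}.
#' @param network An igraph PPI network, or a character vector of protein
#'   identifiers.
#' @param min_size,max_size Bounds on term size. Defaults 3 and 1000.
#' @param min_coverage Minimum fraction of a term's proteins that must be in
#'   the network. Default 0.5.
#' @return The filtered \code{annotation_catalog}.
#' @export
filter_annotations <- function(catalog, network, min_size = 3, max_size = 1000,
                               min_coverage = 0.5) {
  stopifnot(inherits(catalog, "annotation_catalog"),
            min_size >= 2, min_coverage > 0, min_coverage <= 1)
  vertices <- if (inherits(network, "igraph")) igraph::V(network)$name
              else as.character(network)
  keep <- vapply(catalog$sets, function(s) {
    n <- length(s)
    in_net <- sum(s %in% vertices)
    n >= min_size && n <= max_size &&
      in_net / n >= min_coverage && in_net >= min_size
  }, NA)
  annotation_catalog(catalog$sets[keep],
                     term_names = catalog$term_names[keep],
                     namespace = catalog$namespace[keep],
                     shuffled = catalog$shuffled)
}

#' Shuffle term-protein associations preserving both marginals
#'
#' Generates a null catalog for FDR estimation by repeatedly drawing two
#' term-protein associations uniformly at random and swapping their proteins.
#' A draw is rejected (the attempt is still consumed) when both associations
#' involve the same term, or when either term already annotates the other
#' association's protein; accepted swaps therefore preserve every term's set
#' size and every protein's annotation count exactly, while destroying the
#' biological term-protein relationships.
#'
#' Reproducible under \code{set.seed()}.
#'
#' @param catalog An \code{annotation_catalog}.
#' @param n_swaps Number of swap attempts. Default \code{1000 *
#'   n_associations(catalog)}.
#' @return The shuffled \code{annotation_catalog} (\code{shuffled} flag set).
#' @export
shuffle_annotations <- function(catalog, n_swaps = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (is.null(n_swaps)) n_swaps <- 1000 * n_associations(catalog)
  stopifnot(n_swaps >= 0)
  n_assoc <- n_associations(catalog)
  if (n_assoc < 2L) {
    warning("catalog has fewer than 2 associations; nothing to shuffle")
    out <- catalog
    out$shuffled <- TRUE
    return(out)
  }
  proteins <- unique(unlist(catalog$sets, use.names = FALSE))
  pidx <- seq_along(proteins)
  names(pidx) <- proteins
  sets <- lapply(catalog$sets, function(s) unname(pidx[s]))
  sizes <- lengths(sets)
  assoc_term <- rep.int(seq_along(sets), sizes)
  assoc_prot <- unlist(sets, use.names = FALSE)

  done <- 0L
  chunk <- 500000L
  while (done < n_swaps) {
    k <- min(chunk, n_swaps - done)
    ii <- sample.int(n_assoc, k, replace = TRUE)
    jj <- sample.int(n_assoc, k, replace = TRUE)
    for (q in seq_len(k)) {
      i <- ii[q]; j <- jj[q]
      t1 <- assoc_term[i]; t2 <- assoc_term[j]
      if (t1 == t2) next
      p1 <- assoc_prot[i]; p2 <- assoc_prot[j]
      s1 <- sets[[t1]]; s2 <- sets[[t2]]
      if (any(s2 == p1) || any(s1 == p2)) next
      sets[[t1]] <- c(s1[s1 != p1], p2)
      sets[[t2]] <- c(s2[s2 != p2], p1)
      assoc_prot[i] <- p2
      assoc_prot[j] <- p1
    }
    done <- done + k
  }
  out_sets <- lapply(sets, function(s) proteins[s])
  annotation_catalog(stats::setNames(out_sets, names(catalog$sets)),
                     term_names = catalog$term_names,
                     namespace = catalog$namespace,
                     shuffled = TRUE)
}
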