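#' All-pairs weighted shortest-path distances
#'
#' Computes the exact weighted shortest-path distance between every pair of
#' proteins in a connected, positively weighted PPI network (one single-source
#' run per vertex, equivalent to Floyd--Warshall on positive weights).
#'
#' @param network An igraph network with a positive \code{weight} edge
#'   attribute (see [weight_network()]). Must be connected.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to the
#'   protein identifiers.
#' @export
all_pairs_distances <- function(network) {
  stopifnot(inherits(network, "igraph"))
  w <- igraph::E(network)$weight
  if (is.null(w)) stop("network has no weight attribute; call weight_network() first")
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive and finite")
  if (!igraph::is_connected(network)) {
    stop("network is disconnected; pairwise distances would be infinite")
  }
  d <- igraph::distances(network, weights = w, algorithm = "dijkstra")
  dimnames(d) <- list(igraph::V(network)$name, igraph::V(network)$name)
  d
}

#' Total pairwise distance (TPD) of a protein set
#'
#' The clustering statistic: the sum of weighted shortest-path distances over
#' all unordered pairs of the set, each pair counted once. Small TPD means
#' the proteins sit close together in the (expression-weighted) network.
#'
#' @param dist Distance matrix from [all_pairs_distances()].
#' @param proteins Character vector of protein identifiers (>= 2, all present
#'   in \code{dist}), or integer indices into the matrix.
#' @return The TPD (a single non-negative number).
#' @export
tpd <- function(dist, proteins) {
  if (is.character(proteins)) {
    idx <- match(proteins, rownames(dist))
    if (anyNA(idx)) {
      stop("protein(s) not in distance matrix: ",
           paste(proteins[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(proteins)
  }
  if (length(idx) < 2L) stop("TPD requires at least 2 proteins")
  sum(dist[idx, idx]) / 2
}

#' Monte-Carlo null models of the TPD per set size
#'
#' For each requested set size n, draws \code{n_samples} random sets of n
#' distinct proteins from the eligible pool, computes each sample's TPD, and
#' records the sample mean and standard deviation. Two sampling schemes are
#' supported: uniform (every eligible protein equally likely) and
#' annotation-weighted (sequential draws without replacement with probability
#' proportional to each protein's annotation count, so multiply-annotated
#' proteins — which influence many terms — appear in the null more often).
#' Downstream, the null distribution for size n is approximated by a normal
#' with the recorded moments, which extends significance estimation below the
#' 1/\code{n_samples} Monte-Carlo resolution.
#'
#' Reproducible under \code{set.seed()}.
#'
#' @param dist Distance matrix from [all_pairs_distances()].
#' @param eligible Character vector of proteins that may be sampled
#'   (conventionally the network proteins annotated by at least one term).
#' @param sizes Integer vector of set sizes to model (each >= 2 and <=
#'   \code{length(eligible)}).
#' @param n_samples Number of Monte-Carlo samples per size (>= 2).
#' @param weights Optional named numeric vector of per-protein sampling
#'   weights (e.g. [protein_counts()]); \code{NULL} for uniform sampling.
#'   Every eligible protein must have a positive weight.
#' @param keep_samples Keep the raw sampled TPDs (list, one numeric vector
#'   per size) for diagnostics; off by default.
#' @return An object of class \code{tpd_null_model}: a data frame with
#'   columns \code{size}, \code{mean}, \code{sd}, \code{n_samples},
#'   \code{mode}, plus attribute \code{samples} when requested.
#' @export
build_null_model <- function(dist, eligible, sizes, n_samples = 1e4,
                             weights = NULL, keep_samples = FALSE) {
  idx <- match(eligible, rownames(dist))
  if (anyNA(idx)) {
    stop("eligible protein(s) not in distance matrix: ",
         paste(eligible[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  }
  m <- length(idx)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L)) stop("null-model sizes must be >= 2")
  if (any(sizes > m)) {
    stop("null-model size ", max(sizes), " exceeds the ", m,
         " eligible proteins")
  }
  if (n_samples < 2) stop("n_samples must be >= 2 (standard deviation undefined otherwise)")
  dsub <- dist[idx, idx]
  prob <- NULL
  mode <- "uniform"
  if (!is.null(weights)) {
    prob <- rep(0, m)
    hit <- match(eligible, names(weights))
    prob[!is.na(hit)] <- as.numeric(weights)[hit[!is.na(hit)]]
    if (any(prob <= 0)) {
      stop(sum(prob <= 0), " eligible protein(s) have no positive sampling weight")
    }
    mode <- "weighted"
  }
  rows <- vector("list", length(sizes))
  samples <- if (keep_samples) vector("list", length(sizes)) else NULL
  for (si in seq_along(sizes)) {
    n <- sizes[[si]]
    tpds <- if (n == m) {
      rep(sum(dsub) / 2, n_samples)            # degenerate: only one possible set
    } else if (is.null(prob)) {
      vapply(seq_len(n_samples), function(k) {
        s <- sample.int(m, n)
        sum(dsub[s, s]) / 2
      }, 0)
    } else {
      vapply(seq_len(n_samples), function(k) {
        s <- sample.int(m, n, prob = prob)     # sequential renormalized draws
        sum(dsub[s, s]) / 2
      }, 0)
    }
    rows[[si]] <- data.frame(size = n, mean = mean(tpds), sd = stats::sd(tpds),
                             n_samples = n_samples, mode = mode)
    if (keep_samples) samples[[si]] <- tpds
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tpd_null_model", "data.frame")
  if (keep_samples) {
    names(samples) <- as.character(sizes)
    attr(out, "samples") <- samples
  }
  out
}

#' @export
print.tpd_null_model <- function(x, ...) {
  cat(sprintf("TPD null model (%s sampling): %d set size(s), %g samples each\n",
              x$mode[[1L]], nrow(x), x$n_samples[[1L]]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write / read a TPD null model cache
#'
#' Null models are the expensive part of a run; these helpers serialize them
#' to TSV so they can be reused across runs on the same weighted network. The
#' cache carries a \code{key} comment line (a digest of the weighted edge
#' list) and reading verifies it when a key is supplied.
#'
#' @param null A \code{tpd_null_model}.
#' @param file Path to the TSV cache.
#' @param key Optional cache key, e.g. from [network_digest()].
#' @return \code{write_null_model}: the path, invisibly.
#' @export
write_null_model <- function(null, file, key = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(key)) writeLines(paste0("# key=", key), con)
  utils::write.table(as.data.frame(null), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(file, key = NULL) {
  first <- readLines(file, n = 1L)
  has_key <- startsWith(first, "# key=")
  if (!is.null(key)) {
    stored <- if (has_key) sub("^# key=", "", first) else NA_character_
    if (is.na(stored) || stored != key) {
      stop("null-model cache key mismatch: expected ", key, ", found ",
           if (is.na(stored)) "none" else stored)
    }
  }
  out <- utils::read.delim(file, skip = as.integer(has_key),
                           stringsAsFactors = FALSE)
  class(out) <- c("tpd_null_model", "data.frame")
  out
}

#' Digest of a weighted network, for null-model cache keys
#'
#' @param network An igraph network with a \code{weight} edge attribute.
#' @return An MD5 string over the canonicalized weighted edge list.
#' @export
network_digest <- function(network) {
  ends <- igraph::ends(network, igraph::E(network), names = TRUE)
  a <- pmin(ends[, 1L], ends[, 2L])
  b <- pmax(ends[, 1L], ends[, 2L])
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(ends))
  o <- order(a, b)
  txt <- paste(a[o], b[o], format(w[o], digits = 15), sep = "\t", collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Clustering p-value from the normal approximation
#'
#' Probability, under the size-matched null, of a TPD at least as small as
#' the observed one: the lower tail of a normal with the null's Monte-Carlo
#' mean and standard deviation. When sd is 0 (degenerate null, i.e. the set
#' size equals the eligible pool) the p-value is 1 for TPDs at or above the
#' mean and the smallest positive double otherwise.
#'
#' @param tpd_obs Observed TPD (vectorized).
#' @param mu,sigma Null mean and standard deviation (sigma >= 0).
#' @return p-values in (0, 1).
#' @export
clustering_pvalue <- function(tpd_obs, mu, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  n <- max(length(tpd_obs), length(mu), length(sigma))
  tpd_obs <- rep_len(tpd_obs, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  p <- numeric(n)
  degen <- sigma == 0
  p[degen] <- ifelse(tpd_obs[degen] >= mu[degen], 1, .Machine$double.xmin)
  p[!degen] <- stats::pnorm(tpd_obs[!degen], mean = mu[!degen],
                            sd = sigma[!degen])
  pmax(p, .Machine$double.xmin)
}

#' Score annotation terms for clustering in a weighted network
#'
#' For each catalog term, computes the TPD of its effective protein set (the
#' annotated proteins present in the network) and the normal-approximation
#' p-value from the null model entry matching the effective size.
#'
#' @param dist Distance matrix from [all_pairs_distances()].
#' @param catalog A filtered \code{annotation_catalog} (see
#'   [filter_annotations()]).
#' @param null A \code{tpd_null_model} covering every effective size present.
#' @return A data frame with one row per term: \code{term_id},
#'   \code{term_name}, \code{namespace}, \code{size_total},
#'   \code{size_in_network}, \code{tpd}, \code{p_value}.
#' @export
score_terms <- function(dist, catalog, null) {
  stopifnot(inherits(catalog, "annotation_catalog"),
            inherits(null, "tpd_null_model"))
  vnames <- rownames(dist)
  ids <- names(catalog$sets)
  eff <- lapply(catalog$sets, function(s) match(s[s %in% vnames], vnames))
  n_eff <- lengths(eff)
  null_row <- match(n_eff, null$size)
  if (anyNA(null_row)) {
    bad <- ids[is.na(null_row)][[1L]]
    stop("no null model for effective size ", n_eff[is.na(null_row)][[1L]],
         " (term ", bad, ")")
  }
  tpds <- vapply(eff, function(idx) sum(dist[idx, idx]) / 2, 0)
  data.frame(
    term_id = ids,
    term_name = unname(catalog$term_names[ids]),
    namespace = unname(catalog$namespace[ids]),
    size_total = unname(lengths(catalog$sets)),
    size_in_network = unname(n_eff),
    tpd = unname(tpds),
    p_value = unname(clustering_pvalue(tpds, null$mean[null_row],
                                       null$sd[null_row])),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
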