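#' Empirical FDR at a p-value threshold
#'
#' The false discovery rate at threshold p is the number of shuffled-catalog
#' terms with clustering p-value strictly below p, divided by the number of
#' real terms strictly below p. Because shuffled terms carry no biological
#' signal while preserving term sizes and per-protein annotation counts,
#' their call rate estimates the false-positive content of the real calls.
#'
#' @param real_p Numeric vector of clustering p-values of real terms.
#' @param shuffled_p Numeric vector of clustering p-values of shuffled terms.
#' @param p Threshold(s) at which to evaluate the FDR.
#' @return FDR estimate(s); \code{NaN} (with a warning) where no real term
#'   falls below the threshold.
#' @export
estimate_fdr <- function(real_p, shuffled_p, p) {
  stopifnot(length(real_p) > 0, length(shuffled_p) > 0)
  num <- vapply(p, function(th) sum(shuffled_p < th), 0)
  den <- vapply(p, function(th) sum(real_p < th), 0)
  if (any(den == 0)) {
    warning("FDR undefined at ", sum(den == 0),
            " threshold(s): no real term below them")
  }
  ifelse(den == 0, NaN, num / den)
}

#' Empirical FDR curve over observed p-values
#'
#' Evaluates [estimate_fdr()] at every distinct real p-value (a step
#' function). Each row also carries \code{fdr_incl}, the estimate with the
#' threshold moved infinitesimally above that p-value (counts use \code{<=});
#' this is the per-term FDR reported for a term observed exactly at that
#' p-value. No monotonization is applied by default.
#'
#' @param real_p,shuffled_p Clustering p-values of real and shuffled terms.
#' @param monotone Apply a cumulative-minimum from the largest threshold down,
#'   enforcing a non-increasing curve in p. Default \code{FALSE}.
#' @return A data frame of class \code{fdr_curve}: \code{p} (sorted
#'   evaluation points), \code{n_real}, \code{n_shuffled} (strict counts),
#'   \code{fdr}, and \code{fdr_incl}.
#' @export
fdr_curve <- function(real_p, shuffled_p, monotone = FALSE) {
  stopifnot(length(real_p) > 0, length(shuffled_p) > 0)
  pts <- sort(unique(real_p))
  n_real <- vapply(pts, function(th) sum(real_p < th), 0)
  n_shuf <- vapply(pts, function(th) sum(shuffled_p < th), 0)
  fdr <- ifelse(n_real == 0, NaN, n_shuf / n_real)
  n_real_incl <- vapply(pts, function(th) sum(real_p <= th), 0)
  n_shuf_incl <- vapply(pts, function(th) sum(shuffled_p <= th), 0)
  fdr_incl <- n_shuf_incl / n_real_incl
  if (monotone) {
    ok <- !is.nan(fdr)
    fdr[ok] <- rev(cummin(rev(fdr[ok])))
    fdr_incl <- rev(cummin(rev(fdr_incl)))
  }
  out <- data.frame(p = pts, n_real = n_real, n_shuffled = n_shuf,
                    fdr = fdr, fdr_incl = fdr_incl)
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Operative significance threshold
#'
#' Implements the calling rule: terms are significant up to the largest
#' evaluated p-value threshold whose FDR is under \code{target} (default
#' 0.001); when no threshold achieves that, the point with the smallest FDR
#' strictly above 0 is used instead (the highest confidence the shuffle can
#' certify), unless \code{fallback = FALSE}, in which case \code{NULL} is
#' returned and nothing is called.
#'
#' Thresholds sit infinitesimally above the observed p-values: selection uses
#' the curve's inclusive column, so a candidate threshold at observed p counts
#' the terms at p itself (with \code{use = "strict"} the raw strict-count
#' column is used instead, in which case a lone best term can never certify
#' itself because the count at its own p excludes it).
#'
#' @param curve An \code{fdr_curve}.
#' @param target FDR target in (0, 1). Default 0.001.
#' @param fallback Use the smallest-positive-FDR fallback when no point beats
#'   the target. Default \code{TRUE}.
#' @param use \code{"inclusive"} (default) or \code{"strict"} curve column.
#' @return A list \code{(p, fdr, inclusive)}: the operative threshold, its
#'   FDR, and whether terms at exactly \code{p} are called; or \code{NULL}
#'   (only when \code{fallback = FALSE} finds nothing).
#' @export
operative_threshold <- function(curve, target = 0.001, fallback = TRUE,
                                use = c("inclusive", "strict")) {
  stopifnot(inherits(curve, "fdr_curve"), target > 0, target < 1)
  use <- match.arg(use)
  fdr <- if (use == "inclusive") curve$fdr_incl else curve$fdr
  ok <- !is.nan(fdr)
  if (!any(ok)) stop("all FDR estimates are undefined; increase shuffles or terms")
  hit <- ok & fdr < target
  if (any(hit)) {
    i <- max(which(hit))
    return(list(p = curve$p[[i]], fdr = fdr[[i]], inclusive = use == "inclusive"))
  }
  if (!fallback) return(NULL)
  pos <- ok & fdr > 0
  if (!any(pos)) {
    stop("no positive FDR estimate available; increase shuffles")
  }
  i <- which(pos)[which.min(fdr[pos])]
  list(p = curve$p[[i]], fdr = fdr[[i]], inclusive = use == "inclusive")
}

#' Call significant terms from real and shuffled scores
#'
#' Builds the FDR curve, picks the operative threshold, and returns the real
#' term table augmented with per-term FDR and a significance flag (p-value at
#' or below the operative threshold, which sits just above an observed
#' p-value; see [operative_threshold()]).
#'
#' @param scores Data frame from [score_terms()] for the real catalog.
#' @param shuffled_scores Data frame from [score_terms()] for the shuffled
#'   catalog.
#' @param target FDR target. Default 0.001.
#' @param fallback See [operative_threshold()].
#' @param monotone See [fdr_curve()].
#' @return \code{scores} with columns \code{fdr} (the per-term
#'   \code{fdr_incl}), \code{significant}, plus attributes \code{curve} and
#'   \code{threshold}.
#' @export
call_significant <- function(scores, shuffled_scores, target = 0.001,
                             fallback = TRUE, monotone = FALSE) {
  curve <- fdr_curve(scores$p_value, shuffled_scores$p_value,
                     monotone = monotone)
  thr <- operative_threshold(curve, target = target, fallback = fallback)
  scores$fdr <- curve$fdr_incl[match(scores$p_value, curve$p)]
  scores$significant <- if (is.null(thr)) {
    rep(FALSE, nrow(scores))
  } else if (isTRUE(thr$inclusive)) {
    scores$p_value <= thr$p
  } else {
    scores$p_value < thr$p
  }
  attr(scores, "curve") <- curve
  attr(scores, "threshold") <- thr
  scores
}

#' Contrast expression-weighted and unweighted network results
#'
#' Marks the weighted-network terms that are significant there but absent
#' from the unweighted network's significant set: clustering that only
#' appears once edges are shortened by differential expression, i.e. the
#' dysregulated annotations, as opposed to terms whose proteins are innately
#' clustered in the PPI network.
#'
#' @param weighted Result table from [call_significant()] on the
#'   expression-weighted network.
#' @param unweighted Result table from [call_significant()] on the
#'   all-ones-weight network.
#' @return \code{weighted} with a logical \code{unique_to_weighted} column.
#' @export
contrast_results <- function(weighted, unweighted) {
  sig_unw <- unweighted$term_id[unweighted$significant]
  weighted$unique_to_weighted <- weighted$significant &
    !(weighted$term_id %in% sig_unw)
  weighted
}
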