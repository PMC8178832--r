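#' Read a quantitative expression table
#'
#' Loads a TSV of per-sample protein quantifications (one protein-ID column
#' followed by numeric sample columns) together with a sample-to-condition
#' map, as produced by quantitative proteomics pipelines (e.g. super-SILAC
#' intensities or ratios-to-standard).
#'
#' @param file Path to a tab-separated table with a header row; the first
#'   column holds protein identifiers, remaining columns one sample each.
#' @param conditions Either a named character vector mapping sample IDs to
#'   condition labels, or a path to a two-column TSV (sample, condition).
#' @return An object of class \code{expression_table}: a list with
#'   \code{values} (numeric matrix, proteins x samples) and
#'   \code{conditions} (character vector, one label per sample column).
#' @export
read_expression <- function(file, conditions) {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a protein column and >= 1 sample column")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1L]])
  if (length(conditions) == 1L && file.exists(conditions)) {
    cm <- utils::read.delim(conditions, header = FALSE, stringsAsFactors = FALSE)
    if (tolower(cm[1, 1]) %in% c("sample", "sample_id")) cm <- cm[-1L, , drop = FALSE]
    conditions <- stats::setNames(as.character(cm[[2L]]), as.character(cm[[1L]]))
  }
  expression_table(values, conditions)
}

#' Construct an expression table
#'
#' @param values Numeric matrix of expression values (rows: proteins, with
#'   row names; columns: samples, with column names). Missing values allowed.
#' @param conditions Named character vector mapping sample IDs (names) to
#'   condition labels, or an unnamed vector of labels in column order.
#' @return An \code{expression_table} object.
#' @export
expression_table <- function(values, conditions) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (!is.null(names(conditions))) {
    missing <- setdiff(colnames(values), names(conditions))
    if (length(missing)) {
      stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
    }
    conditions <- unname(conditions[colnames(values)])
  }
  if (length(conditions) != ncol(values)) {
    stop("conditions must label every sample column")
  }
  structure(list(values = values, conditions = as.character(conditions)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("Expression table: %d proteins x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' Per-protein fold-changes between two conditions
#'
#' The fold-change f(v) of a protein is the ratio of its average expression
#' in the numerator condition over its average expression in the denominator
#' condition, with missing values ignored in each mean. Proteins with no
#' usable value in either condition, or a zero denominator mean, are assigned
#' f(v) = 1 (no evidence of differential expression).
#'
#' @param expr An \code{expression_table}.
#' @param numerator,denominator Condition labels to compare.
#' @return A named numeric vector of fold-changes, class
#'   \code{fold_change_map}, one entry per protein in \code{expr}.
#' @export
compute_fold_changes <- function(expr, numerator, denominator) {
  stopifnot(inherits(expr, "expression_table"))
  for (cond in c(numerator, denominator)) {
    if (!cond %in% expr$conditions) stop("condition not in table: ", cond)
  }
  num <- rowMeans(expr$values[, expr$conditions == numerator, drop = FALSE],
                  na.rm = TRUE)
  den <- rowMeans(expr$values[, expr$conditions == denominator, drop = FALSE],
                  na.rm = TRUE)
  f <- num / den
  degenerate <- !is.finite(f) | f <= 0
  if (any(den == 0 & is.finite(num) & num > 0, na.rm = TRUE)) {
    warning("zero denominator mean for ",
            sum(den == 0 & is.finite(num) & num > 0, na.rm = TRUE),
            " protein(s); fold-change set to 1")
  }
  f[degenerate] <- 1
  fold_change_map(f)
}

#' Construct a fold-change map
#'
#' @param f Named numeric vector: protein identifier -> positive fold-change.
#' @return A \code{fold_change_map} (named numeric vector).
#' @export
fold_change_map <- function(f) {
  stopifnot(is.numeric(f), !is.null(names(f)))
  if (any(!is.finite(f)) || any(f <= 0)) stop("fold-changes must be positive and finite")
  structure(f, class = "fold_change_map")
}

#' Read a pre-computed fold-change table
#'
#' Two-column TSV (protein, fold-change); a header row is detected and
#' skipped if the second field is non-numeric.
#'
#' @param file Path to the TSV.
#' @return A \code{fold_change_map}.
#' @export
read_fold_changes <- function(file) {
  tab <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1L, , drop = FALSE]
  fold_change_map(stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]])))
}

#' Dysregulation weight of an interaction
#'
#' Maps the fold-changes of an edge's two endpoint proteins to a weight in
#' (0, 1]: with mean fold-change m = (f1 + f2) / 2, the weight is m when
#' m <= 1 and 1/m otherwise, i.e. min(m, 1/m). Strong up- or down-regulation
#' of the endpoints both shrink the weight, pulling dysregulated interacting
#' proteins closer in the weighted network; unchanged proteins (f = 1) keep
#' weight 1.
#'
#' @param f1,f2 Positive fold-changes of the two endpoints (vectorized).
#' @param mean_type \code{"arithmetic"} (default) or \code{"geometric"} mean
#'   of the two fold-changes.
#' @return Numeric vector of edge weights in (0, 1].
#' @export
edge_weight <- function(f1, f2, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (any(!is.finite(f1)) || any(!is.finite(f2)) || any(f1 <= 0) || any(f2 <= 0)) {
    stop("fold-changes must be positive and finite")
  }
  m <- if (mean_type == "arithmetic") (f1 + f2) / 2 else sqrt(f1 * f2)
  ifelse(m <= 1, m, 1 / m)
}

#' Weight a PPI network by differential expression
#'
#' Attaches a \code{weight} edge attribute: in \code{"weighted"} mode each
#' edge gets [edge_weight()] of its endpoints' fold-changes (proteins absent
#' from the map default to f = 1); in \code{"unweighted"} mode every edge
#' gets weight 1, reducing distances to hop counts. Protein identifiers are
#' matched case-insensitively after trimming.
#'
#' @param network An igraph PPI network (e.g. from [build_network()]).
#' @param fold_changes A \code{fold_change_map}, or \code{NULL} (all f = 1).
#' @param mode \code{"weighted"} or \code{"unweighted"}.
#' @param mean_type Passed to [edge_weight()].
#' @param verbose Report how many quantified proteins matched the network.
#' @return The network with a \code{weight} edge attribute in (0, 1] and a
#'   \code{fold_change} vertex attribute.
#' @export
weight_network <- function(network, fold_changes = NULL,
                           mode = c("weighted", "unweighted"),
                           mean_type = "arithmetic", verbose = FALSE) {
  mode <- match.arg(mode)
  vnames <- igraph::V(network)$name
  f <- rep(1, length(vnames))
  names(f) <- vnames
  if (!is.null(fold_changes) && mode == "weighted") {
    key <- tolower(trimws(names(fold_changes)))
    idx <- match(tolower(trimws(vnames)), key)
    f[!is.na(idx)] <- as.numeric(fold_changes)[idx[!is.na(idx)]]
    if (verbose) {
      message(sprintf("  %d of %d quantified proteins matched the network; %d weighted",
                      sum(!is.na(match(key, tolower(trimws(vnames)))))
                      , length(fold_changes), sum(f != 1)))
    }
  }
  igraph::V(network)$fold_change <- unname(f)
  if (mode == "unweighted") {
    igraph::E(network)$weight <- 1
  } else {
    ends <- igraph::ends(network, igraph::E(network), names = TRUE)
    igraph::E(network)$weight <- edge_weight(f[ends[, 1L]], f[ends[, 2L]],
                                             mean_type = mean_type)
  }
  network$weight_mode <- mode
  network
}
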