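#' Run the end-to-end enrichment pipeline from input files
#'
#' File-level driver around [ppigo()]: reads an interaction file, an
#' annotation file, and either an expression table with a condition map or a
#' pre-computed fold-change table; runs the analysis; and writes the result
#' tables, the null-model caches, and a JSON run manifest (all parameters,
#' the seed, and MD5 digests of the inputs — enough to reproduce any output
#' byte-identically).
#'
#' @param config Named list (or path to a JSON/YAML file holding one) with
#'   fields:
#'   \describe{
#'     \item{network}{path to the interaction file (required).}
#'     \item{network_format}{\code{"biogrid"} (default), \code{"string"}, or
#'       \code{"edges"} (plain two-column TSV with a header).}
#'     \item{taxon}{BioGRID taxon filter, default 9606.}
#'     \item{min_score}{STRING combined-score cutoff, default 400.}
#'     \item{hub_cutoff}{degree cutoff, default 1000.}
#'     \item{annotations}{path to a GMT/TSV annotation file (required).}
#'     \item{expression, conditions, numerator, denominator}{expression TSV,
#'       sample-to-condition map TSV, and the two condition labels; or}
#'     \item{fold_changes}{path to a two-column fold-change TSV.}
#'     \item{null_sampling, n_samples, min_size, max_size, min_coverage,
#'       fdr_target, swap_multiplier, seed}{as in [ppigo()].}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @param verbose Log stage progress. Default \code{TRUE}.
#' @return Invisibly, a list with the \code{ppigo} fit and the written
#'   \code{paths}.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  need <- function(field) {
    if (is.null(config[[field]])) stop("config field missing: ", field)
    config[[field]]
  }
  default <- function(field, value) {
    if (is.null(config[[field]])) value else config[[field]]
  }
  in_paths <- c(network = need("network"), annotations = need("annotations"))
  for (f in c("expression", "conditions", "fold_changes")) {
    if (!is.null(config[[f]]) && !(f == "conditions" && length(config[[f]]) > 1L)) {
      in_paths[[f]] <- config[[f]]
    }
  }
  for (p in in_paths) {
    if (!file.exists(p)) stop("[input] file not found: ", p)
  }
  out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    if (verbose) message("[", name, "]")
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  format <- default("network_format", "biogrid")
  records <- stage("parse network", switch(
    format,
    biogrid = read_biogrid(config$network, taxon = default("taxon", 9606)),
    string = read_string(config$network, min_score = default("min_score", 400)),
    edges = utils::read.delim(config$network, stringsAsFactors = FALSE),
    stop("unknown network_format: ", format)))
  network <- stage("build network",
                   build_network(records,
                                 hub_cutoff = default("hub_cutoff", 1000),
                                 verbose = verbose))

  fold_changes <- NULL
  expression <- NULL
  conditions <- NULL
  if (!is.null(config$fold_changes)) {
    fold_changes <- stage("fold-changes", read_fold_changes(config$fold_changes))
  } else if (!is.null(config$expression)) {
    expression <- stage("expression",
                        read_expression(config$expression, need("conditions")))
    conditions <- c(need("numerator"), need("denominator"))
  } else {
    stop("config needs either fold_changes or expression + conditions")
  }
  annotations <- stage("annotations", read_annotations(config$annotations))

  fit <- stage("enrichment", ppigo(
    network, annotations, fold_changes = fold_changes,
    expression = expression, conditions = conditions,
    null_sampling = default("null_sampling", "weighted"),
    n_samples = default("n_samples", 1e6),
    min_size = default("min_size", 3),
    max_size = default("max_size", 1000),
    min_coverage = default("min_coverage", 0.5),
    fdr_target = default("fdr_target", 0.001),
    swap_multiplier = default("swap_multiplier", 1000),
    seed = default("seed", NULL),
    verbose = verbose))

  paths <- c(weighted = file.path(out_dir, "results_weighted.tsv"),
             unweighted = file.path(out_dir, "results_unweighted.tsv"),
             contrast = file.path(out_dir, "results_contrast.tsv"),
             null_weighted = file.path(out_dir, "null_model_weighted.tsv"),
             null_unweighted = file.path(out_dir, "null_model_unweighted.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage("write outputs", {
    write_tsv(fit$results[setdiff(names(fit$results), "unique_to_weighted")],
              paths[["weighted"]])
    write_tsv(fit$unweighted, paths[["unweighted"]])
    write_tsv(fit$results, paths[["contrast"]])
    write_null_model(fit$null_models$weighted, paths[["null_weighted"]])
    write_null_model(fit$null_models$unweighted, paths[["null_unweighted"]])
    manifest <- list(
      package_version = as.character(utils::packageVersion("ppigo")),
      parameters = fit$params,
      network_format = format,
      inputs = as.list(tools::md5sum(in_paths)),
      n_terms = list(input = fit$n_terms_input, tested = fit$n_terms_tested,
                     shuffled = fit$n_terms_shuffled),
      thresholds = fit$thresholds,
      network_stage_counts = network$stage_counts)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })
  if (verbose) print(fit)
  invisible(list(fit = fit, paths = paths))
}
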