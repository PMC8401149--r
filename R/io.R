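# Cohort CSV round-trip, model serialization, and run manifests.

cohort_columns <- function() {
  c("id", "age", "gender", "height_cm", "weight_kg", "bmi",
    "frailty_status", phenotype_names(), feature_table()$name)
}

#' Write a cohort to CSV
#'
#' Canonical schema: `id`, demographics, `frailty_status`, the five
#' phenotype flags, then the twelve feature columns in [feature_table()]
#' order.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(cohort_columns(), names(cohort))
  utils::write.csv(cohort[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Accepts feature columns under canonical snake_case names or the display
#' names, in any order; the canonical order is restored. Rows violating the
#' Fried consistency invariant (`frailty_status` must equal the indicator of
#' at least one phenotype flag) or with out-of-range feature values
#' (negative counts/durations; posture percentages outside [0, 100] or
#' summing above 100, with a small numeric tolerance) are dropped with a
#' row-numbered warning.
#'
#' @param path CSV file path.
#' @return A `frail_cohort` data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tab <- feature_table()
  # canonicalize any display-name feature headers
  nm <- names(raw)
  m <- match(nm, tab$display)
  nm[!is.na(m)] <- tab$name[m[!is.na(m)]]
  names(raw) <- nm
  required <- cohort_columns()
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stopf("cohort file is missing column(s): %s", paste(missing, collapse = ", "))
  }
  raw <- raw[, required]
  flags <- as.matrix(raw[, phenotype_names()])
  bad_label <- raw$frailty_status != as.integer(rowSums(flags) >= 1L)
  feat <- as.matrix(raw[, tab$name])
  bad_neg <- rowSums(feat < -1e-9) > 0L
  post <- feat[, posture_features(), drop = FALSE]
  bad_post <- rowSums(post > 100 + 1e-6) > 0L | rowSums(post) > 100 + 1e-6
  bad <- which(bad_label | bad_neg | bad_post)
  if (length(bad) > 0L) {
    warnf("dropping %d invalid row(s): %s",
          length(bad), paste(utils::head(bad, 20L), collapse = ", "))
    raw <- raw[-bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stopf("no valid rows in %s", path)
  rownames(raw) <- NULL
  class(raw) <- c("frail_cohort", "data.frame")
  raw
}

#' Serialize a logistic model to JSON
#'
#' @param model A `frail_logit`.
#' @param path Output path; when NULL the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "frail_logit"))
  doc <- list(feature_names = model$feature_names,
              beta0 = model$beta0, betas = as.list(model$betas),
              standardization = if (is.null(model$center)) NULL else
                list(center = as.list(model$center),
                     scale = as.list(model$scale)),
              converged = model$converged,
              n_iterations = model$n_iterations,
              separation = model$separation)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a logistic model from JSON
#' @param path File written by [write_model_json()].
#' @return A `frail_logit`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  betas <- unlist(doc$betas)
  ctr <- scl <- NULL
  if (!is.null(doc$standardization)) {
    ctr <- unlist(doc$standardization$center)
    scl <- unlist(doc$standardization$scale)
  }
  b_std <- if (is.null(scl)) betas else betas * scl
  b0_std <- if (is.null(scl)) doc$beta0 else doc$beta0 + sum(b_std * ctr / scl)
  structure(list(feature_names = doc$feature_names,
                 beta0 = doc$beta0, betas = betas,
                 beta0_std = b0_std, betas_std = b_std,
                 center = ctr, scale = scl,
                 converged = isTRUE(doc$converged),
                 n_iterations = doc$n_iterations %||% 0L,
                 separation = isTRUE(doc$separation)),
            class = "frail_logit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline run configuration
#'
#' @param seed Integer seed for every random stage.
#' @param B Number of bootstrap pairs (default 2000, the published scale).
#' @param criterion Elimination criterion (see [run_rfe()]).
#' @param l_stop Last-loop active feature count.
#' @param threshold Classification threshold in (0, 1).
#' @param auc_band Acceptable AUC band for subset selection.
#' @param cohort Path to a cohort CSV, or `"synthetic"`.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, B = 2000L,
                       criterion = "leave_one_out", l_stop = 2L,
                       threshold = 0.5, auc_band = c(0.7, 0.8),
                       cohort = "synthetic", out_dir = ".") {
  if (!is_count(B, 1L)) stopf("B must be a positive integer")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (auc_band[1] >= auc_band[2]) stopf("auc_band lower must be below upper")
  structure(list(seed = as.integer(seed), B = as.integer(B),
                 criterion = criterion, l_stop = as.integer(l_stop),
                 threshold = threshold, auc_band = auc_band,
                 cohort = cohort, out_dir = out_dir),
            class = "run_config")
}

#' Assemble a run report
#'
#' Writes every provided table as CSV and a JSON manifest carrying the
#' configuration echo, seed, software version, and any fit/skip counters.
#' Emitted tables are re-readable by the pipeline's own readers.
#'
#' @param config A [run_config()].
#' @param tables Named list of data.frames, written as `<name>.csv`.
#' @param extra Named list merged into the manifest (e.g. `fit_count`).
#' @return Path of the manifest file, invisibly.
#' @export
assemble_report <- function(config, tables = list(), extra = list()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    written <- c(written, basename(f))
  }
  manifest <- c(list(package = "actifrail",
                     version = as.character(utils::packageVersion("actifrail")),
                     config = unclass(config),
                     tables = written),
                extra)
  mf <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), mf)
  invisible(mf)
}

# Render a proportion-scale metric table as percentages with one decimal,
# the reporting convention of the published tables.
format_metric_table <- function(df) {
  for (col in intersect(c("mean", "lower", "upper"), names(df))) {
    df[[paste0(col, "_pct")]] <- round(100 * df[[col]], 1L)
  }
  df
}
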