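#' Default pipeline configuration
#'
#' Nested list mirroring every stage of the analysis chain: cohort groups,
#' excitation, disturbances, spectral window, coherence QC, statistics, ROC
#' and machine-learning settings, and the master seed. All randomness is
#' controlled by explicit seeds so that every artifact is reconstructible
#' from the configuration alone.
#'
#' @param seed Master seed.
#' @return A named list of class `fot_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    schema_version = 1L,
    seed = as.integer(seed),
    # the group-size key is `n_subjects` (never `n`: YAML 1.1 parses a bare
    # `n` key as the boolean FALSE)
    groups = lapply(purrr::transpose(default_groups()), function(g) {
      names(g)[names(g) == "n"] <- "n_subjects"
      g
    }),
    n_exams = 3L,
    excitation = list(component_freqs = seq(4, 32, by = 2), peak_to_peak = 2,
                      fs = 1024, duration = 16, phase_seed = 1L),
    noise = list(breathing_freq = 0.25, breathing_flow_amplitude = 0.4,
                 pressure_noise_sd = 0.02, flow_noise_sd = 0.01),
    window = list(block_len = 4096L, overlap = 0.5, taper = "hann",
                  detrend = "linear"),
    qc = list(coherence_min = 0.9),
    stats = list(features = c("r0", "rm", "r4", "s", "xm", "fr", "cdyn", "z4"),
                 alpha = 0.05),
    roc = list(features = c("r0", "rm", "r4", "s", "xm", "fr", "cdyn", "z4"),
               positive_group = "AE", negative_group = "control"),
    ml = list(classifier = "parzen", search = "exhaustive",
              features = c("r0", "rm", "r4", "s", "xm", "fr", "cdyn", "z4"),
              cv = list(scheme = "loocv", k = 10L, stratified = TRUE),
              positive_group = "AE", negative_group = "control")
  ), class = "fot_config")
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the expected schema and value bounds,
#' reporting the offending key on failure.
#'
#' @param config A configuration list.
#' @return The validated config (invisibly classed `fot_config`).
#' @export
validate_config <- function(config) {
  need <- c("seed", "groups", "excitation", "noise", "window", "qc",
            "stats", "roc", "ml")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    abort(paste0("Config is missing section(s): ", paste(missing, collapse = ", ")),
          class = "oscillab_config_error")
  }
  check <- function(ok, key, msg) {
    if (!ok) abort(paste0("Invalid config at `", key, "`: ", msg),
                   class = "oscillab_config_error")
  }
  check(is.numeric(config$seed) && length(config$seed) == 1, "seed", "must be one integer")
  qc <- config$qc$coherence_min
  check(is.numeric(qc) && qc >= 0 && qc <= 1, "qc.coherence_min", "must lie in [0, 1]")
  check(is.numeric(config$window$overlap) && config$window$overlap >= 0 &&
          config$window$overlap < 1, "window.overlap", "must lie in [0, 1)")
  check(config$window$taper %in% c("hann", "rectangular"), "window.taper",
        "must be 'hann' or 'rectangular'")
  check(config$window$detrend %in% c("linear", "mean", "none"), "window.detrend",
        "must be 'linear', 'mean' or 'none'")
  for (g in config$groups) {
    size <- g$n_subjects %||% g$n
    check(is.numeric(size) && length(size) == 1 && size > 0, "groups.n_subjects",
          "each group needs a positive `n_subjects`")
  }
  check(config$ml$classifier %in% c("parzen", "svm_linear", "svm_rbf", "knn",
                                    "random_forest", "adaboost_tree"),
        "ml.classifier", "unknown classifier")
  check(config$ml$cv$scheme %in% c("kfold", "loocv"), "ml.cv.scheme",
        "must be 'kfold' or 'loocv'")
  # excitation bounds are enforced by excitation_spec()
  do.call(excitation_spec, config$excitation)
  do.call(noise_spec, config$noise)
  invisible(structure(config, class = "fot_config"))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file, merges it over [default_config()] (so partial
#' configurations are allowed) and validates the result.
#'
#' @param path Path to a YAML file.
#' @return A validated `fot_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merged <- merge_config(unclass(default_config()), user)
  validate_config(merged)
  structure(merged, class = "fot_config")
}

# Recursive merge of a partial user config over the defaults. Named lists
# merge key by key; unnamed lists (e.g. the `groups` sequence) and scalars
# replace the default wholesale.
merge_config <- function(base, user) {
  named <- function(x) is.list(x) && length(x) > 0 &&
    !is.null(names(x)) && all(names(x) != "")
  if (!named(base) || !named(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (nm %in% names(base)) merge_config(base[[nm]], user[[nm]])
                  else user[[nm]]
  }
  base
}

config_groups_tbl <- function(config) {
  purrr::map_dfr(config$groups, function(g) {
    names(g)[names(g) == "n_subjects"] <- "n"
    do.call(group_config, g)
  })
}

#' Run the full simulation-to-decision pipeline
#'
#' Executes the whole chain from one configuration: simulate the cohort's
#' ground-truth models and forced-oscillation records, estimate impedance
#' with coherence QC, extract the eight oscillometry parameters per
#' subject, compare them across groups, run per-feature ROC analyses
#' between the configured positive and reference groups, and evaluate the
#' machine-learning decision-support layer. Records are synthesized and
#' reduced subject-by-subject, so memory stays bounded. Idempotent given
#' the configuration.
#'
#' @param config A validated configuration (see [default_config()],
#'   [read_config()]).
#' @param out_dir Optional directory; when given, the feature table, group
#'   statistics, ROC summaries, ML report and a JSON manifest (config hash,
#'   seeds, counts) are written there as CSV/JSON.
#' @return A list of class `fot_pipeline_result` with elements `cohort`
#'   (truth table), `features`, `stats`, `roc`, `ml`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  excitation <- do.call(excitation_spec, config$excitation)
  noise <- do.call(noise_spec, config$noise)
  window <- do.call(window_spec, config$window)
  groups <- config_groups_tbl(config)

  cohort <- generate_cohort(groups, master_seed = config$seed,
                            n_exams = config$n_exams %||% 3L,
                            excitation = excitation, noise = noise,
                            keep_records = FALSE)
  features <- cohort_features(cohort, window = window,
                              coherence_min = config$qc$coherence_min)

  stats_res <- purrr::map(config$stats$features, function(f) {
    compare_groups(features, f, alpha = config$stats$alpha)
  })
  names(stats_res) <- config$stats$features
  stats_tbl <- purrr::map_dfr(stats_res, glance)

  roc_res <- purrr::map(config$roc$features, function(f) {
    roc_analysis(features, f, positive_group = config$roc$positive_group,
                 negative_group = config$roc$negative_group)
  })
  names(roc_res) <- config$roc$features
  roc_tbl <- purrr::map_dfr(roc_res, function(r) r$summary)

  ml_data <- dplyr::filter(
    features,
    .data$group %in% c(config$ml$positive_group, config$ml$negative_group)
  )
  spec <- classifier_spec(config$ml$classifier)
  cv <- cv_spec(scheme = config$ml$cv$scheme, k = config$ml$cv$k %||% 10L,
                stratified = config$ml$cv$stratified %||% TRUE,
                seed = config$seed)
  ml_res <- if (identical(config$ml$search, "exhaustive")) {
    exhaustive_search(spec, ml_data, config$ml$features, cv = cv,
                      positive = config$ml$positive_group)
  } else {
    cross_validate(spec, ml_data, config$ml$features, cv = cv,
                   positive = config$ml$positive_group)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oscillab")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_subjects = nrow(cohort),
    n_records = nrow(cohort) * (config$n_exams %||% 3L),
    n_groups = nrow(groups),
    n_features_extracted = sum(features$n_exams_used > 0)
  )

  result <- structure(
    list(config = config, cohort = cohort, features = features,
         stats = stats_res, stats_summary = stats_tbl,
         roc = roc_res, roc_summary = roc_tbl,
         ml = ml_res, manifest = manifest),
    class = "fot_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.fot_pipeline_result <- function(x, ...) {
  cat("<fot_pipeline_result>", x$manifest$n_subjects, "subjects,",
      x$manifest$n_records, "records\n")
  cat("  ROC summary:\n")
  print(x$roc_summary[, c("feature", "auc", "band", "adequate", "se", "sp")])
  ml <- if (inherits(x$ml, "fot_search_result")) x$ml$best else x$ml
  cat(sprintf("  ML (%s): AUC = %.3f, Se = %.1f%%, Sp = %.1f%%\n",
              ml$classifier$name, ml$auc, ml$se, ml$sp))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' @param result A `fot_pipeline_result`.
#' @param out_dir Target directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(result$cohort, -dplyr::any_of("records")),
                   file.path(out_dir, "cohort_truth.csv"))
  readr::write_csv(result$features, file.path(out_dir, "features.csv"))
  readr::write_csv(result$stats_summary, file.path(out_dir, "group_stats.csv"))
  readr::write_csv(result$roc_summary, file.path(out_dir, "roc_summary.csv"))
  ml <- if (inherits(result$ml, "fot_search_result")) result$ml$best else result$ml
  jsonlite::write_json(
    c(result$manifest,
      list(ml = list(classifier = ml$classifier$name,
                     features = ml$features, auc = ml$auc,
                     se = ml$se, sp = ml$sp))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Write / read a pressure-flow record as CSV
#'
#' Records are stored as plain CSV with columns `t_s`, `p_cmh2o`, `q_lps`;
#' generation metadata (seed, true model, specs) travels in a JSON sidecar
#' next to the CSV.
#'
#' @param record A `fot_record`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fot_record <- function(record, path) {
  readr::write_csv(tibble::as_tibble(record), path)
  meta <- attr(record, "meta")
  if (!is.null(meta)) {
    side <- list(
      seed = meta$seed,
      model = meta$model[c("variant", "R", "I", "C", "S")],
      excitation = meta$excitation[c("component_freqs", "peak_to_peak", "fs",
                                     "duration", "phase_seed")],
      noise = unclass(meta$noise)
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @describeIn write_fot_record Read a record CSV back as a `fot_record`.
#' @param path CSV path.
#' @export
read_fot_record <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  stopifnot(all(c("t_s", "p_cmh2o", "q_lps") %in% names(out)))
  class(out) <- c("fot_record", class(out))
  out
}
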