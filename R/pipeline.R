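#' Study configuration
#'
#' A single structured configuration drives the end-to-end pipeline.
#' All randomness flows from the named seeds; no global random state is
#' consulted.
#'
#' @param source `"table"` (fixture gait table sampled directly) or
#'   `"landmarks"` (fixture landmark walks piped through preprocessing
#'   and kinematics).
#' @param fixture A [fixture_spec()] describing the emulated cohort.
#' @param constraints A [constraint_set()] for generation-time
#'   validation.
#' @param grid A [model_grid()] for both evaluation phases.
#' @param preprocess A [preprocess_config()].
#' @param kinematics A [kinematics_config()] (landmark source only).
#' @param max_retries Constraint-validation retry budget.
#' @param bins Hellinger bin count.
#' @param seeds Named list of integer seeds: `fixture`, `fit`, `sample`,
#'   `split`, `train`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(source = c("table", "landmarks"),
                         fixture = fixture_spec(),
                         constraints = gait_constraints(),
                         grid = model_grid(),
                         preprocess = preprocess_config(),
                         kinematics = kinematics_config(),
                         max_retries = 10,
                         bins = 30,
                         seeds = list(fixture = 101, fit = 202,
                                      sample = 303, split = 404,
                                      train = 505)) {
  source <- match.arg(source)
  needed <- c("fixture", "fit", "sample", "split", "train")
  missing_seeds <- setdiff(needed, names(seeds))
  if (length(missing_seeds)) {
    stop("seeds must name: ", paste(missing_seeds, collapse = ", "),
         call. = FALSE)
  }
  structure(list(source = source, fixture = fixture,
                 constraints = constraints, grid = grid,
                 preprocess = preprocess, kinematics = kinematics,
                 max_retries = max_retries, bins = bins, seeds = seeds),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognized top-level keys (all optional) override the defaults of
#' [study_config()]: `source`, `seeds`, `max_retries`, `bins`, plus
#' nested `fixture`, `grid`, `preprocess` and `constraints` (a list of
#' `{a, b, cmp, rho}` entries).
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$source)) args$source <- raw$source
  if (!is.null(raw$seeds)) args$seeds <- raw$seeds
  if (!is.null(raw$max_retries)) args$max_retries <- raw$max_retries
  if (!is.null(raw$bins)) args$bins <- raw$bins
  if (!is.null(raw$fixture)) args$fixture <- do.call(fixture_spec, raw$fixture)
  if (!is.null(raw$grid)) args$grid <- do.call(model_grid, raw$grid)
  if (!is.null(raw$preprocess)) {
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$constraints)) {
    args$constraints <- do.call(constraint_set, raw$constraints)
  }
  do.call(study_config, args)
}

# landmark-source path: simulate walks, preprocess, run the kinematics
fixture_real_table <- function(config) {
  spec <- config$fixture
  if (config$source == "table") {
    return(simulate_gait_table(spec, seed = config$seeds$fixture))
  }
  cohort <- simulate_cohort(spec, seed = config$seeds$fixture)
  lens <- fixture_entity_lengths(spec)
  tabs <- lapply(seq_len(nrow(cohort)), function(i) {
    seq <- simulate_landmark_walk(cohort[i, ], spec,
                                  seed = config$seeds$fixture + i,
                                  duration = lens[i] / spec$fps)
    seq <- preprocess_landmarks(seq, config$preprocess)
    compute_gait_table(seq, cohort[i, ], config$kinematics)
  })
  do.call(rbind, tabs)
}

#' Run the full study pipeline
#'
#' Executes, in order: fixture generation (or a user-provided real
#' table), outlier preprocessing, metadata derivation, synthesizer fit,
#' constraint-validated generation, fidelity scoring, TRTR and TSTR
#' evaluation, and comparison. Any stage failure aborts with the stage
#' name attached. When `out_dir` is given, all artifacts (tables as CSV,
#' reports and a provenance record as JSON) are written there.
#'
#' @param config A [study_config()].
#' @param real Optional real gait table; when `NULL` the fixture
#'   generator supplies it.
#' @param out_dir Optional output directory.
#' @return A list of class `study_result`: `real`, `synthetic`,
#'   `fidelity`, `trtr`, `tstr`, `comparison`, `constraint_report`,
#'   `config`.
#' @export
run_study <- function(config = study_config(), real = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(real)) {
    real <- stage("fixture", fixture_real_table(config))
  }
  real <- stage("preprocess", preprocess_gait_table(real, config$preprocess))
  metadata <- stage("metadata", derive_metadata(real))
  model <- stage("fit", fit_synthesizer(real, metadata,
                                        seed = config$seeds$fit))
  synthetic <- stage("generate", generate_validated(
    model, config$constraints, max_retries = config$max_retries,
    seed = config$seeds$sample))
  fid <- stage("fidelity", fidelity_report(real, synthetic, metadata,
                                           bins = config$bins))
  trtr <- stage("trtr", run_trtr(real, config$grid,
                                 seed = config$seeds$split))
  tstr <- stage("tstr", run_tstr(synthetic, real, config$grid,
                                 seed = config$seeds$train))
  comparison <- stage("compare", compare_reports(trtr, tstr))

  result <- structure(
    list(real = real, synthetic = synthetic, fidelity = fid,
         trtr = trtr, tstr = tstr, comparison = comparison,
         constraint_report = attr(synthetic, "constraint_report"),
         config = config),
    class = "study_result"
  )
  if (!is.null(out_dir)) write_study(result, out_dir)
  result
}

# serialize every artifact plus a provenance record
write_study <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gait_table(result$real, file.path(out_dir, "real.csv"))
  write_gait_table(result$synthetic, file.path(out_dir, "synthetic.csv"))
  fid <- result$fidelity
  jsonlite::write_json(
    list(column_shapes = fid$column_shapes, pair_trends = fid$pair_trends,
         overall = fid$overall, columns = fid$columns,
         hellinger = as.list(fid$hellinger),
         hellinger_overall = fid$hellinger_overall,
         hellinger_bins = fid$hellinger_bins),
    file.path(out_dir, "fidelity.json"), auto_unbox = TRUE, digits = NA)
  report_json <- function(rep) {
    list(mode = rep$mode, metrics = unclass(rep$metrics),
         best_params = rep$best_params,
         shap = as.list(rep$shap$mean_abs_shap),
         shap_base = rep$shap$base_value,
         n_train = rep$n_train, n_test = rep$n_test, seed = rep$seed)
  }
  jsonlite::write_json(
    list(trtr = report_json(result$trtr), tstr = report_json(result$tstr),
         comparison = list(metrics = result$comparison$metrics,
                           shap = result$comparison$shap)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seeds = result$config$seeds,
         source = result$config$source,
         constraints = as.data.frame(result$config$constraints),
         constraint_report = result$constraint_report$results,
         attempts = attr(result$synthetic, "attempts"),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("gaitsynth"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  real rows: %d | synthetic rows: %d\n",
              nrow(x$real), nrow(x$synthetic)))
  cat(sprintf("  fidelity overall: %.4f | Hellinger: %.4f\n",
              x$fidelity$overall, x$fidelity$hellinger_overall))
  cat(sprintf("  TRTR R2 %.4f vs TSTR R2 %.4f\n",
              x$trtr$metrics$r2, x$tstr$metrics$r2))
  invisible(x)
}
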