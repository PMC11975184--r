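#' Configure the end-to-end optimization pipeline
#'
#' Bundles the knobs of every stage: dataset generation, cleaning,
#' feature-selection audit, train/test split, the final surrogate, and the
#' screening/validation trial.  The configuration round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param seed Global seed; it determines every downstream seed.
#' @param design_kind Design label for [build_design()] (default
#'   \code{"FULL_58"}).
#' @param sim_params [simulator_params()] for data generation and
#'   ground-truth validation.
#' @param flag_fraction Fraction of daily samples given QC flags.
#' @param selection_threshold Feature-importance threshold.
#' @param excluded_features Features excluded a priori from selection.
#' @param train_fraction,split_unit Train/test split controls.
#' @param final_spec [model_spec()] of the production surrogate.
#' @param tune If TRUE, run [tune_hyperparameters()] over
#'   \code{tuning_space} and use the winner instead of \code{final_spec}.
#' @param tuning_space Optional list of specs for tuning.
#' @param m_candidates Screening candidates (default 1e5 here; raise to 1e6
#'   for a full-scale trial).
#' @param titer_threshold Screening titer filter, g/L.
#' @param pool,picks,titer_picks Proposal-selection controls.
#' @param ph_shift_value pH applied after sampled shift days.
#' @param use_selected_features If TRUE, train the surrogate only on the
#'   features chosen by the selection stage; default FALSE (all nine
#'   canonical inputs, matching the reference workflow's final input list).
#' @param out_dir Optional directory; when set, stage artifacts are
#'   persisted there (runs, points, reports) as JSON/CSV.
#'
#' @return An object of class \code{cho_pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, design_kind = "FULL_58",
                            sim_params = simulator_params(),
                            flag_fraction = 0.025,
                            selection_threshold = 0.1,
                            excluded_features = character(0),
                            train_fraction = 0.8,
                            split_unit = "run",
                            final_spec = model_spec("feedforward_net",
                                                    hidden_layers = c(100L, 50L, 25L, 50L, 100L),
                                                    alpha = 0.1, learning_rate = 0.01,
                                                    max_epochs = 8000L, patience = 800L),
                            tune = FALSE, tuning_space = NULL,
                            m_candidates = 1e5, titer_threshold = 4.6,
                            pool = 10L, picks = 4L, titer_picks = 5L,
                            ph_shift_value = 7.4,
                            use_selected_features = FALSE,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "cho_pipeline_config"
  cfg
}

#' Read and write pipeline configurations as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return \code{write_config}: the path, invisibly; \code{read_config}:
#'   the reconstructed \code{cho_pipeline_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cho_pipeline_config"))
  plain <- unclass(config)
  plain$sim_params <- unclass(plain$sim_params)
  plain$final_spec <- unclass(plain$final_spec)
  plain$tuning_space <- if (!is.null(plain$tuning_space)) lapply(plain$tuning_space, unclass)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$sim_params <- do.call(simulator_params, plain$sim_params)
  fs <- plain$final_spec
  plain$final_spec <- model_spec(fs$family, components = fs$components, trees = fs$trees,
                                 hidden_layers = fs$hidden_layers, alpha = fs$alpha,
                                 learning_rate = fs$learning_rate,
                                 max_epochs = fs$max_epochs, tol = fs$tol)
  if (!is.null(plain$tuning_space)) {
    plain$tuning_space <- lapply(plain$tuning_space, function(fs) {
      model_spec(fs$family, components = fs$components, trees = fs$trees,
                 hidden_layers = fs$hidden_layers, alpha = fs$alpha,
                 learning_rate = fs$learning_rate, max_epochs = fs$max_epochs,
                 tol = fs$tol)
    })
  }
  plain$excluded_features <- as.character(unlist(plain$excluded_features))
  do.call(pipeline_config, plain)
}

#' Run the full optimization loop
#'
#' Executes, in order: simulate the design; persist/validate the run
#' records (when \code{out_dir} is set); flatten to the point table; clean
#' flagged points; run the feature-selection audit; split train/test; fit
#' (optionally tune) the surrogate; screen the candidate space; select
#' diverse proposals; validate them against the ground-truth simulator; and
#' assemble the headline report (best validated titer vs STD, percent
#' increase, prediction deviation).  Every stage output carries the seed
#' that produced it; a fixed config yields a bit-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return A list of class \code{cho_pipeline_result} with elements
#'   \code{dataset_summary}, \code{feature_selection}, \code{split_sizes},
#'   \code{surrogate}, \code{test_r2}, \code{screening_summary},
#'   \code{day12_dominance}, \code{proposals}, \code{validation},
#'   \code{headline} and \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cho_pipeline_config"))
  seeds <- derive_seeds(config$seed, 8L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_choopt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  design <- stage("design", build_design(config$design_kind))
  runs <- stage("simulate", generate_dataset(design, config$sim_params,
                                             seed = seeds[1], flag_fraction = config$flag_fraction))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stage("store", write_runs(runs, file.path(config$out_dir, "runs.ndjson")))
  }
  points <- stage("flatten", flatten_to_points(runs))
  n_raw <- nrow(points)
  cleaned <- stage("clean", suppressMessages(clean_points(points)))

  selection <- stage("feature_selection", iterative_feature_selection(
    cleaned, candidate_features = input_features(), target = "titer_at_t",
    threshold = config$selection_threshold, seed = seeds[2],
    excluded_a_priori = config$excluded_features))
  features <- if (config$use_selected_features && length(selection$selected) >= 2L) {
    selection$selected
  } else {
    input_features()
  }

  split <- stage("split", split_train_test(cleaned, config$train_fraction,
                                           unit = config$split_unit, seed = seeds[3]))
  spec <- config$final_spec
  tuning <- NULL
  if (isTRUE(config$tune) && length(config$tuning_space) > 0L) {
    tuning <- stage("tune", tune_hyperparameters(split$train, config$tuning_space,
                                                 seed = seeds[4]))
    spec <- tuning$best
  }
  surrogate <- stage("train", fit_surrogate(split$train, spec, seed = seeds[5],
                                            features = features))
  test_pred <- stage("evaluate", predict_kpis(surrogate, split$test))
  test_r2 <- r2_score(as.matrix(split$test[, kpi_names()]),
                      as.matrix(test_pred[, kpi_names()]))

  space <- stage("candidates", candidate_space(split$train, m = config$m_candidates,
                                               ph_shift_value = config$ph_shift_value))
  candidates <- stage("candidates", generate_candidates(space, seed = seeds[6]))
  screening <- stage("screen", screen_candidates(surrogate, candidates,
                                                 threshold = config$titer_threshold))
  proposals <- stage("select", select_proposals(screening, scaler = surrogate$input_scaler,
                                                pool = config$pool, picks = config$picks,
                                                titer_picks = config$titer_picks))
  validation <- stage("validate", validate_in_silico(
    proposals, truth_params = config$sim_params, seed = seeds[7],
    ph_shift_value = config$ph_shift_value))

  vt <- validation$table
  best <- vt[which.max(vt$validated_titer), ]
  top_titer <- vt[vt$block == "titer_at_t", ]
  headline <- list(
    std_validated_titer = unname(validation$std["titer_at_t"]),
    best_validated_titer = best$validated_titer,
    best_block = best$block,
    titer_increase_abs = best$validated_titer - unname(validation$std["titer_at_t"]),
    titer_increase_pct = best$titer_change_vs_std_pct,
    prediction_deviation = best$titer_deviation,
    prediction_deviation_pct = 100 * best$titer_deviation / best$predicted_titer,
    median_top_titer_validated = stats::median(top_titer$validated_titer),
    median_top_titer_increase_pct = stats::median(top_titer$titer_change_vs_std_pct)
  )

  result <- list(
    dataset_summary = list(n_runs = length(runs), n_points = n_raw,
                           n_flagged = n_raw - nrow(cleaned), n_clean = nrow(cleaned)),
    feature_selection = selection,
    split_sizes = c(train = nrow(split$train), test = nrow(split$test)),
    tuning = tuning,
    surrogate = surrogate,
    test_r2 = test_r2,
    screening_summary = list(n_candidates = screening$n_candidates,
                             n_survivors = screening$n_survivors,
                             survivor_fraction = screening$survivor_fraction,
                             threshold = screening$threshold),
    day12_dominance = day12_dominance(screening),
    proposals = proposals,
    validation = validation,
    headline = headline,
    config = config
  )
  class(result) <- "cho_pipeline_result"

  if (!is.null(config$out_dir)) {
    write_points(cleaned, file.path(config$out_dir, "points.csv"))
    utils::write.csv(proposals, file.path(config$out_dir, "proposals.csv"), row.names = FALSE)
    utils::write.csv(vt, file.path(config$out_dir, "validation.csv"), row.names = FALSE)
    jsonlite::write_json(list(dataset = result$dataset_summary,
                              screening = result$screening_summary,
                              day12_dominance = result$day12_dominance,
                              test_r2 = test_r2, headline = headline),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.cho_pipeline_result <- function(x, ...) {
  d <- x$dataset_summary
  cat(sprintf("<pipeline> %d runs -> %d points (%d flagged) | test R2 %.3f\n",
              d$n_runs, d$n_points, d$n_flagged, x$test_r2))
  s <- x$screening_summary
  cat(sprintf("  screening: %d/%d survivors > %.1f g/L; day-12 dominance %.0f%%\n",
              s$n_survivors, s$n_candidates, s$threshold, 100 * x$day12_dominance))
  h <- x$headline
  cat(sprintf("  best validated titer %.2f g/L vs STD %.2f (%+.1f%%); prediction off by %.2f g/L\n",
              h$best_validated_titer, h$std_validated_titer, h$titer_increase_pct,
              h$prediction_deviation))
  invisible(x)
}

#' Predicted / validated / standard KPI comparison report
#'
#' Renders the headline arithmetic of a validation campaign for one
#' proposed condition: the absolute and percent deviation of the validated
#' value from the prediction (denominator: the predicted value), and the
#' absolute and percent increase of the validated value over the validated
#' standard (denominator: the standard).
#'
#' @param predicted,validated,std_validated Named numeric vectors sharing
#'   KPI names (any subset of KPIs; titer alone is enough for the headline
#'   numbers).
#' @return Data frame with one row per KPI: \code{kpi}, \code{predicted},
#'   \code{validated}, \code{std_validated}, \code{deviation_abs},
#'   \code{deviation_pct}, \code{increase_abs}, \code{increase_pct}.
#' @examples
#' validation_report(predicted = c(titer = 4.71), validated = c(titer = 4.65),
#'                   std_validated = c(titer = 3.15))
#' @export
validation_report <- function(predicted, validated, std_validated) {
  kpis <- names(validated)
  if (is.null(kpis) || is.null(names(predicted)) || is.null(names(std_validated))) {
    stop_choopt("validation_report: inputs must be named vectors")
  }
  missing <- setdiff(kpis, intersect(names(predicted), names(std_validated)))
  if (length(missing) > 0L) {
    stop_choopt("validation_report: missing KPI(s): %s", paste(missing, collapse = ", "))
  }
  data.frame(
    kpi = kpis,
    predicted = unname(predicted[kpis]),
    validated = unname(validated[kpis]),
    std_validated = unname(std_validated[kpis]),
    deviation_abs = unname(abs(predicted[kpis] - validated[kpis])),
    deviation_pct = unname(100 * abs(predicted[kpis] - validated[kpis]) / predicted[kpis]),
    increase_abs = unname(validated[kpis] - std_validated[kpis]),
    increase_pct = unname(100 * (validated[kpis] - std_validated[kpis]) / std_validated[kpis]),
    stringsAsFactors = FALSE
  )
}
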