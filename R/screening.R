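#' Define the in-silico candidate space
#'
#' The screening trial draws candidate process settings uniformly at
#' random: continuous inputs uniform within their training-data ranges (the
#' surrogate cannot be trusted far beyond the data, so bounds clamp to the
#' observed range), discrete inputs uniform over the categories observed in
#' training.  Process time is sampled like any other input; whether day 12
#' dominates the top predictions is a diagnostic, not an assumption.
#'
#' @param train_points Training point table; ranges and category sets are
#'   taken from it.
#' @param m Number of candidate combinations (default 1e6).
#' @param ph_shift_value pH setpoint applied after a sampled shift day when
#'   candidate rows are turned back into full conditions (default 7.4).
#' @param continuous,discrete Optional overrides: \code{continuous} a named
#'   list of \code{c(min, max)} bounds, \code{discrete} a named list of
#'   value sets.
#'
#' @return An object of class \code{cho_candidate_space}.
#' @export
candidate_space <- function(train_points, m = 1e6, ph_shift_value = 7.4,
                            continuous = NULL, discrete = NULL) {
  if (!is_number(m) || m < 1) stop_choopt("candidate_space: m must be >= 1")
  cont_vars <- c("ph_setpoint", "do_setpoint", "vcd0", "glc_start", "gln_start")
  disc_vars <- c("glc_feed_target", "feed_start_day", "ph_shift_day", "process_time")
  cont <- lapply(cont_vars, function(v) range(train_points[[v]]))
  names(cont) <- cont_vars
  disc <- lapply(disc_vars, function(v) sort(unique(train_points[[v]])))
  names(disc) <- disc_vars
  if (!is.null(continuous)) {
    for (v in names(continuous)) {
      b <- continuous[[v]]
      if (length(b) != 2L || b[1] > b[2]) stop_choopt("candidate_space: bad bounds for %s", v)
      # clamp user bounds to the observed training range
      cont[[v]] <- c(max(b[1], cont[[v]][1]), min(b[2], cont[[v]][2]))
    }
  }
  if (!is.null(discrete)) {
    for (v in names(discrete)) {
      vals <- intersect(discrete[[v]], disc[[v]])
      if (length(vals) == 0L) stop_choopt("candidate_space: empty value set for %s", v)
      disc[[v]] <- sort(vals)
    }
  }
  out <- list(continuous = cont, discrete = disc, m = as.integer(m),
              ph_shift_value = ph_shift_value)
  class(out) <- "cho_candidate_space"
  out
}

#' Draw candidate process settings
#'
#' @param space A [candidate_space()].
#' @param seed Integer seed.
#' @return Data frame of \code{space$m} rows with the nine input columns in
#'   canonical order.
#' @export
generate_candidates <- function(space, seed = 1L) {
  stopifnot(inherits(space, "cho_candidate_space"))
  with_seed(seed, {
    cols <- list()
    for (v in names(space$continuous)) {
      b <- space$continuous[[v]]
      cols[[v]] <- stats::runif(space$m, b[1], b[2])
    }
    for (v in names(space$discrete)) {
      vals <- space$discrete[[v]]
      if (length(vals) == 0L) stop_choopt("generate_candidates: empty discrete set for %s", v)
      cols[[v]] <- vals[sample.int(length(vals), space$m, replace = TRUE)]
    }
    as.data.frame(cols)[, CHO_INPUT_FEATURES]
  })
}

#' Screen candidates through the surrogate
#'
#' Predicts the four KPIs for every candidate (in chunks, so a million rows
#' fit comfortably in memory), retains the rows whose predicted titer
#' strictly exceeds the threshold, and ranks the survivors per KPI in
#' descending order (ties broken by ascending candidate index).
#'
#' @param model A \code{cho_surrogate}, or a function mapping a candidate
#'   data frame to a matrix/data frame of the four KPI columns (used for
#'   analytic test oracles).
#' @param candidates Candidate data frame from [generate_candidates()].
#' @param threshold Titer threshold in g/L (default 4.6, strict
#'   greater-than).
#' @param chunk_size Rows per prediction batch.
#'
#' @return An object of class \code{cho_screening}: \code{survivors} (the
#'   surviving settings with predicted KPIs, \code{extrapolated} flag and
#'   original \code{candidate_index}), \code{rankings} (per-KPI permutations
#'   of survivor rows), \code{threshold}, counts and survivor fraction.
#' @export
screen_candidates <- function(model, candidates, threshold = 4.6,
                              chunk_size = 100000L) {
  n <- nrow(candidates)
  if (n == 0L) stop_choopt("screen_candidates: no candidates")
  predict_fun <- if (inherits(model, "cho_surrogate")) {
    function(df) predict_kpis(model, df)
  } else if (is.function(model)) {
    function(df) {
      out <- as.data.frame(model(df))
      if (is.null(out$extrapolated)) out$extrapolated <- FALSE
      out
    }
  } else {
    stop_choopt("screen_candidates: model must be a cho_surrogate or a function")
  }

  survivors <- list()
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    chunk <- candidates[idx, , drop = FALSE]
    pred <- predict_fun(chunk)
    if (any(!is.finite(as.matrix(pred[, CHO_KPI_NAMES])))) {
      bad <- idx[rowSums(!is.finite(as.matrix(pred[, CHO_KPI_NAMES]))) > 0]
      stop_choopt("screen_candidates: non-finite predictions at row(s) %s",
                  paste(utils::head(bad, 5L), collapse = ", "))
    }
    keep <- pred$titer_at_t > threshold
    if (any(keep)) {
      out <- cbind(chunk[keep, , drop = FALSE], pred[keep, , drop = FALSE])
      out$candidate_index <- idx[keep]
      survivors[[length(survivors) + 1L]] <- out
    }
  }
  survivors <- if (length(survivors)) do.call(rbind, survivors) else {
    empty <- candidates[0, , drop = FALSE]
    for (k in CHO_KPI_NAMES) empty[[k]] <- numeric(0)
    empty$extrapolated <- logical(0)
    empty$candidate_index <- integer(0)
    empty
  }
  rownames(survivors) <- NULL
  rankings <- lapply(CHO_KPI_NAMES, function(k) {
    order(-survivors[[k]], survivors$candidate_index)
  })
  names(rankings) <- CHO_KPI_NAMES
  out <- list(survivors = survivors, rankings = rankings, threshold = threshold,
              n_candidates = n, n_survivors = nrow(survivors),
              survivor_fraction = nrow(survivors) / n)
  class(out) <- "cho_screening"
  out
}

#' @export
print.cho_screening <- function(x, ...) {
  cat(sprintf("<screening> %d / %d candidates above %.2f g/L (%.3f%%)\n",
              x$n_survivors, x$n_candidates, x$threshold, 100 * x$survivor_fraction))
  invisible(x)
}

#' Day-12 dominance diagnostic
#'
#' Fraction of the top-n titer-ranked survivors whose sampled process time
#' is the final day.  In the reference workflow every top prediction used
#' the full 12-day duration; this diagnostic makes that observation
#' checkable instead of assumed.
#'
#' @param screening A \code{cho_screening}.
#' @param top_n How many top titer survivors to inspect (default 100).
#' @param day The "final day" value (default 12).
#' @return Fraction in [0, 1] (NA when there are no survivors).
#' @export
day12_dominance <- function(screening, top_n = 100L, day = 12) {
  stopifnot(inherits(screening, "cho_screening"))
  if (screening$n_survivors == 0L) return(NA_real_)
  top <- utils::head(screening$rankings$titer_at_t, top_n)
  mean(screening$survivors$process_time[top] == day)
}

#' Select diverse validation proposals per KPI
#'
#' From each KPI's top-\code{pool} survivors, greedily picks settings that
#' are far apart: the top-ranked survivor seeds the selection, then each
#' further pick maximizes the minimum pairwise Euclidean distance (in
#' scaled input space) to the already-selected settings.  This formalizes
#' the "not too similar" manual judgment of the original screening.  Titer,
#' the primary optimization target, gets one extra pick by default.
#'
#' @param screening A \code{cho_screening}.
#' @param scaler The input scaler used for distances (a \code{cho_scaler},
#'   typically \code{model$input_scaler}); NULL falls back to scaling by
#'   the survivor table itself.
#' @param pool Per-KPI pool of top-ranked survivors to pick from
#'   (default 10).
#' @param picks Picks per KPI (default 4).
#' @param titer_picks Picks for the titer block (default 5).
#' @return Data frame of proposals: \code{block} (the KPI optimized),
#'   \code{rank_in_pool}, the nine inputs, predicted KPIs and
#'   \code{extrapolated}.
#' @export
select_proposals <- function(screening, scaler = NULL, pool = 10L, picks = 4L,
                             titer_picks = 5L) {
  stopifnot(inherits(screening, "cho_screening"))
  surv <- screening$survivors
  X <- as.matrix(surv[, CHO_INPUT_FEATURES, drop = FALSE])
  Xs <- if (!is.null(scaler)) {
    apply_scaler(scaler, X)
  } else if (nrow(X) > 1L) {
    suppressWarnings(apply_scaler(fit_scaler(X), X))
  } else {
    X
  }
  blocks <- lapply(CHO_KPI_NAMES, function(k) {
    n_pick <- if (k == "titer_at_t") titer_picks else picks
    ranked <- screening$rankings[[k]]
    if (length(ranked) < pool) {
      stop_choopt("select_proposals: KPI %s has only %d survivors; lower pool (%d)",
                  k, length(ranked), pool)
    }
    cand <- utils::head(ranked, pool)
    n_pick <- min(n_pick, pool)
    if (n_pick == pool) {
      chosen <- cand
    } else {
      chosen <- cand[1L]
      remaining <- cand[-1L]
      while (length(chosen) < n_pick) {
        dmin <- vapply(remaining, function(i) {
          min(sqrt(rowSums((Xs[chosen, , drop = FALSE] -
                              matrix(Xs[i, ], nrow = length(chosen),
                                     ncol = ncol(Xs), byrow = TRUE))^2)))
        }, numeric(1))
        # maximize separation; break ties by pool rank (earlier = better KPI)
        best <- remaining[which.max(dmin)]
        if (max(dmin) == 0) {
          warning(sprintf("select_proposals: identical settings in %s pool; separation 0", k))
          best <- remaining[1L]
        }
        chosen <- c(chosen, best)
        remaining <- setdiff(remaining, best)
      }
    }
    out <- surv[chosen, , drop = FALSE]
    out$block <- k
    out$rank_in_pool <- match(chosen, cand)
    out
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  cols <- c("block", "rank_in_pool", CHO_INPUT_FEATURES, CHO_KPI_NAMES,
            "extrapolated", "candidate_index")
  out[, intersect(cols, names(out))]
}

# turn one proposal row (nine inputs) back into a full condition
proposal_to_condition <- function(row, ph_shift_value = 7.4) {
  process_condition(
    ph_setpoint = row$ph_setpoint, do_setpoint = row$do_setpoint,
    vcd0 = row$vcd0, glc_start = row$glc_start, gln_start = row$gln_start,
    glc_feed_target = row$glc_feed_target,
    feed_start_day = as.integer(round(row$feed_start_day)),
    ph_shift_day = as.integer(round(row$ph_shift_day)),
    ph_shift_value = ph_shift_value
  )
}

#' Validate proposals against the ground-truth simulator
#'
#' Runs every proposed setting (plus standard-condition replicates) through
#' the simulator that generated the training data and compares the
#' surrogate's predicted KPIs with the simulated ("validated") ones --- the
#' in-silico analogue of re-running the proposed conditions in the
#' bioreactor.  KPIs are evaluated at each proposal's process time via the
#' metrics module: running maximum VCD and diameter, titer at the day, and
#' the mean specific productivity [qp_mean()].
#'
#' @param proposals Data frame from [select_proposals()].
#' @param truth_params [simulator_params()] of the ground-truth simulator.
#' @param n_std_replicates Standard-condition replicate runs (default 3).
#' @param seed Integer seed for the validation runs.
#' @param ph_shift_value pH value applied on sampled shift days.
#' @param std STD condition (default [std_condition()]).
#'
#' @return A list of class \code{cho_validation}: \code{table} (one row per
#'   proposal: block, inputs, predicted vs validated KPIs, deviations, and
#'   percent change of validated titer over validated STD titer) and
#'   \code{std} (the STD replicate KPI means).
#' @export
validate_in_silico <- function(proposals, truth_params = simulator_params(),
                               n_std_replicates = 3L, seed = 1L,
                               ph_shift_value = 7.4, std = std_condition()) {
  if (nrow(proposals) == 0L) stop_choopt("validate_in_silico: no proposals")
  seeds <- derive_seeds(seed, nrow(proposals) + n_std_replicates)

  run_kpis <- function(run, t_day) {
    s <- run$samples[run$samples$day <= t_day, , drop = FALSE]
    c(vcd_max_to_t = max(s$vcd), titer_at_t = s$titer[nrow(s)],
      diameter_max_to_t = max(s$diameter),
      qp_mean_to_t = if (nrow(s) < 2L) 0 else qp_mean(s$titer, s$vcd))
  }

  std_kpis <- vapply(seq_len(n_std_replicates), function(i) {
    run <- simulate_run(std, truth_params, seed = seeds[nrow(proposals) + i])
    run_kpis(run, 12)
  }, numeric(4))
  std_mean <- rowMeans(std_kpis)

  rows <- lapply(seq_len(nrow(proposals)), function(i) {
    row <- proposals[i, , drop = FALSE]
    cond <- proposal_to_condition(row, ph_shift_value)
    t_day <- as.integer(round(row$process_time))
    run <- simulate_run(cond, truth_params, seed = seeds[i])
    valid <- run_kpis(run, t_day)
    pred <- unlist(row[CHO_KPI_NAMES])
    data.frame(
      block = row$block, rank_in_pool = row$rank_in_pool,
      row[CHO_INPUT_FEATURES],
      predicted_titer = pred["titer_at_t"], validated_titer = valid["titer_at_t"],
      predicted_vcd_max = pred["vcd_max_to_t"], validated_vcd_max = valid["vcd_max_to_t"],
      predicted_diameter = pred["diameter_max_to_t"],
      validated_diameter = valid["diameter_max_to_t"],
      predicted_qp = pred["qp_mean_to_t"], validated_qp = valid["qp_mean_to_t"],
      titer_deviation = abs(pred["titer_at_t"] - valid["titer_at_t"]),
      titer_change_vs_std_pct =
        100 * (valid["titer_at_t"] - std_mean["titer_at_t"]) / std_mean["titer_at_t"],
      extrapolated = row$extrapolated,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- list(table = do.call(rbind, rows), std = std_mean,
              n_std_replicates = n_std_replicates, seed = as.integer(seed))
  class(out) <- "cho_validation"
  out
}

#' @export
print.cho_validation <- function(x, ...) {
  cat(sprintf("<validation> %d proposals vs STD (titer %.2f g/L)\n",
              nrow(x$table), x$std["titer_at_t"]))
  best <- x$table[which.max(x$table$validated_titer), ]
  cat(sprintf("  best validated titer %.2f g/L (%+.1f%% vs STD, block %s)\n",
              best$validated_titer, best$titer_change_vs_std_pct, best$block))
  invisible(x)
}
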