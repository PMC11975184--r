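#' Kinetic parameters of the synthetic cultivation simulator
#'
#' The simulator propagates a fed-batch CHO culture through daily discrete
#' difference equations (one step per sampling day).  Growth follows a
#' Monod-type law in glucose, glutamine and dissolved oxygen with a Gaussian
#' pH optimum; death increases with culture age and under glucose
#' starvation; antibody production has a growth-associated and a
#' non-growth-associated term, the latter with its own (higher) pH optimum
#' and a glutamine saturation gain.  Defaults are calibrated once so that a
#' noise-free standard run reproduces the reference process KPIs
#' (VCD_max about 23.7e6 cells/mL, final titer about 3.0 g/L, maximal mean
#' diameter about 17.3 um, mean specific productivity about 22 pg/cell/day)
#' and are frozen.
#'
#' @param mu_max Maximum specific growth rate, 1/day.
#' @param ph_opt,ph_width Gaussian pH optimum and width for growth, pH units.
#' @param do_halfsat Half-saturation DO for growth, \% air saturation.
#' @param vcd_cap Carrying capacity of the culture, 1e6 cells/mL; growth is
#'   scaled by the logistic factor \code{1 - vcd/vcd_cap}.
#' @param k_glc,k_gln Monod half-saturations for glucose (g/L) and
#'   glutamine (mM).
#' @param death_rate_base Baseline death rate, 1/day.
#' @param death_age_gain Linear increase of the death rate with culture age,
#'   1/day per day.
#' @param starvation_death_boost Extra death rate while glucose < 0.5 g/L,
#'   1/day.
#' @param yield_glc Glucose consumption, g/L per (1e6 cells/mL) per day.
#' @param yield_gln Glutamine consumption, mM per (1e6 cells/mL) per day.
#' @param glc_bolus,gln_bolus Daily macro/micro nutrient feed increments
#'   (glucose g/L, glutamine mM) applied from the feeding start day on.
#' @param qp_alpha Growth-associated specific productivity, pg/cell.
#' @param qp_beta Non-growth-associated specific productivity, pg/cell/day.
#' @param qp_ph_opt,qp_ph_width Gaussian pH optimum and width of the
#'   non-growth-associated production term, pH units.
#' @param qp_gln_gain Dimensionless gain of production with glutamine
#'   saturation.
#' @param k_gln_qp Glutamine half-saturation of the production gain, mM.
#' @param lac_yield Lactate produced per g/L glucose consumed (overflow).
#' @param lac_cons Lactate re-consumption rate at low glucose,
#'   g/L per (1e6 cells/mL) per day.
#' @param diameter_base Mean cell diameter at inoculation, um.
#' @param diameter_age_gain Maximal daily diameter increase, um/day
#'   (realized fully when growth stalls).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noise-free), fraction in [0, 0.5].
#' @param seed Default RNG seed used when \code{simulate_run} is called
#'   without one.
#'
#' @return An object of class \code{cho_sim_params}.
#' @seealso [simulate_run()], [generate_dataset()]
#' @export
simulator_params <- function(mu_max = 1.05,
                             ph_opt = 7.2, ph_width = 0.35,
                             do_halfsat = 12, vcd_cap = 27,
                             k_glc = 0.4, k_gln = 0.35,
                             death_rate_base = 0.015,
                             death_age_gain = 0.16,
                             starvation_death_boost = 0.35,
                             yield_glc = 0.17, yield_gln = 0.13,
                             glc_bolus = 0.5, gln_bolus = 1.6,
                             qp_alpha = 2, qp_beta = 26.5,
                             qp_ph_opt = 7.45, qp_ph_width = 0.40,
                             qp_gln_gain = 0.8, k_gln_qp = 2.0,
                             lac_yield = 0.35, lac_cons = 0.08,
                             diameter_base = 14.5, diameter_age_gain = 0.42,
                             noise_cv = 0.05, seed = 1L) {
  p <- as.list(environment())
  pos <- c("mu_max", "ph_width", "do_halfsat", "vcd_cap", "k_glc", "k_gln",
           "death_rate_base", "starvation_death_boost", "yield_glc",
           "yield_gln", "qp_ph_width", "k_gln_qp", "diameter_base")
  for (nm in pos) {
    if (!is_number(p[[nm]]) || p[[nm]] <= 0) {
      stop_choopt("simulator_params: %s must be a positive number", nm)
    }
  }
  if (!is_number(noise_cv) || noise_cv < 0 || noise_cv > 0.5) {
    stop_choopt("simulator_params: noise_cv must lie in [0, 0.5]")
  }
  class(p) <- "cho_sim_params"
  p
}

#' Simulate one fed-batch cultivation run
#'
#' Propagates the culture state (VCD, glucose, glutamine, lactate, titer,
#' mean diameter, viability) day by day from day 0 to day 12 under the given
#' condition.  Feeding adds fixed daily nutrient boluses from the feeding
#' start day on; from day 5 on glucose is additionally topped up to the
#' condition's feed target when it falls below it (target 0 = never).  A pH
#' shift changes the setpoint once on the shift day and holds.  Measurement
#' noise is multiplicative lognormal with CV \code{params$noise_cv}; titer
#' noise is applied to the daily increments so measured titer stays
#' non-decreasing.
#'
#' @param condition A [process_condition()].
#' @param params A [simulator_params()] object.
#' @param seed Integer RNG seed (defaults to \code{params$seed}); the
#'   caller's RNG state is left untouched.
#'
#' @return An object of class \code{cho_run}: a list with \code{run_id},
#'   \code{condition}, \code{samples} (data frame of 13 daily samples with
#'   columns day, vcd, viability, diameter, glc, gln, lac, titer),
#'   \code{sample_flags} (character vector, "" = clean), \code{flags} and
#'   \code{metadata}.
#' @examples
#' run <- simulate_run(std_condition(), simulator_params(noise_cv = 0))
#' max(run$samples$vcd)          # ~ 23.7e6 cells/mL
#' run$samples$titer[13]         # ~ 3.0 g/L
#' @export
simulate_run <- function(condition, params = simulator_params(), seed = NULL) {
  stopifnot(inherits(condition, "cho_condition"))
  validate_condition(condition)
  if (!inherits(params, "cho_sim_params")) stop_choopt("params must come from simulator_params()")
  if (is.null(seed)) seed <- params$seed

  days <- 0:12
  n_days <- length(days)
  state <- list(vcd = condition$vcd0, glc = condition$glc_start,
                gln = condition$gln_start, lac = 0, titer = 0,
                diam = params$diameter_base, viab = 100)
  traj <- matrix(NA_real_, nrow = n_days, ncol = 7,
                 dimnames = list(NULL, c("vcd", "glc", "gln", "lac", "titer_inc", "diam", "viab")))
  traj[1, ] <- c(state$vcd, state$glc, state$gln, state$lac, 0, state$diam, state$viab)
  cum_stress <- 0

  for (n in seq_len(n_days - 1L)) {
    day <- days[n]
    ph <- if (condition$ph_shift_day != CHO_NONE && day >= condition$ph_shift_day) {
      condition$ph_shift_value
    } else {
      condition$ph_setpoint
    }
    # daily nutrient feed, then glucose top-up (from day 5, if below target)
    if (condition$feed_start_day != CHO_NONE && day >= condition$feed_start_day) {
      state$glc <- state$glc + params$glc_bolus
      state$gln <- state$gln + params$gln_bolus
    }
    if (condition$glc_feed_target > 0 && day >= 5 && state$glc < condition$glc_feed_target) {
      state$glc <- condition$glc_feed_target
    }

    mu <- params$mu_max *
      exp(-((ph - params$ph_opt) / params$ph_width)^2) *
      condition$do_setpoint / (params$do_halfsat + condition$do_setpoint) *
      state$glc / (params$k_glc + state$glc) *
      state$gln / (params$k_gln + state$gln) *
      max(0, 1 - state$vcd / params$vcd_cap)
    kd <- params$death_rate_base * (1 + params$death_age_gain * day^1.5) +
      if (state$glc < 0.5) params$starvation_death_boost else 0

    vcd_next <- max(state$vcd * (1 + mu - kd), 0)
    vcd_avg <- (state$vcd + vcd_next) / 2

    uptake_glc <- min(state$glc, params$yield_glc * vcd_avg * state$glc / (params$k_glc + state$glc))
    uptake_gln <- min(state$gln, params$yield_gln * vcd_avg * state$gln / (params$k_gln + state$gln))
    glc_next <- state$glc - uptake_glc
    gln_next <- state$gln - uptake_gln
    lac_next <- max(state$lac + params$lac_yield * uptake_glc -
                      if (state$glc < 2) params$lac_cons * vcd_avg else 0, 0)

    qp <- (params$qp_alpha * mu +
             params$qp_beta * exp(-((ph - params$qp_ph_opt) / params$qp_ph_width)^2)) *
      (1 + params$qp_gln_gain * state$gln / (params$k_gln_qp + state$gln))
    titer_inc <- qp * vcd_avg / 1000  # pg/cell/day * 1e6 cells/mL -> g/L

    diam_next <- state$diam + params$diameter_age_gain * (1 - mu / params$mu_max)
    cum_stress <- cum_stress + kd
    viab_next <- 100 / (1 + exp(3 * (cum_stress - 1.8)))

    nxt <- c(vcd = vcd_next, glc = glc_next, gln = gln_next, lac = lac_next,
             titer_inc = titer_inc, diam = diam_next, viab = viab_next)
    bad <- !is.finite(nxt) | (nxt < 0 & names(nxt) != "titer_inc")
    if (any(bad)) {
      stop_choopt("simulation failure on day %d: non-finite or negative %s",
                  day + 1L, paste(names(nxt)[bad], collapse = ", "))
    }
    traj[n + 1L, ] <- nxt
    state <- list(vcd = vcd_next, glc = glc_next, gln = gln_next, lac = lac_next,
                  titer = state$titer + titer_inc, diam = diam_next, viab = viab_next)
  }

  samples <- with_seed(seed, {
    noisy <- function(x, cv) {
      if (cv <= 0) return(x)
      sigma <- sqrt(log(1 + cv^2))
      x * exp(stats::rnorm(length(x), mean = -sigma^2 / 2, sd = sigma))
    }
    cv <- params$noise_cv
    data.frame(
      day = days,
      vcd = noisy(traj[, "vcd"], cv),
      viability = pmin(noisy(traj[, "viab"], cv / 5), 100),
      diameter = noisy(traj[, "diam"], cv / 2),
      glc = noisy(traj[, "glc"], cv),
      gln = noisy(traj[, "gln"], cv),
      lac = noisy(traj[, "lac"], cv),
      titer = cumsum(noisy(traj[, "titer_inc"], cv))
    )
  })

  run <- list(
    run_id = sprintf("run_%08x", as.integer(seed) %% 0x7fffffff),
    condition = condition,
    samples = samples,
    sample_flags = rep("", n_days),
    flags = character(0),
    metadata = list(seed = as.integer(seed))
  )
  class(run) <- "cho_run"
  run
}

#' @export
print.cho_run <- function(x, ...) {
  cat(sprintf("<cho_run %s> %d daily samples; VCD_max %.1f, final titer %.2f g/L\n",
              x$run_id, nrow(x$samples), max(x$samples$vcd), x$samples$titer[nrow(x$samples)]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a whole design
#'
#' Runs [simulate_run()] for every condition in a design; per-run seeds are
#' derived deterministically from the dataset seed, so the same
#' (design, params, seed) triple always yields a bit-identical dataset.
#' Optionally a fraction of daily samples receives a QC flag
#' (\code{CONTAMINATED} or \code{ANALYTICS_FAILURE}) so that downstream
#' cleaning has something to do.
#'
#' @param design Named list of conditions from [build_design()] (or any list
#'   of [process_condition()] objects).
#' @param params [simulator_params()].
#' @param seed Integer seed for the whole dataset.
#' @param flag_fraction Fraction of daily samples to mark with a QC flag
#'   (default 0).
#'
#' @return List of \code{cho_run} objects.
#' @examples
#' runs <- generate_dataset(build_design("STD"), simulator_params(), seed = 1)
#' length(runs)
#' @export
generate_dataset <- function(design, params = simulator_params(), seed = 1L,
                             flag_fraction = 0) {
  if (length(design) == 0L) stop_choopt("generate_dataset: design is empty")
  if (flag_fraction < 0 || flag_fraction >= 1) {
    stop_choopt("generate_dataset: flag_fraction must lie in [0, 1)")
  }
  seeds <- derive_seeds(seed, length(design) + 1L)
  labels <- names(design)
  if (is.null(labels)) labels <- sprintf("COND_%02d", seq_along(design))
  runs <- vector("list", length(design))
  for (i in seq_along(design)) {
    runs[[i]] <- tryCatch(
      simulate_run(design[[i]], params, seed = seeds[i]),
      error = function(e) stop_choopt("run %d (%s): %s", i, labels[i], conditionMessage(e))
    )
    runs[[i]]$run_id <- sprintf("run%02d_%s", i, labels[i])
    runs[[i]]$metadata$design_label <- labels[i]
  }
  if (flag_fraction > 0) {
    runs <- with_seed(seeds[length(seeds)], {
      n_samples <- sum(vapply(runs, function(r) nrow(r$samples), integer(1)))
      n_flag <- round(flag_fraction * n_samples)
      if (n_flag > 0) {
        idx <- sample.int(n_samples, n_flag)
        labels_pool <- c("CONTAMINATED", "ANALYTICS_FAILURE")
        offsets <- cumsum(c(0, vapply(runs, function(r) nrow(r$samples), integer(1))))
        for (k in idx) {
          ri <- findInterval(k - 1L, offsets, rightmost.closed = FALSE)
          si <- k - offsets[ri]
          runs[[ri]]$sample_flags[si] <- sample(labels_pool, 1L)
        }
      }
      runs
    })
  }
  runs
}
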