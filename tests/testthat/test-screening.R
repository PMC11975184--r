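# analytic stand-in model: titer depends only on pH, other KPIs constant
analytic_model <- function(df) {
  data.frame(vcd_max_to_t = rep(20, nrow(df)),
             titer_at_t = -(df$ph_setpoint - 7.4)^2 + 4.8,
             diameter_max_to_t = rep(17, nrow(df)),
             qp_mean_to_t = rep(25, nrow(df)))
}

test_that("candidate spaces clamp to the training data ranges", {
  pts <- cached_points()
  space <- candidate_space(pts, m = 100)
  expect_equal(space$continuous$ph_setpoint, range(pts$ph_setpoint))
  expect_setequal(space$discrete$glc_feed_target, unique(pts$glc_feed_target))
  wide <- candidate_space(pts, m = 10, continuous = list(ph_setpoint = c(5, 9)))
  expect_equal(wide$continuous$ph_setpoint, range(pts$ph_setpoint))
  expect_error(candidate_space(pts, m = 0), "m must be")
  expect_error(candidate_space(pts, m = 10, discrete = list(feed_start_day = 99)),
               "empty value set")
})

test_that("candidate generation is seeded, in-domain and marginally uniform", {
  pts <- cached_points()
  space <- candidate_space(pts, m = 10)
  a <- generate_candidates(space, seed = 3)
  expect_identical(a, generate_candidates(space, seed = 3))
  expect_equal(dim(a), c(10L, 9L))
  for (v in names(space$continuous)) {
    expect_true(all(a[[v]] >= space$continuous[[v]][1] & a[[v]] <= space$continuous[[v]][2]))
  }
  for (v in names(space$discrete)) {
    expect_true(all(a[[v]] %in% space$discrete[[v]]))
  }

  # degenerate continuous interval collapses to a constant column
  pts0 <- pts
  pts0$vcd0 <- 0.3
  space0 <- candidate_space(pts0, m = 50)
  expect_true(all(generate_candidates(space0, seed = 1)$vcd0 == 0.3))

  # multinomial 3-sigma check of a discrete marginal
  big <- generate_candidates(candidate_space(pts, m = 20000), seed = 7)
  vals <- candidate_space(pts, m = 1)$discrete$feed_start_day
  counts <- table(factor(big$feed_start_day, levels = vals))
  expected <- 20000 / length(vals)
  tol <- 3 * sqrt(20000 * (1 / length(vals)) * (1 - 1 / length(vals)))
  expect_true(all(abs(counts - expected) <= tol))
})

test_that("the titer filter matches its closed form and is monotone", {
  pts <- cached_points()
  space <- candidate_space(pts, m = 1000)
  cands <- generate_candidates(space, seed = 5)

  res <- screen_candidates(analytic_model, cands, threshold = 4.6)
  # survivors iff |pH - 7.4| < sqrt(0.2)
  expect_equal(sort(res$survivors$candidate_index),
               which(abs(cands$ph_setpoint - 7.4) < sqrt(0.2)))
  expect_true(all(res$survivors$titer_at_t > 4.6))

  all_in <- screen_candidates(analytic_model, cands, threshold = -Inf)
  expect_equal(all_in$n_survivors, nrow(cands))

  counts <- vapply(c(4.0, 4.4, 4.6, 4.75, 4.79), function(th) {
    screen_candidates(analytic_model, cands, threshold = th)$n_survivors
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # batch-splitting equivalence
  a <- screen_candidates(analytic_model, cands[1:400, , drop = FALSE], threshold = 4.6)
  b <- screen_candidates(analytic_model, cands[401:1000, , drop = FALSE], threshold = 4.6)
  expect_equal(res$n_survivors, a$n_survivors + b$n_survivors)

  # rankings are permutations of survivor rows, titer ranking non-increasing
  for (r in res$rankings) expect_setequal(r, seq_len(res$n_survivors))
  ranked_titer <- res$survivors$titer_at_t[res$rankings$titer_at_t]
  expect_true(all(diff(ranked_titer) <= 0))
})

test_that("screening a fitted surrogate equals a per-row brute-force recomputation", {
  pts <- cached_points()
  m <- fit_surrogate(pts, model_spec("tree_ensemble", trees = 8L), seed = 2)
  cands <- generate_candidates(candidate_space(pts, m = 800), seed = 9)
  res <- screen_candidates(m, cands, threshold = 3.5, chunk_size = 137L)
  brute <- which(vapply(seq_len(nrow(cands)), function(i) {
    predict_kpis(m, cands[i, , drop = FALSE])$titer_at_t > 3.5
  }, logical(1)))
  expect_equal(sort(res$survivors$candidate_index), brute)
})

test_that("proposal selection favors spread and degrades gracefully", {
  # collinear pool: 10 points on a line in input space, decreasing titer rank
  base <- cached_points()[rep(1, 10), ]
  base$ph_setpoint <- seq(6.9, 7.5, length.out = 10)
  base$titer_at_t <- seq(5.8, 4.9, length.out = 10)
  base$vcd_max_to_t <- 20; base$diameter_max_to_t <- 17; base$qp_mean_to_t <- 25
  base$extrapolated <- FALSE
  base$candidate_index <- 1:10
  scr <- list(survivors = base,
              rankings = lapply(kpi_names(), function(k) order(-base[[k]], base$candidate_index)),
              threshold = 4.6, n_candidates = 10L, n_survivors = 10L,
              survivor_fraction = 1)
  names(scr$rankings) <- kpi_names()
  class(scr) <- "cho_screening"

  picks <- select_proposals(scr, pool = 10, picks = 4, titer_picks = 4)
  titer_block <- picks[picks$block == "titer_at_t", ]
  # both extremes of the line must be picked (max-min spread)
  expect_true(all(c(min(base$ph_setpoint), max(base$ph_setpoint)) %in%
                    titer_block$ph_setpoint))

  # picks = pool returns the whole pool in rank order
  all_of_them <- select_proposals(scr, pool = 10, picks = 10, titer_picks = 10)
  tb <- all_of_them[all_of_them$block == "titer_at_t", ]
  expect_equal(tb$rank_in_pool, 1:10)

  # identical pool: fall back to rank order with a warning
  same <- scr
  same$survivors[] <- same$survivors[rep(1, 10), ]
  same$survivors$candidate_index <- 1:10
  w <- testthat::capture_warnings(
    degenerate <- select_proposals(same, pool = 10, picks = 3, titer_picks = 3)
  )
  expect_true(any(grepl("identical settings", w)))
  expect_equal(degenerate$rank_in_pool[degenerate$block == "titer_at_t"], 1:3)

  expect_error(select_proposals(scr, pool = 20), "lower pool")
})

test_that("proposal selection is invariant to survivor row order", {
  pts <- cached_points()
  m <- fit_surrogate(pts, model_spec("tree_ensemble", trees = 8L), seed = 2)
  cands <- generate_candidates(candidate_space(pts, m = 2000), seed = 10)
  res <- screen_candidates(m, cands, threshold = 3.0)
  perm <- sample(seq_len(res$n_survivors))
  res2 <- res
  res2$survivors <- res$survivors[perm, ]
  res2$rankings <- lapply(kpi_names(), function(k) {
    order(-res2$survivors[[k]], res2$survivors$candidate_index)
  })
  names(res2$rankings) <- kpi_names()
  a <- select_proposals(res, scaler = m$input_scaler)
  b <- select_proposals(res2, scaler = m$input_scaler)
  expect_equal(a$candidate_index, b$candidate_index)
})

test_that("in-silico validation of the standard condition reproduces STD exactly", {
  p0 <- noise_free()
  std <- std_condition()
  proposal <- data.frame(block = "titer_at_t", rank_in_pool = 1L,
                         do_setpoint = std$do_setpoint, ph_setpoint = std$ph_setpoint,
                         gln_start = std$gln_start, glc_start = std$glc_start,
                         ph_shift_day = std$ph_shift_day, vcd0 = std$vcd0,
                         feed_start_day = std$feed_start_day,
                         glc_feed_target = std$glc_feed_target, process_time = 12,
                         vcd_max_to_t = 23, titer_at_t = 3.1,
                         diameter_max_to_t = 17, qp_mean_to_t = 25,
                         extrapolated = FALSE)
  val <- validate_in_silico(proposal, truth_params = p0, seed = 4)
  expect_equal(val$table$validated_titer, unname(val$std["titer_at_t"]))
  expect_equal(val$table$titer_change_vs_std_pct, 0)
  expect_equal(val$table$titer_deviation,
               abs(val$table$predicted_titer - val$table$validated_titer))
})
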