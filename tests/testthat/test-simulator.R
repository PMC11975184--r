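test_that("noise-free standard run reproduces the reference process KPIs", {
  run <- simulate_run(std_condition(), noise_free(), seed = 1)
  k <- run_final_kpis(run)
  expect_lt(abs(k[["vcd_max"]] - 23.71), 3)
  expect_lt(abs(k[["titer"]] - 3.02), 0.5)
  expect_lt(abs(k[["diameter"]] - 17.3), 1)
  expect_gt(k[["qp"]], 20)
  expect_lt(k[["qp"]], 30)
})

test_that("conditions enforce their invariants", {
  expect_error(process_condition(vcd0 = 0), "vcd0")
  expect_error(process_condition(ph_setpoint = 9), "ph_setpoint")
  expect_error(process_condition(do_setpoint = 10), "do_setpoint")
  expect_error(process_condition(feed_start_day = 7), "feed_start_day")
  expect_error(process_condition(ph_shift_day = 9), "ph_shift_day")
  expect_error(process_condition(glc_start = -1), "glc_start")
})

test_that("a batch process (no feeding) produces less antibody than STD", {
  std <- simulate_run(std_condition(), noise_free(), seed = 1)
  batch <- simulate_run(process_condition(feed_start_day = -1, glc_feed_target = 0),
                        noise_free(), seed = 1)
  expect_lt(tail(batch$samples$titer, 1), tail(std$samples$titer, 1))
})

test_that("simulation is deterministic given a seed", {
  p <- simulator_params(noise_cv = 0.08)
  a <- simulate_run(std_condition(), p, seed = 99)
  b <- simulate_run(std_condition(), p, seed = 99)
  expect_identical(a, b)
  c <- simulate_run(std_condition(), p, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("titer is non-decreasing within every run, with and without noise", {
  runs <- generate_dataset(build_design("FULL_58"), simulator_params(noise_cv = 0.08),
                           seed = 5)
  for (run in runs) expect_true(all(diff(run$samples$titer) >= 0))
})

test_that("final titer has an interior pH optimum", {
  phs <- seq(6.8, 7.6, by = 0.05)
  titers <- vapply(phs, function(ph) {
    run <- simulate_run(process_condition(ph_setpoint = ph), noise_free(), seed = 1)
    tail(run$samples$titer, 1)
  }, numeric(1))
  i <- which.max(titers)
  expect_gt(i, 1)
  expect_lt(i, length(phs))
  expect_gt(phs[i], 6.8)
  expect_lt(phs[i], 7.6)
})

test_that("earlier feeding with high starting glutamine does not hurt the titer", {
  early <- simulate_run(process_condition(feed_start_day = 1, gln_start = 12),
                        noise_free(), seed = 1)
  late <- simulate_run(process_condition(feed_start_day = 5, gln_start = 12),
                       noise_free(), seed = 1)
  expect_gte(tail(early$samples$titer, 1), tail(late$samples$titer, 1))
})

test_that("replicate noise is calibrated: zero-noise replicates identical, 5% CV bounded", {
  p0 <- noise_free()
  r1 <- simulate_run(std_condition(), p0, seed = 1)
  r2 <- simulate_run(std_condition(), p0, seed = 2)
  expect_equal(r1$samples, r2$samples)

  p <- simulator_params(noise_cv = 0.05)
  finals <- vapply(1:100, function(s) {
    tail(simulate_run(std_condition(), p, seed = s)$samples$titer, 1)
  }, numeric(1))
  expect_lt(sd(finals) / mean(finals), 0.15)
})

test_that("day-0 sample reflects the inoculation density", {
  run <- simulate_run(process_condition(vcd0 = 0.42), noise_free(), seed = 1)
  expect_equal(run$samples$vcd[1], 0.42)
  expect_equal(run$samples$titer[1], 0)
})

test_that("designs have the documented geometry and sizes", {
  ccc <- build_design("CCC_PH_DO")
  expect_length(ccc, 9)
  pts <- unique(t(vapply(ccc, function(c) c(c$ph_setpoint, c$do_setpoint), numeric(2))))
  expect_equal(nrow(pts), 9)  # 4 factorial + 4 axial + 1 center, all distinct

  shifts <- build_design("PH_SHIFT")
  expect_length(shifts, 8)
  expect_setequal(unique(vapply(shifts, `[[`, integer(1), "ph_shift_day")), c(0L, 3L, 4L, 5L))
  expect_true(all(vapply(shifts, `[[`, numeric(1), "ph_setpoint") == 7.1))
  expect_true(all(vapply(shifts, `[[`, numeric(1), "ph_shift_value") == 7.3))

  expect_length(build_design("FULL_58"), 58)
  expect_length(build_design("STD"), 3)
  expect_error(build_design("NOPE"), "unknown design")
  expect_error(build_design("CCC_PH_DO", ranges = list(ph = c(7.5, 6.8), do = c(20, 100))),
               "min < max")
})

test_that("generate_dataset is reproducible and sized as designed", {
  runs <- cached_dataset()
  expect_length(runs, 58)
  expect_equal(sum(vapply(runs, function(r) nrow(r$samples), integer(1))), 754)
  again <- generate_dataset(build_design("FULL_58"), simulator_params(),
                            seed = 11, flag_fraction = 0.025)
  expect_identical(runs, again)
  expect_error(generate_dataset(list(), simulator_params(), seed = 1), "empty")
})
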