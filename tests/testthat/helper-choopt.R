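# shared fixtures, all generated in code

noise_free <- function() simulator_params(noise_cv = 0)

# memoized simulated datasets so independent test files don't regenerate them
.choopt_cache <- new.env(parent = emptyenv())

cached_dataset <- function(seed = 11L, flag_fraction = 0.025) {
  key <- sprintf("runs_%d_%g", seed, flag_fraction)
  if (is.null(.choopt_cache[[key]])) {
    .choopt_cache[[key]] <- generate_dataset(build_design("FULL_58"), simulator_params(),
                                             seed = seed, flag_fraction = flag_fraction)
  }
  .choopt_cache[[key]]
}

cached_points <- function(seed = 11L) {
  key <- sprintf("points_%d", seed)
  if (is.null(.choopt_cache[[key]])) {
    .choopt_cache[[key]] <-
      suppressMessages(clean_points(flatten_to_points(cached_dataset(seed))))
  }
  .choopt_cache[[key]]
}

run_final_kpis <- function(run) {
  s <- run$samples
  c(vcd_max = max(s$vcd), titer = s$titer[nrow(s)],
    diameter = max(s$diameter), qp = qp_mean(s$titer, s$vcd))
}

# small noiseless linear multi-output problem for model sanity checks
linear_toy <- function(n = 150L, seed = 42L) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  pts <- cbind(run_id = rep(sprintf("r%02d", 1:10), length.out = n), X)
  B <- matrix(c(1, -2, 0.5, 2, 1, -1, 0, 3, 1, -1, 0, 2), nrow = 3)
  Y <- as.matrix(X) %*% B
  colnames(Y) <- kpi_names()
  cbind(pts, as.data.frame(Y))
}
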