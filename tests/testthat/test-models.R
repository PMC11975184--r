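toy_features <- c("x1", "x2", "x3")

test_that("the linear family nails noiseless linear data", {
  pts <- linear_toy()
  m <- fit_surrogate(pts, model_spec("linear"), seed = 1, features = toy_features)
  expect_gte(m$provenance$train_r2, 0.999)
})

test_that("fits and predictions are deterministic given a seed", {
  pts <- cached_points()[1:120, ]
  spec <- model_spec("feedforward_net", hidden_layers = c(16L, 8L), max_epochs = 300L)
  m1 <- fit_surrogate(pts, spec, seed = 9)
  m2 <- fit_surrogate(pts, spec, seed = 9)
  p1 <- predict_kpis(m1, pts)
  expect_identical(p1, predict_kpis(m2, pts))

  spec_rf <- model_spec("tree_ensemble", trees = 10L)
  r1 <- fit_surrogate(pts, spec_rf, seed = 4)
  r2 <- fit_surrogate(pts, spec_rf, seed = 4)
  expect_equal(predict_kpis(r1, pts), predict_kpis(r2, pts))
})

test_that("predictions preserve row order, units and flag extrapolation", {
  pts <- cached_points()
  m <- fit_surrogate(pts, model_spec("tree_ensemble", trees = 10L), seed = 2)
  batch <- pts[c(40, 1, 200), ]
  pred <- predict_kpis(m, batch)
  expect_equal(nrow(pred), 3)
  expect_equal(names(pred), c(kpi_names(), "extrapolated"))
  single <- predict_kpis(m, pts[40, ])
  expect_equal(unlist(pred[1, kpi_names()]), unlist(single[1, kpi_names()]))
  expect_false(any(pred$extrapolated))  # training rows are inside the range

  out <- pts[1, ]
  out$gln_start <- 99
  expect_true(predict_kpis(m, out)$extrapolated)

  expect_error(predict_kpis(m, pts[, 1:4]), "missing")
})

test_that("output scaling round-trips: scaled prediction equals physical prediction", {
  pts <- cached_points()[1:150, ]
  m <- fit_surrogate(pts, model_spec("linear"), seed = 1)
  X <- as.matrix(pts[, input_features()])
  Xs <- apply_scaler(m$input_scaler, X)
  direct <- as.matrix(predict_kpis(m, pts)[, kpi_names()])
  via_scaled <- inverse_scaler(m$output_scaler, choopt:::predict_scaled(m, Xs))
  expect_equal(unname(direct), unname(via_scaled), tolerance = 1e-9)
})

test_that("every family interpolates noiseless linear data well in CV", {
  pts <- linear_toy(n = 600)
  specs <- list(
    linear = model_spec("linear"),
    latent_projection = model_spec("latent_projection", components = 3L),
    tree_ensemble = model_spec("tree_ensemble", trees = 100L),
    feedforward_net = model_spec("feedforward_net", hidden_layers = c(32L, 16L),
                                 alpha = 1e-4, max_epochs = 3000L, patience = 500L)
  )
  cmp <- compare_models(pts, specs = specs, folds = 3, unit = "point", seed = 1,
                        features = toy_features)
  expect_true(all(cmp$summary$cv_r2 >= 0.95))
})

test_that("training scores are optimistic relative to held-out scores", {
  deltas <- vapply(1:10, function(s) {
    runs <- generate_dataset(build_design("STD"), simulator_params(noise_cv = 0.1),
                             seed = s)
    runs <- c(runs, generate_dataset(build_design("CCC_PH_DO"),
                                     simulator_params(noise_cv = 0.1), seed = s + 100))
    pts <- flatten_to_points(runs)
    cmp <- compare_models(pts, specs = list(tree = model_spec("tree_ensemble", trees = 8L)),
                          folds = 3, unit = "point", seed = s)
    cmp$summary$train_r2 - cmp$summary$cv_r2
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("hyperparameter tuning is exhaustive, seeded and tie-broken", {
  pts <- linear_toy(n = 120)
  space <- list(model_spec("linear"))
  res <- tune_hyperparameters(pts, space, seed = 1, features = toy_features)
  expect_equal(res$best_label, "linear")

  # the family able to represent the truth wins over a clearly misspecified one
  space2 <- list(model_spec("linear"), model_spec("tree_ensemble", trees = 2L))
  res2 <- tune_hyperparameters(pts, space2, folds = 3, unit = "point", seed = 5,
                               features = toy_features)
  expect_equal(res2$best$family, "linear")
  res2b <- tune_hyperparameters(pts, space2, folds = 3, unit = "point", seed = 5,
                                features = toy_features)
  expect_identical(res2$trials, res2b$trials)

  expect_error(tune_hyperparameters(pts, list(), seed = 1), "empty")
})

test_that("surrogates refuse unusable training input", {
  pts <- cached_points()
  expect_error(fit_surrogate(pts[1:5, ], model_spec("linear")), "20 training points")
  bad <- pts[1:50, ]
  bad$gln_start[3] <- NA
  expect_error(fit_surrogate(bad, model_spec("linear")), "non-finite")
})
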