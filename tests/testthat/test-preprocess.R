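test_that("cleaning removes exactly the flagged points and nothing else", {
  runs <- cached_dataset()  # flag_fraction 0.025 of 754 samples -> 19 flags
  pts <- flatten_to_points(runs)
  expect_equal(sum(nzchar(pts$flags)), 19)
  cleaned <- suppressMessages(clean_points(pts))
  expect_equal(nrow(cleaned), 754 - 19)
  expect_true(all(cleaned$flags == ""))
  expect_equal(nrow(attr(cleaned, "removed")), 19)
  # surviving values are untouched
  kept <- pts[pts$flags == "", ]
  rownames(kept) <- NULL
  expect_equal(cleaned$titer_at_t, kept$titer_at_t)

  unflagged <- pts[pts$flags == "", ]
  expect_equal(nrow(clean_points(unflagged)), nrow(unflagged))

  all_flagged <- pts[nzchar(pts$flags), ]
  expect_warning(suppressMessages(res <- clean_points(all_flagged)), "empty")
  expect_equal(nrow(res), 0)
})

test_that("scaler uses population statistics from training data only", {
  sc <- fit_scaler(matrix(c(2, 4), ncol = 1, dimnames = list(NULL, "a")))
  expect_equal(unname(sc$center), 3)
  expect_equal(unname(sc$scale), 1)  # population sd, not sample sd
  expect_equal(unname(apply_scaler(sc, matrix(c(2, 4), ncol = 1))[, 1]), c(-1, 1))

  set.seed(3)
  X <- matrix(rnorm(60, 5, 2), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(colMeans(Z^2) - 1) < 1e-6))
  expect_equal(inverse_scaler(sc, Z), X, tolerance = 1e-12)

  expect_warning(sc0 <- fit_scaler(matrix(c(5, 5, 5), ncol = 1)), "constant")
  expect_equal(unname(apply_scaler(sc0, matrix(c(5, 5, 5), ncol = 1))[, 1]), c(0, 0, 0))

  # no leakage: perturbing rows that were never fitted changes nothing
  sc2 <- fit_scaler(X)
  test_rows <- X + 100
  expect_equal(sc2$center, sc$center)
  expect_equal(apply_scaler(sc, test_rows), sweep(sweep(test_rows, 2, sc$center), 2, sc$scale, "/"))
})

test_that("train/test split respects fraction, unit and seed", {
  pts <- data.frame(run_id = rep(sprintf("r%02d", 1:10), each = 13), x = rnorm(130))

  sp <- split_train_test(pts, 0.8, unit = "run", seed = 7)
  expect_equal(length(unique(sp$train$run_id)), 8)
  expect_equal(length(unique(sp$test$run_id)), 2)
  expect_length(intersect(sp$train$run_id, sp$test$run_id), 0)

  again <- split_train_test(pts, 0.8, unit = "run", seed = 7)
  expect_identical(sp, again)

  # point-level 80% of 735 -> floor = 588 train, 147 test
  pts2 <- data.frame(run_id = "r", x = seq_len(735))
  sp2 <- split_train_test(pts2, 0.8, unit = "point", seed = 1)
  expect_equal(nrow(sp2$train), 588)
  expect_equal(nrow(sp2$test), 147)

  expect_error(split_train_test(pts, 1.2), "train_fraction")
  expect_error(split_train_test(pts[pts$run_id == "r01", ], unit = "run"), "two runs")
})

test_that("feature selection recovers a single exact driver", {
  set.seed(10)
  n <- 300
  pts <- data.frame(x1 = runif(n, -2, 2), n1 = runif(n), n2 = runif(n),
                    n3 = runif(n), n4 = runif(n))
  pts$y <- pts$x1^2
  rep <- iterative_feature_selection(pts, c("x1", "n1", "n2", "n3", "n4"),
                                     target = "y", seed = 1)
  expect_equal(rep$selected[1], "x1")
  expect_false(any(c("n1", "n2", "n3", "n4") %in% rep$selected))
  # x1 exceeded the threshold in the first iteration
  expect_gt(rep$iterations[[1]]["x1"], 0.1)
})

test_that("feature selection terminates when nothing clears the threshold", {
  set.seed(4)
  n <- 200
  pts <- data.frame(a = runif(n), b = runif(n), c = runif(n), d = runif(n),
                    e = runif(n), f = runif(n), g = runif(n), h = runif(n))
  pts$y <- rnorm(n)  # pure noise target: importances ~ 1/8 but threshold-ish
  rep <- iterative_feature_selection(pts, letters[1:8], target = "y",
                                     threshold = 0.5, seed = 1)
  expect_length(rep$selected, 0)
  expect_length(rep$iterations, 1)
})

test_that("importances are normalized and selection ignores candidate order", {
  pts <- cached_points()
  feats <- input_features()
  a <- iterative_feature_selection(pts, feats, seed = 21)
  b <- iterative_feature_selection(pts, rev(feats), seed = 21)
  expect_identical(a$selected, b$selected)
  for (imp in a$iterations) expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_length(intersect(a$selected, a$excluded_a_priori), 0)
})

test_that("feature selection rejects bad inputs", {
  pts <- data.frame(a = 1:10, y = 1:10)
  expect_error(iterative_feature_selection(pts, "a", target = "y"), "two candidate")
  expect_error(iterative_feature_selection(cbind(pts, b = letters[1:10]),
                                           c("a", "b"), target = "y"), "not numeric")
  expect_error(iterative_feature_selection(cbind(pts, b = 1:10),
                                           c("a", "b", "y"), target = "y"), "target")
})
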