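#' Specify a surrogate model
#'
#' Four regressor families map the nine process inputs to the four KPIs:
#' ordinary least squares (\code{linear}), partial least squares
#' (\code{latent_projection}), random forests (\code{tree_ensemble}, one
#' forest per output) and a feedforward neural network
#' (\code{feedforward_net}, multi-output, ReLU activations, Adam solver,
#' L2 penalty).  Defaults follow the study configuration: 4 latent
#' components, 4 trees, hidden layers (50, 25, 25, 50) for the
#' model-comparison phase and (100, 50, 25, 50, 100) with alpha 0.1 for the
#' final network.
#'
#' @param family One of \code{"linear"}, \code{"latent_projection"},
#'   \code{"tree_ensemble"}, \code{"feedforward_net"}.
#' @param components Latent components (latent_projection only).
#' @param trees Trees per forest (tree_ensemble only).
#' @param hidden_layers Integer vector of hidden layer sizes
#'   (feedforward_net only).
#' @param alpha L2 regularization weight of the network loss.
#' @param learning_rate,max_epochs,tol Network training controls: Adam step
#'   size, epoch cap, and minimum loss improvement before early stopping.
#' @param patience Epochs without a loss improvement of at least \code{tol}
#'   before training stops early.
#'
#' @return An object of class \code{cho_model_spec}.
#' @examples
#' model_spec("feedforward_net", hidden_layers = c(100, 50, 25, 50, 100))
#' @export
model_spec <- function(family = c("feedforward_net", "linear",
                                  "latent_projection", "tree_ensemble"),
                       components = 4L, trees = 4L,
                       hidden_layers = c(50L, 25L, 25L, 50L), alpha = 0.1,
                       learning_rate = 0.01, max_epochs = 2000L, tol = 1e-6,
                       patience = 250L) {
  family <- match.arg(family)
  if (any(hidden_layers <= 0)) stop_choopt("model_spec: hidden layer sizes must be positive")
  if (!is_number(alpha) || alpha < 0) stop_choopt("model_spec: alpha must be >= 0")
  spec <- list(family = family, components = as.integer(components),
               trees = as.integer(trees), hidden_layers = as.integer(hidden_layers),
               activation = "relu", solver = "adam", alpha = alpha,
               learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
               tol = tol, patience = as.integer(patience))
  class(spec) <- "cho_model_spec"
  spec
}

# rough parameter count, used as the tie-break in hyperparameter tuning
spec_param_count <- function(spec, n_in = 9L, n_out = 4L) {
  switch(spec$family,
    linear = (n_in + 1L) * n_out,
    latent_projection = spec$components * (n_in + n_out),
    tree_ensemble = spec$trees * n_out * 50L,
    feedforward_net = {
      sizes <- c(n_in, spec$hidden_layers, n_out)
      sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
    })
}

spec_label <- function(spec) {
  switch(spec$family,
    linear = "linear",
    latent_projection = sprintf("latent_projection(ncomp=%d)", spec$components),
    tree_ensemble = sprintf("tree_ensemble(trees=%d)", spec$trees),
    feedforward_net = sprintf("feedforward_net(%s, alpha=%g)",
                              paste(spec$hidden_layers, collapse = ","), spec$alpha))
}

#' Fit a multi-output surrogate on training points
#'
#' Fits the input and output standard scalers on the training partition
#' only, trains the requested regressor family on the scaled data, and
#' records training provenance (seed, final regularized loss, training
#' R-squared, feature ranges for extrapolation flagging).
#'
#' @param train_points Point table (training partition).
#' @param spec A [model_spec()].
#' @param seed Integer seed; given identical data and seed the fit is
#'   bit-reproducible.
#' @param features Input column names (default the nine canonical inputs).
#' @param outputs Output column names (default the four KPIs).
#'
#' @return An object of class \code{cho_surrogate}.
#' @export
fit_surrogate <- function(train_points, spec = model_spec(), seed = 1L,
                          features = input_features(), outputs = kpi_names()) {
  stopifnot(inherits(spec, "cho_model_spec"))
  if (nrow(train_points) < 20L) stop_choopt("fit_surrogate: need at least 20 training points")
  X <- as.matrix(train_points[, features, drop = FALSE])
  Y <- as.matrix(train_points[, outputs, drop = FALSE])
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop_choopt("fit_surrogate: non-finite values in features or outputs")
  }
  in_scaler <- suppressWarnings(fit_scaler(X))
  out_scaler <- suppressWarnings(fit_scaler(Y))
  Xs <- apply_scaler(in_scaler, X)
  Ys <- apply_scaler(out_scaler, Y)

  fit <- switch(spec$family,
    linear = {
      lm_fit <- stats::lm.fit(cbind(1, Xs), Ys)
      list(coef = lm_fit$coefficients)
    },
    latent_projection = {
      ncomp <- min(spec$components, ncol(Xs))
      pls_fit <- with_seed(seed, mixOmics::pls(Xs, Ys, ncomp = ncomp, mode = "regression"))
      list(pls = pls_fit, ncomp = ncomp)
    },
    tree_ensemble = {
      seeds <- derive_seeds(seed, ncol(Ys))
      forests <- lapply(seq_len(ncol(Ys)), function(j) {
        with_seed(seeds[j], randomForest::randomForest(
          x = as.data.frame(Xs), y = Ys[, j], ntree = spec$trees))
      })
      list(forests = forests)
    },
    feedforward_net = {
      net <- mlp_fit(Xs, Ys, hidden = spec$hidden_layers, alpha = spec$alpha,
                     learning_rate = spec$learning_rate,
                     max_epochs = spec$max_epochs, tol = spec$tol,
                     n_iter_no_change = spec$patience, seed = seed)
      list(net = net)
    })

  model <- list(spec = spec, fit = fit, input_scaler = in_scaler,
                output_scaler = out_scaler, features = features, outputs = outputs,
                train_range = list(min = apply(X, 2, min), max = apply(X, 2, max)))
  class(model) <- "cho_surrogate"

  Ys_hat <- predict_scaled(model, Xs)
  wns <- if (spec$family == "feedforward_net") mlp_weight_norm_sq(fit$net) else 0
  model$provenance <- list(
    seed = as.integer(seed), n_train = nrow(X),
    final_loss = loss_mse_l2(Ys, Ys_hat, alpha = spec$alpha, weight_norm_sq = wns),
    train_r2 = r2_score(Ys, Ys_hat),
    label = spec_label(spec), fitted_at = format(Sys.time(), tz = "UTC")
  )
  model
}

# forward pass on already-scaled inputs, returning scaled outputs
predict_scaled <- function(model, Xs) {
  out <- switch(model$spec$family,
    linear = cbind(1, Xs) %*% model$fit$coef,
    latent_projection = {
      colnames(Xs) <- model$features
      pr <- stats::predict(model$fit$pls, Xs)
      pr$predict[, , model$fit$ncomp, drop = TRUE]
    },
    tree_ensemble = {
      df <- as.data.frame(Xs)
      do.call(cbind, lapply(model$fit$forests, function(f) stats::predict(f, df)))
    },
    feedforward_net = mlp_predict(model$fit$net, Xs)
  )
  out <- matrix(out, nrow = nrow(Xs))
  colnames(out) <- model$outputs
  out
}

#' @export
print.cho_surrogate <- function(x, ...) {
  cat(sprintf("<cho_surrogate> %s | %d train points | train R2 %.3f\n",
              x$provenance$label, x$provenance$n_train, x$provenance$train_r2))
  invisible(x)
}

#' Predict the four KPIs for new process settings
#'
#' Scales the inputs with the training scalers, runs the fitted regressor
#' and back-scales the outputs to physical units.  Rows with any input
#' outside the training range are predicted anyway but flagged as
#' extrapolations (column \code{extrapolated}); the screening report uses
#' the flag to distinguish interpolated from extrapolated optima.
#'
#' @param model A \code{cho_surrogate}.
#' @param inputs Data frame or matrix containing the model's input columns.
#' @return Data frame with the four KPI columns (physical units) and a
#'   logical \code{extrapolated} column.
#' @export
predict_kpis <- function(model, inputs) {
  stopifnot(inherits(model, "cho_surrogate"))
  inputs <- as.data.frame(inputs)
  missing <- setdiff(model$features, names(inputs))
  if (length(missing) > 0L) {
    stop_choopt("predict_kpis: expected features [%s]; missing [%s]",
                paste(model$features, collapse = ", "), paste(missing, collapse = ", "))
  }
  X <- as.matrix(inputs[, model$features, drop = FALSE])
  if (any(!is.finite(X))) stop_choopt("predict_kpis: non-finite inputs")
  Xs <- apply_scaler(model$input_scaler, X)
  Ys_hat <- predict_scaled(model, Xs)
  Y <- inverse_scaler(model$output_scaler, Ys_hat)
  extrap <- rowSums(sweep(X, 2, model$train_range$min, "<") |
                      sweep(X, 2, model$train_range$max, ">")) > 0
  out <- as.data.frame(Y)
  names(out) <- model$outputs
  out$extrapolated <- as.logical(extrap)
  rownames(out) <- NULL
  out
}

# fold assignment at run or point level, seeded
make_folds <- function(points, folds, unit = "run", seed = 1L) {
  if (unit == "run") {
    ids <- unique(points$run_id)
    if (length(ids) < folds) stop_choopt("need at least %d runs for %d folds", folds, folds)
    fold_of_id <- with_seed(seed, sample(rep_len(seq_len(folds), length(ids))))
    names(fold_of_id) <- ids
    fold_of_id[points$run_id]
  } else {
    with_seed(seed, sample(rep_len(seq_len(folds), nrow(points))))
  }
}

cv_r2 <- function(points, spec, folds = 3L, unit = "run", seed = 1L,
                  features = input_features(), outputs = kpi_names()) {
  assignment <- make_folds(points, folds, unit, seed)
  r2s <- vapply(seq_len(folds), function(k) {
    train <- points[assignment != k, , drop = FALSE]
    test <- points[assignment == k, , drop = FALSE]
    model <- fit_surrogate(train, spec, seed = seed + k, features = features,
                           outputs = outputs)
    pred <- predict_kpis(model, test)
    r2_score(as.matrix(test[, outputs]), as.matrix(pred[, outputs]))
  }, numeric(1))
  mean(r2s)
}

#' Compare surrogate families by cross-validated R-squared
#'
#' Fits each candidate family on the full point set (training R-squared)
#' and in k-fold cross-validation with folds split at the configured unit
#' (runs by default, so no cultivation contributes to both sides of a
#' fold).  Optionally records a learning curve of CV R-squared versus
#' training size.
#'
#' @param points Cleaned point table.
#' @param specs Named list of [model_spec()]s; defaults to the four study
#'   families.
#' @param folds Number of CV folds (default 3).
#' @param unit Fold unit, \code{"run"} or \code{"point"}.
#' @param seed Integer seed.
#' @param learning_curve If TRUE, also evaluate each family on nested
#'   subsets of the training folds (fractions 0.25, 0.5, 1).
#' @param features,outputs Input and output column names (defaults: the
#'   nine canonical inputs and the four KPIs).
#'
#' @return An object of class \code{cho_model_comparison}: data frame
#'   \code{summary} (family, label, train_r2, cv_r2) plus optional
#'   \code{learning_curves}.
#' @export
compare_models <- function(points, specs = NULL, folds = 3L,
                           unit = c("run", "point"), seed = 1L,
                           learning_curve = FALSE,
                           features = input_features(), outputs = kpi_names()) {
  unit <- match.arg(unit)
  if (folds < 2L) stop_choopt("compare_models: folds must be >= 2")
  if (is.null(specs)) {
    specs <- list(
      linear = model_spec("linear"),
      latent_projection = model_spec("latent_projection", components = 4L),
      tree_ensemble = model_spec("tree_ensemble", trees = 4L),
      feedforward_net = model_spec("feedforward_net", hidden_layers = c(50L, 25L, 25L, 50L))
    )
  }
  assignment <- make_folds(points, folds, unit, seed)
  curves <- list()
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    full <- fit_surrogate(points, spec, seed = seed, features = features,
                          outputs = outputs)
    fold_r2 <- vapply(seq_len(folds), function(k) {
      train <- points[assignment != k, , drop = FALSE]
      test <- points[assignment == k, , drop = FALSE]
      model <- fit_surrogate(train, spec, seed = seed + k, features = features,
                             outputs = outputs)
      pred <- predict_kpis(model, test)
      r2_score(as.matrix(test[, outputs]), as.matrix(pred[, outputs]))
    }, numeric(1))
    if (learning_curve) {
      fracs <- c(0.25, 0.5, 1)
      curves[[nm]] <<- data.frame(
        fraction = fracs,
        cv_r2 = vapply(fracs, function(fr) {
          mean(vapply(seq_len(folds), function(k) {
            train <- points[assignment != k, , drop = FALSE]
            ids <- unique(train$run_id)
            keep <- with_seed(seed + k, sample(ids, max(2L, floor(fr * length(ids)))))
            train <- train[train$run_id %in% keep, , drop = FALSE]
            test <- points[assignment == k, , drop = FALSE]
            model <- fit_surrogate(train, spec, seed = seed + k,
                                   features = features, outputs = outputs)
            pred <- predict_kpis(model, test)
            r2_score(as.matrix(test[, outputs]), as.matrix(pred[, outputs]))
          }, numeric(1)))
        }, numeric(1)))
    }
    data.frame(family = spec$family, label = spec_label(spec),
               train_r2 = full$provenance$train_r2, cv_r2 = mean(fold_r2),
               stringsAsFactors = FALSE)
  })
  out <- list(summary = do.call(rbind, rows), folds = folds, unit = unit,
              seed = seed, learning_curves = if (learning_curve) curves else NULL)
  class(out) <- "cho_model_comparison"
  out
}

#' @export
print.cho_model_comparison <- function(x, ...) {
  cat(sprintf("<model comparison> %d-fold CV at %s level\n", x$folds, x$unit))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Grid search over model specifications
#'
#' Evaluates every spec in the search space by k-fold cross-validated
#' R-squared and returns the best.  Ties (within 1e-12) are broken by the
#' smaller parameter count, then by the lexicographically smaller label.
#'
#' @param points Cleaned point table.
#' @param space Non-empty list of [model_spec()]s.
#' @param folds CV folds (default 3).
#' @param unit Fold unit.
#' @param seed Integer seed.
#' @param features,outputs Input and output column names.
#' @return List with \code{best} (the winning spec), \code{best_label} and
#'   \code{trials} (data frame label/cv_r2/params).
#' @export
tune_hyperparameters <- function(points, space, folds = 3L,
                                 unit = c("run", "point"), seed = 1L,
                                 features = input_features(), outputs = kpi_names()) {
  unit <- match.arg(unit)
  if (length(space) == 0L) stop_choopt("tune_hyperparameters: empty search space")
  trials <- data.frame(
    label = vapply(space, spec_label, character(1)),
    cv_r2 = vapply(space, function(s) {
      cv_r2(points, s, folds, unit, seed, features = features, outputs = outputs)
    }, numeric(1)),
    params = vapply(space, spec_param_count, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-trials$cv_r2, trials$params, trials$label)
  trials <- trials[ord, ]
  rownames(trials) <- NULL
  list(best = space[[ord[1L]]], best_label = trials$label[1L], trials = trials)
}
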