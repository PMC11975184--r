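#' Remove QC-flagged data points
#'
#' Drops every point whose \code{flags} entry is non-empty (contamination,
#' analytics failures), leaving the surviving points untouched.  The
#' removals are summarised in a message and attached as the
#' \code{"removed"} attribute for auditing.
#'
#' @param points Point table from [flatten_to_points()].
#' @return The cleaned point table; attribute \code{"removed"} holds the
#'   dropped rows with their flag reasons.
#' @examples
#' pts <- data.frame(x = 1:3, flags = c("", "CONTAMINATED", ""))
#' nrow(clean_points(pts))  # 2
#' @export
clean_points <- function(points) {
  flags <- points$flags
  if (is.null(flags)) stop_choopt("clean_points: points carry no 'flags' column")
  flags[is.na(flags)] <- ""
  keep <- !nzchar(flags)
  removed <- points[!keep, , drop = FALSE]
  if (nrow(removed) > 0L) {
    message(sprintf("clean_points: removed %d flagged point(s) (%s)", nrow(removed),
                    paste(sprintf("%s x%d", names(table(removed$flags)),
                                  as.integer(table(removed$flags))), collapse = ", ")))
  }
  out <- points[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("clean_points: all points were flagged; result is empty")
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Iterative impurity-based feature selection
#'
#' Repeatedly fits a tree-ensemble regressor (random forest, 100 trees,
#' impurity importances normalized to sum 1) of the remaining candidate
#' features against the target.  Features whose normalized importance
#' exceeds the threshold (strictly) are appended to the selected set and
#' removed from the pool; iteration stops when no feature exceeds the
#' threshold or fewer than two candidates remain.  Candidates are processed
#' in lexicographic order so the result is invariant to input ordering.
#'
#' Because the normalized importances of one iteration always sum to 1, a
#' pool containing no informative feature would still put some features
#' above any threshold below 1/pool-size.  Importances are therefore only
#' acted on while the iteration's forest retains out-of-bag predictive
#' skill (OOB R-squared > 0); once the remaining pool cannot predict the
#' target at all, the iteration is recorded and selection stops.
#'
#' @param points Point table.
#' @param candidate_features Character vector of candidate input columns
#'   (at least two).
#' @param target Target column name (default \code{"titer_at_t"}); must not
#'   be among the candidates.
#' @param threshold Importance threshold (default 0.1, strict
#'   greater-than).
#' @param seed RNG seed for the forests.
#' @param excluded_a_priori Features removed from the pool before the first
#'   iteration (e.g. inputs with too unbalanced a distribution to trust).
#' @param ntree Trees per forest (default 100).
#'
#' @return An object of class \code{cho_feature_selection}: list with
#'   \code{iterations} (list of named importance vectors, each summing to
#'   1), \code{selected} (character, in selection order), \code{threshold}
#'   and \code{excluded_a_priori}.
#' @export
iterative_feature_selection <- function(points, candidate_features,
                                        target = "titer_at_t", threshold = 0.1,
                                        seed = 1L, excluded_a_priori = character(0),
                                        ntree = 100L) {
  candidate_features <- sort(setdiff(unique(candidate_features), excluded_a_priori))
  if (target %in% candidate_features) {
    stop_choopt("feature selection: target '%s' cannot be a candidate", target)
  }
  if (length(candidate_features) < 2L) {
    stop_choopt("feature selection: need at least two candidate features")
  }
  for (f in c(candidate_features, target)) {
    if (!f %in% names(points)) stop_choopt("feature selection: column '%s' not found", f)
    if (!is.numeric(points[[f]])) stop_choopt("feature selection: column '%s' is not numeric", f)
  }

  pool <- candidate_features
  selected <- character(0)
  iterations <- list()
  seeds <- derive_seeds(seed, 50L)
  it <- 0L
  while (length(pool) >= 2L) {
    it <- it + 1L
    X <- points[, pool, drop = FALSE]
    y <- points[[target]]
    # mtry = all features: every split may pick the strongest remaining
    # feature, which keeps spurious importance of uninformative features low
    fit <- with_seed(seeds[it], randomForest::randomForest(
      x = X, y = y, ntree = ntree, mtry = ncol(X), importance = FALSE))
    imp <- fit$importance[, "IncNodePurity"]
    imp <- imp / sum(imp)
    imp <- imp[order(-imp, names(imp))]
    iterations[[it]] <- imp
    oob_r2 <- fit$rsq[length(fit$rsq)]
    if (!is.finite(oob_r2) || oob_r2 <= 0) break
    hits <- names(imp)[imp > threshold]
    if (length(hits) == 0L) break
    selected <- c(selected, hits)
    pool <- setdiff(pool, hits)
  }
  out <- list(iterations = iterations, selected = selected,
              threshold = threshold, excluded_a_priori = excluded_a_priori)
  class(out) <- "cho_feature_selection"
  out
}

#' @export
print.cho_feature_selection <- function(x, ...) {
  cat(sprintf("<feature selection> %d iteration(s), threshold %.2f\n",
              length(x$iterations), x$threshold))
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Split points into training and test sets
#'
#' Splits at the point level (mirroring a plain random split of the data
#' table) or at the run level, which keeps all daily points of one
#' cultivation on the same side and therefore prevents trajectory leakage
#' between the partitions.  The training partition receives
#' \code{floor(train_fraction * n_units)} units.
#'
#' @param points Point table with a \code{run_id} column.
#' @param train_fraction Fraction of units assigned to training
#'   (default 0.8).
#' @param unit \code{"run"} (default) or \code{"point"}.
#' @param seed RNG seed.
#' @return List with data frames \code{train} and \code{test}.
#' @examples
#' pts <- data.frame(run_id = rep(sprintf("r%d", 1:10), each = 13), x = 0)
#' sp <- split_train_test(pts, seed = 1)
#' length(unique(sp$train$run_id))  # 8
#' @export
split_train_test <- function(points, train_fraction = 0.8,
                             unit = c("run", "point"), seed = 1L) {
  unit <- match.arg(unit)
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_choopt("split_train_test: train_fraction must lie in (0, 1)")
  }
  if (unit == "run") {
    ids <- unique(points$run_id)
    if (length(ids) < 2L) stop_choopt("split_train_test: need at least two runs")
    n_train <- floor(train_fraction * length(ids))
    if (n_train < 1L || n_train >= length(ids)) {
      stop_choopt("split_train_test: fraction leaves an empty partition")
    }
    train_ids <- with_seed(seed, sample(ids, n_train))
    train <- points[points$run_id %in% train_ids, , drop = FALSE]
    test <- points[!points$run_id %in% train_ids, , drop = FALSE]
  } else {
    n <- nrow(points)
    if (n < 2L) stop_choopt("split_train_test: need at least two points")
    n_train <- floor(train_fraction * n)
    if (n_train < 1L || n_train >= n) {
      stop_choopt("split_train_test: fraction leaves an empty partition")
    }
    idx <- with_seed(seed, sample.int(n, n_train))
    train <- points[idx, , drop = FALSE]
    test <- points[-idx, , drop = FALSE]
  }
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Standard scaling fitted on training data only
#'
#' \code{fit_scaler} computes per-column means and population (ddof 0)
#' standard deviations on the training matrix; \code{apply_scaler} centers
#' and scales any matrix with those training statistics, and
#' \code{inverse_scaler} undoes the transform.  Constant columns get scale
#' 1 (with a warning) so they map to 0 rather than NaN.
#'
#' @param x Numeric matrix or data frame (rows = samples).
#' @param scaler A \code{cho_scaler} from \code{fit_scaler}.
#' @return \code{fit_scaler}: a \code{cho_scaler} (features, center,
#'   scale).  \code{apply_scaler}/\code{inverse_scaler}: a numeric matrix.
#' @examples
#' sc <- fit_scaler(matrix(c(2, 4), ncol = 1))
#' apply_scaler(sc, matrix(c(2, 4), ncol = 1))  # -1, 1
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_choopt("fit_scaler: input must be numeric")
  center <- colMeans(x)
  n <- nrow(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  if (any(scale == 0)) {
    warning(sprintf("fit_scaler: constant column(s) %s; scale set to 1",
                    paste(colnames(x)[scale == 0], collapse = ", ")))
    scale[scale == 0] <- 1
  }
  out <- list(features = colnames(x), center = center, scale = scale)
  class(out) <- "cho_scaler"
  out
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "cho_scaler"))
  x <- as.matrix(x)
  if (!is.null(scaler$features) && !is.null(colnames(x))) {
    if (!identical(colnames(x), scaler$features)) {
      if (!all(scaler$features %in% colnames(x))) {
        stop_choopt("apply_scaler: missing column(s): %s",
                    paste(setdiff(scaler$features, colnames(x)), collapse = ", "))
      }
      x <- x[, scaler$features, drop = FALSE]
    }
  }
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
inverse_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "cho_scaler"))
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$center, "+")
  colnames(out) <- scaler$features
  out
}
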