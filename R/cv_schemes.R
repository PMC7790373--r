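#' Chronological train/test split
#'
#' The first `floor(n * train_fraction)` days form the training region and
#' the remainder is held out for final testing, preserving time order.
#' Cross-validation fold plans operate only inside the training region.
#'
#' @param n number of days (feature-matrix rows); must be >= 10.
#' @param train_fraction proportion in (0, 1); default 0.70.
#' @return list with integer index vectors `train` and `test` (1-based,
#'   contiguous, ordered).
#' @examples
#' chronological_split(10)          # train 1..7, test 8..10
#' lengths(chronological_split(1818))  # 1272 / 546
#' @export
chronological_split <- function(n, train_fraction = 0.70) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must be in (0, 1)")
  }
  if (n < 10) stopf("need at least 10 days to split")
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    stopf("split leaves an empty train or test set (n = %d, fraction = %g)",
          n, train_fraction)
  }
  list(train = seq_len(n_train), test = seq.int(n_train + 1L, n))
}

new_fold_plan <- function(scheme, folds, blocks = NULL) {
  structure(list(scheme = scheme, folds = folds, blocks = blocks),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> scheme = %s, %d folds\n", x$scheme,
              length(x$folds)))
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: train %d, validation %d\n", i,
                length(f$train), length(f$validation)))
  }
  invisible(x)
}

# cut `idx` (ordered) into k contiguous blocks whose sizes differ by <= 1;
# earlier blocks absorb the remainder.
contiguous_blocks <- function(idx, k) {
  n <- length(idx)
  base <- n %/% k
  sizes <- base + as.integer(seq_len(k) <= n %% k)
  split(idx, rep(seq_len(k), times = sizes))
}

#' Random five-fold CV over the training region
#'
#' Training-region indices are randomly permuted under `seed` and dealt
#' into `k` near-equal validation sets; each fold trains on the other
#' `k - 1` sets.  This is the conventional shuffled K-fold scheme, kept as
#' the baseline that serial data may punish.
#'
#' @param train_idx ordered training-region indices.
#' @param k folds (default 5); `k = length(train_idx)` gives leave-one-out.
#' @param seed integer seed; the plan is a pure function of
#'   `(train_idx, k, seed)`.
#' @return a `fold_plan`.
#' @export
five_fold_folds <- function(train_idx, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stopf("k must be >= 2")
  if (k > length(train_idx)) stopf("k exceeds the training-region size")
  perm <- with_seed(seed, sample(train_idx))
  vals <- contiguous_blocks(perm, k)
  folds <- lapply(vals, function(v) {
    list(train = sort(setdiff(train_idx, v)), validation = sort(v))
  })
  new_fold_plan("five_fold", unname(folds))
}

#' Leave-one-block-out CV (LOBO-CV)
#'
#' The training region is cut into `k` contiguous blocks; each block in
#' turn is the validation set and ALL remaining blocks -- both before and
#' after it -- train the model.  Like leave-one-out but on blocks of
#' consecutive days, so the serial structure inside each block is intact
#' while still using the full training region.
#'
#' @param train_idx ordered training-region indices.
#' @param k number of blocks/folds (default 5).
#' @return a `fold_plan` with block boundaries attached.
#' @export
lobo_folds <- function(train_idx, k = 5L) {
  k <- as.integer(k)
  if (k < 2) stopf("k must be >= 2 (a single block leaves nothing to train on)")
  if (k > length(train_idx)) stopf("k exceeds the training-region size")
  blocks <- contiguous_blocks(train_idx, k)
  folds <- lapply(seq_len(k), function(i) {
    list(train = sort(unlist(blocks[-i], use.names = FALSE)),
         validation = blocks[[i]])
  })
  new_fold_plan("lobo", folds, blocks = blocks)
}

#' Temporal-block CV (TB-CV, forward chaining)
#'
#' Strict temporal precedence: only blocks that come before the validation
#' block may train the model, so later data never predicts earlier
#' outcomes.  By default the training region is cut into `k + 1` contiguous
#' blocks and fold `i` trains on blocks `1..i` and validates on block
#' `i + 1`, producing exactly `k` validation errors with strictly growing
#' training sets (the first fold's being the smallest).  `mode =
#' "drop_first"` instead cuts `k` blocks and yields `k - 1` folds.
#'
#' @param train_idx ordered training-region indices.
#' @param k number of validation folds (default 5).
#' @param mode `"forward_chain"` (default, k+1 blocks) or `"drop_first"`.
#' @return a `fold_plan`.
#' @export
tb_folds <- function(train_idx, k = 5L, mode = c("forward_chain", "drop_first")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1) stopf("k must be >= 1")
  n_blocks <- if (mode == "forward_chain") k + 1L else k
  if (n_blocks > length(train_idx)) {
    stopf("training region too small for %d non-empty blocks", n_blocks)
  }
  if (mode == "drop_first" && k < 2) stopf("drop_first mode needs k >= 2")
  blocks <- contiguous_blocks(train_idx, n_blocks)
  folds <- lapply(seq_len(n_blocks - 1L), function(i) {
    list(train = sort(unlist(blocks[seq_len(i)], use.names = FALSE)),
         validation = blocks[[i + 1L]])
  })
  new_fold_plan("tb", folds, blocks = blocks)
}

#' CV error: the mean of per-fold validation MSEs
#'
#' @param fold_mses numeric vector of per-fold validation mean squared
#'   errors; all finite and non-negative.
#' @return their arithmetic mean.
#' @export
cv_error <- function(fold_mses) {
  if (length(fold_mses) == 0) stopf("no fold MSEs")
  if (any(!is.finite(fold_mses)) || any(fold_mses < 0)) {
    stopf("fold MSEs must be finite and non-negative")
  }
  mean(fold_mses)
}

#' Check a fold plan against the scheme's structural guarantees
#'
#' Scheme-agnostic brute-force checker operating on raw index sets:
#' train/validation disjointness in every fold; for `five_fold` and `lobo`,
#' pairwise-disjoint validation sets covering the whole training region
#' (and for `lobo`, each fold's train set equal to the region minus its
#' block); for `tb`, strict temporal precedence and strictly growing
#' training sets.
#'
#' @param plan a `fold_plan`.
#' @param train_idx the training-region indices the plan was built from.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_fold_plan <- function(plan, train_idx) {
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    if (length(intersect(f$train, f$validation)) > 0) {
      stopf("fold %d: train and validation overlap", i)
    }
    if (length(f$train) == 0 || length(f$validation) == 0) {
      stopf("fold %d: empty train or validation set", i)
    }
    if (!all(c(f$train, f$validation) %in% train_idx)) {
      stopf("fold %d: indices outside the training region", i)
    }
  }
  vals <- lapply(plan$folds, `[[`, "validation")
  if (plan$scheme %in% c("five_fold", "lobo")) {
    flat <- unlist(vals)
    if (anyDuplicated(flat)) stopf("validation sets overlap across folds")
    if (!setequal(flat, train_idx)) {
      stopf("validation sets do not cover the training region")
    }
    if (plan$scheme == "lobo") {
      for (i in seq_along(plan$folds)) {
        if (!setequal(plan$folds[[i]]$train,
                      setdiff(train_idx, vals[[i]]))) {
          stopf("lobo fold %d: train set is not the region minus its block", i)
        }
      }
    }
  }
  if (plan$scheme == "tb") {
    sizes <- vapply(plan$folds, function(f) length(f$train), integer(1))
    if (any(diff(sizes) <= 0)) stopf("tb training sets must strictly grow")
    for (i in seq_along(plan$folds)) {
      f <- plan$folds[[i]]
      if (max(f$train) >= min(f$validation)) {
        stopf("tb fold %d: training data does not strictly precede validation", i)
      }
    }
  }
  invisible(TRUE)
}

#' Run one cross-validation pass of the network over a fold plan
#'
#' For each fold: continuous inputs are standardized with statistics from
#' the fold's training rows only, a network is trained on those rows, and
#' the validation MSE is recorded.  Per-fold seeds derive deterministically
#' from `spec$seed`, so the whole pass is reproducible.  Lag features are
#' taken as given -- lags are observed predictors, so a validation row may
#' legitimately carry lagged values originating from earlier days.
#'
#' @param features a `feature_matrix` (or plain matrix `X` with `y` given).
#' @param plan a `fold_plan` whose indices refer to feature rows.
#' @param spec a [network_spec()].
#' @param y outcome vector; defaults to `features$y`.
#' @return a `cv_result`: list with `fold_mses`, `cv_error`, `scheme`,
#'   `hidden`, `seed`.
#' @export
cv_run <- function(features, plan, spec, y = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$X else
    as.matrix(features)
  if (is.null(y)) {
    if (!inherits(features, "feature_matrix")) stopf("y must be supplied")
    y <- features$y
  }
  fold_mses <- vapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    sc <- standardize(X[f$train, , drop = FALSE])
    scaling <- attr(sc, "scaling")
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, i)
    net <- train_network(sc, y[f$train], fold_spec)
    pred <- predict(net, apply_scaling(scaling, X[f$validation, , drop = FALSE]))
    mse(pred, y[f$validation])
  }, numeric(1))
  structure(list(fold_mses = fold_mses, cv_error = cv_error(fold_mses),
                 scheme = plan$scheme, hidden = spec$hidden,
                 seed = spec$seed),
            class = "cv_result")
}
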