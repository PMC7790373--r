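#' Permute a training outcome vector
#'
#' Draws a uniformly random permutation of `y` under `seed`, preserving the
#' multiset of values exactly.  This constructs the null hypothesis of no
#' association between the outcome and the (correlated, lagged) predictors
#' while leaving the predictors themselves untouched.
#'
#' @param y outcome vector, length >= 2.
#' @param seed integer seed.
#' @return permuted copy of `y`.
#' @export
permute_outcome <- function(y, seed = 1L) {
  if (length(y) < 2) stopf("need at least 2 outcomes to permute")
  with_seed(seed, sample(y))
}

#' CV error under the permutation null
#'
#' For each of `n_permutations` replicates, the outcomes over the training
#' region (the union of the plan's indices) are shuffled among themselves
#' and the identical CV procedure -- same folds, same network spec, same
#' per-fold seeds -- is rerun on the shuffled outcomes.  The mean CV error
#' over replicates estimates the error of a model that can learn nothing
#' beyond the outcome's marginal distribution.
#'
#' Only the outcome vector is permuted; lagged-mortality feature columns
#' are NOT rebuilt from the shuffled series.  This is the minimal exchange
#' that severs the outcome-predictor association: rebuilding lags from
#' shuffled outcomes would also destroy the predictors' internal serial
#' structure and thereby change the null being simulated.
#'
#' @param features `feature_matrix` (or matrix with `y` supplied).
#' @param plan a `fold_plan`.
#' @param spec a [network_spec()].
#' @param n_permutations replicates (default 1; 20+ gives stabler ratios).
#' @param seed base seed; replicate seeds derive deterministically from it.
#' @param y outcome vector; defaults to `features$y`.
#' @return list with `cv_error_permuted` (mean over replicates),
#'   `replicate_errors`, `n_permutations`, `seed`.
#' @export
permuted_cv_error <- function(features, plan, spec, n_permutations = 1L,
                              seed = 1L, y = NULL) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (is.null(y)) {
    if (!inherits(features, "feature_matrix")) stopf("y must be supplied")
    y <- features$y
  }
  region <- sort(unique(unlist(lapply(plan$folds, function(f)
    c(f$train, f$validation)))))
  reps <- vapply(seq_len(n_permutations), function(r) {
    y_perm <- y
    y_perm[region] <- permute_outcome(y[region], seed = derive_seed(seed, r))
    cv_run(features, plan, spec, y = y_perm)$cv_error
  }, numeric(1))
  list(cv_error_permuted = mean(reps), replicate_errors = reps,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Permutation ratio
#'
#' `PR = min(1, cv_observed / cv_permuted)`.  A ratio near 1 means the
#' model predicts no better than it does on shuffled outcomes -- it learned
#' nothing beyond the marginal distribution; a ratio near 0 means the
#' predictors explain nearly all the validation error.  The ratio is
#' clamped at 1 and is invariant to a common rescaling of both errors.
#'
#' @param cv_observed CV error on the observed outcomes (> 0).
#' @param cv_permuted CV error on permuted outcomes (> 0).
#' @return the ratio, in (0, 1].
#' @examples
#' permutation_ratio(53.66, 81.85)   # 0.6556...
#' @export
permutation_ratio <- function(cv_observed, cv_permuted) {
  if (any(cv_observed <= 0) || any(cv_permuted <= 0)) {
    stopf("CV errors must be positive")
  }
  pmin(1, cv_observed / cv_permuted)
}

#' Model contribution implied by a permutation ratio
#'
#' `(1 - PR) * 100`: the percentage of the permuted-baseline prediction
#' error that the trained model removes, read as its contribution to
#' prediction accuracy (an R-squared-like summary for the CV scheme).
#'
#' @param pr permutation ratio in (0, 1].
#' @return percentage in \[0, 100).
#' @examples
#' contribution(0.656)  # 34.4
#' @export
contribution <- function(pr) {
  if (any(pr <= 0) || any(pr > 1)) stopf("pr must lie in (0, 1]")
  (1 - pr) * 100
}

#' Observed-vs-permuted CV comparison for one model
#'
#' Convenience wrapper: runs the observed CV pass and the permuted pass on
#' the same plan and spec, and bundles the ratio and contribution.
#'
#' @inheritParams permuted_cv_error
#' @return a `pr_result` list: `cv_error_observed`, `cv_error_permuted`,
#'   `pr`, `contribution_percent`, `n_permutations`, `seed`.
#' @export
pr_compare <- function(features, plan, spec, n_permutations = 1L, seed = 1L,
                       y = NULL) {
  obs <- cv_run(features, plan, spec, y = y)$cv_error
  perm <- permuted_cv_error(features, plan, spec,
                            n_permutations = n_permutations, seed = seed,
                            y = y)$cv_error_permuted
  pr <- permutation_ratio(obs, perm)
  structure(list(cv_error_observed = obs, cv_error_permuted = perm, pr = pr,
                 contribution_percent = contribution(pr),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf(
    "<pr_result> observed %.3f / permuted %.3f -> PR %.3f (contribution %.1f%%)\n",
    x$cv_error_observed, x$cv_error_permuted, round_half_away(x$pr, 3),
    x$contribution_percent))
  invisible(x)
}
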