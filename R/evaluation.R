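#' Per-step predictive error curve
#'
#' The predictive error at forecast step `s` is the mean squared error
#' across the `n` state dimensions between the predicted and the true state
#' at that step — the same per-element squared norm used by the training
#' losses, tracked along the forecast horizon.
#'
#' @param pred,truth `n x p` matrices (or trajectories), columns = forecast
#'   steps `1..p`.
#' @param label optional model label attached to the curve.
#' @return data frame with columns `step` and `error` (class `error_curve`).
#' @export
predictive_error <- function(pred, truth, label = NULL) {
  pred <- traj_values(pred); truth <- traj_values(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth must have identical shapes")
  out <- data.frame(step = seq_len(ncol(pred)),
                    error = colMeans((pred - truth)^2))
  if (!is.null(label)) out$model <- label
  class(out) <- c("error_curve", "data.frame")
  out
}

traj_values <- function(x) {
  if (inherits(x, "ekatp_trajectory")) x$values else as.matrix(x)
}

#' Pearson correlation between predicted and true trajectories
#'
#' Computes the Pearson correlation coefficient over all `p` forecast steps,
#' flattening the state dimensions, with the grand means of the predicted
#' and true values as centering constants.
#'
#' @param pred,truth equal-shaped matrices or trajectories.
#' @export
pcc <- function(pred, truth) {
  pred <- traj_values(pred); truth <- traj_values(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth must have identical shapes")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop("correlation undefined for a zero-variance trajectory")
  stats::cor(as.vector(pred), as.vector(truth))
}

#' Root mean squared error between trajectories
#'
#' `sqrt(mean over steps of the squared Euclidean norm of the per-step
#' residual)`: residual norms are summed over state dimensions within a
#' step, then averaged over the `p` steps.
#'
#' @param pred,truth equal-shaped matrices or trajectories.
#' @export
rmse <- function(pred, truth) {
  pred <- traj_values(pred); truth <- traj_values(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth must have identical shapes")
  sqrt(mean(colSums((pred - truth)^2)))
}

#' Multi-run summary statistics
#'
#' Summarizes a per-run scalar (e.g. the predictive error at a fixed
#' forecast step across independently seeded datasets) by its minimum,
#' maximum, average, and sample variance (`n - 1` denominator: the runs are
#' a sample of datasets).
#'
#' @param errors numeric vector, one value per run (`>= 2` runs).
#' @return list with `min`, `max`, `avg`, `var`.
#' @export
summarize_runs <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 2) stop("need at least 2 runs to summarize")
  list(min = min(errors), max = max(errors), avg = mean(errors),
       var = stats::var(errors))
}

#' Paired significance test between two models' per-run errors
#'
#' Two-sided paired test across runs; the default is the Wilcoxon
#' signed-rank test (normal approximation, robust to the heavy-tailed error
#' distributions long-horizon forecasts produce), with a paired t-test
#' available. Identical samples return `p = 1`.
#'
#' @param errors_a,errors_b equal-length numeric vectors (`>= 5` pairs).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return the two-sided p-value.
#' @export
paired_significance <- function(errors_a, errors_b,
                                method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(errors_a) != length(errors_b))
    stop("paired test needs equal-length error vectors")
  if (length(errors_a) < 5) stop("need at least 5 pairs")
  if (all(errors_a == errors_b)) return(1)
  if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(errors_a, errors_b, paired = TRUE,
                                        exact = FALSE)$p.value)
  } else {
    stats::t.test(errors_a, errors_b, paired = TRUE)$p.value
  }
}

#' Noise-robustness sweep
#'
#' Runs the full simulate / lift / train / predict / score pipeline of the
#' metabolomics (fluid-flow) protocol once per noise intensity and reports
#' the Pearson correlation and RMSE between the predicted and observed
#' trajectories, both computed on the 3-dimensional projections of the
#' held-out forecast window.
#'
#' @param sigmas noise intensities to sweep (default: the six-point grid
#'   0.001–0.5).
#' @param seed master integer seed.
#' @param profile `"smoke"`, `"ci"`, or `"full"` (see [ekatp_profile()]).
#' @param init fluid initial condition (default preset `zeta1`).
#' @return data frame with columns `sigma`, `pcc`, `rmse`.
#' @export
noise_sweep <- function(sigmas = c(0.001, 0.005, 0.010, 0.050, 0.100, 0.500),
                        seed = 1, profile = "ci", init = fluid_init("zeta1")) {
  if (any(sigmas < 0)) stop("sigma must be non-negative")
  rows <- lapply(sigmas, function(s) {
    run <- metabolomics_run_one(sigma = s, seed = seed, profile = profile,
                                init = init)
    data.frame(sigma = s, pcc = run$pcc, rmse = run$rmse)
  })
  do.call(rbind, rows)
}
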