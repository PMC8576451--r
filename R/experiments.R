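#' Experiment profiles
#'
#' Problem sizes for the three reproduction families. `"full"` is the
#' complete protocol (300 epochs, 20 independently seeded datasets per
#' condition); `"ci"` is the package's scaled-down default (50 epochs,
#' 5 datasets), sized so the whole suite runs on one desktop CPU core in
#' minutes while preserving every qualitative conclusion; `"smoke"`
#' (10 epochs, 2 datasets) merely exercises every code path.
#'
#' @param profile `"smoke"`, `"ci"` or `"full"`.
#' @return list with `epochs` and `n_datasets`.
#' @export
ekatp_profile <- function(profile = c("ci", "smoke", "full")) {
  switch(match.arg(profile),
         smoke = list(epochs = 10L, n_datasets = 2L),
         ci = list(epochs = 50L, n_datasets = 5L),
         full = list(epochs = 300L, n_datasets = 20L))
}

# Shared simulate -> corrupt -> lift -> train -> predict pipeline. The
# trajectory is simulated from `sys_params`, white Gaussian noise of
# intensity `sigma` is added to the latent states, the result is lifted to
# `n_amb` dimensions by a seeded random orthogonal map, a model is trained
# on the first `train_steps` steps, and `horizon` steps are predicted
# forward from the last training state.
pipeline_run <- function(sys_params, sigma, n_amb, hidden, train_steps,
                         horizon, seed, epochs, operator = "companion",
                         L = 16, k = 8) {
  traj <- switch(class(sys_params)[1],
                 lorenz_params = simulate_lorenz(sys_params),
                 pendulum_params = simulate_pendulum(sys_params),
                 fluid_params = simulate_fluid(sys_params),
                 stop("unknown system parameters"))
  noisy <- add_noise(traj, sigma, seed = seed)
  map <- make_orthogonal_lift(n_amb, nrow(traj$values), seed = seed)
  Fobs <- lift(noisy, map)
  model <- ekatp_model(n_amb, L = L, hidden = hidden, operator = operator,
                       seed = seed)
  fit <- train_ekatp(model, Fobs,
                     train_config(k = k, epochs = epochs,
                                  train_steps = train_steps, seed = seed))
  pred <- predict_ekatp(fit, Fobs$values[, train_steps], k = horizon)
  truth <- Fobs$values[, train_steps + seq_len(horizon), drop = FALSE]
  list(fit = fit, map = map, observed = Fobs, pred = pred, truth = truth,
       curve = predictive_error(pred, truth),
       split = c(train = train_steps, test = horizon), seed = seed)
}

#' Reproduce the gene-expression (chaotic Lorenz map) experiment
#'
#' Simulates the chaotic map at `T = 1050` steps, lifts the 3-dimensional
#' trajectory to 96 dimensions, trains on the first 1000 steps and predicts
#' the last 50, for every cell of the condition grid
#' `h in {0.003, 0.006} x sigma in {0.00, 0.01}`. With
#' `large_scale = TRUE` a single `T = 15000` clean trajectory is generated
#' instead and three disjoint randomly-placed 1050-step periods are each
#' trained and predicted with the same 1000/50 split.
#'
#' @param seed master seed; per-condition runs derive their seeds from it.
#' @param profile see [ekatp_profile()].
#' @param large_scale run the three-period generalizability variant.
#' @return list of per-condition pipeline results (`error_curve` in
#'   `$curve`), plus the resolved conditions.
#' @export
run_genomics <- function(seed = 1, profile = "ci", large_scale = FALSE) {
  prof <- ekatp_profile(profile)
  if (large_scale) {
    big <- simulate_lorenz(lorenz_params(h = 0.003, T = 15000))
    starts <- with_local_seed(seed, {
      ok <- FALSE
      while (!ok) {  # three disjoint 1050-step periods
        s <- sort(sample.int(15000 - 1050, 3))
        ok <- all(diff(s) >= 1050)
      }
      s
    })
    runs <- lapply(seq_along(starts), function(i) {
      seg <- latent_trajectory(big$values[, starts[i] + 1:1050])
      map <- make_orthogonal_lift(96, 3, seed = seed + i)
      Fobs <- lift(seg, map)
      model <- ekatp_model(96, hidden = c(256, 128), seed = seed + i)
      fit <- train_ekatp(model, Fobs,
                         train_config(epochs = prof$epochs,
                                      train_steps = 1000, seed = seed + i))
      pred <- predict_ekatp(fit, Fobs$values[, 1000], k = 50)
      truth <- Fobs$values[, 1001:1050]
      list(start = starts[i], fit = fit, pred = pred, truth = truth,
           pred_latent = project(lifted_trajectory(pred), map),
           curve = predictive_error(pred, truth))
    })
    return(list(variant = "large_scale", periods = runs, seed = seed))
  }
  grid <- expand.grid(h = c(0.003, 0.006), sigma = c(0.00, 0.01))
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    c(list(h = grid$h[i], sigma = grid$sigma[i]),
      pipeline_run(lorenz_params(h = grid$h[i], T = 1050), grid$sigma[i],
                   n_amb = 96, hidden = c(256, 128), train_steps = 1000,
                   horizon = 50, seed = seed + i, epochs = prof$epochs))
  })
  list(variant = "small_scale", conditions = grid, runs = runs, seed = seed)
}

# One proteomics (pendulum) dataset: returns the full per-step error curve
# for the 1000-step forecast of the last 1000 of T = 1600 steps. The
# training horizon k = L = 16 here: the 1000-step forecast needs the
# operator spectrum pinned to the unit circle, which shorter horizons do
# not enforce (see the methods vignette).
proteomics_run_one <- function(h, sigma, seed, epochs, operator = "companion") {
  pipeline_run(pendulum_params(theta0 = h, T = 1600), sigma, n_amb = 64,
               hidden = c(128, 64), train_steps = 600, horizon = 1000,
               seed = seed, epochs = epochs, operator = operator, k = 16)
}

#' Reproduce the proteomics (nonlinear pendulum) experiments
#'
#' `run_proteomics()` computes 1000-step predictive-error curves for both
#' the EKATP and the KAE ablation on every cell of the grid
#' `h in {0.8, 2.4} x sigma in {0.00, 0.03, 0.08}` (one dataset per cell).
#' `run_table1()` is the multi-dataset harness: for each condition
#' `h in {0.8, 2.4} x sigma in {0.00, 0.03}` it trains both models on
#' `n_datasets` independently seeded datasets (seeds control the noise
#' draws and the random orthogonal lift), records each dataset's predictive
#' error at forecast step 1000, and summarizes min/max/avg/var per model
#' with a paired two-sided significance test between the models.
#'
#' @param seed master seed; dataset `i` uses `seed + i`.
#' @param profile see [ekatp_profile()].
#' @return `run_table1()`: list with `summary` (data frame with columns
#'   `model, h, sigma, min, max, avg, var, p_value`) and the raw per-dataset
#'   step-1000 `errors`.
#' @export
run_proteomics <- function(seed = 1, profile = "ci") {
  prof <- ekatp_profile(profile)
  grid <- expand.grid(h = c(0.8, 2.4), sigma = c(0.00, 0.03, 0.08))
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    list(h = grid$h[i], sigma = grid$sigma[i],
         ekatp = proteomics_run_one(grid$h[i], grid$sigma[i], seed + i,
                                    prof$epochs)$curve,
         kae = proteomics_run_one(grid$h[i], grid$sigma[i], seed + i,
                                  prof$epochs, operator = "dense")$curve)
  })
  list(conditions = grid, runs = runs, seed = seed)
}

#' @rdname run_proteomics
#' @param at_step forecast step at which the per-dataset error is read off.
#' @export
run_table1 <- function(seed = 1, profile = "ci", at_step = 1000) {
  prof <- ekatp_profile(profile)
  grid <- expand.grid(h = c(0.8, 2.4), sigma = c(0.00, 0.03))
  summary_rows <- list()
  errors <- list()
  for (i in seq_len(nrow(grid))) {
    h <- grid$h[i]; sigma <- grid$sigma[i]
    e_ek <- numeric(prof$n_datasets)
    e_ka <- numeric(prof$n_datasets)
    for (d in seq_len(prof$n_datasets)) {
      ds_seed <- seed + d
      e_ek[d] <- proteomics_run_one(h, sigma, ds_seed,
                                    prof$epochs)$curve$error[at_step]
      e_ka[d] <- proteomics_run_one(h, sigma, ds_seed, prof$epochs,
                                    operator = "dense")$curve$error[at_step]
    }
    pv <- if (prof$n_datasets >= 5) paired_significance(e_ka, e_ek) else NA_real_
    for (m in c("KAE", "EKATP")) {
      s <- summarize_runs(if (m == "EKATP") e_ek else e_ka)
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(model = m, h = h, sigma = sigma, min = s$min, max = s$max,
                   avg = s$avg, var = s$var, p_value = pv)
    }
    errors[[sprintf("h%.1f_s%.2f", h, sigma)]] <-
      list(ekatp = e_ek, kae = e_ka)
  }
  list(summary = do.call(rbind, summary_rows), errors = errors,
       conditions = grid, n_datasets = prof$n_datasets, at_step = at_step,
       seed = seed)
}

# One metabolomics (fluid-flow) dataset: T = 900, train on the first 800
# steps, forecast the last 100, score PCC/RMSE on the 3-dimensional
# projections of the forecast window.
metabolomics_run_one <- function(sigma, seed, profile = "ci",
                                 init = fluid_init("zeta1"),
                                 operator = "companion") {
  prof <- ekatp_profile(profile)
  run <- pipeline_run(fluid_params(T = 900, init = init), sigma,
                      n_amb = 96, hidden = c(256, 128), train_steps = 800,
                      horizon = 100, seed = seed, epochs = prof$epochs,
                      operator = operator)
  Vhat <- project(lifted_trajectory(run$pred), run$map)
  Vobs <- project(lifted_trajectory(run$truth), run$map)
  c(run, list(pred_latent = Vhat, truth_latent = Vobs,
              pcc = pcc(Vhat, Vobs), rmse = rmse(Vhat, Vobs)))
}

#' Reproduce the metabolomics (mean-field fluid flow) experiment
#'
#' Runs the clean/low-noise condition grid (initial condition presets
#' `zeta1` (low complexity) and `zeta2` (high complexity), each at
#' `sigma in {0.000, 0.001}`) and, optionally, the strong-noise sweep over
#' `sigma in {0.001, ..., 0.5}` via [noise_sweep()].
#'
#' @param seed master seed.
#' @param profile see [ekatp_profile()].
#' @param sweep also run the six-point noise sweep.
#' @export
run_metabolomics <- function(seed = 1, profile = "ci", sweep = FALSE) {
  grid <- expand.grid(complexity = c("zeta1", "zeta2"),
                      sigma = c(0.000, 0.001), stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    c(list(complexity = grid$complexity[i], sigma = grid$sigma[i]),
      metabolomics_run_one(grid$sigma[i], seed + i, profile,
                           init = fluid_init(grid$complexity[i])))
  })
  out <- list(conditions = grid, runs = runs, seed = seed)
  if (sweep) out$sweep <- noise_sweep(seed = seed, profile = profile)
  out
}

#' Write run artifacts to a directory
#'
#' Persists everything needed to re-derive a run's numbers offline: the
#' loss history as CSV, predictions and truth as TSV, metrics as JSON, and
#' the resolved configuration.
#'
#' @param run a pipeline result (an element of a `run_*()` output).
#' @param dir output directory (created if needed).
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$fit$history, file.path(dir, "loss_history.csv"),
                   row.names = FALSE)
  write_trajectory_tsv(run$pred, file.path(dir, "predictions.tsv"))
  write_trajectory_tsv(run$truth, file.path(dir, "truth.tsv"))
  metrics <- list(seed = run$seed, split = as.list(run$split),
                  final_loss = run$fit$history$total[nrow(run$fit$history)],
                  error_at_end = run$curve$error[nrow(run$curve)])
  if (!is.null(run$pcc)) metrics$pcc <- run$pcc
  if (!is.null(run$rmse)) metrics$rmse <- run$rmse
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  save_ekatp(run$fit, file.path(dir, "model.json"))
  invisible(dir)
}
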