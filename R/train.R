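#' Training configuration
#'
#' @param k prediction horizon (steps) used inside the loss windows; each
#'   training window spans `2k + 1` consecutive states.
#' @param epochs number of passes over the training windows.
#' @param batch_size number of sliding windows per gradient step.
#' @param lr Adam learning rate.
#' @param train_steps number of initial steps forming the training segment
#'   (0-based steps `0 .. train_steps - 1`); `NULL` uses the whole series.
#' @param seed integer seed controlling batching; together with the model's
#'   initialization seed this makes training fully reproducible.
#' @param freeze_autoencoder train only the latent operators, keeping the
#'   encoder/decoder weights fixed (used for operator-recovery diagnostics).
#' @param engine `"cpp"` (default), the single-precision compiled training
#'   core, or `"r"`, the double-precision reference implementation; both
#'   follow the identical batch schedule under a given seed.
#' @param verbose print one line per 25 epochs.
#' @export
train_config <- function(k = 8, epochs = 100, batch_size = 64, lr = 1e-3,
                         train_steps = NULL, seed = 1,
                         freeze_autoencoder = FALSE, engine = c("cpp", "r"),
                         verbose = FALSE) {
  if (k < 1) stop("horizon k must be at least 1")
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(k = as.integer(k), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 train_steps = if (!is.null(train_steps)) as.integer(train_steps),
                 seed = as.integer(seed),
                 freeze_autoencoder = isTRUE(freeze_autoencoder),
                 engine = match.arg(engine),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a model on a lifted trajectory
#'
#' Minimizes the composite objective by Adam over sliding windows
#' `F_{t-k} .. F_{t+k}` drawn with stride 1 from the training segment
#' (windows needing indices outside the segment are dropped). The structural
#' constraints on the companion coefficients (`a_1 != 0`, `b_L != 0`) are
#' checked after every epoch and training aborts with a diagnostic if either
#' collapses below `1e-6` in magnitude, as does a non-finite loss.
#'
#' @param model an [ekatp_model()].
#' @param data a [lifted_trajectory()] or an `n x T` matrix.
#' @param cfg a [train_config()].
#' @return an `ekatp_fit`: list with the trained `model`, a per-epoch
#'   `history` data frame (`epoch, l_id, l_fwd, l_bwd, l_idy, l_con, total`),
#'   and the resolved `config`.
#' @export
train_ekatp <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "ekatp_model"))
  F <- if (inherits(data, "ekatp_trajectory")) data$values else as.matrix(data)
  if (nrow(F) != model$n)
    stop(sprintf("data dimension %d does not match model n = %d",
                 nrow(F), model$n))
  k <- cfg$k
  Ttr <- if (is.null(cfg$train_steps)) ncol(F) else cfg$train_steps
  if (Ttr > ncol(F)) stop("train_steps exceeds trajectory length")
  if (Ttr < 2 * k + 2)
    stop(sprintf("training segment (%d steps) shorter than 2k + 2 = %d",
                 Ttr, 2 * k + 2))
  dense <- model$op$type == "dense"

  # window centers, 0-based steps k .. Ttr-1-k; column index is step + 1.
  # The whole batch schedule is drawn up front from the config seed so that
  # both engines follow it identically.
  centers <- seq.int(k, Ttr - 1L - k)
  offsets <- seq.int(-k, k)
  set.seed(cfg$seed)
  perms <- t(vapply(seq_len(cfg$epochs), function(e) sample(centers),
                    integer(length(centers))))

  if (cfg$engine == "cpp") {
    res <- .cpp_train(list(W = model$enc$W, b = model$enc$b),
                      list(W = model$dec$W, b = model$dec$b),
                      model$op[setdiff(names(model$op), "type")],
                      dense, model$activation == "tanh", F, perms,
                      k, cfg$batch_size, cfg$lr, cfg$freeze_autoencoder,
                      unlist(model$weights))
    model$enc$W <- res$enc$W; model$enc$b <- lapply(res$enc$b, drop)
    model$dec$W <- res$dec$W; model$dec$b <- lapply(res$dec$b, drop)
    if (dense) model$op$K <- res$op$K
    else { model$op$a <- drop(res$op$a); model$op$b <- drop(res$op$b) }
    model$trained <- TRUE
    hist <- res$history
    colnames(hist) <- c("l_id", "l_fwd", "l_bwd", "l_idy", "l_con", "total")
    return(structure(list(model = model,
                          history = data.frame(epoch = seq_len(cfg$epochs),
                                               hist),
                          config = cfg),
                     class = "ekatp_fit"))
  }

  par <- list(enc = list(W = model$enc$W, b = model$enc$b),
              dec = list(W = model$dec$W, b = model$dec$b),
              op = if (dense) list(K = model$op$K)
                   else list(a = model$op$a, b = model$op$b))
  opt <- adam_init(par, lr = cfg$lr)

  hist <- matrix(NA_real_, cfg$epochs, 6)
  colnames(hist) <- c("l_id", "l_fwd", "l_bwd", "l_idy", "l_con", "total")

  for (epoch in seq_len(cfg$epochs)) {
    perm <- perms[epoch, ]
    nb <- ceiling(length(perm) / cfg$batch_size)
    acc <- numeric(6)
    for (i in seq_len(nb)) {
      idx <- perm[(((i - 1L) * cfg$batch_size) + 1L):min(i * cfg$batch_size,
                                                         length(perm))]
      B <- length(idx)
      cols <- rep(idx, times = 2L * k + 1L) +
        rep(offsets, each = B) + 1L
      Fall <- F[, cols, drop = FALSE]
      model$enc$W <- par$enc$W; model$enc$b <- par$enc$b
      model$dec$W <- par$dec$W; model$dec$b <- par$dec$b
      if (dense) model$op$K <- par$op$K
      else { model$op$a <- par$op$a; model$op$b <- par$op$b }
      res <- ekatp_loss_grad(model, Fall, B = B, k = k, want_grad = TRUE)
      r <- res$report
      if (!is.finite(r$total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      if (cfg$freeze_autoencoder) {
        res$grad$enc <- tree_map(function(x) x * 0, res$grad$enc)
        res$grad$dec <- tree_map(function(x) x * 0, res$grad$dec)
      }
      st <- adam_step(opt, par, res$grad)
      opt <- st$state
      par <- st$par
      acc <- acc + c(r$l_id, r$l_fwd, r$l_bwd, r$l_idy, r$l_con, r$total)
    }
    hist[epoch, ] <- acc / nb
    if (!dense &&
        (abs(par$op$a[1]) < 1e-6 || abs(par$op$b[model$L]) < 1e-6))
      stop(sprintf(
        "companion constraint violated at epoch %d (a1 = %.2e, bL = %.2e)",
        epoch, par$op$a[1], par$op$b[model$L]))
    if (cfg$verbose && epoch %% 25 == 0)
      message(sprintf("epoch %d: total %.4g", epoch, hist[epoch, "total"]))
  }

  model$enc$W <- par$enc$W; model$enc$b <- par$enc$b
  model$dec$W <- par$dec$W; model$dec$b <- par$dec$b
  if (dense) model$op$K <- par$op$K
  else { model$op$a <- par$op$a; model$op$b <- par$op$b }
  model$trained <- TRUE

  structure(list(model = model,
                 history = data.frame(epoch = seq_len(cfg$epochs), hist),
                 config = cfg),
            class = "ekatp_fit")
}

#' @export
print.ekatp_fit <- function(x, ...) {
  cat(sprintf("<ekatp fit: %d epochs, final total loss %.4g>\n",
              nrow(x$history), x$history$total[nrow(x$history)]))
  invisible(x)
}

#' Multi-step prediction in the ambient space
#'
#' Encodes the start state, evolves the latent state `s = 1..k` steps with
#' the forward operator (`C^s`, or the dense operator for a KAE model) or
#' the backward operator (`D^s`), and decodes each step. With `k = 0` the
#' pure reconstruction `decode(encode(F_t))` is returned.
#'
#' @param model a trained `ekatp_model` (an `ekatp_fit` is also accepted).
#' @param F_t ambient start state (`n`-vector).
#' @param k horizon (number of predicted steps).
#' @param direction `"forward"` or `"backward"`.
#' @return `n x k` matrix, column `s` holding the prediction at `t +/- s`
#'   (an `n x 1` matrix of the reconstruction for `k = 0`).
#' @export
predict_ekatp <- function(model, F_t, k, direction = c("forward", "backward")) {
  if (inherits(model, "ekatp_fit")) model <- model$model
  direction <- match.arg(direction)
  if (!isTRUE(model$trained))
    warning("predicting with an untrained model")
  y <- encode(model, as.numeric(F_t))
  if (k == 0) return(decode(model, matrix(y, ncol = 1)))
  dense <- model$op$type == "dense"
  if (dense && direction == "backward")
    stop("a dense-operator (KAE) model has no backward operator")
  step <- if (dense) function(v) drop(model$op$K %*% v)
          else if (direction == "forward") function(v) comp_fwd_apply(model$op$a, v)
          else function(v) comp_bwd_apply(model$op$b, v)
  Y <- matrix(0, model$L, k)
  for (s in seq_len(k)) { y <- step(y); Y[, s] <- y }
  if (!all(is.finite(Y)))
    stop("latent prediction diverged; operator spectrum is unstable")
  decode(model, Y)
}

#' Save and load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the architecture, the
#' operator coefficients, all layer weights, and the loss weights.
#'
#' @param model an `ekatp_model` or `ekatp_fit`.
#' @param path file path for the JSON checkpoint.
#' @export
save_ekatp <- function(model, path) {
  if (inherits(model, "ekatp_fit")) model <- model$model
  obj <- list(n = model$n, L = model$L, hidden = model$hidden,
              activation = model$activation, operator = model$op$type,
              trained = model$trained, weights = model$weights,
              enc_W = model$enc$W, enc_b = model$enc$b,
              dec_W = model$dec$W, dec_b = model$dec$b,
              op = model$op[setdiff(names(model$op), "type")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ekatp
#' @export
load_ekatp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- ekatp_model(n = obj$n, L = obj$L, hidden = obj$hidden,
                       activation = obj$activation,
                       operator = obj$operator, seed = 0L)
  model$weights <- obj$weights
  model$enc$W <- lapply(obj$enc_W, as.matrix)
  model$enc$b <- lapply(obj$enc_b, as.numeric)
  model$dec$W <- lapply(obj$dec_W, as.matrix)
  model$dec$b <- lapply(obj$dec_b, as.numeric)
  if (obj$operator == "dense") model$op$K <- as.matrix(obj$op$K)
  else { model$op$a <- as.numeric(obj$op$a); model$op$b <- as.numeric(obj$op$b) }
  model$trained <- isTRUE(obj$trained)
  model
}
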