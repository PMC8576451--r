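#' Loss weights for the composite training objective
#'
#' The training objective is the weighted sum
#' `L = lambda_id*L_id + lambda_fwd*L_fwd + lambda_bwd*L_bwd +
#'  lambda_idy*L_idy + lambda_con*L_con`, combining autoencoder
#' reconstruction, forward/backward prediction in the ambient space, latent
#' linearity under the operators, and forward-backward consistency. All
#' weights default to 1.
#'
#' @param id,fwd,bwd,idy,con non-negative scalars, not all zero.
#' @export
loss_weights <- function(id = 1, fwd = 1, bwd = 1, idy = 1, con = 1) {
  w <- c(id = id, fwd = fwd, bwd = bwd, idy = idy, con = con)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (all(w == 0)) stop("at least one loss weight must be positive")
  as.list(w)
}

#' Construct an EKATP model
#'
#' Builds the full model: a fully connected encoder approximating the delay
#' embedding (ambient dimension `n` to latent dimension `L`), a mirrored
#' decoder approximating its conjugate (inverse) map, and the latent
#' operators. With `operator = "companion"` (the default) the latent state
#' evolves under the structured forward/backward companion pair `C`/`D`
#' with `L` trainable coefficients each; `operator = "dense"` is the
#' Koopman-autoencoder (KAE) ablation with a single unstructured `L x L`
#' forward matrix and no backward/consistency terms.
#'
#' Companion coefficients are initialized near the one-step shift while
#' honoring the constraints `a_1 != 0`, `b_L != 0`:
#' `a = (eps, 0, ..., 0, 1)` and `b = (1, 0, ..., 0, eps)` with `eps = 1e-2`.
#'
#' @param n ambient (observed) dimension.
#' @param L latent (delay-embedding) dimension, `>= 2`. Default 16, giving
#'   comfortable headroom over the `2d + 1` embedding-sufficiency bound for
#'   the `d <= 3` benchmark systems.
#' @param hidden integer vector of hidden-layer widths (mirrored in the
#'   decoder).
#' @param activation hidden-layer activation: `"tanh"` (default) or
#'   `"linear"`.
#' @param operator `"companion"` (EKATP) or `"dense"` (KAE ablation).
#' @param weights a [loss_weights()] list.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `ekatp_model`.
#' @export
ekatp_model <- function(n, L = 16, hidden = c(128, 64), activation = "tanh",
                        operator = c("companion", "dense"),
                        weights = NULL, seed = NULL) {
  operator <- match.arg(operator)
  if (L < 2) stop("latent dimension L must be at least 2")
  if (is.null(weights))
    weights <- if (operator == "dense") loss_weights(bwd = 0, con = 0)
               else loss_weights()
  model <- with_local_seed(seed, {
    enc <- mlp_init(n, L, hidden, activation)
    dec <- mlp_init(L, n, rev(hidden), activation)
    op <- if (operator == "companion") {
      list(type = "companion",
           a = c(1e-2, rep(0, L - 2), 1),
           b = c(1, rep(0, L - 2), 1e-2))
    } else {
      list(type = "dense", K = diag(L) + matrix(stats::rnorm(L * L, sd = 1e-2), L, L))
    }
    list(enc = enc, dec = dec, op = op)
  })
  structure(list(n = n, L = L, hidden = hidden, activation = activation,
                 enc = model$enc, dec = model$dec, op = model$op,
                 weights = weights, trained = FALSE, seed = seed),
            class = "ekatp_model")
}

#' @rdname ekatp_model
#' @param ... passed on to [ekatp_model()].
#' @details `make_kae()` is a convenience wrapper building the ablation:
#' identical encoder/decoder, one dense forward operator (`L^2` trainable
#' entries versus the EKATP's `L`), trained with `lambda_bwd = lambda_con =
#' 0` and only the forward half of the latent-linearity loss.
#' @export
make_kae <- function(n, L = 16, hidden = c(128, 64), ...) {
  ekatp_model(n, L, hidden, operator = "dense", ...)
}

#' @export
print.ekatp_model <- function(x, ...) {
  cat(sprintf("<%s model: n = %d, L = %d, hidden = [%s], %s>\n",
              if (x$op$type == "companion") "EKATP" else "KAE",
              x$n, x$L, paste(x$hidden, collapse = ", "),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Encode and decode states
#'
#' `encode()` maps ambient states to latent delay-coordinate states through
#' the encoder; `decode()` maps latent states back to the ambient space.
#' Both accept a single vector or a matrix whose columns are states (order
#' preserved).
#'
#' @param model an `ekatp_model`.
#' @param x ambient `n`-vector / `n x m` matrix (`encode`) or latent
#'   `L`-vector / `L x m` matrix (`decode`).
#' @export
encode <- function(model, x) {
  run_net(model$enc, x, model$n, "encode")
}

#' @rdname encode
#' @export
decode <- function(model, x) {
  run_net(model$dec, x, model$L, "decode")
}

run_net <- function(net, x, expect_dim, what) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) != expect_dim)
    stop(sprintf("%s expects states of dimension %d, got %d",
                 what, expect_dim, nrow(X)))
  if (!all(is.finite(X))) stop(sprintf("%s input contains non-finite values", what))
  out <- mlp_forward(net, X)
  if (vec) drop(out) else out
}

#' Mean-squared-error reconstruction loss
#'
#' Per-element mean squared error between a reconstructed and a true state
#' (or batch of states); the norm used by every loss term in the package.
#'
#' @param F_hat,F equal-shaped numeric vectors or matrices.
#' @export
loss_id <- function(F_hat, F) {
  if (!identical(dim(as.matrix(F_hat)), dim(as.matrix(F))))
    stop("shape mismatch between reconstruction and target")
  mean((F_hat - F)^2)
}

#' All five loss terms on a prediction window
#'
#' Evaluates the model's loss terms on a window `F_{t-k}, ..., F_{t+k}`
#' centered at `t`:
#' reconstruction `L_id` at the center; `L_fwd`/`L_bwd`, the average over
#' horizons `s = 1..k` of the ambient MSE of the decoded `s`-step
#' forward/backward latent predictions; `L_idy`, the latent MSE between
#' operator-evolved and directly-encoded states in both directions; and
#' `L_con`, the ambient MSE of the decoded round trips `D^s C^s Y_t` and
#' `C^s D^s Y_t` against `F_t`. For a dense-operator (KAE) model only the
#' forward half of `L_idy` is defined and `L_bwd`/`L_con` are zero.
#'
#' @param model an `ekatp_model`.
#' @param window `n x (2k+1)` matrix, center column `k + 1` is `F_t`.
#' @param k horizon; defaults to the widest the window allows.
#' @return a `loss_report` list with `l_id`, `l_fwd`, `l_bwd`, `l_idy`,
#'   `l_con` and the weighted `total`.
#' @export
ekatp_losses <- function(model, window, k = NULL) {
  window <- as.matrix(window)
  if (is.null(k)) k <- (ncol(window) - 1) %/% 2
  if (ncol(window) < 2 * k + 1)
    stop(sprintf("window has %d columns; need 2k+1 = %d", ncol(window), 2 * k + 1))
  if (ncol(window) > 2 * k + 1) {  # keep the central 2k+1 columns
    mid <- (ncol(window) + 1) %/% 2
    window <- window[, (mid - k):(mid + k), drop = FALSE]
  }
  if (nrow(window) != model$n) stop("window row dimension does not match model n")
  res <- ekatp_loss_grad(model, window, B = 1L, k = k, want_grad = FALSE)
  res$report
}

#' @rdname ekatp_losses
#' @export
loss_fwd <- function(model, window, k = NULL) ekatp_losses(model, window, k)$l_fwd

#' @rdname ekatp_losses
#' @export
loss_bwd <- function(model, window, k = NULL) ekatp_losses(model, window, k)$l_bwd

#' @rdname ekatp_losses
#' @export
loss_idy <- function(model, window, k = NULL) ekatp_losses(model, window, k)$l_idy

#' @rdname ekatp_losses
#' @export
loss_con <- function(model, window, k = NULL) ekatp_losses(model, window, k)$l_con

#' Composite objective from a loss report
#'
#' @param report a `loss_report` (or any list with the five `l_*` fields).
#' @param w a [loss_weights()] list.
#' @export
total_loss <- function(report, w) {
  w$id * report$l_id + w$fwd * report$l_fwd + w$bwd * report$l_bwd +
    w$idy * report$l_idy + w$con * report$l_con
}

# ---------------------------------------------------------------------------
# Core batched loss + gradient evaluation.
#
# Fall: n x ((2k+1) * B) matrix; column block j (of B columns) holds the
# states at window offset j - (k + 1), i.e. blocks run from -k to +k and the
# center block index is k + 1. Returns the loss report and, when requested,
# the full parameter gradient tree (enc, dec, op).
ekatp_loss_grad <- function(model, Fall, B, k, want_grad = TRUE) {
  n <- model$n; L <- model$L
  w <- model$weights
  dense <- model$op$type == "dense"
  jc <- k + 1L
  blk <- function(j) ((j - 1L) * B + 1L):(j * B)

  enc <- mlp_forward(model$enc, Fall, want_cache = TRUE)
  Yall <- enc$out
  Y0 <- Yall[, blk(jc), drop = FALSE]
  Fc <- Fall[, blk(jc), drop = FALSE]

  # latent operator chains ---------------------------------------------------
  a <- model$op$a; b <- model$op$b; K <- model$op$K
  step_fwd <- if (dense) function(y) K %*% y else function(y) comp_fwd_apply(a, y)
  ZC <- vector("list", k)
  prev <- Y0
  for (s in seq_len(k)) { prev <- step_fwd(prev); ZC[[s]] <- prev }
  if (!dense) {
    ZD <- vector("list", k)
    prev <- Y0
    for (s in seq_len(k)) { prev <- comp_bwd_apply(b, prev); ZD[[s]] <- prev }
    # consistency chains: U_s = D^s C^s Y0, V_s = C^s D^s Y0, with all
    # intermediate states kept for backpropagation
    Uchain <- Vchain <- vector("list", k)
    for (s in seq_len(k)) {
      u <- vector("list", s + 1L); u[[1]] <- ZC[[s]]
      for (r in seq_len(s)) u[[r + 1]] <- comp_bwd_apply(b, u[[r]])
      Uchain[[s]] <- u
      v <- vector("list", s + 1L); v[[1]] <- ZD[[s]]
      for (r in seq_len(s)) v[[r + 1]] <- comp_fwd_apply(a, v[[r]])
      Vchain[[s]] <- v
    }
  }

  # one decoder pass over every latent state that reaches the ambient space --
  dec_blocks <- c(list(Y0), ZC,
                  if (!dense) ZD,
                  if (!dense) lapply(Uchain, function(u) u[[length(u)]]),
                  if (!dense) lapply(Vchain, function(v) v[[length(v)]]))
  Xdec <- do.call(cbind, dec_blocks)
  dec <- mlp_forward(model$dec, Xdec, want_cache = TRUE)
  Fdec <- dec$out
  nb <- length(dec_blocks)
  dblk <- function(j) ((j - 1L) * B + 1L):(j * B)

  # residuals and loss terms -------------------------------------------------
  sc_amb <- 2 / (n * B)
  sc_lat <- 2 / (L * B)
  R_id <- Fdec[, dblk(1L), drop = FALSE] - Fc
  l_id <- mean(R_id^2)
  l_fwd <- 0; l_bwd <- 0; l_idy <- 0; l_con <- 0
  R_fwd <- vector("list", k); E_f <- vector("list", k)
  if (!dense) { R_bwd <- vector("list", k); E_b <- vector("list", k)
                R_u <- vector("list", k); R_v <- vector("list", k) }
  for (s in seq_len(k)) {
    R_fwd[[s]] <- Fdec[, dblk(1L + s), drop = FALSE] -
      Fall[, blk(jc + s), drop = FALSE]
    l_fwd <- l_fwd + mean(R_fwd[[s]]^2) / k
    E_f[[s]] <- ZC[[s]] - Yall[, blk(jc + s), drop = FALSE]
    l_idy <- l_idy + mean(E_f[[s]]^2) / k
    if (!dense) {
      R_bwd[[s]] <- Fdec[, dblk(1L + k + s), drop = FALSE] -
        Fall[, blk(jc - s), drop = FALSE]
      l_bwd <- l_bwd + mean(R_bwd[[s]]^2) / k
      E_b[[s]] <- ZD[[s]] - Yall[, blk(jc - s), drop = FALSE]
      l_idy <- l_idy + mean(E_b[[s]]^2) / k
      R_u[[s]] <- Fdec[, dblk(1L + 2L * k + s), drop = FALSE] - Fc
      R_v[[s]] <- Fdec[, dblk(1L + 3L * k + s), drop = FALSE] - Fc
      l_con <- l_con + (mean(R_u[[s]]^2) + mean(R_v[[s]]^2)) / k
    }
  }
  report <- structure(list(l_id = l_id, l_fwd = l_fwd, l_bwd = l_bwd,
                           l_idy = l_idy, l_con = l_con),
                      class = "loss_report")
  report$total <- total_loss(report, w)
  if (!want_grad) return(list(report = report))

  # gradient assembly --------------------------------------------------------
  dXdec <- Fdec * 0
  dXdec[, dblk(1L)] <- w$id * sc_amb * R_id
  for (s in seq_len(k)) {
    dXdec[, dblk(1L + s)] <- (w$fwd / k) * sc_amb * R_fwd[[s]]
    if (!dense) {
      dXdec[, dblk(1L + k + s)] <- (w$bwd / k) * sc_amb * R_bwd[[s]]
      dXdec[, dblk(1L + 2L * k + s)] <- (w$con / k) * sc_amb * R_u[[s]]
      dXdec[, dblk(1L + 3L * k + s)] <- (w$con / k) * sc_amb * R_v[[s]]
    }
  }
  decb <- mlp_backward(model$dec, dec, dXdec)
  dLat <- decb$dX

  gYall <- Yall * 0
  da <- if (!dense) a * 0
  db <- if (!dense) b * 0
  dK <- if (dense) K * 0

  # gradient received by each forward/backward chain state
  gZC <- vector("list", k)
  if (!dense) gZD <- vector("list", k)
  for (s in seq_len(k)) {
    gZC[[s]] <- dLat[, dblk(1L + s), drop = FALSE] +
      (w$idy / k) * sc_lat * E_f[[s]]
    gYall[, blk(jc + s)] <- gYall[, blk(jc + s), drop = FALSE] -
      (w$idy / k) * sc_lat * E_f[[s]]
    if (!dense) {
      gZD[[s]] <- dLat[, dblk(1L + k + s), drop = FALSE] +
        (w$idy / k) * sc_lat * E_b[[s]]
      gYall[, blk(jc - s)] <- gYall[, blk(jc - s), drop = FALSE] -
        (w$idy / k) * sc_lat * E_b[[s]]
    }
  }

  if (!dense) {
    # consistency chains: backpropagate decoder gradients through the
    # D^s (resp. C^s) tail back onto ZC[[s]] (resp. ZD[[s]])
    for (s in seq_len(k)) {
      g <- dLat[, dblk(1L + 2L * k + s), drop = FALSE]
      u <- Uchain[[s]]
      for (r in s:1) {
        inp <- u[[r]]
        db <- db + drop(inp %*% g[1L, ])
        gnew <- outer(b, g[1L, ])
        gnew[seq_len(L - 1L), ] <- gnew[seq_len(L - 1L), , drop = FALSE] +
          g[2L:L, , drop = FALSE]
        g <- gnew
      }
      gZC[[s]] <- gZC[[s]] + g
      g <- dLat[, dblk(1L + 3L * k + s), drop = FALSE]
      v <- Vchain[[s]]
      for (r in s:1) {
        inp <- v[[r]]
        da <- da + drop(inp %*% g[L, ])
        gnew <- outer(a, g[L, ])
        gnew[2L:L, ] <- gnew[2L:L, , drop = FALSE] +
          g[seq_len(L - 1L), , drop = FALSE]
        g <- gnew
      }
      gZD[[s]] <- gZD[[s]] + g
    }
  }

  # main chains, from horizon k back to the encoded center state
  gY0 <- dLat[, dblk(1L), drop = FALSE]
  g <- Y0 * 0
  for (s in k:1) {
    g <- g + gZC[[s]]
    inp <- if (s > 1L) ZC[[s - 1L]] else Y0
    if (dense) {
      dK <- dK + tcrossprod(g, inp)
      g <- crossprod(K, g)
    } else {
      da <- da + drop(inp %*% g[L, ])
      gnew <- outer(a, g[L, ])
      gnew[2L:L, ] <- gnew[2L:L, , drop = FALSE] + g[seq_len(L - 1L), , drop = FALSE]
      g <- gnew
    }
  }
  gY0 <- gY0 + g
  if (!dense) {
    g <- Y0 * 0
    for (s in k:1) {
      g <- g + gZD[[s]]
      inp <- if (s > 1L) ZD[[s - 1L]] else Y0
      db <- db + drop(inp %*% g[1L, ])
      gnew <- outer(b, g[1L, ])
      gnew[seq_len(L - 1L), ] <- gnew[seq_len(L - 1L), , drop = FALSE] +
        g[2L:L, , drop = FALSE]
      g <- gnew
    }
    gY0 <- gY0 + g
  }

  gYall[, blk(jc)] <- gYall[, blk(jc), drop = FALSE] + gY0
  encb <- mlp_backward(model$enc, enc, gYall)

  grad <- list(enc = list(W = encb$W, b = encb$b),
               dec = list(W = decb$W, b = decb$b),
               op = if (dense) list(K = dK) else list(a = da, b = db))
  list(report = report, grad = grad)
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("losses: id %.3g fwd %.3g bwd %.3g idy %.3g con %.3g | total %.3g\n",
              x$l_id, x$l_fwd, x$l_bwd, x$l_idy, x$l_con, x$total))
  invisible(x)
}
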