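# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: dense matrices are written out index by index, and
# recurrences are unrolled scalar by scalar.

# Dense forward companion matrix: shift rows + coefficient last row.
dense_forward <- function(a) {
  L <- length(a)
  M <- matrix(0, L, L)
  for (i in seq_len(L - 1)) M[i, i + 1] <- 1
  for (j in seq_len(L)) M[L, j] <- a[j]
  M
}

# Dense backward companion matrix: coefficient first row + sub-shift.
dense_backward <- function(b) {
  L <- length(b)
  M <- matrix(0, L, L)
  for (j in seq_len(L)) M[1, j] <- b[j]
  for (i in seq_len(L - 1)) M[i + 1, i] <- 1
  M
}

# Monic polynomial with the given roots, returned as the companion
# coefficients a of z^L - a_L z^{L-1} - ... - a_1 (so that the companion
# matrix built from a has exactly those eigenvalues).
companion_coefs_from_roots <- function(roots) {
  p <- 1
  for (r in roots) p <- c(0, p) - r * c(p, 0)  # multiply by (z - r)
  # p = c(c_0, ..., c_{L-1}, 1) in ascending powers
  -p[seq_along(roots)]
}

# Scalar linear recurrence y_{t+L} = sum_i a_i y_{t+i-1}, unrolled.
companion_series <- function(a, y0, steps) {
  L <- length(a)
  y <- c(y0, numeric(steps))
  for (t in seq_len(steps)) y[L + t] <- sum(a * y[t:(t + L - 1)])
  y
}

# Delay-coordinate states of a scalar series: column t is (y_t ... y_{t+L-1}).
delay_states <- function(y, L) {
  vapply(seq_len(length(y) - L + 1), function(i) y[i:(i + L - 1)], numeric(L))
}

# A model whose encoder and decoder are exact identities (linear activation,
# square hidden layer) with the given companion pair; n must equal L.
identity_model <- function(a, b = NULL) {
  L <- length(a)
  m <- ekatp_model(n = L, L = L, hidden = L, activation = "linear", seed = 1)
  m$enc <- ekatp:::mlp_identity(L)
  m$dec <- ekatp:::mlp_identity(L)
  m$op$a <- a
  m$op$b <- if (is.null(b)) companion_inverse(companion_forward(a))$b else b
  m
}

# Flatten/restore helpers for finite-difference gradient checks.
model_par <- function(m) {
  if (m$op$type == "dense")
    list(enc = list(W = m$enc$W, b = m$enc$b),
         dec = list(W = m$dec$W, b = m$dec$b), op = list(K = m$op$K))
  else
    list(enc = list(W = m$enc$W, b = m$enc$b),
         dec = list(W = m$dec$W, b = m$dec$b),
         op = list(a = m$op$a, b = m$op$b))
}

model_set_par <- function(m, p) {
  m$enc$W <- p$enc$W; m$enc$b <- p$enc$b
  m$dec$W <- p$dec$W; m$dec$b <- p$dec$b
  if (m$op$type == "dense") m$op$K <- p$op$K
  else { m$op$a <- p$op$a; m$op$b <- p$op$b }
  m
}

batch_total <- function(m, Fall, B, k) {
  ekatp:::ekatp_loss_grad(m, Fall, B = B, k = k, want_grad = FALSE)$report$total
}
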