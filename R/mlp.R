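# Minimal fully-connected network machinery used for the encoder and decoder.
# Nets are plain lists (W, b, act) so they serialize to JSON and can be walked
# generically by the optimizer; hidden layers use the configured activation,
# the output layer is always linear.

mlp_init <- function(input_dim, output_dim, hidden, activation = "tanh") {
  if (length(hidden) < 1) stop("at least one hidden layer is required")
  if (!activation %in% c("tanh", "linear"))
    stop("activation must be 'tanh' or 'linear'")
  dims <- c(input_dim, hidden, output_dim)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(dims[l + 1] * fan_in, sd = 1 / sqrt(fan_in)),
                     dims[l + 1], fan_in)
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, act = activation)
}

# Exact identity network (linear activation, square hidden layer); used to
# hand-construct zero-loss reference configurations.
mlp_identity <- function(dim) {
  list(W = list(diag(dim), diag(dim)), b = list(numeric(dim), numeric(dim)),
       act = "linear")
}

mlp_forward <- function(net, X, want_cache = FALSE) {
  nl <- length(net$W)
  A <- if (want_cache) vector("list", nl + 1) else NULL
  cur <- X
  if (want_cache) A[[1]] <- cur
  for (l in seq_len(nl)) {
    cur <- net$W[[l]] %*% cur + net$b[[l]]
    if (l < nl && net$act == "tanh") cur <- tanh(cur)
    if (want_cache) A[[l + 1]] <- cur
  }
  if (want_cache) list(out = cur, A = A) else cur
}

# dOut: gradient of the loss w.r.t. the network output (same shape as out).
# Returns parameter gradients and the gradient w.r.t. the input matrix.
mlp_backward <- function(net, cache, dOut) {
  nl <- length(net$W)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  dZ <- dOut
  for (l in nl:1) {
    dW[[l]] <- tcrossprod(dZ, cache$A[[l]])
    db[[l]] <- rowSums(dZ)
    dA <- crossprod(net$W[[l]], dZ)
    if (l > 1 && net$act == "tanh") dA <- dA * (1 - cache$A[[l]]^2)
    dZ <- dA
  }
  list(W = dW, b = db, dX = dZ)
}

# ---- generic tree utilities over nested lists of numeric leaves -------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

# Adam optimizer over a parameter tree; state carries first/second moments
# and the step counter.
adam_init <- function(par, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = tree_map(function(x) x * 0, par),
       v = tree_map(function(x) x * 0, par),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, par, grad) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                       state$m, grad)
  state$v <- tree_map2(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                       state$v, grad)
  corr1 <- 1 - state$beta1^state$t
  corr2 <- 1 - state$beta2^state$t
  upd <- tree_map2(function(m, v) state$lr * (m / corr1) /
                     (sqrt(v / corr2) + state$eps),
                   state$m, state$v)
  list(state = state, par = tree_map2(`-`, par, upd))
}
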