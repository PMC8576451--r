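#' Structured companion Koopman operators
#'
#' The latent dynamics are modelled as linear evolution of a delay-coordinate
#' state `Y_t = (y_t, ..., y_{t+L-1})` under a pair of companion matrices:
#' the forward operator `C` advances the window one step (rows 1..L-1 are a
#' fixed shift, the last row holds the trainable recurrence coefficients
#' `a_1..a_L`, with `a_1 != 0`); the backward operator `D` retracts it
#' (row 1 holds `b_1..b_L` with `b_L != 0`, rows 2..L are the shift). Only
#' the `L` coefficients of each operator are trainable; the shift structure
#' is exact by construction, never learned.
#'
#' @param a,b numeric coefficient vectors of length `L >= 2`.
#' @return an operator object of class `companion_forward` /
#'   `companion_backward`.
#' @export
companion_forward <- function(a) {
  a <- as.numeric(a)
  if (length(a) < 2) stop("companion operator needs L >= 2")
  structure(list(a = a, L = length(a)), class = "companion_forward")
}

#' @rdname companion_forward
#' @export
companion_backward <- function(b) {
  b <- as.numeric(b)
  if (length(b) < 2) stop("companion operator needs L >= 2")
  structure(list(b = b, L = length(b)), class = "companion_backward")
}

# Raw kernels used in training loops: y may be a length-L vector or an
# L x B matrix of batched states.
comp_fwd_apply <- function(a, y) {
  if (is.matrix(y)) rbind(y[-1, , drop = FALSE], colSums(y * a), deparse.level = 0)
  else c(y[-1], sum(a * y))
}
comp_bwd_apply <- function(b, y) {
  if (is.matrix(y)) rbind(colSums(y * b), y[-length(b), , drop = FALSE], deparse.level = 0)
  else c(sum(b * y), y[-length(b)])
}

#' Apply a companion operator to a latent state
#'
#' `apply_forward()` computes `C y` (one step ahead), `apply_backward()`
#' computes `D y` (one step back); both are O(L) shift-plus-dot-product
#' kernels, exact in the structural zeros and ones. `k_step()` iterates an
#' operator `k` times (`k = 0` is the identity).
#'
#' @param op a `companion_forward` or `companion_backward`.
#' @param y latent state: length-`L` vector or `L x B` matrix (batch).
#' @param k non-negative integer step count.
#' @export
apply_forward <- function(op, y) {
  stopifnot(inherits(op, "companion_forward"))
  check_state_length(op, y)
  comp_fwd_apply(op$a, y)
}

#' @rdname apply_forward
#' @export
apply_backward <- function(op, y) {
  stopifnot(inherits(op, "companion_backward"))
  check_state_length(op, y)
  comp_bwd_apply(op$b, y)
}

check_state_length <- function(op, y) {
  len <- if (is.matrix(y)) nrow(y) else length(y)
  if (len != op$L)
    stop(sprintf("state length %d does not match operator L = %d", len, op$L))
  invisible(y)
}

#' @rdname apply_forward
#' @export
k_step <- function(op, y, k) {
  if (k < 0) stop("k must be non-negative")
  check_state_length(op, y)
  step <- if (inherits(op, "companion_forward")) {
    function(v) comp_fwd_apply(op$a, v)
  } else if (inherits(op, "companion_backward")) {
    function(v) comp_bwd_apply(op$b, v)
  } else stop("unknown operator type")
  for (i in seq_len(k)) y <- step(y)
  y
}

#' Materialize a companion operator as a dense matrix
#'
#' Expands the structured operator into its full `L x L` matrix form. Used
#' for tests and diagnostics only; applications always go through the O(L)
#' kernels.
#'
#' @param op a companion operator.
#' @return a dense `L x L` matrix.
#' @export
materialize <- function(op) {
  L <- op$L
  M <- matrix(0, L, L)
  if (inherits(op, "companion_forward")) {
    M[cbind(seq_len(L - 1), seq_len(L - 1) + 1)] <- 1
    M[L, ] <- op$a
  } else {
    M[1, ] <- op$b
    M[cbind(seq_len(L - 1) + 1, seq_len(L - 1))] <- 1
  }
  M
}

#' Backward companion inverting a forward companion
#'
#' For a forward operator with coefficients `a` (requires `a_1 != 0`), the
#' exact inverse dynamics are again a companion operator, with
#' `b_i = -a_{i+1}/a_1` for `i < L` and `b_L = 1/a_1`; the returned backward
#' operator satisfies `D = solve(C)`.
#'
#' @param op a `companion_forward`.
#' @export
companion_inverse <- function(op) {
  stopifnot(inherits(op, "companion_forward"))
  a <- op$a
  if (abs(a[1]) < 1e-12) stop("a_1 must be nonzero to invert the dynamics")
  companion_backward(c(-a[-1] / a[1], 1 / a[1]))
}

#' Least-squares companion coefficient fit
#'
#' Estimates the forward recurrence coefficients `a` from a sequence of
#' consecutive delay-coordinate states by ordinary least squares: each
#' consecutive pair contributes one equation `y_next[L] = sum(a * y)`. With
#' noiseless companion-generated data the fit is exact; it serves as a warm
#' start and as an independent diagnostic for gradient-trained operators.
#'
#' @param states `L x m` matrix whose columns are consecutive latent states
#'   (`m >= L + 1`), or a numeric vector scalar series (then `L` must be
#'   given and delay vectors are formed from it).
#' @param L embedding dimension (only for a scalar series input).
#' @return a `companion_forward`.
#' @export
fit_companion_lsq <- function(states, L = NULL) {
  if (!is.matrix(states)) {
    if (is.null(L)) stop("L is required when fitting from a scalar series")
    y <- as.numeric(states)
    if (length(y) < 2 * L)
      stop("scalar series too short to form L+1 delay states")
    states <- vapply(seq_len(length(y) - L + 1),
                     function(i) y[i:(i + L - 1)], numeric(L))
  }
  L <- nrow(states)
  m <- ncol(states)
  if (m < L + 1) stop("need at least L + 1 consecutive states")
  X <- t(states[, -m, drop = FALSE])
  z <- states[L, -1]
  dec <- qr(X)
  if (dec$rank < L)
    stop("singular companion fit: delay states are rank deficient")
  companion_forward(qr.coef(dec, z))
}

#' Serialize operators to and from JSON
#'
#' @param fwd a `companion_forward`; @param bwd optional `companion_backward`.
#' @param path file path; `operators_from_json()` returns the operator pair.
#' @export
operators_to_json <- function(fwd, bwd = NULL, path) {
  obj <- list(L = fwd$L, a = fwd$a)
  if (!is.null(bwd)) obj$b <- bwd$b
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname operators_to_json
#' @export
operators_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(forward = companion_forward(obj$a))
  if (!is.null(obj$b)) out$backward <- companion_backward(obj$b)
  out
}
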