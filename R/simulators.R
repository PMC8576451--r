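#' Simulator parameter sets
#'
#' Constructors for the three benchmark systems used to emulate multi-omics
#' time series: a discrete chaotic Lorenz-type map (gene-expression style
#' chaotic behaviour), a nonlinear pendulum (protein-abundance style
#' oscillation), and a mean-field fluid-flow model (metabolite-level flow
#' behaviour). All defaults are the study conditions used throughout the
#' package's experiments; every field is configurable.
#'
#' @param eta,rho Prandtl and Rayleigh numbers (dimensionless).
#' @param beta geometry factor (dimensionless).
#' @param h discrete step size controlling the nonlinearity level of the map;
#'   larger `h` gives more complicated interactions.
#' @param T total number of steps (columns of the trajectory).
#' @param init initial state vector.
#' @return a parameter list of class `lorenz_params`, `pendulum_params`, or
#'   `fluid_params`.
#' @export
lorenz_params <- function(eta = 10, rho = 28, beta = 8 / 3, h = 0.003,
                          T = 1050, init = c(1, 1, 1)) {
  stopifnot(h > 0, T >= 2, length(init) == 3)
  structure(list(eta = eta, rho = rho, beta = beta, h = h,
                 T = as.integer(T), init = as.numeric(init)),
            class = "lorenz_params")
}

#' @rdname lorenz_params
#' @param g_over_l gravity over pendulum length (1/time^2).
#' @param theta0 initial angle in radians; this is the complexity level of the
#'   oscillator (larger initial angle, stronger anharmonicity).
#' @param theta_dot0 initial angular velocity (radians/time).
#' @param dt integration step (time).
#' @export
pendulum_params <- function(g_over_l = 1, theta0 = 0.8, theta_dot0 = 0,
                            dt = 0.01, T = 1600) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(T >= 2)
  structure(list(g_over_l = g_over_l, theta0 = theta0,
                 theta_dot0 = theta_dot0, dt = dt, T = as.integer(T)),
            class = "pendulum_params")
}

#' @rdname lorenz_params
#' @param gamma,omega,A size parameters of the mean-field fluid model
#'   (dimensionless).
#' @param lam relaxation speed of the z coordinate onto the paraboloid
#'   z = x^2 + y^2 (1/time).
#' @export
fluid_params <- function(gamma = 0.1, omega = 1, A = -0.1, lam = 10,
                         dt = 0.01, T = 900, init = fluid_init("zeta1")) {
  if (dt <= 0) stop("dt must be positive")
  if (lam <= 0) stop("lam must be positive")
  stopifnot(length(init) == 3)
  structure(list(gamma = gamma, omega = omega, A = A, lam = lam, dt = dt,
                 T = as.integer(T), init = as.numeric(init)),
            class = "fluid_params")
}

#' @rdname lorenz_params
#' @param preset `"zeta1"` (low complexity, x=0, y=-0.01, z=0) or `"zeta2"`
#'   (high complexity, x=0.01, y=-0.1, z=0.5).
#' @export
fluid_init <- function(preset = c("zeta1", "zeta2")) {
  switch(match.arg(preset),
         zeta1 = c(0, -0.01, 0),
         zeta2 = c(0.01, -0.1, 0.5))
}

#' Simulate the discrete Lorenz-type map
#'
#' Iterates the three-variable map
#' \deqn{x_{t+1} = x_t + h\,\eta\,(y_t - z_t)}
#' \deqn{y_{t+1} = y_t + h\,(x_t(\rho - z_t) - y_t)}
#' \deqn{z_{t+1} = z_t + h\,(x_t y_t - \beta z_t)}
#' where the default `"classic"` x-forcing is the textbook
#' \eqn{x_{t+1} = x_t + h\,\eta\,(y_t - x_t)}; the `"printed"` variant
#' replaces it with \eqn{h\,\eta\,(y_t - z_t)}. The printed variant is
#' provided for completeness but is dynamically unstable under the
#' classical parameterization (trajectories from generic initial states
#' overflow within a few hundred steps at `h = 0.003`), so bounded chaotic
#' benchmark series require the classic forcing.
#'
#' @param params a [lorenz_params()] object.
#' @param variant `"classic"` (default) or `"printed"`; see Details.
#' @return a [latent_trajectory()] of shape `3 x T`.
#' @export
simulate_lorenz <- function(params, variant = c("classic", "printed")) {
  variant <- match.arg(variant)
  V <- matrix(0, 3, params$T)
  V[, 1] <- params$init
  h <- params$h; eta <- params$eta; rho <- params$rho; beta <- params$beta
  for (t in seq_len(params$T - 1)) {
    x <- V[1, t]; y <- V[2, t]; z <- V[3, t]
    xf <- if (variant == "printed") y - z else y - x
    V[1, t + 1] <- x + h * eta * xf
    V[2, t + 1] <- y + h * (x * (rho - z) - y)
    V[3, t + 1] <- z + h * (x * y - beta * z)
    if (!all(is.finite(V[, t + 1])))
      stop(sprintf("Lorenz map diverged at step %d", t), call. = FALSE)
  }
  latent_trajectory(V)
}

# RK4 integration of an autonomous ODE on a fixed-step grid; returns d x T.
integrate_rk4 <- function(deriv, init, dt, T, label) {
  times <- seq(0, by = dt, length.out = T)
  sol <- deSolve::ode(y = init, times = times,
                      func = function(t, y, p) list(deriv(y)),
                      parms = NULL, method = "rk4")
  V <- t(unname(sol[, -1, drop = FALSE]))
  if (!all(is.finite(V))) {
    bad <- which(!apply(is.finite(V), 2, all))[1]
    stop(sprintf("%s integration diverged at step %d", label, bad - 1L),
         call. = FALSE)
  }
  V
}

#' Simulate the nonlinear pendulum
#'
#' Integrates \eqn{\ddot\theta + (g/l)\sin\theta = 0} with fixed-step RK4 and
#' returns the `(theta, theta_dot)` trajectory, sampled every `dt`.
#'
#' @param params a [pendulum_params()] object.
#' @return a [latent_trajectory()] of shape `2 x T`.
#' @export
simulate_pendulum <- function(params) {
  gl <- params$g_over_l
  V <- integrate_rk4(function(y) c(y[2], -gl * sin(y[1])),
                     c(params$theta0, params$theta_dot0),
                     params$dt, params$T, "pendulum")
  latent_trajectory(V)
}

#' Simulate the mean-field fluid-flow model
#'
#' Integrates, with fixed-step RK4,
#' \deqn{\dot x = \gamma x - \omega y + A x z}
#' \deqn{\dot y = \omega x + \gamma y + A y z}
#' \deqn{\dot z = -\lambda (z - x^2 - y^2)}
#' For large \eqn{\lambda} the z coordinate relaxes quickly onto the slow
#' manifold \eqn{z = x^2 + y^2}.
#'
#' @param params a [fluid_params()] object.
#' @return a [latent_trajectory()] of shape `3 x T`.
#' @export
simulate_fluid <- function(params) {
  g <- params$gamma; w <- params$omega; A <- params$A; lam <- params$lam
  V <- integrate_rk4(function(y) {
    c(g * y[1] - w * y[2] + A * y[1] * y[3],
      w * y[1] + g * y[2] + A * y[2] * y[3],
      -lam * (y[3] - y[1]^2 - y[2]^2))
  }, params$init, params$dt, params$T, "fluid")
  latent_trajectory(V)
}

#' Add white Gaussian observation noise
#'
#' Perturbs every entry of the trajectory by an independent draw from
#' \eqn{N(0, \sigma^2)}; `sigma` is the noise intensity. Noise is
#' observational and applied to the stored states after simulation.
#'
#' @param traj an `ekatp_trajectory`.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return a trajectory of the same class and shape.
#' @export
add_noise <- function(traj, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  values <- traj$values
  if (sigma > 0) {
    eps <- with_local_seed(seed, matrix(stats::rnorm(length(values), 0, sigma),
                                        nrow(values), ncol(values)))
    values <- values + eps
  }
  out <- traj
  out$values <- values
  out
}

# Evaluate expr under a temporary RNG seed (restoring the caller's stream),
# or under the current stream when seed is NULL.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random orthogonal lifting maps
#'
#' `make_orthogonal_lift()` draws an `n x d` matrix `P` with orthonormal
#' columns (thin QR of a standard-Gaussian matrix, column signs fixed so the
#' QR `R` factor has positive diagonal, making the draw deterministic under a
#' seed). `lift()` maps a d-dimensional latent trajectory to the
#' n-dimensional observation `F = P V`; `project()` applies the orthogonal
#' inverse transformation `t(P) F`, so `project(lift(V)) == V`.
#'
#' @param n ambient (observed) dimension, `n > d`.
#' @param d latent dimension.
#' @param seed optional integer seed.
#' @return `make_orthogonal_lift()`: a `lifting_map` with fields `P`, `n`,
#'   `d`, `seed`.
#' @export
make_orthogonal_lift <- function(n, d, seed = NULL) {
  if (n <= d) stop("ambient dimension n must exceed latent dimension d")
  if (d < 1) stop("latent dimension must be at least 1")
  M <- with_local_seed(seed, matrix(stats::rnorm(n * d), n, d))
  dec <- qr(M)
  Q <- qr.Q(dec)
  signs <- sign(diag(qr.R(dec)))
  signs[signs == 0] <- 1
  Q <- sweep(Q, 2, signs, "*")
  structure(list(P = Q, n = n, d = d, seed = seed), class = "lifting_map")
}

#' @rdname make_orthogonal_lift
#' @param traj a [latent_trajectory()] (`lift`) or [lifted_trajectory()]
#'   (`project`).
#' @param map a `lifting_map`.
#' @export
lift <- function(traj, map) {
  if (map$d != nrow(traj$values))
    stop(sprintf("lifting map expects d = %d but trajectory has d = %d",
                 map$d, nrow(traj$values)))
  lifted_trajectory(map$P %*% traj$values,
                    provenance = list(latent = traj, map = map))
}

#' @rdname make_orthogonal_lift
#' @export
project <- function(traj, map) {
  if (map$n != nrow(traj$values))
    stop(sprintf("lifting map expects n = %d but trajectory has n = %d",
                 map$n, nrow(traj$values)))
  latent_trajectory(crossprod(map$P, traj$values))
}
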