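test_that("Lorenz map honors its fixed point and the printed update rules", {
  zero <- simulate_lorenz(lorenz_params(init = c(0, 0, 0), T = 50))
  expect_equal(zero$values, matrix(0, 3, 50))

  # one hand-computed step of the printed variant from (1, 1, 1) with
  # eta=10, rho=28, beta=8/3, h=0.003: x1 = 1 + 0.003*10*(1 - 1) = 1,
  # y1 = 1 + 0.003*(27 - 1) = 1.078, z1 = 1 + 0.003*(1 - 8/3) = 0.995
  tr <- simulate_lorenz(lorenz_params(h = 0.003, T = 2, init = c(1, 1, 1)),
                        variant = "printed")
  expect_equal(tr$values[, 2], c(1.0, 1.078, 0.995), tolerance = 1e-12)

  # the two variants differ in the x forcing only
  cl <- simulate_lorenz(lorenz_params(h = 0.003, T = 2, init = c(1, 2, 3)))
  pr <- simulate_lorenz(lorenz_params(h = 0.003, T = 2, init = c(1, 2, 3)),
                        variant = "printed")
  expect_equal(cl$values[2:3, 2], pr$values[2:3, 2])
  expect_equal(cl$values[1, 2], 1 + 0.003 * 10 * (2 - 1))
  expect_equal(pr$values[1, 2], 1 + 0.003 * 10 * (2 - 3))

  expect_equal(dim(simulate_lorenz(lorenz_params(T = 1050))$values),
               c(3L, 1050L))
  # the default stays bounded over the full benchmark horizon
  expect_lt(max(abs(simulate_lorenz(lorenz_params(T = 1050))$values)), 100)
})

test_that("Lorenz divergence is reported with the offending step", {
  expect_error(simulate_lorenz(lorenz_params(h = 10, T = 500)),
               "diverged at step")
  # the printed x-forcing is unstable at the benchmark settings
  expect_error(simulate_lorenz(lorenz_params(T = 1050), variant = "printed"),
               "diverged at step")
})

test_that("pendulum integration is accurate and energy conserving", {
  still <- simulate_pendulum(pendulum_params(theta0 = 0, theta_dot0 = 0,
                                             T = 100))
  expect_equal(still$values, matrix(0, 2, 100))

  # small-angle limit: period of 2*pi for g/l = 1; measure it as twice the
  # spacing of successive zeros of theta_dot (linearly interpolated)
  small <- simulate_pendulum(pendulum_params(theta0 = 0.01, T = 800))
  td <- small$values[2, ]
  cross <- which(td[-1] * td[-length(td)] < 0)
  tz <- (cross - 1 + td[cross] / (td[cross] - td[cross + 1])) * 0.01
  period <- 2 * diff(tz[1:2])
  expect_lt(abs(period - 2 * pi) / (2 * pi), 0.01)

  # energy E = theta_dot^2/2 - cos(theta) must be conserved by RK4 at
  # dt = 0.01 over the full proteomics horizon
  big <- simulate_pendulum(pendulum_params(theta0 = 2.4, T = 1600))
  E <- big$values[2, ]^2 / 2 - cos(big$values[1, ])
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("integrator converges at its nominal order (Richardson check)", {
  final_state <- function(dt) {
    p <- pendulum_params(theta0 = 2.4, dt = dt, T = round(8 / dt) + 1)
    simulate_pendulum(p)$values[, round(8 / dt) + 1]
  }
  e1 <- sqrt(sum((final_state(0.02) - final_state(0.01))^2))
  e2 <- sqrt(sum((final_state(0.01) - final_state(0.005))^2))
  expect_gt(e1 / e2, 8)   # 4th order: halving dt cuts the error ~16x
  expect_lt(e1 / e2, 32)
})

test_that("fluid model: fixed point, presets, and slow-manifold relaxation", {
  zero <- simulate_fluid(fluid_params(init = c(0, 0, 0), T = 50))
  expect_equal(zero$values, matrix(0, 3, 50))

  z1 <- simulate_fluid(fluid_params(T = 5))
  expect_equal(z1$values[, 1], c(0, -0.01, 0))
  expect_equal(fluid_init("zeta2"), c(0.01, -0.1, 0.5))

  # starting on z = x^2 + y^2 with fast relaxation, the trajectory stays
  # near the slow manifold; the attainable deviation is bounded by a
  # half-step reference integration
  on_manifold <- function(dt) {
    p <- fluid_params(init = c(0.3, 0, 0.09), lam = 10, dt = dt,
                      T = round(5 / dt) + 1)
    v <- simulate_fluid(p)$values
    max(abs(v[3, ] - v[1, ]^2 - v[2, ]^2))
  }
  expect_lt(on_manifold(0.01), 1.2 * on_manifold(0.005) + 1e-10)
})

test_that("white observation noise has the right moments and determinism", {
  tr <- latent_trajectory(matrix(1, 3, 10000))

  expect_identical(add_noise(tr, 0)$values, tr$values)
  expect_error(add_noise(tr, -0.1), "non-negative")

  noisy <- add_noise(tr, 0.1, seed = 11)
  resid <- noisy$values - tr$values
  se_var <- 0.01 * sqrt(2 / (length(resid) - 1))
  expect_lt(abs(var(as.vector(resid)) - 0.01), 3 * se_var)
  expect_lt(abs(mean(resid)), 3 * 0.1 / sqrt(length(resid)))

  expect_identical(add_noise(tr, 0.1, seed = 7)$values,
                   add_noise(tr, 0.1, seed = 7)$values)
})

test_that("orthogonal lifts are orthonormal, deterministic, isometric", {
  map <- make_orthogonal_lift(96, 3, seed = 1)
  expect_lt(max(abs(crossprod(map$P) - diag(3))), 1e-10)
  expect_equal(dim(make_orthogonal_lift(64, 2, seed = 1)$P), c(64L, 2L))
  expect_identical(make_orthogonal_lift(96, 3, seed = 5)$P,
                   make_orthogonal_lift(96, 3, seed = 5)$P)
  expect_error(make_orthogonal_lift(3, 3), "must exceed")

  set.seed(2)
  V <- latent_trajectory(matrix(rnorm(3 * 40), 3))
  Fl <- lift(V, map)
  expect_equal(sqrt(colSums(Fl$values^2)), sqrt(colSums(V$values^2)),
               tolerance = 1e-10)
})

test_that("project inverts lift, and projected noise is t(P) E", {
  map <- make_orthogonal_lift(96, 3, seed = 3)
  set.seed(4)
  V <- latent_trajectory(matrix(rnorm(3 * 25), 3))
  expect_equal(project(lift(V, map), map)$values, V$values,
               tolerance = 1e-10)

  E <- matrix(rnorm(96 * 25), 96)
  noisy <- lifted_trajectory(map$P %*% V$values + E)
  expect_equal(project(noisy, map)$values,
               V$values + t(map$P) %*% E, tolerance = 1e-10)

  expect_error(lift(latent_trajectory(matrix(0, 2, 5)), map), "d = 3")
  expect_error(project(lifted_trajectory(matrix(0, 5, 5)), map), "n = 96")
})

test_that("trajectories round-trip through TSV at full precision", {
  set.seed(9)
  V <- latent_trajectory(matrix(rnorm(3 * 17), 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(V, path)
  back <- read_trajectory_tsv(path)
  expect_equal(back$values, V$values, tolerance = 1e-14)
  expect_identical(back$time, V$time)
  header <- readLines(path, n = 1)
  expect_identical(header, "t\ts1\ts2\ts3")
})

test_that("non-finite states are rejected on construction", {
  expect_error(latent_trajectory(matrix(c(1, NaN), 1)), "non-finite")
})
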