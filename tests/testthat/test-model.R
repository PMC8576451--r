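test_that("reconstruction loss is a per-element MSE", {
  expect_identical(loss_id(c(1, 2), c(1, 2)), 0)
  expect_equal(loss_id(c(1, 4), c(1, 2)), 2)
  r <- matrix(rnorm(12, sd = 2), 3)
  f <- matrix(rnorm(12), 3)
  expect_equal(loss_id(f + 3 * r, f), 9 * loss_id(f + r, f))
  expect_error(loss_id(1:4, 1:3), "shape mismatch")
})

test_that("total loss is the exact weighted sum", {
  rep1 <- list(l_id = 1, l_fwd = 1, l_bwd = 1, l_idy = 1, l_con = 1)
  expect_equal(total_loss(rep1, loss_weights()), 5)
  rep2 <- list(l_id = 2, l_fwd = 3, l_bwd = 1, l_idy = 4, l_con = 2)
  w <- loss_weights(id = 0.1, fwd = 1, bwd = 1, idy = 0.5, con = 0.5)
  expect_equal(total_loss(rep2, w), 7.2)

  # reported total always equals the weighted recombination
  set.seed(1)
  m <- ekatp_model(4, L = 3, hidden = 5, seed = 2,
                   weights = loss_weights(0.3, 1.2, 0.7, 2, 0.1))
  win <- matrix(rnorm(4 * 5), 4)
  rep3 <- ekatp_losses(m, win, k = 2)
  expect_equal(rep3$total, total_loss(rep3, m$weights), tolerance = 1e-10)

  expect_error(loss_weights(id = -1), "non-negative")
  expect_error(loss_weights(0, 0, 0, 0, 0), "at least one")
})

test_that("encode/decode preserve batch order and handle edge inputs", {
  m <- ekatp_model(6, L = 4, hidden = 8, seed = 3)
  X <- matrix(rnorm(6 * 7), 6)
  Y <- encode(m, X)
  expect_equal(dim(Y), c(4L, 7L))
  for (j in c(1, 4, 7)) expect_equal(Y[, j], encode(m, X[, j]))
  expect_equal(dim(decode(m, Y)), c(6L, 7L))

  # zero weights and biases give the zero map
  z <- m
  z$enc$W <- lapply(z$enc$W, function(w) w * 0)
  z$enc$b <- lapply(z$enc$b, function(b) b * 0)
  expect_equal(encode(z, X), matrix(0, 4, 7))

  expect_error(encode(m, rep(1, 5)), "dimension")
  expect_error(encode(m, c(NA, 1, 2, 3, 4, 5)), "non-finite")
})

test_that("exact delay-map configuration drives every loss below 1e-10", {
  # master oracle: companion-generated latent data, identity lift (n = L),
  # identity encoder/decoder, true companion pair C and D = C^{-1}
  a <- companion_coefs_from_roots(c(0.95, -0.9, 0.8 * 1i, -0.8 * 1i))
  a <- Re(a)
  y <- companion_series(a, c(0.4, -0.3, 0.2, 0.5), 60)
  states <- delay_states(y, 4)
  m <- identity_model(a)

  k <- 3
  for (center in c(10, 25, 40)) {
    win <- states[, (center - k):(center + k)]
    rep <- ekatp_losses(m, win, k = k)
    expect_lt(rep$l_id, 1e-10)
    expect_lt(rep$l_fwd, 1e-10)
    expect_lt(rep$l_bwd, 1e-10)
    expect_lt(rep$l_idy, 1e-10)
    expect_lt(rep$l_con, 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  fd_check <- function(m, B = 2, k = 2, h = 1e-4) {
    set.seed(10)
    Fall <- matrix(rnorm(m$n * (2 * k + 1) * B), m$n)
    g <- ekatp:::ekatp_loss_grad(m, Fall, B = B, k = k)$grad
    p0 <- model_par(m)
    flat <- unlist(p0)
    gflat <- unlist(g)
    idx <- seq(1, length(flat), length.out = min(60, length(flat)))
    idx <- unique(round(idx))
    fd <- vapply(idx, function(i) {
      up <- flat; up[i] <- up[i] + h
      dn <- flat; dn[i] <- dn[i] - h
      (batch_total(model_set_par(m, relist(up, p0)), Fall, B, k) -
         batch_total(model_set_par(m, relist(dn, p0)), Fall, B, k)) / (2 * h)
    }, numeric(1))
    max(abs(fd - gflat[idx])) / max(abs(fd))
  }
  expect_lt(fd_check(ekatp_model(5, L = 4, hidden = 6, seed = 7)), 1e-4)
  expect_lt(fd_check(make_kae(5, L = 4, hidden = 6, seed = 7)), 1e-4)
  # a zeroed weight removes that term's gradient contribution entirely
  m_fwd_only <- ekatp_model(5, L = 4, hidden = 6, seed = 7,
                            weights = loss_weights(0, 1, 0, 0, 0))
  expect_lt(fd_check(m_fwd_only), 1e-4)
})

test_that("k = 1 window losses match a hand-unrolled computation", {
  # tiny model: n = L = 2, identity autoencoder, a = (0, 1), b = (1, 0)
  m <- identity_model(c(0, 1), b = c(1, 0))
  win <- matrix(c(1, 2, 3, 5, 8, 13), nrow = 2)  # F_{t-1}, F_t, F_{t+1}

  # by hand: Y_t = (3,5); C Y_t = (5, 0*3+1*5) = (5,5); decode = itself
  # L_fwd = mean((5-8)^2, (5-13)^2) = (9+64)/2
  # D Y_t = (1*3+0*5, 3) = (3,3); L_bwd = mean((3-1)^2, (3-2)^2) = 2.5
  # L_idy = mean((5-8)^2,(5-13)^2) + mean((3-1)^2,(3-2)^2)
  # DCY_t = D(5,5) = (5,5); CDY_t = C(3,3) = (3,3)
  # L_con = mean((5-3)^2,(5-5)^2) + mean((3-3)^2,(3-5)^2)
  rep <- ekatp_losses(m, win, k = 1)
  expect_equal(rep$l_id, 0, tolerance = 1e-12)
  expect_equal(rep$l_fwd, (9 + 64) / 2, tolerance = 1e-12)
  expect_equal(rep$l_bwd, (4 + 1) / 2, tolerance = 1e-12)
  expect_equal(rep$l_idy, (9 + 64) / 2 + (4 + 1) / 2, tolerance = 1e-12)
  expect_equal(rep$l_con, (4 + 0) / 2 + (0 + 4) / 2, tolerance = 1e-12)

  expect_error(ekatp_losses(m, win, k = 2), "need 2k\\+1")
})

test_that("training is deterministic and decreases the objective", {
  set.seed(20)
  traj <- simulate_pendulum(pendulum_params(theta0 = 0.8, T = 260))
  map <- make_orthogonal_lift(12, 2, seed = 20)
  Fobs <- lift(traj, map)
  cfg <- train_config(k = 4, epochs = 8, train_steps = 200, seed = 20)
  m <- ekatp_model(12, L = 6, hidden = c(16, 8), seed = 20)

  f1 <- train_ekatp(m, Fobs, cfg)
  f2 <- train_ekatp(m, Fobs, cfg)
  expect_identical(f1$model$op$a, f2$model$op$a)
  expect_identical(f1$model$enc$W, f2$model$enc$W)
  expect_lt(f1$history$total[nrow(f1$history)], f1$history$total[1])

  # compiled and reference engines follow the same schedule
  fr <- train_ekatp(m, Fobs, train_config(k = 4, epochs = 2,
                                          train_steps = 200, seed = 20,
                                          engine = "r"))
  fc <- train_ekatp(m, Fobs, train_config(k = 4, epochs = 2,
                                          train_steps = 200, seed = 20,
                                          engine = "cpp"))
  expect_equal(fr$history$total, fc$history$total, tolerance = 1e-4)
  expect_equal(fr$model$op$a, fc$model$op$a, tolerance = 1e-4)
})

test_that("gradient training recovers companion coefficients on linear data", {
  # all recurrence roots on the unit circle: every mode stays excited over
  # the whole series, so the coefficients are uniquely identified
  a_star <- Re(companion_coefs_from_roots(exp(c(0.3i, -0.3i, 1.1i, -1.1i))))
  y <- companion_series(a_star, c(0.3, -0.2, 0.5, 0.1), 500)
  states <- delay_states(y, 4)
  m <- identity_model(c(1e-2, 0, 0, 1), b = c(1, 0, 0, 1e-2))
  fit <- train_ekatp(m, states,
                     train_config(k = 3, epochs = 600, batch_size = 64,
                                  lr = 5e-3, seed = 1,
                                  freeze_autoencoder = TRUE))
  expect_lt(max(abs(fit$model$op$a - a_star)), 1e-2)
  # and the gradient-trained estimate agrees with the least-squares one
  expect_lt(max(abs(fit$model$op$a - fit_companion_lsq(states)$a)), 1e-2)
  # the backward operator converges to the inverse dynamics
  b_star <- companion_inverse(companion_forward(a_star))$b
  expect_lt(max(abs(fit$model$op$b - b_star)), 1e-2)
})

test_that("prediction decodes operator-evolved latent states", {
  m <- ekatp_model(10, L = 5, hidden = 12, seed = 30)
  m$trained <- TRUE
  F_t <- rnorm(10)
  p0 <- predict_ekatp(m, F_t, k = 0)
  expect_equal(drop(p0), decode(m, encode(m, F_t)))
  pf <- predict_ekatp(m, F_t, k = 7)
  expect_equal(dim(pf), c(10L, 7L))
  # column s is decode(C^s encode(F_t))
  y <- encode(m, F_t)
  C <- companion_forward(m$op$a)
  expect_equal(pf[, 3], decode(m, k_step(C, y, 3)), tolerance = 1e-12)
  pb <- predict_ekatp(m, F_t, k = 4, direction = "backward")
  D <- companion_backward(m$op$b)
  expect_equal(pb[, 2], decode(m, k_step(D, y, 2)), tolerance = 1e-12)

  expect_warning(predict_ekatp(ekatp_model(10, L = 5, hidden = 12, seed = 1),
                               F_t, k = 1), "untrained")

  # with an exact model (zero consistency loss), predicting k forward and
  # then k backward from the endpoint returns the start state
  a <- Re(companion_coefs_from_roots(exp(c(0.4i, -0.4i, 0.9i, -0.9i))))
  em <- identity_model(a)
  em$trained <- TRUE
  y0 <- companion_series(a, c(0.3, -0.2, 0.5, 0.1), 10)[1:4]
  fwd <- predict_ekatp(em, y0, k = 3)
  back <- predict_ekatp(em, fwd[, 3], k = 3, direction = "backward")
  expect_equal(back[, 3], y0, tolerance = 1e-8)
})

test_that("KAE ablation: dense operator, forward-only training surface", {
  kae <- make_kae(10, L = 6, hidden = 8, seed = 5)
  expect_identical(kae$op$type, "dense")
  expect_identical(length(kae$op$K), 36L)          # L^2 trainable entries
  ek <- ekatp_model(10, L = 6, hidden = 8, seed = 5)
  expect_identical(length(ek$op$a) + length(ek$op$b), 12L)  # 2L
  expect_identical(kae$weights$bwd, 0)
  expect_identical(kae$weights$con, 0)

  rep <- ekatp_losses(kae, matrix(rnorm(10 * 5), 10), k = 2)
  expect_identical(rep$l_bwd, 0)
  expect_identical(rep$l_con, 0)
  expect_gt(rep$l_idy, 0)
  kae$trained <- TRUE
  expect_error(predict_ekatp(kae, rnorm(10), k = 2, direction = "backward"),
               "no backward")
})

test_that("checkpoints round-trip through JSON", {
  m <- ekatp_model(8, L = 4, hidden = c(10, 6), seed = 40)
  m$trained <- TRUE
  path <- withr::local_tempfile(fileext = ".json")
  save_ekatp(m, path)
  back <- load_ekatp(path)
  x <- rnorm(8)
  expect_equal(predict_ekatp(back, x, k = 5), predict_ekatp(m, x, k = 5),
               tolerance = 1e-12)

  kae <- make_kae(8, L = 4, hidden = 6, seed = 41)
  kae$trained <- TRUE
  save_ekatp(kae, path)
  expect_equal(predict_ekatp(load_ekatp(path), x, k = 3),
               predict_ekatp(kae, x, k = 3), tolerance = 1e-12)
})

test_that("training aborts on violated companion constraints", {
  # force a1 to collapse: start it at the threshold and freeze nothing
  m <- ekatp_model(6, L = 4, hidden = 6, seed = 50)
  m$op$a[1] <- 1e-7
  set.seed(51)
  X <- matrix(rnorm(6 * 120), 6)
  expect_error(
    train_ekatp(m, X, train_config(k = 2, epochs = 1, lr = 1e-12, seed = 51)),
    "constraint violated")
})
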