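test_that("losses evaluate their printed forms", {
  p <- crnn_parameters(matrix(1, 2, 2), c(1, 1), matrix(1, 2, 2))
  obs <- matrix(runif(20), 10, 2)
  expect_equal(loss_mae_l2(p, obs, obs, l2 = 0), 0)
  expect_equal(loss_mae_l2(p, obs + 0.1, obs, l2 = 0), 0.1)
  # unit parameter vector of length 10 with l2 = 1e-5 adds 1e-4
  expect_equal(loss_mae_l2(p, obs, obs, l2 = 1e-5), 1e-4)
  expect_equal(loss_mape_l1_l2(p, obs, obs), 0)
  expect_equal(loss_mape_l1_l2(p, 1.1 * obs, obs), 10)
  # L1 on the stoichiometric block only
  p2 <- p; p2$stoich_weights <- matrix(c(20, 10, 15, 5), 2, 2)
  expect_equal(loss_mape_l1_l2(p2, obs, obs, l1 = 1e-4), 5e-3)
  # L2 in the MAPE loss touches only orders and biases
  expect_equal(loss_mape_l1_l2(p2, obs, obs, l2 = 1),
               sum(p2$order_weights^2) + sum(1, 1))
  expect_error(loss_mae_l2(p, obs[1:3, ], obs), "shape")
})

test_that("the step-size schedule is positive and non-increasing", {
  expect_equal(step_size(1:100, alpha = 0.002, gamma = 0),
               rep(0.002, 100))
  # benchmark values at t = 1
  expect_equal(step_size(1, 0.001, 0.15, 0.005), 0.001 * 1.15^(-0.005),
               tolerance = 1e-12)
  expect_equal(step_size(1, 0.001, 0.15, 0.005), 9.9930e-4,
               tolerance = 1e-4)
  eps <- step_size(1:5000)
  expect_true(all(eps > 0))
  expect_true(all(diff(eps) <= 0))
})

test_that("pSGLD updates the moving average and preconditioner as specified", {
  ctrl <- crnn_control(beta = 0.9, lambda = 1e-6, alpha = 1e-3,
                       step_gamma = 0, grad_clip = Inf, ema = "printed")
  # beta = 1 makes V the current squared gradient exactly
  ctrl1 <- crnn_control(beta = 1, grad_clip = Inf, ema = "printed")
  st <- list(theta = c(1, 2), v = c(5, 5), epoch = 1L)
  g <- c(0.3, -0.4)
  out <- psgld_step(st, g, ctrl1, n = 1e12)
  expect_equal(out$v, g^2)
  # zero gradient with (numerically) suppressed noise leaves theta fixed
  out0 <- psgld_step(list(theta = c(1, 2), v = c(0.04, 0.04), epoch = 1L),
                     c(0, 0), ctrl, n = 1e12)
  expect_equal(out0$theta, c(1, 2), tolerance = 1e-9)
  expect_equal(out0$epoch, 2L)
  # constant unit gradient: V -> 1, so the preconditioned step approaches
  # the plain gradient step eps * g
  st <- list(theta = 0, v = 0, epoch = 1L)
  for (i in 1:200) {
    before <- st$theta
    st <- psgld_step(st, 1, ctrl, n = 1e12)
  }
  expect_equal(st$v, 1, tolerance = 1e-6)
  expect_equal(before - st$theta, 1e-3 / (1e-6 + 1), tolerance = 1e-4)
  # preconditioner entries are bounded by 1/lambda
  expect_lte(attr(st, "precond_max"), 1 / ctrl$lambda)
  # constraint projection clips listed coordinates
  stp <- psgld_step(list(theta = c(-1, -1), v = c(1, 1), epoch = 1L),
                    c(0, 0), ctrl, n = 1e12, nonneg_idx = 1L)
  expect_equal(stp$theta[1], 0)
  expect_lt(stp$theta[2], 0)
  st2 <- list(theta = c(1, 2), v = c(1, 1), epoch = 1L)
  expect_error(psgld_step(st2, c(1, NaN), ctrl), "non-finite")
  expect_error(psgld_step(st2, c(1, 2, 3), ctrl), "shape")
})

test_that("plain SGLD is pSGLD with the identity preconditioner", {
  ctrl <- crnn_control(lambda = 1, beta = 0.9, alpha = 1e-3,
                       step_gamma = 0, grad_clip = Inf)
  st <- list(theta = 0.5, v = 0, epoch = 3L)
  # V = 0 and lambda = 1 give G = 1 in both samplers
  set.seed(42); a <- psgld_step(st, 0, ctrl, n = 5)
  set.seed(42); b <- sgld_step(st, 0, ctrl, n = 5)
  expect_equal(a$theta, b$theta)
  # noise variance honors the printed eps/n^2 scaling
  set.seed(9)
  eps <- step_size(3, ctrl$alpha, ctrl$step_b, ctrl$step_gamma)
  draws <- replicate(20000, sgld_step(st, 0, ctrl, n = 5)$theta - 0.5)
  expect_equal(var(draws), eps / 25, tolerance = 0.05)
})

test_that("without noise the preconditioned descent is monotone on a quadratic", {
  ctrl <- crnn_control(alpha = 0.01, step_gamma = 0, grad_clip = Inf)
  st <- list(theta = 3, v = 0, epoch = 1L)
  loss <- function(th) 0.5 * th^2
  trace <- numeric(300)
  for (i in 1:300) {
    st <- psgld_step(st, st$theta, ctrl, n = 1e12)
    trace[i] <- loss(st$theta)
  }
  expect_true(all(diff(trace) <= 1e-12))
  expect_lt(trace[300], loss(3))
})

test_that("sampling-phase detection finds plateaus and rejects descents", {
  # flat trace: earliest admissible epoch
  flat <- rep(1, 400)
  expect_equal(detect_sampling_phase(flat, window = 50, threshold = 1e-3,
                                     patience = 10, min_burn_in = 100), 100)
  # steep monotone decrease: no sampling phase
  expect_true(is.na(detect_sampling_phase(10 * exp(-(1:400) / 400),
                                          window = 50, threshold = 1e-3,
                                          patience = 10, min_burn_in = 100)))
  # exponential decay to a plateau at epoch ~500 (decay constant 100)
  trace <- 1 + exp(-(1:1500) / 100)
  start <- detect_sampling_phase(trace, window = 50, threshold = 1e-3,
                                 patience = 50, min_burn_in = 100)
  expect_gte(start, 500)
  expect_lte(start, 700)
  expect_error(detect_sampling_phase(numeric()), "empty")
})

test_that("training is deterministic under a fixed seed and honors sentinels", {
  coll <- toy_collection()
  ctrl <- quick_control(max_epochs = 60L, seed = 3L)
  f1 <- bcrnn(coll, n_hidden = 1, control = ctrl)
  f2 <- bcrnn(coll, n_hidden = 1, control = ctrl)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$samples, f2$samples)
  # zero epoch budget: empty ensemble, sentinel sampling start
  f0 <- bcrnn(coll, n_hidden = 1,
              control = quick_control(max_epochs = 0L))
  expect_equal(nrow(f0$samples), 0)
  expect_true(is.na(f0$sampling_start_epoch))
  expect_true(f0$shortfall)
  expect_equal(nrow(f0$loss_trace), 0)
})

test_that("interrupted training resumes bit-identically from a checkpoint", {
  coll <- toy_collection()
  ckpt <- withr::local_tempfile(fileext = ".json")
  ctrl40 <- quick_control(max_epochs = 40L, min_burn_in = 1000L, seed = 5L)
  full <- bcrnn(coll, n_hidden = 1, control = ctrl40)
  ctrl20 <- quick_control(max_epochs = 20L, min_burn_in = 1000L, seed = 5L)
  part <- bcrnn(coll, n_hidden = 1, control = ctrl20,
                checkpoint_path = ckpt, checkpoint_every = 20L)
  resumed <- bcrnn(coll, n_hidden = 1, control = ctrl40, resume = ckpt)
  expect_equal(resumed$loss_trace, full$loss_trace)
  expect_equal(resumed$state$theta, full$state$theta)
})

test_that("training on a one-reaction toy system approaches the truth", {
  coll <- toy_collection(n = 8, seed = 2)
  ctrl <- crnn_control(max_epochs = 2500, min_burn_in = 800,
                       detect_window = 50, detect_patience = 20,
                       n_posterior = 200, patience_stop = 400, seed = 4)
  fit <- bcrnn(coll, n_hidden = 1, control = ctrl)
  expect_s3_class(fit, "bcrnn")
  expect_gt(nrow(fit$samples), 0)
  k_hat <- exp(coef(fit)$ln_rate_bias)
  expect_lt(abs(k_hat - 0.4) / 0.4, 0.5)
  # preconditioner bound held throughout training
  expect_lte(fit$precond_max, 1 / ctrl$lambda + 1e-9)
})
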