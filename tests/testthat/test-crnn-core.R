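test_that("CRNN rates reproduce the mass-action power law exactly", {
  # zero weights, zero bias: every candidate rate is exp(0) = 1
  p0 <- crnn_parameters(matrix(0, 3, 4), rep(0, 3), matrix(0, 4, 3))
  expect_equal(crnn_rates(p0, runif(4, 0.1, 2)), rep(1, 3))
  # the printed one-reaction example: order 2 on the first species
  p1 <- crnn_parameters(matrix(c(2, 0, 0, 0, 0), 1, 5), log(0.1),
                        matrix(c(-2, 1, 0, 0, 0), 5, 1))
  expect_equal(crnn_rates(p1, rep(1, 5)), 0.1)
  expect_error(crnn_rates(p1, rep(1, 3)), "dimension")
})

test_that("transcribed parameters match the analytic kinetics to machine precision", {
  set.seed(31)
  for (sys in c(list(case1_system(), case2_system()),
                lapply(1:20, function(i) random_system()))) {
    p <- crnn_from_system(sys)
    for (rep in 1:5) {
      y <- runif(length(sys$species_names), 0.01, 2)
      ra <- mass_action_rates(sys, y)
      rc <- crnn_rates(p, y)
      expect_lt(max(abs(rc - ra) / pmax(ra, 1e-300)), 1e-10)
      expect_equal(crnn_rhs(p, y), mass_action_rhs(sys, y),
                   tolerance = 1e-10)
    }
  }
})

test_that("the CRNN right-hand side is bilinear in the output weights", {
  sys <- case1_system()
  p <- crnn_from_system(sys)
  expect_equal(crnn_rhs(p, rep(1, 5)), c(-0.40, -0.20, 0.07, -0.17, 0.30))
  p2 <- p; p2$stoich_weights <- 2 * p$stoich_weights
  y <- runif(5, 0.1, 1)
  expect_equal(crnn_rhs(p2, y), 2 * crnn_rhs(p, y))
  p3 <- p; p3$stoich_weights[] <- 0
  expect_equal(crnn_rhs(p3, y), rep(0, 5))
})

test_that("integrating transcribed parameters reproduces the simulator", {
  sys <- case1_system()
  p <- crnn_from_system(sys)
  times <- seq(0, 40, length.out = 100)
  ref <- simulate_system(sys, c(0.8, 0.4, 0, 0, 0), times)
  crn <- integrate_crnn(p, c(0.8, 0.4, 0, 0, 0), times)
  expect_false(attr(crn, "diverged"))
  expect_lt(max(abs(crn$concentrations - ref$concentrations)), 1e-5)
  # the stiffer benchmark needs substeps but matches as well
  sys2 <- case2_system()
  t2 <- seq(0, 10, length.out = 100)
  y0 <- c(1, 0.5, 0.2, 1, 0.1, 0.4, 0)
  ref2 <- simulate_system(sys2, y0, t2)
  crn2 <- integrate_crnn(crnn_from_system(sys2), y0, t2, substeps = 4)
  expect_lt(max(abs(crn2$concentrations - ref2$concentrations)), 1e-4)
})

test_that("single-point grids return the initial condition", {
  p <- crnn_from_system(toy_system())
  tr <- integrate_crnn(p, c(1, 0), 0)
  expect_equal(unname(tr$concentrations), matrix(c(1, 0), 1))
})

test_that("constraint projection clips orders at zero and is idempotent", {
  p <- crnn_parameters(matrix(c(-0.3, 0.5, 1, -1e-9), 2, 2), c(0, 0),
                       matrix(0, 2, 2))
  q <- project_constraints(p)
  expect_equal(q$order_weights, matrix(c(0, 0.5, 1, 0), 2, 2))
  expect_identical(project_constraints(q), q)
  # already-feasible parameters are untouched
  ok <- crnn_from_system(case1_system())
  expect_identical(project_constraints(ok), ok)
})

test_that("solver gradients agree with finite differences", {
  set.seed(5)
  m <- 3; s <- 4
  W <- abs(matrix(rnorm(m * s, 0, 0.3), m, s))
  b <- rnorm(m, -1, 0.3)
  V <- matrix(rnorm(s * m, 0, 0.4), s, m)
  y0 <- runif(s, 0.2, 1)
  times <- c(0, 0.4, 0.9, 1.5)
  obs <- matrix(runif(4 * s, 0.1, 1), 4, s)
  for (kind in 0:1) {
    out <- bcrnn:::.crnn_loss_grad_cpp(W, b, V, y0, times, obs, kind,
                                       2L, 1e-8, 1e-6, 1e6)
    grads <- c(out$gW, out$gb, out$gV)
    eps <- 1e-6
    num <- numeric(length(grads))
    pack <- function(W, b, V) c(W, b, V)
    th <- pack(W, b, V)
    for (i in seq_along(th)) {
      up <- th; up[i] <- up[i] + eps
      dn <- th; dn[i] <- dn[i] - eps
      f <- function(t_) {
        Wm <- matrix(t_[1:(m * s)], m, s)
        bv <- t_[m * s + 1:m]
        Vm <- matrix(t_[m * s + m + 1:(s * m)], s, m)
        bcrnn:::.crnn_loss_grad_cpp(Wm, bv, Vm, y0, times, obs, kind,
                                    2L, 1e-8, 1e-6, 1e6)$loss
      }
      num[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    expect_lt(max(abs(num - grads)) / max(abs(grads)), 1e-4)
  }
})

test_that("transcription round-trips through a recovered system", {
  for (sys in list(case1_system(), case2_system())) {
    p <- crnn_from_system(sys)
    back <- system_from_crnn(p)
    expect_equal(unname(back$nu_reactant), unname(sys$nu_reactant))
    expect_equal(unname(back$nu_product), unname(sys$nu_product))
    expect_equal(back$rate_constants, sys$rate_constants)
    expect_equal(net_stoichiometry(back), net_stoichiometry(sys),
                 ignore_attr = TRUE)
  }
})

test_that("rates stay positive and integration never returns NaN", {
  set.seed(13)
  for (i in 1:25) {
    m <- sample(2:5, 1); s <- sample(2:5, 1)
    p <- crnn_parameters(abs(matrix(rnorm(m * s, 0, 1), m, s)),
                         rnorm(m, 0, 2),
                         matrix(rnorm(s * m, 0, 1.5), s, m))
    y <- runif(s, 0, 2) * rbinom(s, 1, 0.7)
    expect_true(all(crnn_rates(p, y) > 0))
    tr <- integrate_crnn(p, y, seq(0, 5, length.out = 20))
    expect_false(any(is.nan(tr$concentrations)))
  }
})

test_that("CRNN parameters round-trip through JSON", {
  p <- crnn_from_system(case2_system())
  path <- withr::local_tempfile(fileext = ".json")
  write_crnn_json(p, path)
  q <- read_crnn_json(path)
  expect_equal(q$order_weights, unname(p$order_weights))
  expect_equal(q$ln_rate_bias, p$ln_rate_bias)
  expect_equal(q$stoich_weights, unname(p$stoich_weights))
  expect_equal(q$species, p$species)
})

test_that("tied-weight kinetics equal the untied form with net stoichiometry", {
  set.seed(19)
  m <- 3; s <- 4
  W <- abs(matrix(rnorm(m * s, 0, 0.4), m, s))
  b <- rnorm(m, -1, 0.4)
  P <- abs(matrix(rnorm(s * m, 0, 0.5), s, m))   # product coefficients
  y0 <- runif(s, 0.2, 1)
  times <- seq(0, 2, length.out = 9)
  tied <- bcrnn:::.crnn_integrate_cpp(W, b, P, y0, times, 2L, 1e-8, TRUE)
  untied <- bcrnn:::.crnn_integrate_cpp(W, b, P - t(W), y0, times, 2L,
                                        1e-8, FALSE)
  expect_equal(tied$trajectory, untied$trajectory, tolerance = 1e-14)
  # tied gradients agree with finite differences
  obs <- matrix(runif(9 * s, 0.1, 1), 9, s)
  out <- bcrnn:::.crnn_loss_grad_cpp(W, b, P, y0, times, obs, 0L, 2L,
                                     1e-8, 1e-6, 1e6, TRUE)
  f <- function(W, b, P)
    bcrnn:::.crnn_loss_grad_cpp(W, b, P, y0, times, obs, 0L, 2L,
                                1e-8, 1e-6, 1e6, TRUE)$loss
  eps <- 1e-6
  gW <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    gW[i] <- (f(Wp, b, P) - f(Wm, b, P)) / (2 * eps)
  }
  expect_lt(max(abs(gW - out$gW)) / max(abs(out$gW)), 1e-4)
})
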