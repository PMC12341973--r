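# posterior analyses exercised on hand-constructed ensembles with known
# answers

two_species_ensemble <- function(weights) {
  # weights: list of order-weight pairs (X, Z) for a single reaction
  draws <- lapply(weights, function(w)
    crnn_parameters(matrix(w, 1, 2), 0, matrix(c(-1, 1), 2, 1),
                    species = c("X", "Z")))
  crnn_ensemble(draws)
}

test_that("recovery probability counts samples above the threshold", {
  ens <- two_species_ensemble(list(c(0.9, 0.1), c(1.1, 0)))
  p <- recovery_probability(ens, threshold = 1e-4)
  expect_equal(unname(p[, 1]), c(1, 0.5))
  # all samples above threshold
  all_in <- two_species_ensemble(rep(list(c(0.5, 0.2)), 10))
  expect_equal(unname(recovery_probability(all_in)[, 1]), c(1, 1))
  # 600 of 1000 above
  mix <- two_species_ensemble(c(rep(list(c(1, 1)), 600),
                                rep(list(c(1, 0)), 400)))
  expect_equal(unname(recovery_probability(mix)[, 1]), c(1, 0.6))
  # raising the threshold never increases any probability
  ens2 <- two_species_ensemble(list(c(0.9, 0.1), c(1.1, 0.2), c(0.05, 0)))
  p_lo <- recovery_probability(ens2, 1e-4)
  p_hi <- recovery_probability(ens2, 0.15)
  expect_true(all(p_hi <= p_lo))
  expect_error(recovery_probability(crnn_ensemble(
    matrix(numeric(), 0, 5),
    template = crnn_parameters(matrix(0, 1, 2), 0, matrix(0, 2, 1)))),
    "empty")
})

test_that("the score metric reweights probabilities by summed weight", {
  # two-draw ensemble: p = (1, 0.5), summed weights (2.0, 0.1)
  ens <- two_species_ensemble(list(c(0.9, 0.1), c(1.1, 0)))
  sc <- score_metric(ens, threshold = 1e-4)
  expect_equal(unname(sc[, 1]), c(1 * 2.0 / 2.0, 0.5 * 0.1 / 2.0))
  expect_equal(unname(sc[2, 1]), 0.025)
  # score never exceeds the recovery probability
  p <- recovery_probability(ens)
  expect_true(all(sc <= p + 1e-12))
  # the argmax-weight species of a column attains its probability
  expect_equal(sc[1, 1], p[1, 1])
  # a species absent from every sample scores 0
  only_x <- two_species_ensemble(rep(list(c(0.7, 0)), 5))
  expect_equal(unname(score_metric(only_x)[, 1]), c(1, 0))
  # dead reaction: all-zero weights give a zero score column, not NaN
  dead <- crnn_ensemble(list(
    crnn_parameters(matrix(0, 1, 2), 0, matrix(0, 2, 1)),
    crnn_parameters(matrix(0, 1, 2), 0, matrix(0, 2, 1))))
  expect_equal(unname(score_metric(dead)[, 1]), c(0, 0))
})

test_that("rate posteriors are exp(bias) with order-invariant summaries", {
  d1 <- crnn_parameters(matrix(1, 1, 2), log(0.1), matrix(0, 2, 1))
  ens <- crnn_ensemble(rep(list(d1), 7))
  rp <- rate_posteriors(ens)
  expect_equal(unname(as.numeric(rp$samples)), rep(0.1, 7))
  expect_equal(rp$summary$mean, 0.1)
  expect_equal(rp$summary$sd, 0)
  # lognormal mean oracle: bias ~ N(log 0.2, 0.01^2)
  set.seed(3)
  bs <- rnorm(4000, log(0.2), 0.01)
  draws <- lapply(bs, function(b)
    crnn_parameters(matrix(1, 1, 2), b, matrix(0, 2, 1)))
  rp2 <- rate_posteriors(crnn_ensemble(draws))
  expect_equal(rp2$summary$mean, 0.2 * exp(0.01^2 / 2), tolerance = 0.005)
  # summaries do not depend on sample order
  rp3 <- rate_posteriors(crnn_ensemble(rev(draws)))
  expect_equal(rp3$summary$mean, rp2$summary$mean)
  expect_equal(rp3$summary$sd, rp2$summary$sd)
})

test_that("reaction matching recovers identities, swaps and the brute-force optimum", {
  sys <- case1_system()
  truth_params <- crnn_from_system(sys)
  ens <- crnn_ensemble(rep(list(truth_params), 3))
  m <- match_reactions(ens, sys)
  expect_equal(as.integer(m), 1:4)
  expect_false(attr(m, "ambiguous"))
  # swapped hidden reactions are found by the swapping permutation
  swapped <- truth_params
  perm <- c(3, 1, 4, 2)
  swapped$order_weights <- truth_params$order_weights[perm, ]
  swapped$ln_rate_bias <- truth_params$ln_rate_bias[perm]
  swapped$stoich_weights <- truth_params$stoich_weights[, perm]
  m2 <- match_reactions(crnn_ensemble(rep(list(swapped), 3)), sys)
  expect_equal(perm[as.integer(m2)], 1:4)
  # independent brute force over all 4! assignments on a noisy ensemble
  set.seed(11)
  noisy <- truth_params
  noisy$order_weights <- noisy$order_weights[perm, ] +
    abs(matrix(rnorm(20, 0, 0.05), 4, 5))
  noisy$ln_rate_bias <- noisy$ln_rate_bias[perm]
  noisy$stoich_weights <- noisy$stoich_weights[, perm] +
    matrix(rnorm(20, 0, 0.05), 5, 4)
  ens3 <- crnn_ensemble(rep(list(noisy), 2))
  m3 <- match_reactions(ens3, sys)
  cost_of <- function(assign) {
    mp <- project_constraints(coef(ens3))
    W <- mp$order_weights; W[W < 1e-4] <- 0
    V <- mp$stoich_weights; V[abs(V) < 1e-4] <- 0
    net <- net_stoichiometry(sys)
    sum(vapply(seq_len(4), function(r)
      sum(abs(W[assign[r], ] - sys$nu_reactant[r, ])) +
        sum(abs(V[, assign[r]] - net[, r])), numeric(1)))
  }
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  best_cost <- min(apply(perms, 1, cost_of))
  expect_equal(attr(m3, "cost"), best_cost, tolerance = 1e-10)
})

test_that("percent deviations are averaged per sample after matching", {
  sys <- toy_system(k = 0.4)
  exact <- crnn_from_system(sys)
  ens <- crnn_ensemble(rep(list(exact), 4))
  expect_equal(percent_deviation(ens, sys)$mean_pct, 0)
  # every sample at 1.1 k_true: 10% +/- 0
  up <- exact; up$ln_rate_bias <- log(0.4 * 1.1)
  dev <- percent_deviation(crnn_ensemble(rep(list(up), 4)), sys)
  expect_equal(dev$mean_pct, 10)
  expect_equal(dev$sd_pct, 0)
  # samples at 0.9 and 1.2 k_true: mean 15, sd of {10, 20}
  lo <- exact; lo$ln_rate_bias <- log(0.4 * 0.9)
  hi <- exact; hi$ln_rate_bias <- log(0.4 * 1.2)
  dev2 <- percent_deviation(crnn_ensemble(list(lo, hi)), sys)
  expect_equal(dev2$mean_pct, 15)
  expect_equal(dev2$sd_pct, sd(c(10, 20)))
})

test_that("posterior predictive fans have coherent bands", {
  sys <- toy_system()
  exact <- crnn_from_system(sys)
  ens1 <- crnn_ensemble(rep(list(exact), 6))
  times <- seq(0, 5, length.out = 12)
  fan <- posterior_predictive(ens1, c(1, 0), times, n_draws = 6)
  # degenerate ensemble: zero-width band
  expect_equal(fan$lower, fan$upper, tolerance = 1e-12)
  expect_equal(fan$n_failed, 0)
  # widening the ensemble cannot shrink the central band
  pert <- exact; pert$ln_rate_bias <- log(0.8)
  ens2 <- crnn_ensemble(c(rep(list(exact), 6), list(pert)))
  fan2 <- posterior_predictive(ens2, c(1, 0), times, n_draws = 7)
  width1 <- fan$upper - fan$lower
  width2 <- fan2$upper - fan2$lower
  expect_true(all(width2 >= width1 - 1e-12))
  expect_error(posterior_predictive(ens1, c(1, 0), times, n_draws = 99),
               "exceeds")
})

test_that("extrapolation error scores only the window beyond the split", {
  times <- seq(0, 40, length.out = 100)
  obs <- matrix(runif(200, 0.5, 1), 100, 2)
  tro <- trajectory_dataset(times, obs)
  expect_equal(extrapolation_error(tro, tro, 30)$mape, 0)
  # a uniform +5% prediction error scores 5
  trp <- trajectory_dataset(times, obs * 1.05)
  err <- extrapolation_error(trp, tro, 30)
  expect_equal(err$mape, 5, tolerance = 1e-10)
  expect_equal(unname(err$per_species), c(5, 5), tolerance = 1e-10)
  # errors before the split are invisible
  mixed <- obs; mixed[times <= 30, ] <- 99
  expect_equal(extrapolation_error(trajectory_dataset(times, mixed),
                                   tro, 30)$mape,
               0)
  expect_error(extrapolation_error(tro, tro, 40), "beyond the split")
})
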