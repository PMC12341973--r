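test_that("mass-action rates follow the power law", {
  sys <- case1_system()
  # at unit concentrations every rate equals its rate constant
  expect_equal(mass_action_rates(sys, rep(1, 5)), c(0.1, 0.2, 0.13, 0.3))
  # second-order reaction: doubling the reactant quadruples the rate
  expect_equal(mass_action_rates(sys, c(2, 1, 1, 1, 1))[1], 0.1 * 2^2)
  # a required reactant at zero shuts the reaction off
  r <- mass_action_rates(sys, c(0, 1, 1, 1, 1))
  expect_identical(r[1], 0); expect_identical(r[2], 0)
  expect_gt(r[3], 0)
  # rates are linear in the rate constants
  sys2 <- sys; sys2$rate_constants <- 2 * sys$rate_constants
  y <- runif(5, 0, 2)
  expect_equal(mass_action_rates(sys2, y), 2 * mass_action_rates(sys, y))
})

test_that("rate positivity holds over random states and systems", {
  set.seed(101)
  for (i in 1:50) {
    sys <- random_system()
    y <- runif(3, 0, 3) * rbinom(3, 1, 0.8)  # include exact zeros
    expect_true(all(mass_action_rates(sys, y) >= 0))
  }
})

test_that("the mass-action RHS is the stoichiometry-weighted rate sum", {
  sys <- case1_system()
  expect_equal(mass_action_rhs(sys, rep(1, 5)),
               c(-0.40, -0.20, 0.07, -0.17, 0.30))
  # [1,2,1,1,3] is a conserved moiety: every reaction column is orthogonal
  S <- net_stoichiometry(sys)
  expect_equal(as.numeric(case1_moiety %*% S), rep(0, 4))
  set.seed(7)
  for (i in 1:20) {
    y <- runif(5, 0, 2)
    expect_equal(sum(mass_action_rhs(sys, y) * case1_moiety), 0,
                 tolerance = 1e-12)
  }
})

test_that("invalid states and systems are rejected", {
  sys <- case1_system()
  expect_error(mass_action_rates(sys, rep(1, 4)), "dimension")
  expect_error(mass_action_rates(sys, c(-0.1, 1, 1, 1, 1)), "negative")
  expect_error(reaction_system("A", matrix(1), matrix(0), -1), "positive")
  expect_error(reaction_system("A", matrix(0), matrix(1), 1),
               "at least one reactant")
  expect_error(reaction_system(c("A", "B"), matrix(c(-1, 1), 1, 2),
                               matrix(0, 1, 2), 1), "nonnegative")
})

test_that("the benchmark systems transcribe the printed networks", {
  c1 <- case1_system()
  expect_equal(c1$rate_constants, c(0.1, 0.2, 0.13, 0.3))
  expect_equal(unname(net_stoichiometry(c1)[, 1]), c(-2, 1, 0, 0, 0))
  expect_equal(c1$species_names, c("A", "B", "C", "D", "E"))
  c2 <- case2_system()
  expect_equal(c2$rate_constants, c(10, 2.014, 5.5, 11.74, 0.4, 20))
  expect_equal(length(c2$species_names), 7)
  expect_equal(nrow(c2$nu_reactant), 6)
  # dimerizations consume two molecules
  expect_equal(unname(c2$nu_reactant[1, "EGF_EGFR"]), 2)
  expect_equal(unname(c2$nu_reactant[6, "pSTAT3"]), 2)
})

test_that("simulation conserves moieties and is grid-independent", {
  sys <- case1_system()
  times <- seq(0, 40, length.out = 100)
  tr <- simulate_system(sys, c(0.5, 0.5, 0, 0, 0), times)
  m <- tr$concentrations %*% case1_moiety
  expect_lt(max(abs(m - m[1])) / m[1], 1e-5)
  # E is only ever produced
  expect_true(all(diff(tr$concentrations[, "E"]) >= -1e-9))
  # halving the output spacing does not change shared points
  times2 <- seq(0, 40, length.out = 199)
  tr2 <- simulate_system(sys, c(0.5, 0.5, 0, 0, 0), times2)
  shared <- tr2$concentrations[seq(1, 199, by = 2), ]
  expect_lt(max(abs(shared - tr$concentrations)), 1e-5)
})

test_that("degenerate grids and failures behave as specified", {
  sys <- toy_system()
  tr <- simulate_system(sys, c(1, 0), 0)
  expect_equal(nrow(tr$concentrations), 1L)
  expect_equal(unname(tr$concentrations[1, ]), c(1, 0))
  expect_error(simulate_system(sys, c(1, 0), c(0, 0.5, 0.5)),
               "strictly increasing")
})

test_that("reaction systems round-trip through JSON", {
  for (sys in list(case1_system(), case2_system(), toy_system())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_system_json(sys, path)
    back <- read_system_json(path)
    expect_equal(back$species_names, sys$species_names)
    expect_equal(unname(back$nu_reactant), unname(sys$nu_reactant))
    expect_equal(unname(back$nu_product), unname(sys$nu_product))
    expect_equal(back$rate_constants, sys$rate_constants)
  }
})

test_that("trajectories round-trip through CSV", {
  tr <- simulate_system(case1_system(), c(1, 0.6, 0, 0, 0),
                        seq(0, 10, length.out = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$concentrations, tr$concentrations, tolerance = 1e-12)
  expect_equal(colnames(back$concentrations), case1_system()$species_names)
})
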