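# Shared fixtures: all built in code at test time.

# one-reaction toy system A -> B
toy_system <- function(k = 0.4) {
  reaction_system(c("A", "B"),
                  nu_reactant = matrix(c(1, 0), 1, 2),
                  nu_product = matrix(c(0, 1), 1, 2),
                  rate_constants = k, name = "toy")
}

# tiny corpus for the toy system
toy_collection <- function(n = 6L, noise = 0, seed = 1L, n_points = 25L,
                           t_end = 8) {
  sys <- toy_system()
  times <- seq(0, t_end, length.out = n_points)
  bcrnn:::generate_collection(
    sys, function() c(stats::runif(1, 0.4, 1.2), 0), n, noise, seed, times)
}

# random small mass-action system (for property tests)
random_system <- function(n_species = 3L, n_reactions = 3L) {
  repeat {
    nu_r <- matrix(stats::rbinom(n_reactions * n_species, 2, 0.3),
                   n_reactions, n_species)
    if (all(rowSums(nu_r) > 0)) break
  }
  nu_p <- matrix(stats::rbinom(n_reactions * n_species, 2, 0.3),
                 n_reactions, n_species)
  reaction_system(paste0("S", seq_len(n_species)), nu_r, nu_p,
                  stats::runif(n_reactions, 0.05, 2))
}

# conserved moiety of the five-species benchmark network
case1_moiety <- c(1, 2, 1, 1, 3)

# fast training control for functional tests
quick_control <- function(...) {
  defaults <- list(max_epochs = 150L, min_burn_in = 40L,
                   detect_window = 10L, detect_patience = 10L,
                   n_posterior = 30L, patience_stop = 50L)
  args <- utils::modifyList(defaults, list(...))
  do.call(crnn_control, args)
}
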