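#' CRNN parameter triplet
#'
#' The learnable parameters of a chemical reaction neural network. Each
#' hidden node is one candidate reaction: its input-layer weights are the
#' reaction orders of every species (nonnegative after constraint
#' projection), its bias is the rate constant on the log scale, and its
#' output-layer weights are the net stoichiometric coefficients (negative
#' for consumed species).
#'
#' @param order_weights hidden-reactions x species matrix of candidate
#'   reaction orders.
#' @param ln_rate_bias numeric vector of per-reaction log rate constants.
#' @param stoich_weights species x hidden-reactions matrix of net
#'   stoichiometric coefficients.
#' @param floor positivity floor used when taking log-concentrations.
#' @param species optional species labels.
#' @return an object of class `crnn_parameters`.
#' @export
crnn_parameters <- function(order_weights, ln_rate_bias, stoich_weights,
                            floor = 1e-8, species = NULL) {
  order_weights <- as.matrix(order_weights)
  stoich_weights <- as.matrix(stoich_weights)
  ln_rate_bias <- as.numeric(ln_rate_bias)
  m <- nrow(order_weights); s <- ncol(order_weights)
  if (length(ln_rate_bias) != m)
    stop("ln_rate_bias must have one entry per hidden reaction")
  if (nrow(stoich_weights) != s || ncol(stoich_weights) != m)
    stop("stoich_weights must be species x hidden-reactions")
  if (!all(is.finite(order_weights)) || !all(is.finite(ln_rate_bias)) ||
      !all(is.finite(stoich_weights)))
    stop("CRNN parameters must be finite")
  structure(
    list(order_weights = order_weights, ln_rate_bias = ln_rate_bias,
         stoich_weights = stoich_weights, floor = floor, species = species),
    class = "crnn_parameters")
}

#' @export
print.crnn_parameters <- function(x, digits = 3, ...) {
  cat(sprintf("crnn_parameters: %d hidden reactions x %d species\n",
              nrow(x$order_weights), ncol(x$order_weights)))
  cat("  implied rate constants:",
      paste(signif(exp(x$ln_rate_bias), digits), collapse = ", "), "\n")
  invisible(x)
}

n_hidden <- function(params) nrow(params$order_weights)

# flatten / unflatten: ordering is (order_weights, ln_rate_bias,
# stoich_weights), column-major within each block
flatten_params <- function(params) {
  c(as.numeric(params$order_weights), params$ln_rate_bias,
    as.numeric(params$stoich_weights))
}

unflatten_params <- function(theta, template) {
  m <- nrow(template$order_weights); s <- ncol(template$order_weights)
  stopifnot(length(theta) == m * s + m + s * m)
  W <- matrix(theta[seq_len(m * s)], m, s)
  b <- theta[m * s + seq_len(m)]
  V <- matrix(theta[m * s + m + seq_len(s * m)], s, m)
  crnn_parameters(W, b, V, floor = template$floor, species = template$species)
}

#' Transcribe a ground-truth reaction system into CRNN parameters
#'
#' Exact transcription: order weights are the reactant orders, biases the
#' log rate constants, stoichiometric output weights the net
#' stoichiometry. A CRNN with these parameters reproduces the mass-action
#' kinetics exactly (above the positivity floor).
#'
#' @param system a [reaction_system()].
#' @param floor positivity floor for log-concentrations.
#' @return a [crnn_parameters()].
#' @export
crnn_from_system <- function(system, floor = 1e-8) {
  crnn_parameters(order_weights = system$nu_reactant,
                  ln_rate_bias = log(system$rate_constants),
                  stoich_weights = net_stoichiometry(system),
                  floor = floor, species = system$species_names)
}

#' Recover a reaction system from CRNN parameters
#'
#' Inverse of [crnn_from_system()]: reads each hidden node as one
#' reaction, with reactant orders from the (projected) order weights and
#' products from the positive part of `stoich_weights + order_weights`
#' (net stoichiometry plus consumption gives production). Weights below
#' `threshold` are zeroed.
#'
#' @param params a [crnn_parameters()].
#' @param species species labels (defaults to those stored on `params`).
#' @param threshold presence cut on absolute weights.
#' @return a [reaction_system()].
#' @export
system_from_crnn <- function(params, species = NULL, threshold = 1e-4) {
  params <- project_constraints(params)
  if (is.null(species)) species <- params$species
  if (is.null(species))
    species <- paste0("S", seq_len(ncol(params$order_weights)))
  nu_r <- params$order_weights
  nu_r[nu_r < threshold] <- 0
  nu_p <- t(params$stoich_weights) + nu_r   # net + consumed = produced
  nu_p[abs(nu_p) < threshold] <- 0
  nu_p[nu_p < 0] <- 0
  reaction_system(species, nu_r, nu_p, exp(params$ln_rate_bias))
}

#' Candidate reaction rates of a CRNN
#'
#' Each hidden node evaluates the mass-action power law on the log scale:
#' `r_j = exp(b_j + sum_i W[j,i] * ln(max(C_i, floor)))`. Concentrations
#' are clamped at the positivity floor inside this function only; the
#' data are never modified. Rates are strictly positive by construction.
#'
#' @param params a [crnn_parameters()].
#' @param concentrations numeric vector of species concentrations.
#' @return numeric vector of per-hidden-reaction rates.
#' @export
crnn_rates <- function(params, concentrations) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != ncol(params$order_weights))
    stop("state dimension does not match CRNN species count")
  l <- log(pmax(concentrations, params$floor))
  as.numeric(exp(params$ln_rate_bias + params$order_weights %*% l))
}

#' CRNN right-hand side
#'
#' `dY/dt = stoich_weights %*% crnn_rates(params, Y)`.
#' @inheritParams crnn_rates
#' @return numeric vector of per-species derivatives.
#' @export
crnn_rhs <- function(params, concentrations) {
  as.numeric(params$stoich_weights %*% crnn_rates(params, concentrations))
}

#' Integrate the learned kinetics on a time grid
#'
#' Fixed-step RK4 integration of the CRNN ODE (the same discretization
#' the training gradients are computed through). Divergent integrations
#' under pathological parameters are reported, not raised, so that the
#' sampler can recover.
#'
#' @param params a [crnn_parameters()].
#' @param y0 nonnegative initial concentrations.
#' @param times strictly increasing grid.
#' @param substeps RK4 substeps per grid interval (default 1 for the slow
#'   benchmark grids; use more for stiff systems).
#' @return a [trajectory_dataset()] with attributes `diverged` and
#'   `last_time`.
#' @export
integrate_crnn <- function(params, y0, times, substeps = 1L) {
  y0 <- as.numeric(y0)
  times <- as.numeric(times)
  if (any(y0 < 0)) stop("y0 must be nonnegative")
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  if (length(times) == 1L) {
    traj <- trajectory_dataset(times, matrix(y0, 1L), y0 = y0)
    attr(traj, "diverged") <- FALSE
    attr(traj, "last_time") <- times[1L]
    return(traj)
  }
  out <- .crnn_integrate_cpp(params$order_weights, params$ln_rate_bias,
                             params$stoich_weights, y0, times,
                             as.integer(substeps), params$floor)
  conc <- out$trajectory
  if (!is.null(params$species)) colnames(conc) <- params$species
  traj <- trajectory_dataset(times, conc, y0 = y0)
  attr(traj, "diverged") <- out$diverged
  attr(traj, "last_time") <- out$last_time
  traj
}

#' Project CRNN parameters onto the feasible set
#'
#' Reaction orders are physically nonnegative; projection clips negative
#' order weights at zero and leaves the other fields untouched. Idempotent.
#'
#' @param params a [crnn_parameters()].
#' @return the projected [crnn_parameters()].
#' @export
project_constraints <- function(params) {
  params$order_weights[params$order_weights < 0] <- 0
  params
}

#' Random initialization of CRNN parameters
#'
#' Stoichiometric output weights are Xavier-initialized (signed normal,
#' sd `sqrt(2/(n_hidden + n_species))`). Order weights are drawn from
#' the positive half of a narrower normal (sd 0.1): species that start
#' at zero concentration enter the rate law as `ln(floor)` (about -18),
#' so large initial orders would place every candidate reaction in a
#' dead, gradient-free region of parameter space. Biases start at
#' `ln(1/t_span)`, i.e. initial rate constants of the order of the
#' inverse data horizon, so that initial trajectories neither blow up
#' nor crash to the positivity floor.
#'
#' @param n_hidden number of hidden reaction nodes.
#' @param n_species number of species.
#' @param t_span data time horizon setting the initial rate scale
#'   (default 1: biases start at 0).
#' @param floor positivity floor.
#' @param species optional labels.
#' @return a [crnn_parameters()].
#' @export
init_crnn <- function(n_hidden, n_species, t_span = 1, floor = 1e-8,
                      species = NULL) {
  sd <- sqrt(2 / (n_hidden + n_species))
  W <- abs(matrix(stats::rnorm(n_hidden * n_species, 0, 0.1),
                  n_hidden, n_species))
  V <- matrix(stats::rnorm(n_species * n_hidden, 0, sd), n_species, n_hidden)
  crnn_parameters(W, rep(log(1 / t_span), n_hidden), V, floor = floor,
                  species = species)
}

#' Serialize CRNN parameters to JSON
#' @param params a [crnn_parameters()].
#' @param path optional output path.
#' @return the JSON string, or `path` invisibly.
#' @export
write_crnn_json <- function(params, path = NULL) {
  doc <- list(n_species = ncol(params$order_weights),
              n_hidden = nrow(params$order_weights),
              floor = params$floor,
              species = params$species,
              order_weights = params$order_weights,
              ln_rate_bias = params$ln_rate_bias,
              stoich_weights = params$stoich_weights)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read CRNN parameters from JSON
#' @param path file path or JSON string from [write_crnn_json()].
#' @return a [crnn_parameters()].
#' @export
read_crnn_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  crnn_parameters(matrix(doc$order_weights, doc$n_hidden, doc$n_species),
                  doc$ln_rate_bias,
                  matrix(doc$stoich_weights, doc$n_species, doc$n_hidden),
                  floor = doc$floor,
                  species = if (is.null(doc$species)) NULL
                            else as.character(doc$species))
}
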