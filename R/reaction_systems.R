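#' Construct a mass-action reaction system
#'
#' A `reaction_system` holds a ground-truth chemical reaction network under
#' mass-action kinetics: the species labels, the reactant order matrix
#' (reactions x species, the exponents of the rate law), the product
#' coefficient matrix, and the per-reaction rate constants. The net
#' stoichiometry is always derived as `nu_product - nu_reactant`, never
#' stored separately.
#'
#' @param species character vector of species labels.
#' @param nu_reactant reactions x species matrix of nonnegative reaction
#'   orders (reactant stoichiometry).
#' @param nu_product reactions x species matrix of nonnegative product
#'   coefficients.
#' @param rate_constants positive numeric vector, one rate constant per
#'   reaction. Units must be consistent with the reaction order (e.g. 1/s
#'   for first order, 1/(uM s) for second order); they are carried as
#'   metadata only.
#' @param name optional label for the system.
#' @param units optional list with `concentration` and `time` labels.
#'
#' @return An object of class `reaction_system`.
#' @seealso [case1_system()], [case2_system()], [mass_action_rates()],
#'   [simulate_system()]
#' @export
reaction_system <- function(species, nu_reactant, nu_product, rate_constants,
                            name = NULL, units = NULL) {
  species <- as.character(species)
  nu_reactant <- as.matrix(nu_reactant)
  nu_product <- as.matrix(nu_product)
  rate_constants <- as.numeric(rate_constants)
  n_s <- length(species)
  n_r <- length(rate_constants)
  if (!all(is.finite(nu_reactant)) || !all(is.finite(nu_product)))
    stop("stoichiometric matrices must be finite")
  if (any(nu_reactant < 0) || any(nu_product < 0))
    stop("nu_reactant and nu_product must be nonnegative")
  if (!all(dim(nu_reactant) == c(n_r, n_s)) ||
      !all(dim(nu_product) == c(n_r, n_s)))
    stop("stoichiometric matrices must be reactions x species (",
         n_r, " x ", n_s, ")")
  if (any(!is.finite(rate_constants)) || any(rate_constants <= 0))
    stop("all rate_constants must be positive and finite")
  if (any(rowSums(nu_reactant) == 0))
    stop("every reaction needs at least one reactant (a nonzero row of nu_reactant)")
  dimnames(nu_reactant) <- list(NULL, species)
  dimnames(nu_product) <- list(NULL, species)
  structure(
    list(species_names = species,
         nu_reactant = nu_reactant,
         nu_product = nu_product,
         rate_constants = rate_constants,
         name = name,
         units = units),
    class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("Mass-action reaction system",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  species:  ", paste(x$species_names, collapse = ", "), "\n")
  for (j in seq_along(x$rate_constants)) {
    lhs <- format_side(x$nu_reactant[j, ], x$species_names)
    rhs <- format_side(x$nu_product[j, ], x$species_names)
    cat(sprintf("  R%d: %s -> %s   k = %g\n", j, lhs, rhs,
                x$rate_constants[j]))
  }
  invisible(x)
}

format_side <- function(coefs, species) {
  nz <- which(coefs != 0)
  if (!length(nz)) return("0")
  paste(ifelse(coefs[nz] == 1, species[nz],
               paste0(coefs[nz], " ", species[nz])), collapse = " + ")
}

n_species <- function(system) length(system$species_names)
n_reactions <- function(system) length(system$rate_constants)

#' Net stoichiometry of a reaction system
#'
#' @param system a [reaction_system()].
#' @return species x reactions matrix of net stoichiometric coefficients
#'   (`nu_product - nu_reactant`, transposed); negative entries denote
#'   consumption.
#' @export
net_stoichiometry <- function(system) {
  t(system$nu_product - system$nu_reactant)
}

check_state <- function(system, concentrations) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != n_species(system))
    stop("state dimension (", length(concentrations),
         ") does not match species count (", n_species(system), ")")
  if (any(!is.finite(concentrations)))
    stop("concentrations must be finite")
  if (any(concentrations < 0))
    stop("negative concentrations rejected")
  concentrations
}

#' Mass-action reaction rates
#'
#' Evaluates the law of mass action for every reaction of the system:
#' `rate_j = k_j * prod_i C_i ^ nu_reactant[j, i]`. A rate is exactly zero
#' iff some reactant with positive order has zero concentration.
#'
#' @param system a [reaction_system()].
#' @param concentrations nonnegative numeric vector, one entry per species.
#' @return numeric vector of per-reaction rates (all `>= 0`).
#' @export
mass_action_rates <- function(system, concentrations) {
  conc <- check_state(system, concentrations)
  nu <- system$nu_reactant
  # 0^0 = 1 by R convention, which is the correct mass-action limit here
  rates <- system$rate_constants *
    apply(nu, 1L, function(order) prod(conc^order))
  as.numeric(rates)
}

#' Mass-action right-hand side
#'
#' Time derivative of every species under the system's kinetics:
#' `dY_i/dt = sum_j (nu_product[j,i] - nu_reactant[j,i]) * rate_j`.
#'
#' @inheritParams mass_action_rates
#' @return numeric vector of per-species derivatives.
#' @export
mass_action_rhs <- function(system, concentrations) {
  rates <- mass_action_rates(system, concentrations)
  as.numeric(net_stoichiometry(system) %*% rates)
}

#' Simulate a reaction system on a time grid
#'
#' Integrates the exact mass-action ODE with an adaptive solver
#' (`deSolve::ode`, lsoda) and returns a [trajectory_dataset()]. Solver
#' tolerances default to rtol 1e-6 / atol 1e-8, tight enough that the
#' conserved moieties of the benchmark systems drift by less than 1e-5
#' relative over the default horizons.
#'
#' @param system a [reaction_system()].
#' @param y0 nonnegative initial concentrations (one per species).
#' @param times strictly increasing time grid; the first entry is the
#'   initial time.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return a [trajectory_dataset()] with the clean (noise-free) trajectory.
#' @export
simulate_system <- function(system, y0, times, rtol = 1e-6, atol = 1e-8) {
  y0 <- check_state(system, y0)
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  if (length(times) == 1L) {
    conc <- matrix(y0, nrow = 1L, dimnames = list(NULL, system$species_names))
    return(trajectory_dataset(times, conc, y0 = y0))
  }
  S <- net_stoichiometry(system)
  nu <- system$nu_reactant
  k <- system$rate_constants
  rhs <- function(t, y, parms) {
    yc <- pmax(y, 0)
    rates <- k * apply(nu, 1L, function(order) prod(yc^order))
    list(as.numeric(S %*% rates))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    last_t <- sol[nrow(sol), 1L]
    stop("integration failure: solver stopped at t = ", last_t)
  }
  conc <- unname(sol[, -1L, drop = FALSE])
  if (any(!is.finite(conc)))
    stop("integration failure: non-finite concentrations")
  if (any(conc < -10 * max(atol, rtol)))
    warning("simulated concentrations dip below -tolerance")
  colnames(conc) <- system$species_names
  trajectory_dataset(times, conc, y0 = y0)
}

#' The five-species benchmark network
#'
#' Four irreversible reactions among species A..E:
#' `2A -> B` (k = 0.1), `A -> C` (k = 0.2), `C -> D` (k = 0.13),
#' `B + D -> E` (k = 0.3). The linear combination `[1, 2, 1, 1, 3] . Y`
#' is conserved by all four reactions, which the test-suite uses as an
#' exact simulator oracle.
#'
#' @return a [reaction_system()].
#' @export
case1_system <- function() {
  species <- c("A", "B", "C", "D", "E")
  #            A  B  C  D  E
  nu_r <- rbind(c(2, 0, 0, 0, 0),   # 2A -> B
                c(1, 0, 0, 0, 0),   # A -> C
                c(0, 0, 1, 0, 0),   # C -> D
                c(0, 1, 0, 1, 0))   # B + D -> E
  nu_p <- rbind(c(0, 1, 0, 0, 0),
                c(0, 0, 1, 0, 0),
                c(0, 0, 0, 1, 0),
                c(0, 0, 0, 0, 1))
  reaction_system(species, nu_r, nu_p, c(0.1, 0.2, 0.13, 0.3),
                  name = "case1")
}

#' The simplified EGFR-STAT3 signalling network
#'
#' Seven species and six irreversible reactions of a reduced EGFR-STAT3
#' pathway: receptor dimerization, phosphorylation, STAT3 binding and
#' release, STAT3 phosphorylation, and pSTAT3 homodimerization. Reverse
#' reactions are omitted (they are not identifiable from the forward set
#' in this framework). Rates are in 1/s or 1/(uM s) depending on the
#' reaction order; units are metadata only.
#'
#' @return a [reaction_system()].
#' @export
case2_system <- function() {
  species <- c("EGF_EGFR", "EGF_EGFR2", "pEGF_EGFR2", "STAT3",
               "pEGF_EGFR2_STAT3", "pSTAT3", "pSTAT3_pSTAT3")
  n <- length(species)
  nu_r <- matrix(0, 6, n, dimnames = list(NULL, species))
  nu_p <- matrix(0, 6, n, dimnames = list(NULL, species))
  # 1: EGF-EGFR + EGF-EGFR -> EGF-EGFR2
  nu_r[1, "EGF_EGFR"] <- 2; nu_p[1, "EGF_EGFR2"] <- 1
  # 2: EGF-EGFR2 -> pEGF-EGFR2
  nu_r[2, "EGF_EGFR2"] <- 1; nu_p[2, "pEGF_EGFR2"] <- 1
  # 3: pEGF-EGFR2 + STAT3 -> pEGF-EGFR2-STAT3
  nu_r[3, "pEGF_EGFR2"] <- 1; nu_r[3, "STAT3"] <- 1
  nu_p[3, "pEGF_EGFR2_STAT3"] <- 1
  # 4: pEGF-EGFR2-STAT3 -> pEGF-EGFR2 + STAT3
  nu_r[4, "pEGF_EGFR2_STAT3"] <- 1
  nu_p[4, "pEGF_EGFR2"] <- 1; nu_p[4, "STAT3"] <- 1
  # 5: pEGF-EGFR2-STAT3 -> pEGF-EGFR2 + pSTAT3
  nu_r[5, "pEGF_EGFR2_STAT3"] <- 1
  nu_p[5, "pEGF_EGFR2"] <- 1; nu_p[5, "pSTAT3"] <- 1
  # 6: pSTAT3 + pSTAT3 -> pSTAT3-pSTAT3
  nu_r[6, "pSTAT3"] <- 2; nu_p[6, "pSTAT3_pSTAT3"] <- 1
  reaction_system(species, nu_r, nu_p,
                  c(10, 2.014, 5.5, 11.74, 0.4, 20),
                  name = "case2",
                  units = list(concentration = "uM", time = "s"))
}

#' Default simulation time grid for a benchmark system
#'
#' 100 uniform points on `[0, 40]` s for the five-species benchmark
#' (consistent with the 0-30 training / 30-40 extrapolation split used in
#' the baseline comparisons) and on `[0, 10]` s for the fast EGFR-STAT3
#' network.
#'
#' @param case `"case1"` or `"case2"`.
#' @param n_points number of grid points.
#' @return numeric time grid.
#' @export
default_time_grid <- function(case = c("case1", "case2"), n_points = 100L) {
  case <- match.arg(case)
  t_end <- if (case == "case1") 40 else 10
  seq(0, t_end, length.out = n_points)
}

#' Serialize a reaction system to JSON
#'
#' @param system a [reaction_system()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_system_json <- function(system, path = NULL) {
  doc <- list(
    name = system$name,
    species = system$species_names,
    units = system$units,
    reactions = lapply(seq_along(system$rate_constants), function(j) {
      list(reactants = as.list(system$nu_reactant[j, system$nu_reactant[j, ] != 0]),
           products = as.list(system$nu_product[j, system$nu_product[j, ] != 0]),
           rate = system$rate_constants[j])
    }))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read a reaction system from JSON
#'
#' @param path file path or JSON string produced by [write_system_json()].
#' @return a [reaction_system()].
#' @export
read_system_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  species <- as.character(unlist(doc$species))
  n_r <- length(doc$reactions)
  nu_r <- matrix(0, n_r, length(species), dimnames = list(NULL, species))
  nu_p <- matrix(0, n_r, length(species), dimnames = list(NULL, species))
  rates <- numeric(n_r)
  for (j in seq_len(n_r)) {
    rx <- doc$reactions[[j]]
    for (s in names(rx$reactants)) nu_r[j, s] <- as.numeric(rx$reactants[[s]])
    for (s in names(rx$products)) nu_p[j, s] <- as.numeric(rx$products[[s]])
    rates[j] <- as.numeric(rx$rate)
  }
  reaction_system(species, nu_r, nu_p, rates, name = doc$name,
                  units = doc$units)
}
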