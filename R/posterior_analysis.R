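#' Build a posterior ensemble from explicit parameter draws
#'
#' Wraps a list of [crnn_parameters()] (or a draws x parameters matrix in
#' flattened order) as a minimal fit object so that every posterior
#' analysis -- recovery probabilities, scores, rate posteriors,
#' matching, predictive fans -- can run on hand-constructed or externally
#' produced ensembles.
#'
#' @param draws list of [crnn_parameters()], or a numeric matrix with one
#'   flattened draw per row (then `template` is required).
#' @param template a [crnn_parameters()] giving the shapes.
#' @param control a [crnn_control()] (solver settings for predictive
#'   integration).
#' @return an object of class `bcrnn`.
#' @export
crnn_ensemble <- function(draws, template = NULL,
                          control = crnn_control()) {
  if (is.list(draws) && !is.matrix(draws)) {
    stopifnot(length(draws) >= 1L)
    template <- draws[[1L]]
    S <- do.call(rbind, lapply(draws, flatten_params))
  } else {
    if (is.null(template)) stop("template required for matrix draws")
    S <- as.matrix(draws)
  }
  structure(list(
    samples = S,
    sample_epochs = seq_len(nrow(S)),
    template = template,
    posterior_mean = if (nrow(S)) unflatten_params(colMeans(S), template)
                     else template,
    loss_trace = data.frame(epoch = integer(), train_loss = numeric(),
                            val_loss = numeric(), step_size = numeric()),
    sampling_start_epoch = NA_integer_,
    n_collected = nrow(S), shortfall = FALSE,
    control = control,
    n_hidden = nrow(template$order_weights),
    species = template$species,
    system = NULL),
    class = "bcrnn")
}

#' Reactant recovery probability
#'
#' For every species i and hidden reaction j, the fraction of posterior
#' samples in which the (projected) order weight exceeds the presence
#' threshold: a species counts as a reactant of a reaction in a sample
#' when its learned order is above `threshold`.
#'
#' @param fit a [bcrnn()] fit (or anything accepted by
#'   [posterior_samples()]).
#' @param threshold presence cut on the order weights (default 1e-4).
#' @return species x reactions matrix of probabilities in `[0, 1]`.
#' @export
recovery_probability <- function(fit, threshold = 1e-4) {
  stopifnot(threshold > 0)
  S <- posterior_samples(fit)
  if (!nrow(S)) stop("empty posterior ensemble")
  template <- attr(S, "template")
  m <- nrow(template$order_weights); s <- ncol(template$order_weights)
  iW <- seq_len(m * s)
  counts <- colMeans(S[, iW, drop = FALSE] > threshold)
  p <- t(matrix(counts, m, s))            # species x reactions
  dimnames(p) <- list(template$species, paste0("R", seq_len(m)))
  p
}

#' Score metric for reactant identification
#'
#' Recovery probability reweighted by relative weight magnitude:
#' `score_ij = p_ij * sum_w_ij / max_i(sum_w_ij)` where `sum_w_ij` is the
#' sum over posterior samples of the (nonnegative, projected) order
#' weight of species i in reaction j, and the maximum runs over species
#' within the reaction. A reaction whose weights are all zero across the
#' ensemble (a dead hidden node) gets a zero score column.
#'
#' @inheritParams recovery_probability
#' @return species x reactions matrix of scores; `0 <= score_ij <= p_ij`.
#' @export
score_metric <- function(fit, threshold = 1e-4) {
  S <- posterior_samples(fit)
  if (!nrow(S)) stop("empty posterior ensemble")
  template <- attr(S, "template")
  m <- nrow(template$order_weights); s <- ncol(template$order_weights)
  iW <- seq_len(m * s)
  W <- pmax(S[, iW, drop = FALSE], 0)
  sums <- t(matrix(colSums(W), m, s))     # species x reactions
  p <- recovery_probability(fit, threshold)
  colmax <- apply(sums, 2L, max)
  score <- p * sweep(sums, 2L, ifelse(colmax > 0, colmax, 1), "/")
  score[, colmax == 0] <- 0
  dimnames(score) <- dimnames(p)
  score
}

#' Posterior rate-constant samples and summaries
#'
#' The rate constant of each hidden reaction is `exp(ln_rate_bias)` per
#' posterior draw.
#'
#' @param fit a [bcrnn()] fit.
#' @return list with `samples` (draws x reactions matrix) and `summary`
#'   (data frame: mean, sd, central 95% interval per reaction).
#' @export
rate_posteriors <- function(fit) {
  S <- posterior_samples(fit)
  if (!nrow(S)) stop("empty posterior ensemble")
  template <- attr(S, "template")
  m <- nrow(template$order_weights); s <- ncol(template$order_weights)
  ib <- m * s + seq_len(m)
  k <- exp(S[, ib, drop = FALSE])
  colnames(k) <- paste0("R", seq_len(m))
  qs <- apply(k, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  list(samples = k,
       summary = data.frame(reaction = colnames(k),
                            mean = colMeans(k),
                            sd = apply(k, 2L, stats::sd),
                            q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                            row.names = NULL))
}

# L1 distance between one learned hidden reaction (posterior-mean,
# thresholded) and one true reaction: orders + net stoichiometry
match_cost_matrix <- function(fit, truth, threshold) {
  mean_params <- project_constraints(coef(fit))
  W <- mean_params$order_weights          # hidden x species
  V <- mean_params$stoich_weights         # species x hidden
  W[W < threshold] <- 0
  V[abs(V) < threshold] <- 0
  net <- net_stoichiometry(truth)         # species x true reactions
  nh <- nrow(W); nt <- nrow(truth$nu_reactant)
  cost <- matrix(0, nt, nh)
  for (r in seq_len(nt))
    for (j in seq_len(nh))
      cost[r, j] <- sum(abs(W[j, ] - truth$nu_reactant[r, ])) +
        sum(abs(V[, j] - net[, r]))
  cost
}

all_injections <- function(nt, nh) {
  # all injective maps truth -> hidden (nh >= nt)
  if (nt == 0L) return(list(integer()))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == nt) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (j in remaining) rec(c(chosen, j), setdiff(remaining, j))
  }
  rec(integer(), seq_len(nh))
  out
}

#' Match learned hidden reactions to ground-truth reactions
#'
#' Exhaustive assignment (feasible for <= 8 reactions) minimizing the L1
#' distance between thresholded posterior-mean parameters (orders plus
#' net stoichiometry) and the true reactions. Ties are broken towards
#' the identity-like assignment (lexicographically smallest); an exact
#' tie between assignments that pair rates differently is flagged.
#'
#' @param fit a [bcrnn()] fit with at least as many hidden reactions as
#'   `truth` has reactions.
#' @param truth a [reaction_system()].
#' @param threshold presence cut applied to mean parameters.
#' @return integer vector `perm` with `perm[r]` = hidden reaction index
#'   assigned to true reaction r; attributes `cost` (total) and
#'   `ambiguous` (logical).
#' @export
match_reactions <- function(fit, truth, threshold = 1e-4) {
  cost <- match_cost_matrix(fit, truth, threshold)
  nt <- nrow(cost); nh <- ncol(cost)
  if (nh < nt) stop("fewer hidden reactions than true reactions")
  inj <- all_injections(nt, nh)
  totals <- vapply(inj, function(p) sum(cost[cbind(seq_len(nt), p)]),
                   numeric(1))
  best <- which(totals <= min(totals) + 1e-12)
  perm <- inj[[best[1L]]]
  structure(perm, cost = totals[best[1L]],
            ambiguous = length(best) > 1L)
}

#' Percent deviation of posterior rates from the truth
#'
#' After matching hidden reactions to the true ones, computes
#' `|k_sample - k_true| / k_true * 100` for every posterior sample and
#' reports its mean and sd per true reaction (deviations are averaged
#' over samples, not taken at the posterior-mean rate).
#'
#' @param fit a [bcrnn()] fit.
#' @param truth a [reaction_system()].
#' @param matching optional result of [match_reactions()].
#' @param threshold passed to [match_reactions()].
#' @return data frame with one row per true reaction: `k_true`,
#'   `mean_pct`, `sd_pct`, and the matched hidden reaction index.
#' @export
percent_deviation <- function(fit, truth, matching = NULL,
                              threshold = 1e-4) {
  if (is.null(matching)) matching <- match_reactions(fit, truth, threshold)
  rp <- rate_posteriors(fit)
  k_true <- truth$rate_constants
  res <- lapply(seq_along(k_true), function(r) {
    j <- matching[r]
    dev <- abs(rp$samples[, j] - k_true[r]) / k_true[r] * 100
    c(mean_pct = mean(dev), sd_pct = stats::sd(dev))
  })
  res <- do.call(rbind, res)
  data.frame(reaction = seq_along(k_true), hidden = as.integer(matching),
             k_true = k_true, mean_pct = res[, "mean_pct"],
             sd_pct = res[, "sd_pct"], row.names = NULL)
}

#' Posterior-predictive trajectory fan
#'
#' Integrates the CRNN for `n_draws` posterior samples (uniformly
#' thinned from the ensemble) from a common initial condition and
#' returns the stacked trajectories with the pointwise median and
#' central 95% band. Draws whose integration diverges are dropped and
#' counted.
#'
#' @param fit a [bcrnn()] fit.
#' @param y0 initial condition.
#' @param times time grid.
#' @param n_draws number of posterior draws (default 500, capped at the
#'   ensemble size).
#' @return list of class `crnn_fan`: `times`, `draws` (array draws x
#'   time x species), `median`, `lower`, `upper` (time x species
#'   matrices), `n_failed`.
#' @export
posterior_predictive <- function(fit, y0, times, n_draws = 500L) {
  S <- posterior_samples(fit)
  if (!nrow(S)) stop("empty posterior ensemble")
  if (n_draws > nrow(S))
    stop("n_draws exceeds ensemble size (", nrow(S), ")")
  pick <- unique(round(seq(1L, nrow(S), length.out = n_draws)))
  trajs <- list(); failed <- 0L
  for (i in pick) {
    p <- sample_params(fit, i)
    tr <- integrate_crnn(p, y0, times, substeps = fit$control$substeps)
    if (isTRUE(attr(tr, "diverged"))) failed <- failed + 1L
    else trajs[[length(trajs) + 1L]] <- tr$concentrations
  }
  if (!length(trajs)) stop("all posterior draws diverged")
  arr <- array(unlist(trajs),
               dim = c(length(times), ncol(trajs[[1L]]), length(trajs)))
  med <- apply(arr, c(1, 2), stats::median)
  lo <- apply(arr, c(1, 2), stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(arr, c(1, 2), stats::quantile, probs = 0.975, names = FALSE)
  colnames(med) <- colnames(lo) <- colnames(hi) <- fit$species
  structure(list(times = times, draws = aperm(arr, c(3, 1, 2)),
                 median = med, lower = lo, upper = hi,
                 n_failed = failed),
            class = "crnn_fan")
}

#' Extrapolation error beyond a time split
#'
#' Mean absolute percent error of a predicted trajectory restricted to
#' times strictly after `t_split`, averaged over species and time;
#' entries whose observation is below `mape_floor` are excluded.
#'
#' @param predicted,observed [trajectory_dataset()]s on the same grid
#'   (or time x species matrices plus `times`).
#' @param t_split split time; errors are computed for `t > t_split`.
#' @param times time grid (taken from `predicted` when it is a dataset).
#' @param mape_floor exclusion floor for near-zero observations.
#' @return list with `mape` (pooled) and `per_species`.
#' @export
extrapolation_error <- function(predicted, observed, t_split,
                                times = NULL, mape_floor = 1e-6) {
  if (inherits(predicted, "trajectory_dataset")) {
    times <- predicted$times
    predicted <- predicted$concentrations
  }
  if (inherits(observed, "trajectory_dataset")) {
    if (!isTRUE(all.equal(times, observed$times)))
      stop("prediction and observation grids do not align")
    observed <- observed$concentrations
  }
  if (is.null(times)) stop("times must be supplied")
  sel <- times > t_split
  if (!any(sel)) stop("no time points beyond the split")
  p <- predicted[sel, , drop = FALSE]
  o <- observed[sel, , drop = FALSE]
  ape <- 100 * abs(p - o) / o
  ape[o <= mape_floor] <- NA
  per_species <- colMeans(ape, na.rm = TRUE)
  names(per_species) <- colnames(observed)
  list(mape = mean(ape, na.rm = TRUE), per_species = per_species)
}

#' Summarize a Bayesian CRNN fit
#'
#' Recovery probabilities, score metrics, rate posteriors, and -- when
#' the generating system is known -- the reaction matching and percent
#' deviations from the true rate constants.
#'
#' @param object a [bcrnn()] fit.
#' @param threshold presence threshold.
#' @param truth optional [reaction_system()] (defaults to the
#'   collection's generating system).
#' @param ... unused.
#' @return an object of class `summary.bcrnn`.
#' @export
summary.bcrnn <- function(object, threshold = 1e-4, truth = object$system,
                          ...) {
  out <- list(
    recovery_probability = recovery_probability(object, threshold),
    score = score_metric(object, threshold),
    rates = rate_posteriors(object)$summary,
    sampling_start_epoch = object$sampling_start_epoch,
    n_samples = nrow(object$samples))
  if (!is.null(truth)) {
    matching <- match_reactions(object, truth, threshold)
    out$matching <- matching
    out$deviation <- percent_deviation(object, truth, matching)
  }
  class(out) <- "summary.bcrnn"
  out
}

#' @export
print.summary.bcrnn <- function(x, digits = 3, ...) {
  cat("Posterior summary (", x$n_samples, " samples, sampling from epoch ",
      x$sampling_start_epoch, ")\n\n", sep = "")
  cat("Reactant score metric (species x reactions):\n")
  print(round(x$score, digits))
  cat("\nRate-constant posteriors:\n")
  print(cbind(x$rates[1], signif(x$rates[-1], digits)), row.names = FALSE)
  if (!is.null(x$deviation)) {
    cat("\nPercent deviation from true rates (per true reaction):\n")
    print(cbind(x$deviation[1:3],
                signif(x$deviation[4:5], digits)), row.names = FALSE)
  }
  invisible(x)
}

#' Write the standard analysis artifacts of a fit
#'
#' Recovery-probability and score matrices as CSV (rows species, columns
#' reactions), rate posteriors as CSV (one column per reaction, one row
#' per sample), and a summary JSON (rate summaries, matching and
#' deviations when truth is available).
#'
#' @param fit a [bcrnn()] fit.
#' @param dir output directory (created if needed).
#' @param threshold presence threshold.
#' @param truth optional [reaction_system()].
#' @return invisible character vector of the files written.
#' @export
write_analysis <- function(fit, dir, threshold = 1e-4, truth = fit$system) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summary(fit, threshold = threshold, truth = truth)
  rp <- rate_posteriors(fit)
  files <- c(
    recovery = file.path(dir, "recovery_probability.csv"),
    score = file.path(dir, "score_metric.csv"),
    rates = file.path(dir, "rate_posteriors.csv"),
    summary = file.path(dir, "summary.json"))
  utils::write.csv(as.data.frame(sm$recovery_probability), files["recovery"])
  utils::write.csv(as.data.frame(sm$score), files["score"])
  utils::write.csv(as.data.frame(rp$samples), files["rates"],
                   row.names = FALSE)
  doc <- list(rate_summary = sm$rates,
              sampling_start_epoch = sm$sampling_start_epoch,
              n_samples = sm$n_samples)
  if (!is.null(sm$deviation)) {
    doc$matching <- as.integer(sm$matching)
    doc$deviation <- sm$deviation
  }
  jsonlite::write_json(doc, files["summary"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(files)
}
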