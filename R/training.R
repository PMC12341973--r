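#' Training control parameters
#'
#' Collects every tunable of the Bayesian CRNN training loop. Defaults
#' are the hand-tuned values of the five-species benchmark protocol:
#' preconditioner constant `lambda = 1e-6`, smoothing `beta = 0.9`, L2
#' coefficient `1e-5`, and step-size schedule `alpha = 0.001`,
#' `step_b = 0.15`, `step_gamma = 0.005`. For the EGFR-STAT3 protocol use
#' `loss = "mape"`, `lambda = 1e-8`, `l1 = 1e-4`, `l2 = 1e-5`.
#'
#' @param optimizer `"psgld"` (preconditioned, the default) or `"sgld"`
#'   (identity preconditioner).
#' @param loss `"mae"` (MAE + L2 on all weights, plus the L1 term below
#'   when `l1 > 0`) or `"mape"` (MAPE + L1 on stoichiometric weights +
#'   L2 on rate-determining weights).
#' @param l1 L1 coefficient on the stoichiometric output block
#'   (the product coefficients under tying). Stoichiometric matrices
#'   are sparse, and this sparsity penalty removes the spurious ridge
#'   in which a node both consumes and produces the same species.
#' @param lambda small positive constant protecting the preconditioner
#'   denominator.
#' @param beta smoothing factor of the squared-gradient moving average,
#'   in (0, 1).
#' @param ema direction of the squared-gradient average: `"cited"`
#'   (default) keeps `beta` worth of history per step,
#'   `V = beta*V + (1-beta)*g^2`, the convention of the preconditioned
#'   optimizer this sampler derives from; `"printed"` uses the
#'   transposed form `V = (1-beta)*V + beta*g^2`.
#' @param l2,l1 regularization coefficients.
#' @param alpha,step_b,step_gamma step-size schedule
#'   `eps_t = alpha * (step_b + t)^(-step_gamma)`.
#' @param batch_size mini-batch size (whole trajectories).
#' @param noise_n the divisor n of the injected Langevin noise
#'   `(1/n) N(0, eps*G)`: `"train"` (default) the number of training
#'   trajectories, `"batch"` the mini-batch size, or an explicit number.
#'   n acts as the sampler's temperature (posterior widths scale like
#'   1/n^2), so scaled-down corpora that should emulate the benchmark
#'   protocol pass the benchmark's training-set size here.
#' @param max_epochs epoch budget.
#' @param n_posterior posterior samples to keep (uniform thinning of the
#'   sampling phase).
#' @param preconditioner `"sqrt"` uses `G = 1/(lambda + sqrt(V))` (the
#'   form of the optimizer the algorithm derives from); `"literal"` uses
#'   `G = 1/(lambda + V)` as printed in the update rule.
#' @param noise_scale `"printed"` draws noise `N(0, eps*G)/n`;
#'   `"classical"` draws the textbook Langevin noise `N(0, 2*eps*G)`.
#' @param substeps RK4 substeps per data interval.
#' @param floor concentration clamp floor inside the CRNN rate law.
#' @param mape_floor observations below this are excluded from MAPE.
#' @param cap loss value reported for divergent integrations.
#' @param grad_clip elementwise bound on the gradient entering the
#'   update, in units of the per-trajectory-mean gradient (the bound is
#'   scaled by `grad_scale` internally, so its meaning is independent
#'   of the corpus size). It protects the squared-gradient average from
#'   rare spikes when a mini-batch trajectory grazes divergence and
#'   should not bind on healthy gradients.
#' @param tied tie the consumption side of the stoichiometric output
#'   weights to the reaction orders during training: the third parameter
#'   block then holds nonnegative product coefficients and the net
#'   stoichiometry is products minus orders, so every hidden node is a
#'   physically consistent elementary reaction. Fits are reported in
#'   the untied parameterization either way.
#' @param grad_scale multiplier applied to the data-fit gradient before
#'   the update: `"train"` (default) scales the per-trajectory mean
#'   gradient by the number of training trajectories, giving the
#'   gradient of the dataset-total loss that stochastic-gradient
#'   Langevin methods sample with (the injected noise is calibrated
#'   against it); `"none"` uses the bare mean; a number is used as-is.
#' @param detect_window,detect_threshold,detect_patience,min_burn_in
#'   sampling-phase detection: trailing moving-average window, relative
#'   stagnation threshold, epochs the condition must persist, and the
#'   earliest admissible start.
#' @param val_every cadence (in epochs) of validation-loss evaluation;
#'   between evaluations the last value is carried forward.
#' @param patience_stop early-stopping patience (epochs without
#'   validation improvement after sampling begins).
#' @param failure_budget consecutive fully-divergent epochs tolerated
#'   before training aborts.
#' @param seed integer seed for initialization, batching and the sampler.
#' @return a list of class `crnn_control`.
#' @export
crnn_control <- function(optimizer = c("psgld", "sgld"),
                         loss = c("mae", "mape"),
                         lambda = 1e-6, beta = 0.9, l2 = 1e-5, l1 = 0,
                         alpha = 0.001, step_b = 0.15, step_gamma = 0.005,
                         batch_size = 10L, max_epochs = 10000L,
                         n_posterior = 1000L, noise_n = c("train", "batch"),

                         preconditioner = c("sqrt", "literal"),
                         noise_scale = c("printed", "classical"),
                         substeps = 1L, floor = 1e-8, mape_floor = 1e-6,
                         cap = 1e6, grad_clip = 10,
                         tied = FALSE, grad_scale = c("train", "none"),
                         ema = c("cited", "printed"),
                         detect_window = 100L, detect_threshold = 0.01,
                         detect_patience = 50L, min_burn_in = 1000L,
                         val_every = 1L, patience_stop = 500L,
                         failure_budget = 50L, seed = 1L) {
  ctrl <- list(optimizer = match.arg(optimizer), loss = match.arg(loss),
               lambda = lambda, beta = beta, l2 = l2, l1 = l1,
               alpha = alpha, step_b = step_b, step_gamma = step_gamma,
               batch_size = as.integer(batch_size),
               max_epochs = as.integer(max_epochs),
               n_posterior = as.integer(n_posterior),
               noise_n = if (is.numeric(noise_n)) noise_n
                         else match.arg(noise_n),
               preconditioner = match.arg(preconditioner),
               noise_scale = match.arg(noise_scale),
               substeps = as.integer(substeps), floor = floor,
               mape_floor = mape_floor, cap = cap, grad_clip = grad_clip,
               grad_scale = if (is.numeric(grad_scale)) grad_scale
                            else match.arg(grad_scale),
               ema = match.arg(ema), tied = isTRUE(tied),
               detect_window = as.integer(detect_window),
               detect_threshold = detect_threshold,
               detect_patience = as.integer(detect_patience),
               min_burn_in = as.integer(min_burn_in),
               val_every = as.integer(val_every),
               patience_stop = as.integer(patience_stop),
               failure_budget = as.integer(failure_budget),
               seed = as.integer(seed))
  stopifnot(ctrl$beta > 0, ctrl$beta <= 1, ctrl$lambda > 0,
            ctrl$l1 >= 0, ctrl$l2 >= 0, ctrl$alpha > 0,
            ctrl$batch_size >= 1)
  class(ctrl) <- "crnn_control"
  ctrl
}

#' Decreasing step-size schedule
#'
#' `eps_t = alpha * (b + t)^(-gamma)`: positive and non-increasing in the
#' epoch number `t`. With the benchmark values (`alpha = 0.001`,
#' `b = 0.15`, `gamma = 0.005`) the schedule decays very slowly.
#'
#' @param t epoch number (>= 1).
#' @param alpha base step size.
#' @param b shift.
#' @param gamma decay exponent (0 gives a constant step).
#' @return the step size at epoch `t`.
#' @export
step_size <- function(t, alpha = 0.001, b = 0.15, gamma = 0.005) {
  stopifnot(all(t >= 1), alpha > 0, b >= 0, gamma >= 0)
  alpha * (b + t)^(-gamma)
}

#' MAE loss with L2 regularization
#'
#' Mean absolute error over all entries of the predicted trajectory plus
#' `l2 * theta . theta` over the full flattened parameter vector.
#'
#' @param params a [crnn_parameters()].
#' @param predicted,observed matrices of equal shape.
#' @param l2 L2 coefficient.
#' @return scalar loss.
#' @export
loss_mae_l2 <- function(params, predicted, observed, l2 = 0) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)))
    stop("predicted and observed must share shape")
  theta <- flatten_params(params)
  mean(abs(predicted - observed)) + l2 * sum(theta * theta)
}

#' MAPE loss with L1 (stoichiometry) and L2 (rate) regularization
#'
#' Mean absolute percent error over entries whose observation exceeds
#' `mape_floor`, plus `l1 * sum(|stoich_weights|)` and `l2 *
#' (order_weights, ln_rate_bias) . (order_weights, ln_rate_bias)` -- L1
#' sparsifies the stoichiometric output layer while L2 tempers the
#' rate-determining input layer and biases.
#'
#' @inheritParams loss_mae_l2
#' @param l1 L1 coefficient on the stoichiometric weights.
#' @param mape_floor exclusion floor for near-zero observations.
#' @return scalar loss (percent units for the data term).
#' @export
loss_mape_l1_l2 <- function(params, predicted, observed, l1 = 0, l2 = 0,
                            mape_floor = 1e-6) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)))
    stop("predicted and observed must share shape")
  keep <- observed > mape_floor
  if (!any(keep)) stop("no observations above the MAPE floor")
  mape <- 100 * mean(abs(predicted[keep] - observed[keep]) / observed[keep])
  theta_r <- c(params$order_weights, params$ln_rate_bias)
  mape + l1 * sum(abs(params$stoich_weights)) + l2 * sum(theta_r * theta_r)
}

#' One pSGLD update
#'
#' Updates the squared-gradient moving average `V <- (1-beta) V + beta
#' g*g`, forms the diagonal preconditioner `G = 1/(lambda + sqrt(V))`
#' (or `1/(lambda + V)` in literal mode), and moves
#' `theta <- theta - eps * g * G + noise` with per-coordinate noise sd
#' `sqrt(eps * G)/n` (printed scaling) or `sqrt(2 * eps * G)` (classical
#' Langevin). Coordinates listed in `nonneg_idx` are clipped at zero
#' afterwards (constraint projection).
#'
#' @param state list with `theta` (numeric), `v` (numeric, same length,
#'   `>= 0`), and `epoch` (integer, the t of the schedule).
#' @param gradient numeric gradient vector.
#' @param control a [crnn_control()].
#' @param n the batch size entering the noise scaling.
#' @param nonneg_idx optional indices projected to `>= 0` after the step.
#' @param update_v update the squared-gradient average (disabled when a
#'   fully divergent batch yields a capped, gradient-free loss).
#' @return the updated state (epoch incremented); attribute
#'   `precond_max` carries the largest preconditioner entry.
#' @export
psgld_step <- function(state, gradient, control, n = control$batch_size,
                       nonneg_idx = NULL, update_v = TRUE) {
  langevin_step(state, gradient, control, n, nonneg_idx,
                preconditioned = TRUE, update_v = update_v)
}

#' One plain SGLD update
#'
#' Identical to [psgld_step()] with the identity preconditioner
#' (`G = 1`); the squared-gradient average is still tracked so that the
#' two samplers are state-compatible.
#'
#' @inheritParams psgld_step
#' @return the updated state.
#' @export
sgld_step <- function(state, gradient, control, n = control$batch_size,
                      nonneg_idx = NULL, update_v = TRUE) {
  langevin_step(state, gradient, control, n, nonneg_idx,
                preconditioned = FALSE, update_v = update_v)
}

langevin_step <- function(state, gradient, control, n, nonneg_idx,
                          preconditioned, update_v = TRUE) {
  g <- as.numeric(gradient)
  if (length(g) != length(state$theta))
    stop("gradient shape does not match parameters")
  if (any(!is.finite(g)))
    stop("non-finite gradient: step rejected")
  if (!is.null(control$grad_clip) && is.finite(control$grad_clip))
    g <- pmin(pmax(g, -control$grad_clip), control$grad_clip)
  v <- if (!update_v) state$v
       else if (identical(control$ema, "printed"))
         (1 - control$beta) * state$v + control$beta * g * g
       else control$beta * state$v + (1 - control$beta) * g * g
  G <- if (!preconditioned) {
    rep(1, length(v))
  } else if (control$preconditioner == "sqrt") {
    1 / (control$lambda + sqrt(v))
  } else {
    1 / (control$lambda + v)
  }
  eps <- step_size(state$epoch, control$alpha, control$step_b,
                   control$step_gamma)
  sd <- if (control$noise_scale == "printed") {
    sqrt(eps * G) / n
  } else {
    sqrt(2 * eps * G)
  }
  theta <- state$theta - eps * g * G + stats::rnorm(length(g), 0, sd)
  if (!is.null(nonneg_idx)) theta[nonneg_idx] <- pmax(theta[nonneg_idx], 0)
  out <- list(theta = theta, v = v, epoch = state$epoch + 1L)
  attr(out, "precond_max") <- max(G)
  out
}

#' Detect the sampling phase from a loss trace
#'
#' The sampler enters its sampling phase when the loss stagnates. This is
#' declared at the first epoch `tau` from which the relative change of a
#' trailing moving average of the (validation) loss over a lag of
#' `window` epochs stays below `threshold` for `patience` consecutive
#' epochs. Detection is never earlier than `min_burn_in`.
#'
#' @param loss_trace numeric vector of per-epoch losses.
#' @param window moving-average window and comparison lag (epochs).
#' @param threshold relative-change threshold.
#' @param patience epochs the stagnation condition must persist.
#' @param min_burn_in earliest admissible start epoch.
#' @return the sampling start epoch, or `NA_integer_` if the trace never
#'   stagnates ("no sampling phase").
#' @export
detect_sampling_phase <- function(loss_trace, window = 50L,
                                  threshold = 1e-3, patience = 50L,
                                  min_burn_in = 2L * window) {
  n <- length(loss_trace)
  if (n < 1L) stop("empty loss trace")
  first_t <- max(min_burn_in, 2L * window)
  if (n < first_t) return(NA_integer_)
  cs0 <- c(0, cumsum(loss_trace))   # cs0[t + 1] = sum of first t losses
  ts <- first_t:n
  ma_now <- (cs0[ts + 1L] - cs0[ts + 1L - window]) / window
  ma_lag <- (cs0[ts + 1L - window] - cs0[ts + 1L - 2L * window]) / window
  rel <- abs(ma_now - ma_lag) / pmax(abs(ma_lag), .Machine$double.eps)
  ok <- rel < threshold
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= patience) return(ts[i] - patience + 1L)
  }
  NA_integer_
}

# data-fit loss of one dataset at given parameters (forward solve only)
dataset_fit_loss <- function(params, dataset, control,
                             times = dataset$times,
                             obs = dataset$concentrations) {
  traj <- .crnn_integrate_cpp(params$order_weights, params$ln_rate_bias,
                              params$stoich_weights, dataset$y0, times,
                              control$substeps, params$floor)
  if (traj$diverged) return(control$cap)
  pred <- traj$trajectory
  if (control$loss == "mae") {
    mean(abs(pred - obs))
  } else {
    keep <- obs > control$mape_floor
    if (!any(keep)) return(control$cap)
    100 * mean(abs(pred[keep] - obs[keep]) / obs[keep])
  }
}

# summed data-fit loss + gradient over a set of datasets, plus
# regularization; returns list(loss, grad (flat), n_diverged)
batch_loss_grad <- function(theta, template, datasets, control,
                            scale = 1) {
  m <- nrow(template$order_weights); s <- ncol(template$order_weights)
  iW <- seq_len(m * s); ib <- m * s + seq_len(m); iV <- m * s + m + seq_len(s * m)
  W <- matrix(theta[iW], m, s); b <- theta[ib]; V <- matrix(theta[iV], s, m)
  loss_kind <- if (control$loss == "mae") 0L else 1L
  total <- 0; grad <- numeric(length(theta)); ndiv <- 0L
  for (d in datasets) {
    out <- .crnn_loss_grad_cpp(W, b, V, d$y0, d$times, d$concentrations,
                               loss_kind, control$substeps, control$floor,
                               control$mape_floor, control$cap)
    total <- total + out$loss
    if (out$diverged) {
      ndiv <- ndiv + 1L
    } else {
      grad[iW] <- grad[iW] + as.numeric(out$gW)
      grad[ib] <- grad[ib] + out$gb
      grad[iV] <- grad[iV] + as.numeric(out$gV)
    }
  }
  nd <- length(datasets)
  n_ok <- nd - ndiv
  total <- total / nd
  if (n_ok > 0L) grad <- grad / n_ok
  if (control$loss == "mae") {
    total <- total + control$l2 * sum(theta * theta) +
      control$l1 * sum(abs(theta[iV]))
    grad <- grad + 2 * control$l2 * theta
    grad[iV] <- grad[iV] + control$l1 * sign(theta[iV])
  } else {
    total <- total + control$l1 * sum(abs(theta[iV])) +
      control$l2 * sum(theta[c(iW, ib)]^2)
    grad[iV] <- grad[iV] + control$l1 * sign(theta[iV])
    grad[c(iW, ib)] <- grad[c(iW, ib)] + 2 * control$l2 * theta[c(iW, ib)]
  }
  list(loss = total, grad = grad * scale, n_diverged = ndiv)
}

#' Restrict a dataset or collection to a time window
#'
#' Keeps only time points with `t <= t_max`; used for the extrapolation
#' experiments (train on the early window, predict beyond it).
#'
#' @param x a [trajectory_dataset()] or [dataset_collection()].
#' @param t_max inclusive upper time bound.
#' @return the truncated object.
#' @export
restrict_time <- function(x, t_max) {
  if (inherits(x, "dataset_collection")) {
    x$datasets <- lapply(x$datasets, restrict_time, t_max = t_max)
    return(x)
  }
  keep <- x$times <= t_max
  if (sum(keep) < 2L) stop("time window keeps fewer than 2 points")
  trajectory_dataset(x$times[keep], x$concentrations[keep, , drop = FALSE],
                     y0 = x$y0, noise_fraction = x$noise_fraction,
                     seed = x$seed)
}

#' Fit a Bayesian chemical reaction neural network
#'
#' Trains a CRNN on a collection of concentration trajectories with
#' (preconditioned) stochastic gradient Langevin dynamics, per epoch:
#' sample a mini-batch of whole trajectories, integrate the CRNN ODE for
#' each, backpropagate the (regularized) loss through the solver, take
#' one Langevin step, project the reaction orders to be nonnegative, and
#' record training/validation losses. Once the validation loss stagnates
#' (see [detect_sampling_phase()]) every epoch's parameters are collected
#' as posterior samples; training stops at `max_epochs` or once the
#' validation loss has not improved for `patience_stop` epochs after at
#' least `n_posterior` samples were collected. The collected samples are
#' thinned uniformly to `n_posterior`.
#'
#' @param collection a [dataset_collection()].
#' @param n_hidden number of hidden reaction nodes; defaults to the
#'   reaction count of the generating system when known.
#' @param control a [crnn_control()].
#' @param t_max optional training time window (data restricted to
#'   `t <= t_max` before fitting).
#' @param init optional initial [crnn_parameters()] (defaults to Xavier
#'   initialization under the control seed).
#' @param resume optional checkpoint: either the path of a checkpoint
#'   JSON written via `checkpoint_path`, or the parsed state -- training
#'   continues from its epoch with the RNG stream restored, so an
#'   interrupted run resumes bit-identically.
#' @param checkpoint_path optional path; when set, an epoch-stamped
#'   checkpoint JSON is written every `checkpoint_every` epochs.
#' @param checkpoint_every checkpoint cadence in epochs.
#' @param verbose print a progress line every 500 epochs.
#' @return an object of class `bcrnn`; see [summary.bcrnn()],
#'   [coef.bcrnn()], [predict.bcrnn()].
#' @export
bcrnn <- function(collection, n_hidden = NULL, control = crnn_control(),
                  t_max = NULL, init = NULL, resume = NULL,
                  checkpoint_path = NULL, checkpoint_every = 1000L,
                  verbose = FALSE) {
  stopifnot(inherits(collection, "dataset_collection"))
  if (!is.null(t_max)) collection <- restrict_time(collection, t_max)
  species <- colnames(collection$datasets[[1L]]$concentrations)
  s <- ncol(collection$datasets[[1L]]$concentrations)
  if (is.null(n_hidden)) {
    if (is.null(collection$system))
      stop("n_hidden must be given when the collection has no generating system")
    n_hidden <- n_reactions(collection$system)
  }
  train_sets <- collection$datasets[collection$train_indices]
  val_sets <- collection$datasets[collection$validation_indices]
  if (!length(train_sets)) stop("empty training set")
  batch_n <- min(control$batch_size, length(train_sets))

  with_seed(control$seed, {
    t_span <- diff(range(collection$datasets[[1L]]$times))
    template <- if (is.null(init))
      init_crnn(n_hidden, s, t_span = t_span, floor = control$floor,
                species = species)
    else init
    template <- project_constraints(template)
    if (control$tied)  # third block holds nonnegative product coefficients
      template$stoich_weights <- abs(template$stoich_weights)
    m <- n_hidden
    nonneg_idx <- seq_len(m * s)  # order-weight block of the flat vector

    if (is.character(resume)) resume <- read_checkpoint(resume)
    gscale <- if (is.numeric(control$grad_scale)) control$grad_scale
              else if (control$grad_scale == "train") length(train_sets)
              else 1
    max_e <- control$max_epochs
    train_loss <- rep(NA_real_, max_e)
    val_loss <- rep(NA_real_, max_e)
    eps_trace <- rep(NA_real_, max_e)
    samples <- list()
    sample_epochs <- integer()
    sampling_start <- NA_integer_
    best_val <- Inf
    best_val_epoch <- 0L
    consec_fail <- 0L
    precond_max <- 0
    stopped_at <- 0L

    if (!is.null(resume)) {
      state <- list(theta = resume$theta, v = resume$v,
                    epoch = resume$epoch)
      if (!is.null(resume$rng))
        assign(".Random.seed", as.integer(resume$rng), envir = globalenv())
      start_epoch <- resume$epoch
      prev <- min(length(resume$train_loss), max_e)
      train_loss[seq_len(prev)] <- resume$train_loss[seq_len(prev)]
      val_loss[seq_len(prev)] <- resume$val_loss[seq_len(prev)]
      eps_trace[seq_len(prev)] <- resume$eps_trace[seq_len(prev)]
      if (length(resume$samples))
        samples <- lapply(seq_len(nrow(resume$samples)),
                          function(i) as.numeric(resume$samples[i, ]))
      sample_epochs <- as.integer(resume$sample_epochs)
      sampling_start <- if (is.null(resume$sampling_start) ||
                            is.na(resume$sampling_start)) NA_integer_
                        else as.integer(resume$sampling_start)
      if (!is.null(resume$best_val)) best_val <- resume$best_val
      if (!is.null(resume$best_val_epoch))
        best_val_epoch <- as.integer(resume$best_val_epoch)
    } else {
      state <- list(theta = flatten_params(template),
                    v = numeric(length(flatten_params(template))),
                    epoch = 1L)
      start_epoch <- 1L
    }

    n_noise <- if (is.numeric(control$noise_n)) control$noise_n
               else if (control$noise_n == "train") length(train_sets)
               else batch_n
    ctrl_cpp <- list(
      loss = control$loss, lambda = control$lambda, beta = control$beta,
      l2 = control$l2, l1 = control$l1, alpha = control$alpha,
      step_b = control$step_b, step_gamma = control$step_gamma,
      floor = control$floor, mape_floor = control$mape_floor,
      cap = control$cap,
      grad_clip = if (is.finite(control$grad_clip))
                    control$grad_clip * gscale
                  else 1e300,
      gscale = gscale, n_noise = n_noise, substeps = control$substeps,
      ema = control$ema, preconditioner = control$preconditioner,
      noise_scale = control$noise_scale, optimizer = control$optimizer,
      val_every = control$val_every, tied = control$tied)
    P <- length(state$theta)
    val_idx <- as.integer(collection$validation_indices)
    collect_from <- if (!is.na(sampling_start)) start_epoch else Inf

    epoch <- start_epoch
    stop_now <- FALSE
    while (epoch <= max_e && !stop_now) {
      chunk <- min(200L, max_e - epoch + 1L)
      if (!is.null(checkpoint_path) && checkpoint_every > 0L)
        chunk <- min(chunk,
                     checkpoint_every - ((epoch - 1L) %% checkpoint_every))
      epochs <- epoch:(epoch + chunk - 1L)
      idx_mat <- do.call(rbind, lapply(epochs, function(e)
        minibatch(collection, batch_n, control$seed, e)))
      noise_mat <- matrix(stats::rnorm(chunk * P), nrow = chunk,
                          byrow = TRUE)
      out <- .crnn_epochs_cpp(collection$datasets, idx_mat, noise_mat,
                              state$theta, state$v, epoch, m, s,
                              ctrl_cpp, val_idx)
      if (out$max_consec_fail > control$failure_budget)
        stop("training aborted: ", out$max_consec_fail,
             " consecutive epochs with fully divergent integrations")
      state <- list(theta = out$theta, v = out$v,
                    epoch = epoch + chunk)
      train_loss[epochs] <- out$train_loss
      vl_chunk <- out$val_loss
      if (anyNA(vl_chunk)) {
        prev <- if (epoch > 1L) val_loss[epoch - 1L] else vl_chunk[1L]
        vl_chunk[1L] <- ifelse(is.na(vl_chunk[1L]), prev, vl_chunk[1L])
        for (ii in which(is.na(vl_chunk))) vl_chunk[ii] <- vl_chunk[ii - 1L]
      }
      val_loss[epochs] <- vl_chunk
      eps_trace[epochs] <- step_size(epochs, control$alpha,
                                     control$step_b, control$step_gamma)
      precond_max <- max(precond_max, out$precond_max)
      stopped_at <- epoch + chunk - 1L

      for (e in epochs) {
        if (is.na(sampling_start) && e >= control$min_burn_in &&
            e %% 10L == 0L) {
          sampling_start <- detect_sampling_phase(
            val_loss[seq_len(e)], window = control$detect_window,
            threshold = control$detect_threshold,
            patience = control$detect_patience,
            min_burn_in = control$min_burn_in)
          if (!is.na(sampling_start)) {
            best_val <- Inf
            best_val_epoch <- e
            collect_from <- e
          }
        }
        if (!is.na(sampling_start) && e >= collect_from) {
          samples[[length(samples) + 1L]] <- out$thetas[e - epoch + 1L, ]
          sample_epochs <- c(sample_epochs, e)
          if (val_loss[e] < best_val) {
            best_val <- val_loss[e]
            best_val_epoch <- e
          }
          if (length(samples) >= control$n_posterior &&
              e - best_val_epoch >= control$patience_stop) {
            stopped_at <- e
            state$theta <- out$thetas[e - epoch + 1L, ]
            stop_now <- TRUE
            break
          }
        }
      }
      if (verbose)
        message(sprintf("epoch %6d  train %.5g  val %.5g%s", stopped_at,
                        train_loss[stopped_at], val_loss[stopped_at],
                        if (!is.na(sampling_start)) "  [sampling]" else ""))
      if (!stop_now && !is.null(checkpoint_path) && checkpoint_every > 0L &&
          (epoch + chunk - 1L) %% checkpoint_every == 0L) {
        e_end <- epoch + chunk - 1L
        write_checkpoint(checkpoint_path, list(
          theta = state$theta, v = state$v, epoch = e_end + 1L,
          rng = get(".Random.seed", envir = globalenv()),
          train_loss = train_loss[seq_len(e_end)],
          val_loss = val_loss[seq_len(e_end)],
          eps_trace = eps_trace[seq_len(e_end)],
          samples = if (length(samples)) do.call(rbind, samples)
                    else matrix(numeric(), 0L, P),
          sample_epochs = sample_epochs,
          sampling_start = sampling_start,
          best_val = best_val, best_val_epoch = best_val_epoch))
      }
      epoch <- epoch + chunk
    }

    # report everything in the untied parameterization: under tying the
    # third block holds product coefficients, net = products - t(orders)
    tied_to_net <- function(th) {
      W <- matrix(th[seq_len(m * s)], m, s)
      th[m * s + m + seq_len(s * m)] <-
        th[m * s + m + seq_len(s * m)] - as.numeric(t(W))
      th
    }
    if (control$tied) {
      samples <- lapply(samples, tied_to_net)
      state$theta_raw <- state$theta
      state$theta <- tied_to_net(state$theta)
    }

    ran <- seq_len(stopped_at)
    collected <- length(samples)
    if (collected) {
      S <- do.call(rbind, samples)
      if (collected > control$n_posterior) {
        keep <- unique(round(seq(1L, collected,
                                 length.out = control$n_posterior)))
        S <- S[keep, , drop = FALSE]
        sample_epochs <- sample_epochs[keep]
      }
    } else {
      S <- matrix(numeric(), 0L, length(state$theta))
    }

    post_mean <- if (nrow(S)) unflatten_params(colMeans(S), template)
                 else unflatten_params(state$theta, template)

    fit <- structure(list(
      samples = S,
      sample_epochs = sample_epochs,
      template = template,
      posterior_mean = post_mean,
      loss_trace = data.frame(epoch = ran,
                              train_loss = train_loss[ran],
                              val_loss = val_loss[ran],
                              step_size = eps_trace[ran]),
      sampling_start_epoch = sampling_start,
      n_collected = collected,
      shortfall = collected < control$n_posterior,
      control = control,
      n_hidden = n_hidden,
      species = species,
      system = collection$system,
      precond_max = precond_max,
      state = list(theta = state$theta, v = state$v, epoch = state$epoch,
                   rng = get(".Random.seed", envir = globalenv()),
                   train_loss = train_loss[ran], val_loss = val_loss[ran],
                   eps_trace = eps_trace[ran])),
      class = "bcrnn")
    fit
  })
}

write_checkpoint <- function(path, ckpt) {
  jsonlite::write_json(ckpt, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

read_checkpoint <- function(path) {
  ck <- jsonlite::fromJSON(path)
  if (!is.null(ck$samples) && !is.matrix(ck$samples))
    ck$samples <- matrix(ck$samples, nrow = length(ck$sample_epochs))
  if (is.null(ck$samples)) ck$samples <- matrix(numeric(), 0L, length(ck$theta))
  ck
}

#' Posterior ensemble of a fitted model
#'
#' @param fit a [bcrnn()] fit.
#' @return matrix of posterior samples (rows) in flattened parameter
#'   order, with the parameter template as attribute.
#' @export
posterior_samples <- function(fit) {
  stopifnot(inherits(fit, "bcrnn"))
  structure(fit$samples, template = fit$template)
}

# materialize sample i as crnn_parameters
sample_params <- function(fit, i) unflatten_params(fit$samples[i, ], fit$template)

#' @export
print.bcrnn <- function(x, ...) {
  cat("Bayesian CRNN fit\n")
  cat(sprintf("  %d hidden reactions x %d species, optimizer %s, loss %s\n",
              x$n_hidden, length(x$species), x$control$optimizer,
              x$control$loss))
  cat(sprintf("  epochs run: %d; sampling phase from epoch %s\n",
              nrow(x$loss_trace),
              ifelse(is.na(x$sampling_start_epoch), "never (no sampling phase)",
                     x$sampling_start_epoch)))
  cat(sprintf("  posterior samples: %d%s\n", nrow(x$samples),
              if (x$shortfall) sprintf(" (shortfall: %d requested)",
                                       x$control$n_posterior) else ""))
  cat("  posterior-mean rate constants:",
      paste(signif(exp(x$posterior_mean$ln_rate_bias), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Posterior-mean CRNN parameters
#' @param object a [bcrnn()] fit.
#' @param ... unused.
#' @return a [crnn_parameters()].
#' @export
coef.bcrnn <- function(object, ...) object$posterior_mean

#' Posterior-predictive trajectories from a fitted model
#'
#' @param object a [bcrnn()] fit.
#' @param y0 initial condition.
#' @param times time grid.
#' @param draws number of posterior draws to integrate (default
#'   min(500, ensemble size)); `draws = 0` integrates the posterior mean
#'   only.
#' @param ... unused.
#' @return see [posterior_predictive()]; for `draws = 0` a
#'   [trajectory_dataset()].
#' @export
predict.bcrnn <- function(object, y0, times, draws = NULL, ...) {
  if (!is.null(draws) && draws == 0) {
    return(integrate_crnn(object$posterior_mean, y0, times,
                          substeps = object$control$substeps))
  }
  if (is.null(draws)) draws <- min(500L, nrow(object$samples))
  posterior_predictive(object, y0, times, n_draws = draws)
}

#' Loss-trace plot of a fitted model
#' @param x a [bcrnn()] fit.
#' @param log `"y"` (default) for a log loss axis.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bcrnn <- function(x, log = "y", ...) {
  tr <- x$loss_trace
  graphics::matplot(tr$epoch, cbind(tr$train_loss, tr$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", log = log, ...)
  if (!is.na(x$sampling_start_epoch))
    graphics::abline(v = x$sampling_start_epoch, lty = 2)
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
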