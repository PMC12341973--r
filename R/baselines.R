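# Purely data-driven comparators: an unconstrained dense neural ODE and
# an LSTM sequence model, plus the shared extrapolation harness.

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(theta, grad, state, lr = 0.001, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

xavier <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

#' Train the unconstrained dense neural ODE baseline
#'
#' A densely connected network (default two hidden layers of 50 tanh
#' units) defines the ODE right-hand side with no mass-action structure;
#' it is trained by Adam (learning rate 0.001, 2000 epochs by default)
#' on MAE between integrated and observed trajectories, with gradients
#' backpropagated through the same fixed-step RK4 discretization the
#' CRNN uses. Training data are restricted to `t <= t_max`.
#'
#' @param collection a [dataset_collection()].
#' @param t_max training time window (default 30 s).
#' @param hidden widths of the two hidden layers.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size trajectories per mini-batch.
#' @param substeps RK4 substeps per data interval.
#' @param seed RNG seed (initialization and batching).
#' @param verbose print progress every 200 epochs.
#' @return object of class `dense_node` with the weights, the final
#'   training loss, and the training window.
#' @export
train_dense_node <- function(collection, t_max = 30, hidden = c(50L, 50L),
                             epochs = 2000L, lr = 0.001, batch_size = 10L,
                             substeps = 1L, seed = 1L, verbose = FALSE) {
  train_full <- collection$datasets[collection$train_indices]
  train_sets <- lapply(train_full, restrict_time, t_max = t_max)
  s <- ncol(train_sets[[1L]]$concentrations)
  h1 <- hidden[1L]; h2 <- hidden[2L]
  shapes <- list(W1 = c(h1, s), b1 = h1, W2 = c(h2, h1), b2 = h2,
                 W3 = c(s, h2), b3 = s)
  npar <- h1 * s + h1 + h2 * h1 + h2 + s * h2 + s
  unflat <- function(th) {
    i <- 0L; out <- list()
    for (nm in names(shapes)) {
      d <- shapes[[nm]]
      len <- prod(d)
      out[[nm]] <- if (length(d) == 2L) matrix(th[i + seq_len(len)], d[1], d[2])
                   else th[i + seq_len(len)]
      i <- i + len
    }
    out
  }
  batch_n <- min(batch_size, length(train_sets))
  with_seed(seed, {
    theta <- c(as.numeric(xavier(h1, s)), numeric(h1),
               as.numeric(xavier(h2, h1)), numeric(h2),
               as.numeric(xavier(s, h2)), numeric(s))
    ad <- adam_init(npar)
    last_loss <- NA_real_
    for (ep in seq_len(max(epochs, 0L))) {
      idx <- sample.int(length(train_sets), batch_n)
      grad <- numeric(npar); total <- 0
      w <- unflat(theta)
      for (d in train_sets[idx]) {
        out <- .mlp_loss_grad_cpp(w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                                  d$y0, d$times, d$concentrations,
                                  as.integer(substeps))
        total <- total + out$loss
        if (!out$diverged)
          grad <- grad + c(as.numeric(out$gW1), out$gb1,
                           as.numeric(out$gW2), out$gb2,
                           as.numeric(out$gW3), out$gb3)
      }
      grad <- grad / batch_n
      upd <- adam_update(theta, grad, ad, lr = lr)
      theta <- upd$theta; ad <- upd$state
      last_loss <- total / batch_n
      if (verbose && ep %% 200L == 0L)
        message(sprintf("dense node epoch %5d  loss %.5g", ep, last_loss))
    }
    structure(list(weights = unflat(theta), hidden = hidden,
                   substeps = as.integer(substeps), t_max = t_max,
                   epochs = epochs, lr = lr, seed = seed,
                   final_loss = last_loss,
                   species = colnames(train_sets[[1L]]$concentrations)),
              class = "dense_node")
  })
}

#' @export
print.dense_node <- function(x, ...) {
  cat(sprintf("dense neural ODE baseline: %d-%d tanh, trained %d epochs on t <= %g (final loss %.4g)\n",
              x$hidden[1], x$hidden[2], x$epochs, x$t_max, x$final_loss))
  invisible(x)
}

#' Integrate a trained dense neural ODE
#' @param object a `dense_node` model.
#' @param y0 initial condition.
#' @param times time grid (may extend beyond the training window).
#' @param ... unused.
#' @return a [trajectory_dataset()] with a `diverged` attribute.
#' @export
predict.dense_node <- function(object, y0, times, ...) {
  w <- object$weights
  out <- .mlp_integrate_cpp(w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                            as.numeric(y0), as.numeric(times),
                            object$substeps)
  conc <- out$trajectory
  colnames(conc) <- object$species
  traj <- trajectory_dataset(times, conc, y0 = y0)
  attr(traj, "diverged") <- out$diverged
  traj
}

# ------------------------------------------------------------------ LSTM

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(s, hidden, layers, seed_done = TRUE) {
  cells <- vector("list", layers)
  for (l in seq_len(layers)) {
    nin <- if (l == 1L) s else hidden
    cells[[l]] <- list(W = xavier(4L * hidden, nin),
                       U = xavier(4L * hidden, hidden),
                       b = numeric(4L * hidden))
  }
  list(cells = cells, Wy = xavier(s, hidden), by = numeric(s))
}

# forward over a batch of sequences; X: list over time of s x B inputs.
# Returns predictions and the cached activations needed by BPTT.
lstm_forward <- function(par, X, hidden) {
  layers <- length(par$cells)
  Tt <- length(X); B <- ncol(X[[1L]])
  H <- hidden
  h <- lapply(seq_len(layers), function(l) matrix(0, H, B))
  cc <- lapply(seq_len(layers), function(l) matrix(0, H, B))
  cache <- vector("list", Tt)
  preds <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    x <- X[[t]]
    step_cache <- vector("list", layers)
    for (l in seq_len(layers)) {
      cell <- par$cells[[l]]
      z <- cell$W %*% x + cell$U %*% h[[l]] + cell$b
      i <- sigm(z[1:H, , drop = FALSE])
      f <- sigm(z[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- sigm(z[(3 * H + 1):(4 * H), , drop = FALSE])
      cnew <- f * cc[[l]] + i * g
      tc <- tanh(cnew)
      hnew <- o * tc
      step_cache[[l]] <- list(x = x, hprev = h[[l]], cprev = cc[[l]],
                              i = i, f = f, g = g, o = o, tc = tc)
      h[[l]] <- hnew; cc[[l]] <- cnew
      x <- hnew
    }
    cache[[t]] <- step_cache
    preds[[t]] <- par$Wy %*% h[[layers]] + par$by
  }
  list(preds = preds, cache = cache, h = h, c = cc)
}

lstm_backward <- function(par, X, targets, fw, hidden) {
  layers <- length(par$cells); H <- hidden
  Tt <- length(X); B <- ncol(X[[1L]]); s <- nrow(targets[[1L]])
  n_out <- Tt * B * s
  g <- list(cells = lapply(par$cells, function(cell)
    list(W = cell$W * 0, U = cell$U * 0, b = cell$b * 0)),
    Wy = par$Wy * 0, by = par$by * 0)
  dh <- lapply(seq_len(layers), function(l) matrix(0, H, B))
  dc <- lapply(seq_len(layers), function(l) matrix(0, H, B))
  loss <- 0
  for (t in rev(seq_len(Tt))) {
    res <- fw$preds[[t]] - targets[[t]]
    loss <- loss + sum(abs(res))
    dy <- sign(res) / n_out
    hl <- fw$cache[[t]][[layers]]
    htop <- hl$o * hl$tc
    g$Wy <- g$Wy + dy %*% t(htop)
    g$by <- g$by + rowSums(dy)
    dx_up <- t(par$Wy) %*% dy
    for (l in rev(seq_len(layers))) {
      cc <- fw$cache[[t]][[l]]
      dhl <- dh[[l]] + dx_up
      do <- dhl * cc$tc
      dtc <- dhl * cc$o * (1 - cc$tc^2) + dc[[l]]
      df <- dtc * cc$cprev
      di <- dtc * cc$g
      dg <- dtc * cc$i
      dc[[l]] <- dtc * cc$f
      dz <- rbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do * cc$o * (1 - cc$o))
      cell <- par$cells[[l]]
      g$cells[[l]]$W <- g$cells[[l]]$W + dz %*% t(cc$x)
      g$cells[[l]]$U <- g$cells[[l]]$U + dz %*% t(cc$hprev)
      g$cells[[l]]$b <- g$cells[[l]]$b + rowSums(dz)
      dh[[l]] <- t(cell$U) %*% dz
      dx_up <- t(cell$W) %*% dz
    }
  }
  list(grad = g, loss = loss / n_out)
}

lstm_flatten <- function(par) {
  c(unlist(lapply(par$cells, function(cl) c(cl$W, cl$U, cl$b))),
    as.numeric(par$Wy), par$by)
}

lstm_unflatten <- function(theta, template) {
  i <- 0L
  cells <- lapply(template$cells, function(cl) {
    out <- list()
    for (nm in c("W", "U", "b")) {
      len <- length(cl[[nm]])
      v <- theta[i + seq_len(len)]
      out[[nm]] <- if (is.matrix(cl[[nm]]))
        matrix(v, nrow(cl[[nm]]), ncol(cl[[nm]])) else v
      i <<- i + len
    }
    out
  })
  len <- length(template$Wy)
  Wy <- matrix(theta[i + seq_len(len)], nrow(template$Wy),
               ncol(template$Wy))
  i <- i + len
  by <- theta[i + seq_len(length(template$by))]
  list(cells = cells, Wy = Wy, by = by)
}

#' Train the LSTM sequence-model baseline
#'
#' Stacked LSTM layers (default two with 200 hidden units each) feeding
#' a linear output head, trained one step ahead with teacher forcing
#' (`Y_t -> Y_{t+1}`) by Adam on MAE, batched over whole trajectories.
#' At evaluation time the model free-runs beyond the training window.
#'
#' @param collection a [dataset_collection()].
#' @param t_max training time window (default 30 s).
#' @param hidden recurrent width per layer.
#' @param layers number of stacked LSTM layers.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size trajectories per mini-batch.
#' @param seed RNG seed.
#' @param verbose print progress every 50 epochs.
#' @return object of class `lstm_model`.
#' @export
train_lstm <- function(collection, t_max = 30, hidden = 200L, layers = 2L,
                       epochs = 2000L, lr = 0.001, batch_size = 10L,
                       seed = 1L, verbose = FALSE) {
  train_full <- collection$datasets[collection$train_indices]
  train_sets <- lapply(train_full, restrict_time, t_max = t_max)
  s <- ncol(train_sets[[1L]]$concentrations)
  nt <- nrow(train_sets[[1L]]$concentrations)
  batch_n <- min(batch_size, length(train_sets))
  with_seed(seed, {
    par <- lstm_init(s, hidden, layers)
    theta <- lstm_flatten(par)
    ad <- adam_init(length(theta))
    last_loss <- NA_real_
    for (ep in seq_len(max(epochs, 0L))) {
      idx <- sample.int(length(train_sets), batch_n)
      # batch time-major: X[[t]] is s x B
      mats <- lapply(train_sets[idx], function(d) t(d$concentrations))
      X <- lapply(seq_len(nt - 1L), function(t)
        do.call(cbind, lapply(mats, function(m) m[, t])))
      Yt <- lapply(seq_len(nt - 1L), function(t)
        do.call(cbind, lapply(mats, function(m) m[, t + 1L])))
      fw <- lstm_forward(par, X, hidden)
      bw <- lstm_backward(par, X, Yt, fw, hidden)
      upd <- adam_update(theta, lstm_flatten(bw$grad), ad, lr = lr)
      theta <- upd$theta; ad <- upd$state
      par <- lstm_unflatten(theta, par)
      last_loss <- bw$loss
      if (verbose && ep %% 50L == 0L)
        message(sprintf("lstm epoch %5d  loss %.5g", ep, last_loss))
    }
    structure(list(par = par, hidden = hidden, layers = layers,
                   t_max = t_max, epochs = epochs, lr = lr, seed = seed,
                   final_loss = last_loss,
                   species = colnames(train_sets[[1L]]$concentrations)),
              class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("LSTM baseline: %d x %d units + linear head, trained %d epochs on t <= %g (final loss %.4g)\n",
              x$layers, x$hidden, x$epochs, x$t_max, x$final_loss))
  invisible(x)
}

#' Roll out a trained LSTM over a trajectory's grid
#'
#' Within the training window the model is teacher-forced (one-step-ahead
#' predictions from the observed values); beyond it the model free-runs
#' on its own predictions.
#'
#' @param object an `lstm_model`.
#' @param dataset a [trajectory_dataset()] providing the grid and the
#'   observed values inside the training window.
#' @param t_split boundary between teacher forcing and free running
#'   (default the model's training window).
#' @param ... unused.
#' @return a [trajectory_dataset()] of predictions on the full grid.
#' @export
predict.lstm_model <- function(object, dataset, t_split = object$t_max,
                               ...) {
  obs <- t(dataset$concentrations)  # s x T
  Tt <- ncol(obs)
  par <- object$par; H <- object$hidden; layers <- object$layers
  h <- lapply(seq_len(layers), function(l) matrix(0, H, 1L))
  cc <- lapply(seq_len(layers), function(l) matrix(0, H, 1L))
  pred <- matrix(NA_real_, nrow(obs), Tt)
  pred[, 1L] <- obs[, 1L]
  x_next <- obs[, 1L, drop = FALSE]
  for (t in seq_len(Tt - 1L)) {
    x <- if (dataset$times[t] <= t_split) obs[, t, drop = FALSE] else x_next
    for (l in seq_len(layers)) {
      cell <- par$cells[[l]]
      z <- cell$W %*% x + cell$U %*% h[[l]] + cell$b
      i <- sigm(z[1:H, , drop = FALSE])
      f <- sigm(z[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- sigm(z[(3 * H + 1):(4 * H), , drop = FALSE])
      cc[[l]] <- f * cc[[l]] + i * g
      h[[l]] <- o * tanh(cc[[l]])
      x <- h[[l]]
    }
    x_next <- par$Wy %*% h[[layers]] + par$by
    pred[, t + 1L] <- x_next
  }
  conc <- t(pred)
  colnames(conc) <- object$species
  trajectory_dataset(dataset$times, conc, y0 = dataset$y0)
}

#' Extrapolation comparison harness
#'
#' Evaluates a set of trained models on the same clean trajectory: each
#' model predicts the full grid (the CRNN and dense neural ODE integrate
#' from the initial condition; the LSTM is teacher-forced up to the
#' split and free-runs beyond), and the mean absolute percent error over
#' `t > t_split` is reported pooled and per species.
#'
#' @param models named list of fitted models ([bcrnn()], `dense_node`,
#'   `lstm_model`).
#' @param dataset a clean full-horizon [trajectory_dataset()].
#' @param t_split training/extrapolation boundary (default 30 s).
#' @return data frame with one row per model: pooled MAPE, and the mean
#'   and sd of the per-species MAPEs.
#' @export
extrapolation_experiment <- function(models, dataset, t_split = 30) {
  rows <- lapply(names(models), function(nm) {
    mdl <- models[[nm]]
    pred <- if (inherits(mdl, "bcrnn")) {
      integrate_crnn(mdl$posterior_mean, dataset$y0, dataset$times,
                     substeps = mdl$control$substeps)
    } else if (inherits(mdl, "dense_node")) {
      predict(mdl, dataset$y0, dataset$times)
    } else if (inherits(mdl, "lstm_model")) {
      predict(mdl, dataset, t_split = t_split)
    } else stop("unknown model class for '", nm, "'")
    err <- extrapolation_error(pred, dataset, t_split)
    data.frame(model = nm, mape = err$mape,
               mape_species_mean = mean(err$per_species),
               mape_species_sd = stats::sd(err$per_species))
  })
  do.call(rbind, rows)
}
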