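test_that("dense neural ODE gradients agree with finite differences", {
  set.seed(8)
  s <- 3; h1 <- 4; h2 <- 4
  W1 <- matrix(rnorm(h1 * s, 0, 0.5), h1, s); b1 <- rnorm(h1, 0, 0.1)
  W2 <- matrix(rnorm(h2 * h1, 0, 0.5), h2, h1); b2 <- rnorm(h2, 0, 0.1)
  W3 <- matrix(rnorm(s * h2, 0, 0.5), s, h2); b3 <- rnorm(s, 0, 0.1)
  y0 <- runif(s, 0.2, 1)
  times <- c(0, 0.3, 0.8)
  obs <- matrix(runif(3 * s), 3, s)
  out <- bcrnn:::.mlp_loss_grad_cpp(W1, b1, W2, b2, W3, b3, y0, times,
                                    obs, 2L)
  th <- c(W1, b1, W2, b2, W3, b3)
  f <- function(t_) {
    i <- 0
    take <- function(n) { v <- t_[i + seq_len(n)]; i <<- i + n; v }
    bcrnn:::.mlp_loss_grad_cpp(matrix(take(h1 * s), h1, s), take(h1),
                               matrix(take(h2 * h1), h2, h1), take(h2),
                               matrix(take(s * h2), s, h2), take(s),
                               y0, times, obs, 2L)$loss
  }
  grads <- c(out$gW1, out$gb1, out$gW2, out$gb2, out$gW3, out$gb3)
  eps <- 1e-6
  num <- vapply(seq_along(th), function(i) {
    up <- th; up[i] <- up[i] + eps
    dn <- th; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - grads)) / max(abs(grads)), 1e-4)
})

test_that("dense-node training is seeded, windowed, and reduces the loss", {
  coll <- toy_collection(n = 6, seed = 3)
  zero <- train_dense_node(coll, t_max = 5, epochs = 0, seed = 9)
  zero2 <- train_dense_node(coll, t_max = 5, epochs = 0, seed = 9)
  # zero-epoch training leaves the seeded random initialization
  expect_identical(zero$weights, zero2$weights)
  short <- train_dense_node(coll, t_max = 5, epochs = 400,
                            hidden = c(8L, 8L), seed = 9)
  ctrl <- crnn_control()
  ref <- coll$datasets[[coll$train_indices[1]]]
  mape0 <- extrapolation_error(predict(zero, ref$y0, ref$times), ref, 0)
  mape1 <- extrapolation_error(predict(short, ref$y0, ref$times), ref, 0)
  expect_lt(mape1$mape, mape0$mape)
  expect_lt(mape1$mape, 20)
  # predictor extends beyond the training window
  longer <- predict(short, ref$y0, seq(0, 12, length.out = 20))
  expect_equal(nrow(longer$concentrations), 20)
})

test_that("LSTM backpropagation matches finite differences", {
  set.seed(21)
  s <- 2; H <- 3; layers <- 2; Tt <- 4; B <- 2
  par <- bcrnn:::lstm_init(s, H, layers)
  X <- lapply(seq_len(Tt), function(t) matrix(runif(s * B), s, B))
  Yt <- lapply(seq_len(Tt), function(t) matrix(runif(s * B), s, B))
  fw <- bcrnn:::lstm_forward(par, X, H)
  bw <- bcrnn:::lstm_backward(par, X, Yt, fw, H)
  theta <- bcrnn:::lstm_flatten(par)
  grad <- bcrnn:::lstm_flatten(bw$grad)
  f <- function(th) {
    p <- bcrnn:::lstm_unflatten(th, par)
    fw2 <- bcrnn:::lstm_forward(p, X, H)
    loss <- 0
    for (t in seq_len(Tt)) loss <- loss + sum(abs(fw2$preds[[t]] - Yt[[t]]))
    loss / (Tt * B * s)
  }
  eps <- 1e-6
  idx <- seq(1, length(theta), by = 7)  # spot-check a spread of weights
  num <- vapply(idx, function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - grad[idx])) / max(abs(grad[idx])), 1e-4)
})

test_that("an LSTM trained on constant sequences rolls out constants", {
  times <- seq(0, 8, length.out = 15)
  const <- lapply(1:4, function(i) {
    lev <- c(0.3 + 0.1 * i, 0.9 - 0.1 * i)
    trajectory_dataset(times, matrix(rep(lev, each = 15), 15, 2))
  })
  coll <- dataset_collection(const, 1:3, 4L)
  model <- train_lstm(coll, t_max = 8, hidden = 8L, layers = 2L,
                      epochs = 3000, batch_size = 3, seed = 2)
  roll <- predict(model, const[[1]], t_split = 2)
  resid <- roll$concentrations[-1, ] - const[[1]]$concentrations[-1, ]
  expect_lt(max(abs(resid)), 0.1)
})

test_that("the extrapolation harness scores all models on one grid", {
  coll <- toy_collection(n = 6, seed = 4)
  ctrl <- quick_control(max_epochs = 120, seed = 2)
  fit <- bcrnn(coll, n_hidden = 1, control = ctrl, t_max = 5)
  node <- train_dense_node(coll, t_max = 5, epochs = 40,
                           hidden = c(6L, 6L), seed = 2)
  lstm <- train_lstm(coll, t_max = 5, hidden = 6L, epochs = 40, seed = 2)
  ref <- coll$datasets[[coll$validation_indices[1]]]
  tab <- extrapolation_experiment(list(crnn = fit, crnn_again = fit,
                                       dense_node = node, lstm = lstm),
                                  ref, t_split = 5)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$mape)))
  # the same model compared to itself gives identical errors
  expect_equal(tab$mape[1], tab$mape[2])
  expect_equal(tab$mape_species_sd[1], tab$mape_species_sd[2])
})
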