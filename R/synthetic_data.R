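#' A single simulated experiment
#'
#' One experiment of the training corpus: a strictly increasing time grid,
#' the time x species concentration matrix, the initial condition, and the
#' noise metadata needed to regenerate the dataset deterministically.
#'
#' @param times strictly increasing numeric grid.
#' @param concentrations time x species matrix.
#' @param y0 initial condition (defaults to the first row).
#' @param noise_fraction proportional noise level used to corrupt the
#'   clean simulation (0 means clean).
#' @param seed integer seed the noise was drawn with, or `NA`.
#' @return an object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(times, concentrations, y0 = NULL,
                               noise_fraction = 0, seed = NA_integer_) {
  times <- as.numeric(times)
  concentrations <- as.matrix(concentrations)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (nrow(concentrations) != length(times))
    stop("concentrations must have one row per time point")
  if (is.null(y0)) y0 <- concentrations[1L, ]
  structure(
    list(times = times, concentrations = concentrations,
         y0 = as.numeric(y0), noise_fraction = noise_fraction, seed = seed),
    class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf("trajectory_dataset: %d time points x %d species, t in [%g, %g], noise %g%%\n",
              length(x$times), ncol(x$concentrations),
              min(x$times), max(x$times), 100 * x$noise_fraction))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per time point; columns `time` then one per species.
#' @param dataset a [trajectory_dataset()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_trajectory_csv <- function(dataset, path) {
  df <- data.frame(time = dataset$times, dataset$concentrations,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV written by [write_trajectory_csv()]
#' @param path input file.
#' @return a [trajectory_dataset()].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  trajectory_dataset(df$time, as.matrix(df[, -1L, drop = FALSE]))
}

#' A collection of experiments with a train/validation split
#'
#' @param datasets list of [trajectory_dataset()] objects.
#' @param train_indices,validation_indices disjoint index sets that
#'   together cover `datasets` exactly once.
#' @param system the generating [reaction_system()] (optional, kept for
#'   truth-matching).
#' @return an object of class `dataset_collection`.
#' @export
dataset_collection <- function(datasets, train_indices, validation_indices,
                               system = NULL) {
  train_indices <- as.integer(train_indices)
  validation_indices <- as.integer(validation_indices)
  if (length(intersect(train_indices, validation_indices)))
    stop("train and validation indices must be disjoint")
  if (!setequal(c(train_indices, validation_indices), seq_along(datasets)))
    stop("train + validation must cover all datasets exactly once")
  structure(
    list(datasets = datasets, train_indices = train_indices,
         validation_indices = validation_indices, system = system),
    class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  cat(sprintf("dataset_collection: %d datasets (%d train / %d validation)\n",
              length(x$datasets), length(x$train_indices),
              length(x$validation_indices)))
  invisible(x)
}

# Run `expr` under a private RNG stream so that data generation and
# batching are reproducible without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Corrupt a clean trajectory with proportional Gaussian noise
#'
#' Each entry `y` is replaced by `y + e` with `e ~ N(0, (noise_fraction *
#' y)^2)`, drawn independently per entry, so entries that are exactly zero
#' stay zero. Because the CRNN consumes log-concentrations, noised values
#' are floored at `floor` (default 1e-8) rather than allowed to go
#' negative.
#'
#' @param clean a [trajectory_dataset()] with noise_fraction 0.
#' @param noise_fraction standard deviation of the noise as a fraction of
#'   the clean value (0, 0.05 and 0.5 are the benchmark levels).
#' @param seed integer seed for the noise draw.
#' @param floor positivity floor applied after noising.
#' @return a new [trajectory_dataset()] with the noisy matrix.
#' @export
add_noise <- function(clean, noise_fraction, seed, floor = 1e-8) {
  stopifnot(noise_fraction >= 0)
  if (noise_fraction == 0) return(clean)
  conc <- clean$concentrations
  noisy <- with_seed(seed, {
    conc + stats::rnorm(length(conc), mean = 0,
                        sd = noise_fraction * abs(conc))
  })
  noisy[conc == 0] <- conc[conc == 0]   # sd 0: untouched, keeps exact zeros
  noisy <- pmax(noisy, floor)
  noisy[conc == 0] <- 0
  trajectory_dataset(clean$times, noisy, y0 = clean$y0,
                     noise_fraction = noise_fraction, seed = seed)
}

generate_collection <- function(system, sample_y0, n_datasets, noise_fraction,
                                seed, times, train_fraction = 0.9,
                                noise_on_validation = TRUE) {
  if (n_datasets < 2L) stop("n_datasets must be >= 2")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  y0s <- with_seed(seed, lapply(seq_len(n_datasets), function(i) sample_y0()))
  n_train <- round(train_fraction * n_datasets)
  n_train <- min(max(n_train, 1L), n_datasets - 1L)
  train_idx <- seq_len(n_train)
  val_idx <- setdiff(seq_len(n_datasets), train_idx)
  datasets <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    clean <- tryCatch(simulate_system(system, y0s[[i]], times),
                      error = function(e)
                        stop("dataset ", i, ": ", conditionMessage(e)))
    nf <- if (!noise_on_validation && i %in% val_idx) 0 else noise_fraction
    datasets[[i]] <- if (nf > 0)
      add_noise(clean, nf, seed = seed + i) else clean
  }
  dataset_collection(datasets, train_idx, val_idx, system = system)
}

#' Generate the five-species benchmark corpus
#'
#' Simulates `n_datasets` experiments of [case1_system()]: initial
#' concentrations of the first two species drawn uniformly from
#' `[0.2, 1.2]`, the remaining species starting at zero, 100 time points
#' on the default grid, proportional Gaussian noise at `noise_fraction`,
#' and a 90/10 train/validation split (proportional for other sizes).
#'
#' @param n_datasets number of experiments (default 100).
#' @param noise_fraction proportional noise level (0, 0.05 or 0.5 in the
#'   benchmark protocol).
#' @param seed integer seed; fixed seed gives byte-identical regeneration.
#' @param n_points time points per experiment.
#' @param t_end simulation horizon (s).
#' @param noise_on_validation also corrupt the validation experiments
#'   (default TRUE; the generation protocol draws no distinction).
#' @return a [dataset_collection()].
#' @export
generate_case1 <- function(n_datasets = 100L, noise_fraction = 0, seed = 1L,
                           n_points = 100L, t_end = 40,
                           noise_on_validation = TRUE) {
  sys <- case1_system()
  times <- seq(0, t_end, length.out = n_points)
  sample_y0 <- function() c(stats::runif(2, 0.2, 1.2), 0, 0, 0)
  generate_collection(sys, sample_y0, n_datasets, noise_fraction, seed,
                      times, noise_on_validation = noise_on_validation)
}

#' Generate the EGFR-STAT3 benchmark corpus
#'
#' Simulates experiments of [case2_system()] with every species' initial
#' concentration drawn uniformly from `[0, 1]` uM. The default corpus has
#' 300 training examples plus a held-out 10% validation split generated
#' identically (used only for sampling-phase detection / early stopping),
#' and 5% proportional Gaussian noise.
#'
#' @param n_train number of training experiments (default 300).
#' @param noise_fraction proportional noise level (default 0.05).
#' @inheritParams generate_case1
#' @return a [dataset_collection()].
#' @export
generate_case2 <- function(n_train = 300L, noise_fraction = 0.05, seed = 1L,
                           n_points = 100L, t_end = 10,
                           noise_on_validation = TRUE) {
  sys <- case2_system()
  times <- seq(0, t_end, length.out = n_points)
  n_total <- ceiling(n_train / 0.9)
  sample_y0 <- function() stats::runif(n_species(sys), 0, 1)
  coll <- generate_collection(sys, sample_y0, n_total, noise_fraction, seed,
                              times, noise_on_validation = noise_on_validation)
  # trim the training side to exactly n_train
  coll$train_indices <- coll$train_indices[seq_len(min(n_train, length(coll$train_indices)))]
  keep <- sort(c(coll$train_indices, coll$validation_indices))
  datasets <- coll$datasets[keep]
  remap <- match(seq_along(coll$datasets), keep)
  dataset_collection(datasets,
                     remap[coll$train_indices],
                     remap[coll$validation_indices],
                     system = sys)
}

#' Sample a training mini-batch
#'
#' Uniform sampling without replacement from the training indices of a
#' collection, reproducible given `(seed, epoch)`. Validation indices
#' never appear in a batch.
#'
#' @param collection a [dataset_collection()].
#' @param n batch size, between 1 and the number of training datasets.
#' @param seed integer base seed.
#' @param epoch epoch number (>= 1); different epochs give different
#'   batches under the same seed.
#' @return integer vector of dataset indices.
#' @export
minibatch <- function(collection, n, seed, epoch) {
  train <- collection$train_indices
  if (n < 1L || n > length(train))
    stop("batch size must be in [1, ", length(train), "]")
  with_seed(seed * 1000003 + epoch, {
    train[sample.int(length(train), n)]
  })
}
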