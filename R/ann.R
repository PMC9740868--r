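#' Training configuration for the neural surrogate
#'
#' Defaults mirror the conventional feed-forward fitting workflow: a
#' 70/15/15 train/validation/test split, Levenberg-Marquardt updates, and
#' early stopping after 6 consecutive validation failures.
#'
#' @param fractions Train/validation/test fractions; must sum to 1.
#' @param max_epochs Maximum number of accepted weight updates.
#' @param goal_mse Stop once training MSE (normalized scale) falls below this.
#' @param max_validation_failures Consecutive validation-MSE increases allowed
#'   before stopping; the best-validation weights are always restored.
#' @param seed Integer seed for the data split and weight initialization.
#' @return A list of class `training_config`.
#' @export
training_config <- function(fractions = c(0.70, 0.15, 0.15),
                            max_epochs = 1000, goal_mse = 0,
                            max_validation_failures = 6, seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  if (any(fractions <= 0)) stop("all split fractions must be positive")
  if (max_epochs < 1 || max_validation_failures < 1)
    stop("max_epochs and max_validation_failures must be positive")
  structure(list(fractions = fractions, max_epochs = as.integer(max_epochs),
                 goal_mse = goal_mse,
                 max_validation_failures = as.integer(max_validation_failures),
                 algorithm = "levenberg-marquardt", seed = as.integer(seed)),
            class = "training_config")
}

#' Replicate a design into a neural-network training set
#'
#' Each run is duplicated `k` times in run order (run 1's replicates first,
#' then run 2's, ...). With the 29-run packaged design and `k = 3` this yields
#' the 87-point training set used for the surrogate.
#'
#' @param design A [design_table()] with a response.
#' @param k Replication factor (>= 1).
#' @return A list with `inputs` (`(n*k) x 4` matrix, actual units) and
#'   `targets` (length `n*k` vector, mg/g).
#' @export
replicate_dataset <- function(design, k = 3) {
  if (is.null(design$response)) stop("design has no response")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  idx <- rep(seq_len(nrow(design$settings)), each = k)
  list(inputs = design$settings[idx, , drop = FALSE],
       targets = design$response[idx])
}

#' Deterministic train/validation/test split
#'
#' Set sizes follow the largest-remainder rule (floors first, then the
#' leftover samples go to the sets with the largest fractional remainders,
#' earlier set winning ties), so `n = 87` with fractions (0.70, 0.15, 0.15)
#' gives 61/13/13. Assignment of indices to sets is a seeded random shuffle.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return A list of integer index vectors `train`, `validation`, `test`,
#'   disjoint and covering `1:n`.
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3) stop("need at least 3 samples to split, got ", n)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  sizes <- floor(n * fractions)
  rem <- n * fractions - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  perm <- local_rng(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# A constant column maps to 0 and unscales back to its value.
minmax_record <- function(x) {
  x <- as.matrix(x)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

minmax_halfspan <- function(rec) {
  h <- (rec$max - rec$min) / 2
  ifelse(h > 0, h, 1)
}

minmax_scale <- function(x, rec) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, (rec$min + rec$max) / 2, "-"), 2, minmax_halfspan(rec), "/")
}

minmax_unscale <- function(z, rec) {
  z <- as.matrix(z)
  sweep(sweep(z, 2, minmax_halfspan(rec), "*"), 2, (rec$min + rec$max) / 2, "+")
}

ann_forward <- function(w, x) {
  # x: n x 4 scaled inputs; w: list(W1 H x 4, b1 H, w2 H, b2 scalar)
  a <- tanh(sweep(x %*% t(w$W1), 2, w$b1, "+"))
  list(a = a, yhat = drop(a %*% w$w2) + w$b2)
}

ann_pack <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)

ann_unpack <- function(theta, H) {
  list(W1 = matrix(theta[seq_len(4 * H)], nrow = H),
       b1 = theta[4 * H + seq_len(H)],
       w2 = theta[5 * H + seq_len(H)],
       b2 = theta[6 * H + 1])
}

ann_jacobian <- function(w, x, fwd) {
  n <- nrow(x)
  H <- length(w$b1)
  d <- (1 - fwd$a^2) * matrix(w$w2, n, H, byrow = TRUE)  # n x H
  J <- matrix(0, n, 6 * H + 1)
  for (j in 1:4) J[, (j - 1) * H + seq_len(H)] <- d * x[, j]
  J[, 4 * H + seq_len(H)] <- d
  J[, 5 * H + seq_len(H)] <- fwd$a
  J[, 6 * H + 1] <- 1
  J
}

#' Train a single-hidden-layer neural surrogate
#'
#' Fits a 4-H-1 feed-forward network (tanh hidden layer, linear output) to
#' predict the response from the four extraction factors. Inputs and targets
#' are min-max scaled to \[-1, 1\]; weights are initialized uniformly on
#' \[-0.5, 0.5\] scaled by 1/sqrt(fan-in), seeded. Training minimizes the
#' training-set MSE by Levenberg-Marquardt steps (damping factor multiplied by
#' 10 on rejection, divided by 10 on acceptance); each accepted step is one
#' epoch. Training stops at `max_epochs`, at `goal_mse`, after
#' `max_validation_failures` consecutive validation-MSE increases, or when the
#' damping factor overflows; the weights with the best validation MSE seen are
#' restored.
#'
#' @param inputs `n x 4` matrix of factor settings (actual units).
#' @param targets Length-`n` response vector (mg/g).
#' @param hidden Number of hidden neurons H (3--12 is the usual sweep range).
#' @param config A [training_config()].
#' @param seed Optional override of `config$seed`.
#' @param split Optional precomputed split (list of `train`, `validation`,
#'   `test` index vectors); by default [split_data()] with the config seed.
#' @return An object of class `neural_surrogate`: topology, weights, scaling
#'   records, seed, the split, and a per-epoch `history` data frame with
#'   train/validation/test MSE on the normalized scale.
#' @export
#' @examples
#' d <- replicate_dataset(sep_design(), 3)
#' net <- train_surrogate(d$inputs, d$targets, hidden = 7,
#'                        config = training_config(seed = 4))
#' fit_correlation(net, d$inputs, d$targets)
train_surrogate <- function(inputs, targets, hidden = 7,
                            config = training_config(), seed = NULL,
                            split = NULL) {
  inputs <- as.matrix(inputs)
  targets <- as.numeric(targets)
  if (nrow(inputs) != length(targets)) stop("inputs/targets length mismatch")
  if (ncol(inputs) != 4) stop("surrogate expects 4 input factors")
  H <- as.integer(hidden)
  if (H < 1) stop("hidden must be >= 1")
  if (is.null(seed)) seed <- config$seed
  n <- nrow(inputs)
  if (is.null(split)) split <- split_data(n, config$fractions, seed = seed)

  in_rec <- minmax_record(inputs)
  out_rec <- minmax_record(matrix(targets, ncol = 1))
  x <- minmax_scale(inputs, in_rec)
  t_all <- drop(minmax_scale(matrix(targets, ncol = 1), out_rec))

  w <- local_rng(seed, list(
    W1 = matrix(stats::runif(4 * H, -0.5, 0.5) / sqrt(4), nrow = H),
    b1 = stats::runif(H, -0.5, 0.5),
    w2 = stats::runif(H, -0.5, 0.5) / sqrt(H),
    b2 = stats::runif(1, -0.5, 0.5)))

  xt <- x[split$train, , drop = FALSE]; tt <- t_all[split$train]
  xv <- x[split$validation, , drop = FALSE]; tv <- t_all[split$validation]
  xs <- x[split$test, , drop = FALSE]; ts <- t_all[split$test]
  mse <- function(w, x, t) mean((ann_forward(w, x)$yhat - t)^2)

  mu <- 1e-3; mu_max <- 1e10
  theta <- ann_pack(w)
  train_mse <- mse(w, xt, tt)
  best_val <- mse(w, xv, tv)
  best_theta <- theta
  failures <- 0
  hist <- list()
  epoch <- 0
  while (epoch < config$max_epochs && train_mse > config$goal_mse) {
    fwd <- ann_forward(w, xt)
    r <- fwd$yhat - tt
    if (!all(is.finite(r)))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    J <- ann_jacobian(w, xt, fwd)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(solve(JtJ + mu * diag(ncol(J)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- ann_unpack(theta + drop(step), H)
        cand_mse <- mse(cand, xt, tt)
        if (is.finite(cand_mse) && cand_mse < train_mse) {
          theta <- theta + drop(step)
          w <- cand
          train_mse <- cand_mse
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break  # damping overflow: local minimum reached
    epoch <- epoch + 1
    val_mse <- mse(w, xv, tv)
    hist[[epoch]] <- c(epoch = epoch, train_mse = train_mse,
                       val_mse = val_mse, test_mse = mse(w, xs, ts), mu = mu)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_theta <- theta
      failures <- 0
    } else {
      failures <- failures + 1
      if (failures >= config$max_validation_failures) break
    }
  }
  w <- ann_unpack(best_theta, H)
  history <- as.data.frame(do.call(rbind, hist))
  structure(
    list(topology = c(4L, H, 1L), weights = w, input_scaling = in_rec,
         output_scaling = out_rec, seed = as.integer(seed), split = split,
         history = history, epochs = as.integer(epoch),
         final_mse = list(train = mse(w, xt, tt), validation = best_val,
                          test = mse(w, xs, ts))),
    class = "neural_surrogate")
}

#' @export
print.neural_surrogate <- function(x, ...) {
  cat(sprintf("Neural surrogate %d-%d-%d, %d epochs, seed %d\n",
              x$topology[1], x$topology[2], x$topology[3], x$epochs, x$seed))
  cat(sprintf("MSE (normalized): train %.3g, validation %.3g, test %.3g\n",
              x$final_mse$train, x$final_mse$validation, x$final_mse$test))
  invisible(x)
}

#' Predict protein content from a trained surrogate
#'
#' Scales the inputs with the stored min-max records, runs the forward pass,
#' and unscales the output back to mg/g. Deterministic and vectorized.
#'
#' @param object A `neural_surrogate`.
#' @param newdata A point (length-4 vector) or `m x 4` matrix in actual units.
#' @param ... Unused.
#' @return Numeric vector of predictions (mg/g).
#' @export
predict.neural_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  x <- minmax_scale(as.matrix(newdata), object$input_scaling)
  z <- ann_forward(object$weights, x)$yhat
  drop(minmax_unscale(matrix(z, ncol = 1), object$output_scaling))
}

#' Sweep the number of hidden neurons
#'
#' Trains one surrogate per candidate hidden-layer size and selects the one
#' with the lowest validation MSE (ties broken toward the smaller network).
#' All candidates share the same data split and seed so that only the
#' topology varies.
#'
#' @param inputs,targets As in [train_surrogate()].
#' @param h_range Candidate hidden sizes (default 3:12).
#' @param config A [training_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `hidden_sweep`: `table` (data frame with columns
#'   `hidden`, `val_mse`, `epochs`), `selected` (chosen H) and `best`
#'   (the selected `neural_surrogate`).
#' @export
sweep_hidden <- function(inputs, targets, h_range = 3:12,
                         config = training_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  split <- split_data(nrow(as.matrix(inputs)), config$fractions, seed = seed)
  fits <- lapply(h_range, function(H)
    train_surrogate(inputs, targets, hidden = H, config = config,
                    seed = seed, split = split))
  tab <- data.frame(hidden = as.integer(h_range),
                    val_mse = vapply(fits, function(f) f$final_mse$validation,
                                     numeric(1)),
                    epochs = vapply(fits, function(f) f$epochs, integer(1)))
  sel <- which(tab$val_mse == min(tab$val_mse))[1]
  structure(list(table = tab, selected = tab$hidden[sel], best = fits[[sel]]),
            class = "hidden_sweep")
}

#' @export
print.hidden_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected hidden size:", x$selected, "\n")
  invisible(x)
}

#' Correlation between surrogate predictions and measurements
#'
#' Pearson correlation of the surrogate's predictions against the targets over
#' the full dataset, the usual single-number summary of surrogate fit.
#'
#' @param net A trained `neural_surrogate`.
#' @param inputs,targets The evaluation dataset.
#' @return A correlation in \[-1, 1\].
#' @export
fit_correlation <- function(net, inputs, targets) {
  targets <- as.numeric(targets)
  if (stats::sd(targets) == 0)
    stop("correlation undefined: targets have zero variance")
  stats::cor(predict(net, inputs), targets)
}

#' Pooled within-replicate variance of a replicated dataset
#'
#' Groups rows by distinct input settings and pools the within-group
#' variances: sum over groups of (n_i - 1) S_i^2 divided by (N - r). This is
#' a replication-noise diagnostic, distinct from any model's prediction MSE;
#' it is zero for exactly duplicated targets.
#'
#' @param inputs `N x 4` input matrix.
#' @param targets Length-`N` target vector.
#' @return The pooled variance (response units squared).
#' @export
pooled_replicate_mse <- function(inputs, targets) {
  key <- apply(round(as.matrix(inputs), 10), 1, paste, collapse = "|")
  groups <- split(as.numeric(targets), key)
  N <- length(targets)
  r <- length(groups)
  if (N <= r) stop("no replicated inputs: pooled variance undefined")
  sum(vapply(groups, function(y) (length(y) - 1) * stats::var(y), numeric(1)),
      na.rm = TRUE) / (N - r)
}

#' Serialize a surrogate to JSON and back
#'
#' Stores topology, weights, scaling records, seed and epoch count; reading
#' restores an object whose predictions equal the original's.
#'
#' @param net A `neural_surrogate`.
#' @param path JSON file path.
#' @return `write_surrogate_json()` returns `path` invisibly;
#'   `read_surrogate_json()` returns a `neural_surrogate`.
#' @export
write_surrogate_json <- function(net, path) {
  obj <- list(topology = net$topology,
              W1 = net$weights$W1, b1 = net$weights$b1,
              w2 = net$weights$w2, b2 = net$weights$b2,
              input_min = net$input_scaling$min,
              input_max = net$input_scaling$max,
              output_min = net$output_scaling$min,
              output_max = net$output_scaling$max,
              seed = net$seed, epochs = net$epochs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- o$topology[2]
  structure(
    list(topology = as.integer(o$topology),
         weights = list(W1 = matrix(o$W1, nrow = H), b1 = o$b1,
                        w2 = o$w2, b2 = o$b2),
         input_scaling = list(min = o$input_min, max = o$input_max),
         output_scaling = list(min = o$output_min, max = o$output_max),
         seed = as.integer(o$seed), split = NULL, history = NULL,
         epochs = as.integer(o$epochs), final_mse = NULL),
    class = "neural_surrogate")
}
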