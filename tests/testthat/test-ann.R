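test_that("replicate_dataset duplicates runs in order", {
  d <- sep_design()
  r3 <- replicate_dataset(d, 3)
  expect_equal(nrow(r3$inputs), 87)
  expect_length(r3$targets, 87)
  expect_equal(r3$inputs[1:3, ], d$settings[c(1, 1, 1), ])
  key <- apply(r3$inputs, 1, paste, collapse = "|")
  expect_true(all(table(key) %% 3 == 0))

  r1 <- replicate_dataset(d, 1)
  expect_equal(r1$inputs, d$settings)
  expect_equal(r1$targets, d$response)
  expect_error(replicate_dataset(d, 0), ">= 1")
})

test_that("split_data uses largest-remainder sizes and is a seeded partition", {
  s <- split_data(87, seed = 1)
  expect_equal(lengths(s), c(train = 61, validation = 13, test = 13))
  expect_equal(sort(unlist(s)), 1:87, ignore_attr = TRUE)

  s10 <- split_data(10, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(unname(lengths(s10)), c(7, 2, 1))

  expect_identical(split_data(87, seed = 42), split_data(87, seed = 42))
  expect_false(identical(split_data(87, seed = 1), split_data(87, seed = 2)))
  expect_error(split_data(2), "at least 3")
  expect_error(split_data(20, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("a constant target is learned immediately by the bias", {
  set.seed(5)
  x <- matrix(runif(40, 50, 70), 10, 4)
  net <- train_surrogate(x, rep(42, 10), hidden = 3,
                         config = training_config(seed = 1, max_epochs = 5))
  expect_lt(net$final_mse$train, 1e-6)
  expect_equal(predict(net, x), rep(42, 10), tolerance = 1e-4)
})

test_that("a noiseless linear map is fitted to numerical precision", {
  set.seed(7)
  x <- matrix(runif(240, -1, 1), 60, 4)
  y <- 50 + x %*% c(3, -2, 1, 0.5)
  ok <- vapply(1:3, function(s) {
    net <- train_surrogate(x, y, hidden = 5,
                           config = training_config(seed = s,
                                                    max_epochs = 200))
    net$final_mse$train < 1e-6
  }, logical(1))
  expect_true(any(ok))
})

test_that("Levenberg-Marquardt training matches an nls.lm oracle on a noiseless problem", {
  skip_if_not_installed("minpack.lm")
  # both optimizers should drive the same 4-3-1 architecture to (near) zero
  # residual on data generated by such a network
  set.seed(13)
  H <- 3
  w_true <- list(W1 = matrix(runif(12, -1, 1), H), b1 = runif(H, -0.5, 0.5),
                 w2 = runif(H, -1, 1), b2 = 0.2)
  x <- matrix(runif(200, -1, 1), 50, 4)
  a <- tanh(sweep(x %*% t(w_true$W1), 2, w_true$b1, "+"))
  y_scaled <- drop(a %*% w_true$w2) + w_true$b2
  y <- 50 + 5 * y_scaled  # arbitrary affine map to "mg/g"

  net <- train_surrogate(x, y, hidden = H,
                         config = training_config(seed = 2, max_epochs = 500,
                                                  max_validation_failures = 500))
  oracle <- minpack.lm::nls.lm(
    par = rnorm(6 * H + 1, sd = 0.5),
    fn = function(p) {
      W1 <- matrix(p[1:(4 * H)], H)
      b1 <- p[4 * H + 1:H]; w2 <- p[5 * H + 1:H]; b2 <- p[6 * H + 1]
      drop(tanh(sweep(x %*% t(W1), 2, b1, "+")) %*% w2) + b2 - y_scaled
    },
    control = minpack.lm::nls.lm.control(maxiter = 500))
  oracle_mse <- mean(oracle$fvec^2)
  expect_lt(oracle_mse, 1e-8)
  expect_lt(net$final_mse$train, 1e-6)
})

test_that("training is seeded-deterministic and its loss is monotone", {
  d <- replicate_dataset(sep_design(), 3)
  n1 <- train_surrogate(d$inputs, d$targets, 7, seed = 4)
  n2 <- train_surrogate(d$inputs, d$targets, 7, seed = 4)
  expect_identical(n1$weights, n2$weights)
  pt <- c(59.4, 3.0, 0.24, 65.2)
  expect_identical(predict(n1, pt), predict(n2, pt))

  for (s in c(1, 5, 9)) {
    h <- train_surrogate(d$inputs, d$targets, 7, seed = s)$history
    expect_false(is.unsorted(rev(h$train_mse)))
  }
})

test_that("the surrogate interpolates a noiseless quadratic within 0.5 mg/g", {
  sim <- make_study_like(simulation_spec(sigma = 0, seed = 2))
  r <- sim$replicated
  nets <- lapply(1:5, function(s)
    train_surrogate(r$inputs, r$targets, hidden = 7,
                    config = training_config(seed = s, max_epochs = 300)))
  best <- nets[[which.min(vapply(nets, function(n) n$final_mse$validation,
                                 numeric(1)))]]
  truth <- eval_quadratic(sep_reference_coefficients(),
                          code_points(sim$design$settings, sim$design$space))
  expect_lt(max(abs(predict(best, sim$design$settings) - truth)), 0.5)
})

test_that("sweep_hidden tabulates every candidate and selects the argmin", {
  sim <- make_study_like(simulation_spec(sigma = 0, seed = 3))
  sw <- sweep_hidden(sim$replicated$inputs, sim$replicated$targets,
                     h_range = 3:7, config = training_config(seed = 2))
  expect_equal(sw$table$hidden, 3:7)
  expect_equal(nrow(sw$table), 5)
  expect_true(all(sw$table$val_mse[sw$table$hidden == sw$selected] <=
                    sw$table$val_mse))
  expect_equal(sw$best$topology[2], sw$selected)
})

test_that("fit_correlation is Pearson correlation with guarded degeneracies", {
  d <- replicate_dataset(sep_design(), 3)
  net <- train_surrogate(d$inputs, d$targets, 7, seed = 1)
  r <- fit_correlation(net, d$inputs, d$targets)
  expect_equal(r, cor(predict(net, d$inputs), d$targets))
  expect_gt(r, 0.99)
  expect_error(fit_correlation(net, d$inputs, rep(5, 87)), "zero variance")

  # a surrogate fitted to a noiseless surface correlates essentially perfectly
  sim <- make_study_like(simulation_spec(sigma = 0, seed = 4))
  nets <- lapply(1:3, function(s)
    train_surrogate(sim$replicated$inputs, sim$replicated$targets, 7, seed = s))
  cors <- vapply(nets, fit_correlation, numeric(1),
                 inputs = sim$replicated$inputs,
                 targets = sim$replicated$targets)
  expect_gt(max(cors), 0.999)
})

test_that("pooled replicate variance matches the hand-computed group formula", {
  x <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 1),
             c(2, 2, 2, 2), c(2, 2, 2, 2), c(2, 2, 2, 2))
  y <- c(1, 3, 0, 0, 3)
  # groups: var(1,3) = 2 (1 df); var(0,0,3) = 3 (2 df); pooled = 8/3
  expect_equal(pooled_replicate_mse(x, y), 8 / 3)

  # on the exactly replicated study set the only within-group scatter is the
  # center group: 3 copies each of the 5 center responses over 87 - 25 df
  d <- replicate_dataset(sep_design(), 3)
  yc <- sep_design()$response[c(12, 14, 18, 21, 29)]
  expect_equal(pooled_replicate_mse(d$inputs, d$targets),
               3 * sum((yc - mean(yc))^2) / (87 - 25))
  expect_error(pooled_replicate_mse(matrix(1:20, 5), 1:5), "no replicated")
})

test_that("surrogates survive a JSON round trip with identical predictions", {
  d <- replicate_dataset(sep_design(), 3)
  net <- train_surrogate(d$inputs, d$targets, 7, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate_json(net, path)
  net2 <- read_surrogate_json(path)
  grid <- d$inputs[seq(1, 87, by = 5), ]
  expect_equal(predict(net2, grid), predict(net, grid), tolerance = 1e-12)
  expect_equal(net2$topology, net$topology)
})
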