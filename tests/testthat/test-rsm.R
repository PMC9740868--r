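test_that("the quadratic model matrix has the documented basis and full rank", {
  X <- build_model_matrix(matrix(0, 1, 4))
  expect_equal(drop(X), c(1, rep(0, 14)), ignore_attr = TRUE)
  expect_equal(colnames(X),
               c("(Intercept)", "A", "B", "C", "D", "AB", "AC", "AD",
                 "BC", "BD", "CD", "A2", "B2", "C2", "D2"))

  X2 <- build_model_matrix(matrix(c(1, 0, 0, 1), 1, 4))
  on <- c("(Intercept)", "A", "D", "AD", "A2", "D2")
  expect_equal(unname(X2[1, on]), rep(1, 6))
  expect_equal(unname(X2[1, setdiff(colnames(X2), on)]), rep(0, 9))

  d <- sep_design()
  Xf <- build_model_matrix(code_points(d$settings, d$space))
  expect_equal(qr(Xf)$rank, 15)
})

test_that("fit_quadratic is least squares: oracle match, exact recovery, run-order invariance", {
  d <- sep_design()
  fit <- fit_quadratic(d)

  # independent oracle: stats::lm on the coded data frame
  cd <- as.data.frame(code_points(d$settings, d$space))
  names(cd) <- c("a", "b", "c", "dd")
  cd$y <- d$response
  lmfit <- lm(y ~ a + b + c + dd + a:b + a:c + a:dd + b:c + b:dd + c:dd +
                I(a^2) + I(b^2) + I(c^2) + I(dd^2), data = cd)
  expect_equal(unname(coef(fit)[["(Intercept)"]]),
               unname(coef(lmfit)[["(Intercept)"]]), tolerance = 1e-10)
  expect_equal(fit$sse, sum(resid(lmfit)^2), tolerance = 1e-10)
  expect_equal(sort(unname(coef(fit))), sort(unname(coef(lmfit))),
               tolerance = 1e-10)

  # printed-equation reproduction (2 d.p.)
  expect_equal(round(coef(fit)[["(Intercept)"]], 2), 55.58)
  expect_equal(round(coef(fit)[["A"]], 2), 3.56)
  expect_equal(round(coef(fit)[["D2"]], 2), -5.16)

  # noiseless responses from a known coefficient vector are recovered exactly
  theta <- test_theta()
  base <- bbd_design(d$space)
  sim <- simulate_response(simulation_spec(theta = theta, sigma = 0), base)
  expect_lt(max(abs(coef(fit_quadratic(sim)) - theta)), 1e-10)

  # permuting run order leaves the fit unchanged
  perm <- sample(29)
  dp <- design_table(d$settings[perm, ], d$space, response = d$response[perm])
  expect_equal(coef(fit_quadratic(dp)), coef(fit), tolerance = 1e-12)

  # rank-deficient designs are refused
  flat <- design_table(matrix(rep(c(60, 3, 0.25, 60), each = 16), 16, 4),
                       d$space, response = rep(50, 16))
  expect_error(fit_quadratic(flat), "singular")
})

test_that("predictions evaluate the coded polynomial", {
  d <- sep_design()
  fit <- fit_quadratic(d)
  expect_equal(round(predict(fit, c(60, 2, 0.25, 50)), 2), 44.41)
  expect_equal(predict(fit, c(60, 3, 0.25, 60)),
               unname(coef(fit)[["(Intercept)"]]))
  expect_equal(predict(fit, c(62.5, 3.0, 0.25, 62.2)), 56.50,
               tolerance = 0.05 / 56.5)
  expect_warning(predict(fit, c(90, 3, 0.25, 60)), "outside")

  coded <- matrix(c(0.3, -0.7, 0.1, 0.9), 1, 4)
  expect_equal(predict(fit, decode_points(coded, d$space)),
               eval_quadratic(coef(fit), coded), tolerance = 1e-10)
})

test_that("the ANOVA reproduces the study table and its decompositions", {
  d <- sep_design()
  fit <- fit_quadratic(d)
  a <- rsm_anova(fit, d)
  row <- function(src) a[a$source == src, ]

  expect_equal(row("Model")$F, 27.70, tolerance = 0.1 / 27.7)
  expect_equal(row("A")$sum_sq, 152.24, tolerance = 0.2 / 152)
  expect_equal(row("A")$F, 91.82, tolerance = 0.2 / 91.8)
  expect_equal(row("Pure error")$sum_sq, 2.79, tolerance = 0.01)
  expect_equal(row("Pure error")$df, 4)
  expect_equal(row("Residual")$sum_sq, 23.21, tolerance = 0.05 / 23.2)
  expect_equal(row("Lack of fit")$p, 0.1558, tolerance = 0.01)

  # sum-of-squares identities
  expect_equal(row("Model")$sum_sq + row("Residual")$sum_sq,
               row("Cor total")$sum_sq, tolerance = 1e-6)
  expect_equal(row("Lack of fit")$sum_sq + row("Pure error")$sum_sq,
               row("Residual")$sum_sq, tolerance = 1e-6)
  expect_equal(row("Model")$df, 14)
  expect_equal(row("Residual")$df, 29 - 15)

  expect_equal(attr(a, "r2"), 0.9652, tolerance = 5e-4)
  expect_equal(attr(a, "adj_r2"), 0.9303, tolerance = 5e-4)
  expect_equal(attr(a, "pred_r2"), 0.8169, tolerance = 5e-4)
  expect_equal(attr(a, "std_dev"), 1.29, tolerance = 0.005)
  expect_true(attr(a, "pred_r2") <= attr(a, "adj_r2"))
  expect_true(attr(a, "adj_r2") <= attr(a, "r2"))
})

test_that("partial sums of squares match drop-term refits and the BBD closed form", {
  d <- sep_design()
  fit <- fit_quadratic(d)
  a <- rsm_anova(fit, d)
  X <- build_model_matrix(code_points(d$settings, d$space))
  y <- d$response

  # brute-force drop-term oracle via lm.fit on the reduced matrix
  for (term in c("A", "BD", "C2")) {
    j <- which(colnames(X) == term)
    red <- lm.fit(X[, -j, drop = FALSE], y)
    expect_equal(a[a$source == term, "sum_sq"],
                 sum(red$residuals^2) - fit$sse, tolerance = 1e-8)
  }

  # on an exact BBD, linear partial SS = 12 beta^2, interaction SS = 4 beta^2
  for (term in c("A", "B", "C", "D"))
    expect_equal(a[a$source == term, "sum_sq"],
                 12 * coef(fit)[[term]]^2, tolerance = 1e-8)
  for (term in c("AB", "AC", "AD", "BC", "BD", "CD"))
    expect_equal(a[a$source == term, "sum_sq"],
                 4 * coef(fit)[[term]]^2, tolerance = 1e-8)
})

test_that("lack of fit is omitted with a warning when nothing replicates", {
  fs <- sep_factor_space()
  set.seed(21)
  pts <- sweep(sweep(matrix(runif(20 * 4), 20, 4), 2, fs$high - fs$low, "*"),
               2, fs$low, "+")
  sim <- simulate_response(simulation_spec(sigma = 0.5, seed = 3),
                           design_table(pts, fs))
  fit <- fit_quadratic(sim)
  expect_warning(a <- rsm_anova(fit, sim), "no replicated runs")
  expect_false(any(a$source == "Lack of fit"))
})

test_that("residual normal scores use Blom plotting positions on sorted residuals", {
  d <- sep_design()
  fit <- fit_quadratic(d)
  ns <- residual_normal_scores(fit)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
  expect_equal(sum(ns$residual^2), 23.21, tolerance = 0.05)
  expect_false(is.unsorted(ns$residual))
  expect_false(is.unsorted(ns$normal_quantile))
  expect_equal(ns$normal_quantile,
               qnorm(((1:29) - 0.375) / (29 + 0.25)))

  # a perfect fit has all-zero residuals
  base <- bbd_design(d$space)
  sim <- simulate_response(simulation_spec(theta = test_theta(), sigma = 0),
                           base)
  expect_equal(residual_normal_scores(fit_quadratic(sim))$residual,
               rep(0, 29), tolerance = 1e-10)
})

test_that("optimize_surface finds the box-constrained maximum", {
  fs <- sep_factor_space()
  d <- sep_design()

  # separable concave surface: optimum at the center, value = intercept
  theta0 <- c(10, rep(0, 4), rep(0, 6), rep(-1, 4))
  sim <- simulate_response(simulation_spec(theta = theta0, sigma = 0),
                           bbd_design(fs))
  o <- optimize_surface(fit_quadratic(sim))
  expect_equal(o$value, 10, tolerance = 1e-6)
  expect_equal(unname(o$coded), rep(0, 4), tolerance = 1e-3)

  # monotone direction pushes the optimum to the +1 boundary
  theta1 <- theta0
  theta1[2] <- 2    # linear A slope
  theta1[12] <- 0   # no A curvature
  o1 <- optimize_surface(fit_quadratic(
    simulate_response(simulation_spec(theta = theta1, sigma = 0),
                      bbd_design(fs))))
  expect_equal(unname(o1$coded[1]), 1, tolerance = 1e-6)

  # study fit: must match the dense grid oracle and clear the verified optimum
  fit <- fit_quadratic(d)
  opt <- optimize_surface(fit)
  expect_gte(opt$value, 56.50)
  expect_equal(opt$value, grid_max_quadratic(coef(fit), step = 0.1),
               tolerance = 0.05 / 56)
  expect_true(all(opt$coded >= -1 - 1e-8 & opt$coded <= 1 + 1e-8))
})
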