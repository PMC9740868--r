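quad_term_names <- function() {
  pairs <- utils::combn(4, 2)
  f <- c("A", "B", "C", "D")
  c("(Intercept)", f,
    apply(pairs, 2, function(p) paste0(f[p[1]], f[p[2]])),
    paste0(f, "2"))
}

#' Build the full quadratic model matrix on the coded scale
#'
#' Columns, in order: intercept, the 4 linear terms A--D, the 6 pairwise
#' interactions AB, AC, AD, BC, BD, CD, and the 4 pure quadratics A2--D2.
#'
#' @param coded An `n x 4` matrix of coded settings.
#' @return An `n x 15` numeric matrix with term-named columns.
#' @export
build_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  if (ncol(coded) != 4) stop("expected 4 coded columns")
  if (!all(is.finite(coded))) stop("coded settings must be finite")
  pairs <- utils::combn(4, 2)
  inter <- sapply(seq_len(ncol(pairs)), function(p)
    coded[, pairs[1, p]] * coded[, pairs[2, p]])
  X <- cbind(1, coded, matrix(inter, nrow = nrow(coded)), coded^2)
  colnames(X) <- quad_term_names()
  X
}

#' Fit the full quadratic response-surface model
#'
#' Ordinary least squares on the coded scale: 15 coefficients (intercept, 4
#' linear, 6 interaction, 4 quadratic). The fit is invariant to run order.
#'
#' @param design A [design_table()] with a response and at least 16 runs.
#' @return An object of class `rsm_fit` with elements `coefficients` (named,
#'   coded scale), `space`, `n`, `fitted`, `residuals`, `sse`, `hat`
#'   (leverages, used for PRESS) and the coded model matrix `X`.
#' @export
#' @examples
#' fit <- fit_quadratic(sep_design())
#' coef(fit)[["(Intercept)"]]
fit_quadratic <- function(design) {
  if (is.null(design$response)) stop("design has no response to fit")
  n <- nrow(design$settings)
  if (n < 16) stop("need at least 16 runs to fit 15 coefficients, got ", n)
  X <- build_model_matrix(code_points(design$settings, design$space))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular fit: model matrix has rank ", qrX$rank, " < ", ncol(X))
  beta <- qr.coef(qrX, design$response)
  fitted <- drop(X %*% beta)
  res <- design$response - fitted
  Q <- qr.Q(qrX)
  structure(
    list(coefficients = beta, space = design$space, n = n, X = X,
         settings = design$settings,
         response = design$response, fitted = fitted, residuals = res,
         sse = sum(res^2), hat = rowSums(Q^2)),
    class = "rsm_fit")
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat("Quadratic response-surface fit (coded scale), n =", x$n, "\n")
  print(round(x$coefficients, digits))
  cat("SSE:", format(x$sse, digits = digits), "\n")
  invisible(x)
}

#' Predict protein content from a fitted response surface
#'
#' Evaluates the coded-scale polynomial at settings given in actual units.
#' Settings outside the factor box are allowed with a warning (the quadratic
#' extrapolates, but the design gives it no support there).
#'
#' @param object An `rsm_fit`.
#' @param newdata A point (length-4 vector) or `m x 4` matrix of settings in
#'   actual units; defaults to the training settings.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (mg/g).
#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  coded <- code_points(newdata, object$space)
  if (any(coded < -1 - 1e-8) || any(coded > 1 + 1e-8))
    warning("predicting outside the factor box: the model extrapolates there")
  drop(build_model_matrix(coded) %*% object$coefficients)
}

#' ANOVA for a quadratic response-surface fit
#'
#' Partial (drop-one-term) sums of squares for each of the 14 model terms, the
#' overall model test, and a lack-of-fit decomposition of the residual against
#' pure error from replicated runs. Per-term F statistics divide the term mean
#' square by the residual mean square; the lack-of-fit F divides its mean
#' square by the pure-error mean square. Goodness statistics follow the
#' response-surface conventions: R2 = 1 - SSE/SST,
#' adjusted R2 = 1 - (1 - R2)(n - 1)/(n - p), predicted R2 = 1 - PRESS/SST
#' with PRESS the sum of squared leave-one-out residuals e_i/(1 - h_ii), and
#' std_dev = sqrt(SSE/(n - p)).
#'
#' @param fit An `rsm_fit`.
#' @param design The [design_table()] the model was fitted to (supplies the
#'   replicate structure); defaults to the training data stored in `fit`.
#' @return An object of class `rsm_anova`: a data frame with columns `source`,
#'   `sum_sq`, `df`, `mean_sq`, `F`, `p` and attributes `r2`, `adj_r2`,
#'   `pred_r2`, `std_dev`.
#' @export
#' @examples
#' a <- rsm_anova(fit_quadratic(sep_design()))
#' a[a$source == "Lack of fit", ]
rsm_anova <- function(fit, design = NULL) {
  X <- fit$X
  y <- fit$response
  n <- fit$n
  p <- ncol(X)
  sse <- fit$sse
  sst <- sum((y - mean(y))^2)
  ss_model <- sst - sse
  ms_res <- sse / (n - p)

  terms <- colnames(X)[-1]
  ss_term <- vapply(seq_along(terms), function(j) {
    sub <- qr(X[, -(j + 1), drop = FALSE])
    sum(qr.resid(sub, y)^2) - sse
  }, numeric(1))

  src <- c("Model", terms)
  ss <- c(ss_model, ss_term)
  df <- c(p - 1, rep(1L, length(terms)))
  ms <- ss / df
  Fv <- ms / ms_res
  pv <- stats::pf(Fv, df, n - p, lower.tail = FALSE)

  rows <- data.frame(source = src, sum_sq = ss, df = df, mean_sq = ms,
                     F = Fv, p = pv, stringsAsFactors = FALSE)

  if (is.null(design))
    design <- design_table(fit$settings, fit$space, response = fit$response)
  groups <- replicate_groups(design)
  if (length(groups) == 0) {
    warning("no replicated runs: lack-of-fit decomposition omitted")
    rows <- rbind(rows,
                  data.frame(source = "Residual", sum_sq = sse, df = n - p,
                             mean_sq = ms_res, F = NA, p = NA))
  } else {
    ss_pe <- sum(unlist(lapply(groups, function(i) {
      yi <- y[i]
      sum((yi - mean(yi))^2)
    })))
    df_pe <- sum(lengths(groups)) - length(groups)
    ss_lof <- sse - ss_pe
    df_lof <- (n - p) - df_pe
    F_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p_lof <- stats::pf(F_lof, df_lof, df_pe, lower.tail = FALSE)
    rows <- rbind(rows,
      data.frame(source = c("Residual", "Lack of fit", "Pure error"),
                 sum_sq = c(sse, ss_lof, ss_pe),
                 df = c(n - p, df_lof, df_pe),
                 mean_sq = c(ms_res, ss_lof / df_lof, ss_pe / df_pe),
                 F = c(NA, F_lof, NA), p = c(NA, p_lof, NA)))
  }
  rows <- rbind(rows, data.frame(source = "Cor total", sum_sq = sst,
                                 df = n - 1, mean_sq = NA, F = NA, p = NA))

  r2 <- 1 - sse / sst
  press <- sum((fit$residuals / (1 - fit$hat))^2)
  structure(rows, class = c("rsm_anova", "data.frame"),
            r2 = r2,
            adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
            pred_r2 = 1 - press / sst,
            std_dev = sqrt(ms_res))
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  cat(sprintf("R2 = %.4f  Adjusted R2 = %.4f  Predicted R2 = %.4f  Std. Dev. = %.2f\n",
              attr(x, "r2"), attr(x, "adj_r2"), attr(x, "pred_r2"),
              attr(x, "std_dev")))
  invisible(x)
}

#' Write an ANOVA table to CSV
#'
#' @param anova_table An `rsm_anova`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(anova_table, path) {
  df <- as.data.frame(anova_table)
  df$r2 <- c(attr(anova_table, "r2"), rep(NA, nrow(df) - 1))
  df$adj_r2 <- c(attr(anova_table, "adj_r2"), rep(NA, nrow(df) - 1))
  df$pred_r2 <- c(attr(anova_table, "pred_r2"), rep(NA, nrow(df) - 1))
  df$std_dev <- c(attr(anova_table, "std_dev"), rep(NA, nrow(df) - 1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normal-probability scores of the fit residuals
#'
#' Pairs the ordered residuals with Blom-type normal plotting positions
#' qnorm((i - 0.375)/(n + 0.25)), the data behind a normal-probability plot.
#'
#' @param fit An `rsm_fit`.
#' @return A data frame with columns `residual` (ascending) and
#'   `normal_quantile`.
#' @export
residual_normal_scores <- function(fit) {
  r <- sort(fit$residuals)
  n <- length(r)
  data.frame(residual = r,
             normal_quantile = stats::qnorm((seq_len(n) - 0.375) / (n + 0.25)))
}

#' Box-constrained optimum of a fitted response surface
#'
#' Solves the stationary system of the quadratic (gradient = 0). If the
#' stationary point lies inside the coded box and is the right kind of
#' extremum it is the candidate; in every case the candidate is refined by
#' multi-start L-BFGS-B over the box (a deterministic 3^4 grid of starts plus
#' the clipped stationary point), so saddles and boundary optima are handled.
#'
#' @param fit An `rsm_fit`.
#' @param bounds A `4 x 2` matrix of coded lower/upper bounds; defaults to the
#'   cube \[-1, 1\]^4.
#' @param maximize Maximize (default) or minimize the surface.
#' @return A list with `settings` (actual units), `coded`, `value` (predicted
#'   mg/g at the optimum) and `stationary` (the unconstrained stationary point
#'   in coded units, for reference).
#' @export
#' @examples
#' opt <- optimize_surface(fit_quadratic(sep_design()))
#' opt$value
optimize_surface <- function(fit, bounds = NULL, maximize = TRUE) {
  if (is.null(bounds)) bounds <- cbind(rep(-1, 4), rep(1, 4))
  beta <- fit$coefficients
  b1 <- beta[2:5]
  Bm <- diag(beta[12:15], 4)
  pairs <- utils::combn(4, 2)
  for (k in seq_len(6)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    Bm[i, j] <- Bm[i, j] + beta[5 + k] / 2
    Bm[j, i] <- Bm[j, i] + beta[5 + k] / 2
  }
  eval_coded <- function(x) drop(beta[1] + sum(b1 * x) + t(x) %*% Bm %*% x)
  stationary <- tryCatch(drop(solve(2 * Bm, -b1)), error = function(e) rep(0, 4))

  sign <- if (maximize) -1 else 1
  obj <- function(x) sign * eval_coded(x)
  grad <- function(x) sign * drop(b1 + 2 * Bm %*% x)
  starts <- as.matrix(expand.grid(rep(list(c(-0.9, 0, 0.9)), 4)))
  starts <- rbind(starts, pmin(pmax(stationary, bounds[, 1]), bounds[, 2]))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, gr = grad, method = "L-BFGS-B",
                      lower = bounds[, 1], upper = bounds[, 2])
    if (is.null(best) || o$value < best$value) best <- o
  }
  coded <- best$par
  names(coded) <- fit$space$names
  list(settings = drop(decode_points(coded, fit$space)),
       coded = coded,
       value = eval_coded(coded),
       stationary = stationary)
}
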