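#' Reference coded-scale coefficients of the packaged study
#'
#' The 15 coefficients of the reported extraction response surface, on the
#' coded scale and in model-matrix order (intercept; A, B, C, D; AB, AC, AD,
#' BC, BD, CD; A2, B2, C2, D2).
#'
#' @return A named numeric vector of length 15.
#' @export
sep_reference_coefficients <- function() {
  stats::setNames(
    c(55.58, 3.56, -0.9043, -2.36, 2.38,
      1.16, 0.5888, -1.34, -1.16, -2.07, -0.9455,
      -3.37, -2.48, -5.01, -5.16),
    quad_term_names())
}

#' Specification for simulating Box-Behnken study data
#'
#' Defines the generating quadratic surface and noise level for synthetic
#' designs. Defaults reproduce the packaged study's conditions: the reported
#' coefficient vector, response noise with the pure-error standard deviation
#' sigma = sqrt(0.6967) ~= 0.835 mg/g, 5 center replicates and a 3x
#' replicated surrogate training set.
#'
#' @param theta 15-vector of coded-scale coefficients (model-matrix order).
#' @param sigma Response noise standard deviation (mg/g, >= 0).
#' @param n_center Center replicates for the generated design.
#' @param replicate_k Replication factor for the surrogate training set.
#' @param seed Integer seed.
#' @param space The [factor_space()] to generate over.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(theta = sep_reference_coefficients(),
                            sigma = sqrt(0.6967), n_center = 5,
                            replicate_k = 3, seed = 1L,
                            space = sep_factor_space()) {
  theta <- as.numeric(theta)
  if (length(theta) != 15) stop("theta must have 15 coefficients")
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(theta = stats::setNames(theta, quad_term_names()),
                 sigma = sigma, n_center = as.integer(n_center),
                 replicate_k = as.integer(replicate_k),
                 seed = as.integer(seed), space = space),
            class = "simulation_spec")
}

#' Simulate responses over a design
#'
#' Draws Y_i = x_i' theta + eps_i with eps_i i.i.d. N(0, sigma^2), where x_i
#' is the coded quadratic model row for run i. Seeded and deterministic.
#'
#' @param spec A [simulation_spec()].
#' @param design A [design_table()] (response, if any, is ignored).
#' @param seed Optional override of `spec$seed`.
#' @return The design with the simulated response attached.
#' @export
#' @examples
#' d <- simulate_response(simulation_spec(sigma = 0), bbd_design(sep_factor_space()))
#' d$response[25]  # center run: the intercept
simulate_response <- function(spec, design, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  X <- build_model_matrix(code_points(design$settings, design$space))
  mu <- drop(X %*% spec$theta)
  y <- mu + local_rng(seed, stats::rnorm(length(mu), 0, spec$sigma))
  design_table(design$settings, design$space, response = y, run = design$run)
}

#' Generate a study-like dataset pair
#'
#' One Box-Behnken design with simulated responses plus its k-replicated
#' surrogate training set. Replicates get fresh noise draws when sigma > 0
#' (so they behave like true repeated measurements); with sigma = 0 the
#' replicates are exact duplicates.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A list with `design` (a [design_table()], 29 runs under the
#'   defaults) and `replicated` (`inputs` / `targets`, 87 rows under the
#'   defaults).
#' @export
make_study_like <- function(spec = simulation_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  base <- bbd_design(spec$space, n_center = spec$n_center)
  k <- spec$replicate_k
  n <- nrow(base$settings)
  X <- build_model_matrix(code_points(base$settings, spec$space))
  mu <- drop(X %*% spec$theta)
  draws <- local_rng(seed, stats::rnorm(n * (1 + k), 0, spec$sigma))
  design <- design_table(base$settings, spec$space,
                         response = mu + draws[seq_len(n)], run = base$run)
  idx <- rep(seq_len(n), each = k)
  rep_noise <- if (spec$sigma > 0) draws[n + seq_len(n * k)] else rep(0, n * k)
  list(design = design,
       replicated = list(inputs = base$settings[idx, , drop = FALSE],
                         targets = mu[idx] + rep_noise))
}
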