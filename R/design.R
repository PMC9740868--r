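#' Construct a design table
#'
#' A design table couples run settings in actual units with an optional
#' measured response (mg protein per g powder). Settings must lie inside the
#' factor box; responses, when present, must be strictly positive.
#'
#' @param settings An `n x k` matrix or data frame of factor settings in
#'   actual units.
#' @param space The [factor_space()] the settings live in.
#' @param response Optional numeric vector of length `n` (mg/g).
#' @param run Optional integer run identifiers; defaults to `1:n`.
#'
#' @return An object of class `design_table`: a list with elements `run`,
#'   `settings`, `response` (possibly `NULL`) and `space`.
#' @export
design_table <- function(settings, space, response = NULL, run = NULL) {
  settings <- as_setting_matrix(settings, space)
  n <- nrow(settings)
  tol <- 1e-8
  out_lo <- sweep(settings, 2, space$low, "<") &
    abs(sweep(settings, 2, space$low, "-")) > tol
  out_hi <- sweep(settings, 2, space$high, ">") &
    abs(sweep(settings, 2, space$high, "-")) > tol
  if (any(out_lo | out_hi))
    stop("settings outside the factor box in run(s): ",
         paste(which(rowSums(out_lo | out_hi) > 0), collapse = ", "))
  if (!is.null(response)) {
    response <- as.numeric(response)
    if (length(response) != n)
      stop("response length (", length(response), ") != number of runs (", n, ")")
    if (!all(is.finite(response)) || any(response <= 0))
      stop("responses must be finite and strictly positive")
  }
  if (is.null(run)) run <- seq_len(n)
  structure(list(run = as.integer(run), settings = settings,
                 response = response, space = space),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat("Design table: ", nrow(x$settings), " runs, ",
      length(x$space$names), " factors",
      if (is.null(x$response)) " (no response)" else "", "\n", sep = "")
  print(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x$settings) > 8) cat("... ", nrow(x$settings) - 8, " more runs\n")
  invisible(x)
}

#' @export
as.data.frame.design_table <- function(x, ...) {
  df <- data.frame(run = x$run, x$settings, check.names = FALSE)
  if (!is.null(x$response)) df$response_mg_g <- x$response
  df
}

#' Generate a four-factor Box-Behnken design
#'
#' Produces the 24 edge-midpoint runs (every unordered factor pair at coded
#' (+/-1, +/-1) with the remaining two factors at their centers) plus
#' `n_center` replicated center runs, in actual units. Only the four-factor
#' design is supported.
#'
#' @param space A [factor_space()] with exactly 4 factors.
#' @param n_center Number of center-point replicates (>= 1); 5 gives the
#'   classical 29-run layout.
#'
#' @return A [design_table()] without a response.
#' @export
#' @examples
#' d <- bbd_design(sep_factor_space())
#' nrow(d$settings)
bbd_design <- function(space, n_center = 5) {
  if (length(space$names) != 4)
    stop("bbd_design supports exactly 4 factors, got ", length(space$names))
  n_center <- as.integer(n_center)
  if (n_center < 1) stop("n_center must be >= 1")
  pairs <- utils::combn(4, 2)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))[c(1, 3, 2, 4), ]
  coded <- matrix(0, nrow = 4 * ncol(pairs) + n_center, ncol = 4)
  r <- 0
  for (p in seq_len(ncol(pairs))) {
    for (s in seq_len(4)) {
      r <- r + 1
      coded[r, pairs[, p]] <- signs[s, ]
    }
  }
  design_table(decode_points(coded, space), space)
}

#' The packaged 29-run extraction design
#'
#' The Box-Behnken design table of the selenium-enriched rape protein (SEP)
#' alkaline-extraction study: 24 edge runs and 5 center replicates over
#' temperature, time, alkali concentration and liquid-to-material ratio, with
#' the measured protein content (mg/g) as response.
#'
#' @return A [design_table()] with 29 runs and a response.
#' @seealso [sep_predicted_reference()] for the study's reported fitted values.
#' @export
#' @examples
#' d <- sep_design()
#' mean(d$response)
sep_design <- function() {
  path <- system.file("extdata", "sep_bbd_design.csv", package = "protexopt",
                      mustWork = TRUE)
  read_design_csv(path, sep_factor_space())
}

#' Reported model predictions for the packaged design
#'
#' The fitted protein contents (mg/g, 2 d.p.) reported alongside the 29
#' measured responses, kept separate from [sep_design()] as a reference vector
#' for model-comparison metrics.
#'
#' @return A numeric vector of length 29, in run order.
#' @export
sep_predicted_reference <- function() {
  path <- system.file("extdata", "sep_bbd_predicted.csv", package = "protexopt",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  df$predicted_mg_g[order(df$run)]
}

#' Read or write a design table as CSV
#'
#' The CSV dialect has columns `run`, one column per factor (actual units),
#' and optionally `response_mg_g`.
#'
#' @param path File path.
#' @param space The [factor_space()] used to validate the settings.
#' @param design A [design_table()].
#' @return `read_design_csv()` returns a [design_table()];
#'   `write_design_csv()` returns `path` invisibly.
#' @export
read_design_csv <- function(path, space) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("run", space$names), names(df))
  if (length(missing))
    stop("design CSV is missing column(s): ", paste(missing, collapse = ", "))
  resp <- if ("response_mg_g" %in% names(df)) df$response_mg_g else NULL
  design_table(df[, space$names], space, response = resp, run = df$run)
}

#' @rdname read_design_csv
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' Index groups of replicated runs
#'
#' Groups runs whose settings are identical (to within `tol`); used for the
#' pure-error decomposition of the residual sum of squares.
#'
#' @param design A [design_table()].
#' @param tol Absolute tolerance for treating settings as identical.
#' @return A list of integer row-index vectors, one per group with >= 2 runs.
#' @keywords internal
replicate_groups <- function(design, tol = 1e-8) {
  key <- apply(round(design$settings / tol) * tol, 1, paste, collapse = "|")
  idx <- split(seq_along(key), key)
  unname(idx[lengths(idx) >= 2])
}
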