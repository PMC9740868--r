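# Evaluate a 15-coefficient coded quadratic at coded points, independently of
# the package's model-matrix plumbing (plain arithmetic, used as an oracle).
eval_quadratic <- function(theta, coded) {
  coded <- matrix(coded, ncol = 4)
  pairs <- utils::combn(4, 2)
  apply(coded, 1, function(x) {
    theta[1] + sum(theta[2:5] * x) +
      sum(theta[6:11] * x[pairs[1, ]] * x[pairs[2, ]]) +
      sum(theta[12:15] * x^2)
  })
}

# Dense grid search over the coded box: the brute-force oracle for the box
# maximum of a fitted quadratic surface. Chunked so the 0.05-step grid
# (41^4 points) stays within memory.
grid_max_quadratic <- function(theta, step = 0.05) {
  g <- seq(-1, 1, by = step)
  best <- -Inf
  for (a in g) {
    pts <- as.matrix(expand.grid(a = a, b = g, c = g, d = g))
    vals <- eval_quadratic(theta, pts)
    best <- max(best, max(vals))
  }
  best
}

# A coefficient vector with every term active, for recovery tests.
test_theta <- function() {
  c(50, 2, -1, 1.5, -0.5,
    0.8, -0.6, 0.4, -0.3, 0.7, -0.2,
    -3, -2, -4, -2.5)
}
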