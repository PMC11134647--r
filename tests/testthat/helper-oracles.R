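# Independent oracles used across the suite.

# Sum of coefficient products over every directed path from `from` to `to`,
# by depth-first enumeration of nonzero entries of A (A[i, j] = path j -> i).
# Independent of the matrix-inverse decomposition it checks.
brute_force_total <- function(A, from, to) {
  vars <- rownames(A)
  total <- 0
  walk <- function(node, prod) {
    if (node == to) { total <<- total + prod; return() }
    for (nxt in vars[A[, node] != 0])
      walk(nxt, prod * A[nxt, node])
  }
  walk(from, 1)
  total
}

# Random recursive (strictly lower-triangular under a permutation) path
# matrix with k variables and given edge density.
random_recursive_A <- function(k, density = 0.5) {
  vars <- paste0("v", seq_len(k))
  A <- matrix(0, k, k, dimnames = list(vars, vars))
  for (i in 2:k) for (j in 1:(i - 1))
    if (stats::runif(1) < density)
      A[i, j] <- stats::runif(1, -0.6, 0.6)
  A
}

# Simple three-variable mediation dataset x -> m -> y with direct path.
make_mediation_data <- function(n, a = 0.5, b = 0.4, c = 0.3) {
  x <- stats::rnorm(n)
  m <- a * x + stats::rnorm(n)
  y <- c * x + b * m + stats::rnorm(n)
  data.frame(x = x, m = m, y = y)
}

mediation_model <- function() parse_model("m ~ x\ny ~ x + m")

# Population covariance of the one-factor model with loadings (1, .8, .6),
# factor variance 1, unique variances .5 (hand-evaluated lambda lambda' + Theta).
one_factor_sigma <- function() {
  Sig <- rbind(c(1.5, 0.8, 0.6),
               c(0.8, 1.14, 0.48),
               c(0.6, 0.48, 0.86))
  dimnames(Sig) <- list(c("x1", "x2", "x3"), c("x1", "x2", "x3"))
  Sig
}
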