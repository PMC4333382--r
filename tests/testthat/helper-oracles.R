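# Independent oracles used across the suite.

# brute-force hypergeometric upper tail: direct summation of the pmf from
# choose(), no log-space tricks
hyper_tail_bruteforce <- function(N, K, n, k) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# algebraic two-dose solve of v/v0 = (Ki + beta I)/(Ki + I) as a linear
# system, independently of fit_partial_inhibition
solve_two_dose_inhibition <- function(I1, f1, I2, f2) {
  A <- rbind(c(f1 - 1, -I1), c(f2 - 1, -I2))
  b <- c(-f1 * I1, -f2 * I2)
  sol <- solve(A, b)
  c(Ki_app = sol[1], beta = sol[2])
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
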