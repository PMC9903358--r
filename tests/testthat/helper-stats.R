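# two columns with an exact sample correlation r, built from orthonormal
# residual vectors
exact_cor_pair <- function(n, r, seed = 6) {
  set.seed(seed)
  a <- stats::rnorm(n)
  b <- stats::rnorm(n)
  a <- (a - mean(a)) / stats::sd(a)
  b <- stats::residuals(stats::lm(b ~ a))
  b <- (b - mean(b)) / stats::sd(b)
  data.frame(x1 = a, x2 = r * a + sqrt(1 - r^2) * b)
}
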