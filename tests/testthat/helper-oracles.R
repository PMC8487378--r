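# Independent oracles used across the suite.  These deliberately avoid the
# package's own cdf/pdf code paths.

# cdf of the maximum via the mixture representation:
# sum_z P(Z = z) F_Erl(x)^z with Z zero-truncated binomial(n, p)
mixture_cdf <- function(x, k, lam, n, p) {
  z <- seq_len(n)
  pz <- dbinom(z, n, p) / (1 - (1 - p)^n)
  vapply(x, function(xx) {
    sum(pz * pgamma(xx, shape = k, rate = lam)^z)
  }, numeric(1))
}

# Closed-form inclusion-exclusion moments for the maximum of z i.i.d.
# Erlang(2, lam) lifetimes.  With survival S(x) = e^{-lam x}(1 + lam x),
#   E max = int (1 - F^z) = sum_{i=1}^z (-1)^{i+1} C(z,i) int S^i,
#   int_0^inf S^i dx = (1/(i lam)) sum_{j=0}^i C(i,j) j! / i^j,
#   int_0^inf 2 x S^i dx = (2/lam^2) sum_{j=0}^i C(i,j) (j+1)! / i^{j+2}.
emax_erlang2 <- function(z, lam) {
  vapply(z, function(zz) {
    s <- 0
    for (i in seq_len(zz)) {
      j <- 0:i
      s <- s + (-1)^(i + 1) * choose(zz, i) *
        sum(choose(i, j) * factorial(j) / i^j) / (i * lam)
    }
    s
  }, numeric(1))
}

e2max_erlang2 <- function(z, lam) {
  vapply(z, function(zz) {
    s <- 0
    for (i in seq_len(zz)) {
      j <- 0:i
      s <- s + (-1)^(i + 1) * choose(zz, i) *
        2 * sum(choose(i, j) * factorial(j + 1) / i^(j + 2)) / lam^2
    }
    s
  }, numeric(1))
}

# moments of MaxErlB(2, lam, n, p) by mixing the fixed-count closed forms
# over the zero-truncated binomial count
ie_mean <- function(lam, n, p) {
  z <- seq_len(n)
  pz <- dbinom(z, n, p) / (1 - (1 - p)^n)
  sum(pz * emax_erlang2(z, lam))
}

ie_variance <- function(lam, n, p) {
  z <- seq_len(n)
  pz <- dbinom(z, n, p) / (1 - (1 - p)^n)
  sum(pz * e2max_erlang2(z, lam)) - ie_mean(lam, n, p)^2
}

# central finite difference of a scalar function
central_diff <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
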