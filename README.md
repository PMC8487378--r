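# maxerlb

Tools for the **Max Erlang Binomial (MaxErlB)** lifetime distribution: the
law of the maximum of a random number of independent Erlang lifetimes,
where the count is a zero-truncated binomial variate.  It models the
lifetime of a parallel system whose number of working components is random
but at least one — and, as a flexible positive-valued distribution, it is a
candidate model for survival and remission-time data.  The package is aimed
at biostatisticians and reliability analysts who want the distribution
itself (density through random generation), a seeded simulator, a Pearson
chi-square concordance test, and maximum-likelihood fitting via EM.

## The model

Let $X_1, X_2, \ldots$ be i.i.d. Erlang$(k,\lambda)$ lifetimes and
$Z \sim$ zero-truncated binomial$(n, p)$, independent of them.  Then
$U = \max(X_1, \ldots, X_Z) \sim$ MaxErlB$(k, \lambda, n, p)$ with

$$F(x) = \frac{\bigl(1 - p\,S(x)\bigr)^n - (1-p)^n}{1 - (1-p)^n},
\qquad
f(x) = \frac{n p \lambda^k x^{k-1} e^{-\lambda x}\,
        \bigl(1 - p\,S(x)\bigr)^{n-1}}{(k-1)!\,\bigl(1-(1-p)^n\bigr)},$$

where $S(x) = e^{-\lambda x} \sum_{i=0}^{k-1} (\lambda x)^i / i!$ is the
Erlang survival function.  For $k=1$ this is the complementary exponential
binomial distribution; for $n=1$ the plain Erlang.  The same construction
works for any zero-truncated power-series count family with series function
$A(\Theta)$: cdf $A(\Theta F_{Erl}(x))/A(\Theta)$ — the package registers
the binomial, Poisson, logarithmic, geometric, Pascal and negative-binomial
families.

With $k$ and $n$ known, `maxerlb_em()` estimates $(\lambda, p)$ by EM,
treating the component count behind each observed maximum as the missing
datum: the E-step is the closed-form conditional mean
$E[Z \mid x] = 1 + (n-1)\Theta w/(1+\Theta w)$ with $w = F_{Erl}(x)$ and
$\Theta = p/(1-p)$, and the M-step solves two separated one-dimensional
score equations.

## Worked example

```r
library(maxerlb)

# the distribution at the simulation-study parameters
pmaxerlb(0.2, k = 2, lam = 10, n = 3, p = 0.2)
#> [1] 0.5402499
maxerlb_moments(k = 2, lam = 10, n = 3, p = 0.2)
#> # A tibble: 1 × 3
#>    mean variance    sd
#>   <dbl>    <dbl> <dbl>
#> 1 0.217   0.0215 0.147

# simulate, then test concordance with the generating model
u <- rmaxerlb(1e4, k = 2, lam = 10, n = 3, p = 0.2, seed = 2)
mean(u)
#> [1] 0.2171059
glance(maxerlb_gof(u, 2, 10, 3, 0.2, bins = 12, n_estimated = 4))
#> # A tibble: 1 × 6
#>   statistic    df critical alpha reject     n
#>       <dbl> <dbl>    <dbl> <dbl> <lgl>  <int>
#> 1      9.66     7     14.1  0.05 FALSE  10000

# recover (lambda, p) from synthetic data by EM
w <- rmaxerlb(1e5, k = 2, lam = 1, n = 3, p = 0.5, seed = 123)
fit <- maxerlb_em(w, k = 2, n = 3)
tidy(fit)
#> # A tibble: 2 × 2
#>   term   estimate
#>   <chr>     <dbl>
#> 1 lambda    0.997
#> 2 p         0.497

# the bundled bladder-cancer remission times (128 patients, months)
range(bladder_remission()$months)
#> [1]  0.08 79.05
```

The simulated mean (0.2171 at $m = 10^4$) sits on the analytic mean
0.21674; the chi-square statistic 9.66 is below the df-7 critical value
14.067, so concordance with the generating model is not rejected; and the
EM estimates (0.997, 0.497) recover the generating values (1, 0.5) to
three parts in a thousand at $m = 10^5$.

A command-line wrapper with subcommands `simulate`, `moments`, `gof`,
`fit-em` and `demo-remission` ships at
`system.file("cli", "maxerlb_cli.R", package = "maxerlb")`; see
`vignettes/maxerlb-methods.Rmd` for the methods account.

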