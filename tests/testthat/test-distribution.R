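test_that("cdf matches its closed form, the mixture oracle and limits", {
  # frozen from direct evaluation of the closed form; independently equal to
  # the mixture over the truncated-binomial count (helper oracle)
  expect_equal(pmaxerlb(0.2, 2, 10, 3, 0.2), 0.5402499379, tolerance = 1e-9)
  expect_equal(pmaxerlb(0.2, 2, 10, 3, 0.2),
               mixture_cdf(0.2, 2, 10, 3, 0.2), tolerance = 1e-12)
  expect_equal(pmaxerlb(c(-1, 0), 2, 10, 3, 0.2), c(0, 0))
  expect_equal(pmaxerlb(1e3, 2, 10, 3, 0.2), 1)
  # n = 1: maximum of a single Erlang
  x <- c(0.01, 0.1, 0.5, 2)
  expect_equal(pmaxerlb(x, 2, 10, 1, 0.3), pgamma(x, 2, rate = 10),
               tolerance = 1e-14)
})

test_that("cdf equals the mixture representation over random parameters", {
  set.seed(314)
  for (i in 1:200) {
    k <- sample(1:4, 1); n <- sample(1:8, 1)
    lam <- runif(1, 0.1, 20); p <- runif(1, 0.02, 0.98)
    x <- rexp(1, rate = lam / k)
    expect_equal(pmaxerlb(x, k, lam, n, p), mixture_cdf(x, k, lam, n, p),
                 tolerance = 1e-10)
  }
})

test_that("cdf is monotone and pdf is a nonnegative derivative of it", {
  grid <- seq(0.001, 1.5, length.out = 300)
  cdf <- pmaxerlb(grid, 2, 10, 3, 0.2)
  expect_true(all(diff(cdf) >= 0))
  pdf <- dmaxerlb(grid, 2, 10, 3, 0.2)
  expect_true(all(pdf >= 0))
  for (x0 in c(0.05, 0.2, 0.6)) {
    expect_equal(
      dmaxerlb(x0, 2, 10, 3, 0.2),
      central_diff(function(x) pmaxerlb(x, 2, 10, 3, 0.2), x0, h = 1e-6),
      tolerance = 1e-6
    )
  }
})

test_that("pdf matches its frozen value and integrates to one", {
  expect_equal(dmaxerlb(0.2, 2, 10, 3, 0.2), 2.8093983776, tolerance = 1e-8)
  expect_equal(dmaxerlb(c(-0.5, 0), 2, 10, 3, 0.2), c(0, 0))
  for (case in list(c(2, 10, 3, 0.2), c(1, 2, 5, 0.7), c(3, 0.5, 4, 0.4))) {
    total <- integrate(function(x) dmaxerlb(x, case[1], case[2], case[3],
                                            case[4]),
                       0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("k = 1 reduces to the complementary exponential binomial form", {
  lam <- 2; n <- 4; p <- 0.35
  x <- c(0.05, 0.3, 1, 2.5)
  manual <- n * p * lam * exp(-lam * x) * (1 - p * exp(-lam * x))^(n - 1) /
    (1 - (1 - p)^n)
  expect_equal(dmaxerlb(x, 1, lam, n, p), manual, tolerance = 1e-12)
  manual_cdf <- ((1 - p * exp(-lam * x))^n - (1 - p)^n) / (1 - (1 - p)^n)
  expect_equal(pmaxerlb(x, 1, lam, n, p), manual_cdf, tolerance = 1e-12)
})

test_that("generic power-series compound reproduces the binomial special case", {
  x <- seq(0.01, 2, length.out = 50)
  for (case in list(c(2, 10, 3, 0.2), c(1, 1, 5, 0.6), c(4, 3, 2, 0.45))) {
    k <- case[1]; lam <- case[2]; n <- case[3]; p <- case[4]
    fam <- psd_binomial(n)
    th <- theta_from_p(p)
    expect_equal(dmax_compound(x, fam, th, k, lam),
                 dmaxerlb(x, k, lam, n, p), tolerance = 1e-12)
    expect_equal(pmax_compound(x, fam, th, k, lam),
                 pmaxerlb(x, k, lam, n, p), tolerance = 1e-12)
  }
})

test_that("generic compound cdf differentiates to the compound pdf", {
  fam <- psd_poisson()
  for (x0 in c(0.1, 0.5, 1.2)) {
    expect_equal(
      dmax_compound(x0, fam, 1.5, 2, 3),
      central_diff(function(x) pmax_compound(x, fam, 1.5, 2, 3), x0,
                   h = 1e-6),
      tolerance = 1e-6
    )
  }
  # small-x limit stays finite: density ~ theta f(x) A'(0) / A(theta)
  expect_true(is.finite(dmax_compound(1e-9, fam, 1.5, 1, 3)))
})

test_that("quantile function inverts the cdf", {
  expect_equal(qmaxerlb(0, 2, 10, 3, 0.2), 0)
  expect_equal(qmaxerlb(1, 2, 10, 3, 0.2), Inf)
  expect_equal(qmaxerlb(0.5402499379, 2, 10, 3, 0.2), 0.2, tolerance = 1e-8)
  set.seed(7)
  x <- rexp(50, rate = 5)
  q <- pmaxerlb(x, 2, 10, 3, 0.2)
  expect_equal(qmaxerlb(q, 2, 10, 3, 0.2), x, tolerance = 1e-8)
  u <- runif(50)
  expect_equal(pmaxerlb(qmaxerlb(u, 3, 2, 4, 0.6), 3, 2, 4, 0.6), u,
               tolerance = 1e-10)
  expect_error(qmaxerlb(1.5, 2, 10, 3, 0.2), "lie in")
  expect_error(qmaxerlb(-0.1, 2, 10, 3, 0.2), "lie in")
})

test_that("quadrature moments agree with the inclusion-exclusion oracle", {
  for (case in list(c(10, 3, 0.2), c(1, 3, 0.5), c(2, 5, 0.7),
                    c(0.5, 2, 0.35))) {
    lam <- case[1]; n <- case[2]; p <- case[3]
    expect_equal(maxerlb_mean(2, lam, n, p), ie_mean(lam, n, p),
                 tolerance = 1e-8)
    expect_equal(maxerlb_variance(2, lam, n, p), ie_variance(lam, n, p),
                 tolerance = 1e-8)
  }
  # frozen values for the simulation-study parameter set
  expect_equal(maxerlb_mean(2, 10, 3, 0.2), 0.21674256, tolerance = 1e-7)
  expect_equal(maxerlb_variance(2, 10, 3, 0.2), 0.02147490, tolerance = 1e-7)
})

test_that("moments reduce to plain Erlang at n = 1 and grow in n and p", {
  expect_equal(maxerlb_mean(2, 4, 1, 0.5), 2 / 4, tolerance = 1e-10)
  expect_equal(maxerlb_variance(2, 4, 1, 0.5), 2 / 16, tolerance = 1e-10)
  # maximum over more (or likelier) components is stochastically larger
  means_n <- vapply(1:5, function(n) maxerlb_mean(2, 10, n, 0.3), numeric(1))
  expect_true(all(diff(means_n) > 0))
  means_p <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                    function(p) maxerlb_mean(2, 10, 4, p), numeric(1))
  expect_true(all(diff(means_p) > 0))
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(pmaxerlb(1, 0, 10, 3, 0.2), "integer")
  expect_error(pmaxerlb(1, 2, -1, 3, 0.2), "positive rate")
  expect_error(pmaxerlb(1, 2, 10, 3, 0), "strictly in")
  expect_error(pmaxerlb(1, 2, 10, 3, 1), "strictly in")
  pr <- maxerlb(2, 10, 3, 0.2)
  expect_s3_class(pr, "maxerlb")
  expect_equal(pr$theta, 0.25, tolerance = 1e-12)
})
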