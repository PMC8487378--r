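test_that("conditional mean of the latent count has the right limits and value", {
  # x -> 0: the maximum being tiny forces a single component
  expect_equal(maxerlb_estep(1e-10, lam = 1, p = 0.5), 1, tolerance = 1e-9)
  # x -> Inf: tail-conditional mean of the truncated binomial, 1 + (n-1)p
  expect_equal(maxerlb_estep(1e6, lam = 1, p = 0.5), 1 + 2 * 0.5,
               tolerance = 1e-9)
  expect_equal(maxerlb_estep(1e6, lam = 2, p = 0.3), 1 + 2 * 0.3,
               tolerance = 1e-9)
  # frozen from direct evaluation of the k = 2, n = 3 closed form
  expect_equal(maxerlb_estep(1, lam = 1, p = 0.5), 1.4180233,
               tolerance = 1e-6)
})

test_that("closed-form E-step equals the generic series-function route", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:6, 1); k <- sample(1:3, 1)
    lam <- runif(1, 0.2, 5); p <- runif(1, 0.05, 0.95)
    x <- rexp(25, rate = lam / k)
    a <- maxerlb_estep(x, lam = lam, p = p, k = k, n = n)
    b <- psd_estep(x, psd_binomial(n), theta_from_p(p), k = k, lam = lam)
    expect_equal(a, b, tolerance = 1e-12)
    expect_true(all(a >= 1 & a <= n))
  }
})

test_that("E-step is monotone increasing in the observed maximum", {
  x <- seq(0.01, 10, length.out = 200)
  z <- maxerlb_estep(x, lam = 1, p = 0.4)
  expect_true(all(diff(z) > 0))
})

test_that("rate score vanishes at the Erlang estimator when all counts are one", {
  set.seed(21)
  x <- rerlang(500, 2, 3)
  # with z = 1 the score reduces to mk/lambda - sum(x): root at k / xbar
  root <- 2 / mean(x)
  expect_equal(maxerlb:::lambda_score(root, x, rep(1, 500), 2), 0,
               tolerance = 1e-8)
  # and the full M-step correctly refuses the p -> 0 boundary
  expect_error(maxerlb_mstep(x, rep(1, 500)), "degenerate")
})

test_that("probability update solves the truncated-binomial moment equation", {
  set.seed(22)
  x <- rerlang(400, 2, 1)
  z <- rep(1.5, 400)
  upd <- maxerlb_mstep(x, z)
  # oracle: maximize the complete-data p-likelihood directly on a grid
  cll <- function(p) {
    400 * (1.5 * log(p) + 1.5 * log(1 - p) - log(1 - (1 - p)^3))
  }
  opt <- optimize(cll, c(1e-6, 1 - 1e-6), maximum = TRUE)$maximum
  expect_equal(upd$p, opt, tolerance = 1e-5)
  expect_equal(upd$p, 0.381966, tolerance = 1e-5)
  # raw score form vanishes at the returned root
  expect_equal(maxerlb:::p_score(upd$p, 1.5, 400, 3), 0, tolerance = 1e-8)
  # rate score vanishes at the returned rate
  expect_equal(maxerlb:::lambda_score(upd$lam, x, z, 2), 0, tolerance = 1e-6)
})

test_that("observed log-likelihood is additive and matches the density", {
  expect_equal(maxerlb_loglik(0.2, 2, 10, 3, 0.2),
               log(dmaxerlb(0.2, 2, 10, 3, 0.2)))
  expect_equal(maxerlb_loglik(0.2, 2, 10, 3, 0.2), log(2.8093983776),
               tolerance = 1e-8)
  x <- c(0.1, 0.4, 0.7)
  expect_equal(maxerlb_loglik(c(x, 0.4), 2, 10, 3, 0.2),
               maxerlb_loglik(x, 2, 10, 3, 0.2) +
                 log(dmaxerlb(0.4, 2, 10, 3, 0.2)),
               tolerance = 1e-12)
  # n = 1 reduction to the Erlang log-likelihood
  expect_equal(maxerlb_loglik(x, 2, 5, 1, 0.9),
               sum(dgamma(x, 2, rate = 5, log = TRUE)), tolerance = 1e-12)
  expect_error(maxerlb_loglik(c(1, -1), 2, 10, 3, 0.2), "positive")
})

test_that("EM recovers generating parameters from a large synthetic sample", {
  u <- rmaxerlb(1e5, 2, 1, 3, 0.5, seed = 123)
  fit <- maxerlb_em(u, k = 2, n = 3, epsilon = 1e-6)
  expect_true(fit$converged)
  expect_lt(abs(fit$lambda - 1), 0.02)
  expect_lt(abs(fit$p - 0.5), 0.02)
  # log-likelihood ascends along the whole trace
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  # re-running from the optimum is a fixed point
  refit <- maxerlb_em(u, lam0 = fit$lambda, p0 = fit$p, epsilon = 1e-6)
  expect_lt(abs(refit$lambda - fit$lambda), 1e-4)
  expect_lt(abs(refit$p - fit$p), 1e-4)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, c("lambda", "p"))
  expect_equal(glance(fit)$iterations, fit$iterations)
})

test_that("EM ascends the likelihood on many seeded datasets", {
  set.seed(555)
  for (i in 1:20) {
    u <- rmaxerlb(1000, 2, runif(1, 0.5, 5), 3, runif(1, 0.2, 0.8))
    fit <- maxerlb_em(u, epsilon = 1e-5, max_iter = 400)
    expect_true(all(diff(fit$trace$loglik) >= -1e-8))
    expect_true(all(fit$trace$zbar >= 1 & fit$trace$zbar <= 3))
  }
})

test_that("EM and direct numerical maximum likelihood agree", {
  u <- rmaxerlb(1e4, 2, 1, 3, 0.5, seed = 2026)
  fit <- maxerlb_em(u, epsilon = 1e-8)
  mle <- maxerlb_mle(u)
  expect_lt(abs(fit$lambda - mle$lambda), 1e-3)
  expect_lt(abs(fit$p - mle$p), 1e-3)
  # gradient of the observed log-likelihood vanishes at the EM solution
  g1 <- central_diff(function(l) maxerlb_loglik(u, 2, l, 3, fit$p),
                     fit$lambda, h = 1e-5)
  g2 <- central_diff(function(p) maxerlb_loglik(u, 2, fit$lambda, 3, p),
                     fit$p, h = 1e-5)
  expect_lt(abs(g1) / length(u), 1e-4)
  expect_lt(abs(g2) / length(u), 1e-4)
})

test_that("direct MLE is stable to starting-value perturbation", {
  u <- rmaxerlb(5000, 2, 1, 3, 0.5, seed = 31)
  base <- maxerlb_mle(u)
  for (f in c(0.5, 1.5)) {
    alt <- maxerlb_mle(u, init = c(base$lambda * f,
                                   min(0.95, base$p * f)))
    expect_lt(abs(alt$lambda - base$lambda), 1e-3)
    expect_lt(abs(alt$p - base$p), 1e-3)
  }
})

test_that("degenerate and invalid inputs surface as errors, not wrong answers", {
  expect_error(maxerlb_em(c(1, 2, 0)), "positive")
  expect_error(maxerlb_em(numeric(0)), "nonempty")
  expect_error(maxerlb_em(c(1, 2, 3), p0 = 1.5), "invalid starting")
  u <- rmaxerlb(2000, 2, 1, 3, 0.5, seed = 4)
  capped <- maxerlb_em(u, max_iter = 3)
  expect_false(capped$converged)
  expect_equal(capped$iterations, 3L)
  expect_warning(maxerlb_mle(rerlang(100, 2, 1), n = 1), "unidentified")
})
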