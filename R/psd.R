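#' Zero-truncated power-series count families
#'
#' A power-series distribution (PSD) on the positive integers has mass
#' function \eqn{P(Z = z) = a_z \Theta^z / A(\Theta)}, where the \eqn{a_z \ge 0}
#' are fixed coefficients, \eqn{\Theta \in (0, \tau)} is the power parameter
#' and \eqn{A(\Theta) = \sum_{z \ge 1} a_z \Theta^z} is the series function.
#' Because the sum starts at \eqn{z = 1}, every family here is zero-truncated:
#' it models a component count that is known to be at least one.
#'
#' `psd_family()` builds a family object from its ingredients; the
#' constructors below register the classical families:
#'
#' * `psd_binomial(n)` — zero-truncated binomial, \eqn{a_z = \binom{n}{z}},
#'   \eqn{A(\Theta) = (1+\Theta)^n - 1}, \eqn{\Theta = p/(1-p)};
#' * `psd_poisson()` — zero-truncated Poisson, \eqn{a_z = 1/z!},
#'   \eqn{A(\Theta) = e^\Theta - 1};
#' * `psd_logarithmic()` — logarithmic, \eqn{a_z = 1/z},
#'   \eqn{A(\Theta) = -\log(1-\Theta)}, \eqn{\tau = 1};
#' * `psd_geometric()` — geometric on \eqn{z \ge 1}, \eqn{a_z = 1},
#'   \eqn{A(\Theta) = \Theta/(1-\Theta)}, \eqn{\tau = 1};
#' * `psd_pascal(k)` — Pascal (negative binomial counting trials),
#'   \eqn{a_z = \binom{z-1}{k-1}}, \eqn{A(\Theta) = (\Theta/(1-\Theta))^k},
#'   \eqn{\tau = 1};
#' * `psd_negbinomial(k)` — zero-truncated negative binomial (counting
#'   failures), \eqn{a_z = \binom{z+k-1}{z}},
#'   \eqn{A(\Theta) = (1-\Theta)^{-k} - 1}, \eqn{\tau = 1}.
#'
#' Only the binomial family is exercised by the compound-maximum machinery
#' downstream (it is the count law of the MaxErlB distribution); the others
#' expose their mass and series functions for the generic construction.
#'
#' @param name Family label.
#' @param coef Function `z -> a_z` returning the series coefficients.
#' @param series,dseries,ddseries Functions evaluating \eqn{A},
#'   \eqn{A'} and \eqn{A''} on \eqn{(0, \tau)}.
#' @param tau Convergence radius of the power series (may be `Inf`).
#' @param support_max Largest support point (`Inf` for unbounded families).
#' @param shape Named list of family-specific integer shape parameters.
#' @param n Binomial size, integer \eqn{\ge 1}.
#' @param k Shape (number of successes) for Pascal / negative binomial.
#'
#' @return An object of class `psd_family`.
#' @seealso [psd_pmf()], [psd_series()], [rztbinom()], [dmax_compound()]
#' @examples
#' fam <- psd_binomial(3)
#' psd_pmf(fam, 1:3, theta = 0.25)
#' @export
psd_family <- function(name, coef, series, dseries, ddseries, tau,
                       support_max = Inf, shape = list()) {
  stopifnot(is.character(name), is.function(coef), is.function(series),
            is.function(dseries), is.function(ddseries),
            is.numeric(tau), tau > 0)
  structure(
    list(name = name, coef = coef, series = series, dseries = dseries,
         ddseries = ddseries, tau = tau, support_max = support_max,
         shape = shape),
    class = "psd_family"
  )
}

#' @rdname psd_family
#' @export
psd_binomial <- function(n) {
  n <- check_count(n, "n")
  psd_family(
    name = "binomial",
    coef = function(z) ifelse(z >= 1 & z <= n, choose(n, z), 0),
    series = function(t) expm1(n * log1p(t)),   # (1+t)^n - 1, small-t safe
    dseries = function(t) n * (1 + t)^(n - 1),
    ddseries = function(t) n * (n - 1) * (1 + t)^(n - 2),
    tau = Inf, support_max = n, shape = list(n = n)
  )
}

#' @rdname psd_family
#' @export
psd_poisson <- function() {
  psd_family(
    name = "poisson",
    coef = function(z) exp(-lfactorial(z)),
    series = function(t) expm1(t),
    dseries = function(t) exp(t),
    ddseries = function(t) exp(t),
    tau = Inf
  )
}

#' @rdname psd_family
#' @export
psd_logarithmic <- function() {
  psd_family(
    name = "logarithmic",
    coef = function(z) 1 / z,
    series = function(t) -log1p(-t),
    dseries = function(t) 1 / (1 - t),
    ddseries = function(t) 1 / (1 - t)^2,
    tau = 1
  )
}

#' @rdname psd_family
#' @export
psd_geometric <- function() {
  psd_family(
    name = "geometric",
    coef = function(z) rep(1, length(z)),
    series = function(t) t / (1 - t),
    dseries = function(t) 1 / (1 - t)^2,
    ddseries = function(t) 2 / (1 - t)^3,
    tau = 1
  )
}

#' @rdname psd_family
#' @export
psd_pascal <- function(k) {
  k <- check_count(k, "k")
  psd_family(
    name = "pascal",
    coef = function(z) choose(z - 1, k - 1),
    series = function(t) (t / (1 - t))^k,
    dseries = function(t) k * t^(k - 1) / (1 - t)^(k + 1),
    ddseries = function(t) k * t^(k - 2) * (k - 1 + 2 * t) / (1 - t)^(k + 2),
    tau = 1, shape = list(k = k)
  )
}

#' @rdname psd_family
#' @export
psd_negbinomial <- function(k) {
  k <- check_count(k, "k")
  psd_family(
    name = "negbinomial",
    coef = function(z) choose(z + k - 1, z),
    series = function(t) (1 - t)^(-k) - 1,
    dseries = function(t) k * (1 - t)^(-(k + 1)),
    ddseries = function(t) k * (k + 1) * (1 - t)^(-(k + 2)),
    tau = 1, shape = list(k = k)
  )
}

#' @export
print.psd_family <- function(x, ...) {
  sup <- if (is.finite(x$support_max)) paste0("{1, ..., ", x$support_max, "}")
         else "{1, 2, ...}"
  cat("<psd_family> ", x$name, "\n",
      "  support: ", sup, ",  power parameter in (0, ",
      format(x$tau), ")\n", sep = "")
  if (length(x$shape))
    cat("  shape:", paste(names(x$shape), unlist(x$shape), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Power-series probability mass function
#'
#' Evaluates \eqn{P(Z = z) = a_z \Theta^z / A(\Theta)} for a zero-truncated
#' power-series family.
#'
#' @param family A [psd_family] object.
#' @param z Vector of positive integers (values above a finite support
#'   maximum get probability 0).
#' @param theta Power parameter, a single value in \eqn{(0, \tau)}.
#' @return Numeric vector of probabilities.
#' @examples
#' psd_pmf(psd_binomial(3), 1:3, theta_from_p(0.2))
#' @export
psd_pmf <- function(family, z, theta) {
  stopifnot(inherits(family, "psd_family"))
  check_theta(family, theta)
  if (any(z <= 0) || any(z != floor(z)))
    stop("`z` must contain positive integers", call. = FALSE)
  family$coef(z) * theta^z / family$series(theta)
}

#' Series function of a power-series family and its derivatives
#'
#' Evaluates \eqn{A(\Theta)}, \eqn{A'(\Theta)} or \eqn{A''(\Theta)}.
#' The derivatives drive the conditional-mean (E-step) formula of the
#' max-compound EM algorithm.
#'
#' @inheritParams psd_pmf
#' @param order 0, 1 or 2.
#' @return Numeric vector, same length as `theta`.
#' @examples
#' psd_series(psd_binomial(3), 0.25)           # (1.25)^3 - 1
#' psd_series(psd_binomial(3), 0.25, order = 1)
#' @export
psd_series <- function(family, theta, order = 0) {
  stopifnot(inherits(family, "psd_family"))
  check_theta(family, theta)
  switch(as.character(order),
    "0" = family$series(theta),
    "1" = family$dseries(theta),
    "2" = family$ddseries(theta),
    stop("`order` must be 0, 1 or 2", call. = FALSE)
  )
}

#' Convert between a binomial success probability and its power parameter
#'
#' For the zero-truncated binomial family the power parameter is the odds
#' \eqn{\Theta = p/(1-p)}; `p_from_theta()` inverts the map.
#'
#' @param p Success probability, strictly inside (0, 1).
#' @param theta Positive power parameter (odds).
#' @return A numeric vector.
#' @export
theta_from_p <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  p / (1 - p)
}

#' @rdname theta_from_p
#' @export
p_from_theta <- function(theta) {
  if (any(theta <= 0)) stop("`theta` must be positive", call. = FALSE)
  theta / (1 + theta)
}

#' Zero-truncated binomial random draws by rejection
#'
#' Draws the component count of the MaxErlB model: a binomial(n, p) variate
#' conditioned to be nonzero, obtained by redrawing zeros (the acceptance
#' probability is \eqn{1 - (1-p)^n}, so the number of attempts per draw is
#' geometric).
#'
#' @param m Number of draws.
#' @param n Binomial size, integer \eqn{\ge 1}.
#' @param p Success probability in (0, 1).
#' @return Integer vector of length `m` with values in `1:n`; the total
#'   number of rejected (zero) draws is attached as attribute `"rejections"`.
#' @examples
#' set.seed(1)
#' table(rztbinom(1000, n = 3, p = 0.2))
#' @export
rztbinom <- function(m, n, p) {
  n <- check_count(n, "n")
  if (length(p) != 1 || p <= 0 || p >= 1)
    stop("`p` must be a single value strictly in (0, 1)", call. = FALSE)
  m <- check_count(m, "m")
  z <- stats::rbinom(m, n, p)
  rejections <- 0L
  repeat {
    zero <- which(z == 0L)
    if (!length(zero)) break
    rejections <- rejections + length(zero)
    z[zero] <- stats::rbinom(length(zero), n, p)
  }
  attr(z, "rejections") <- rejections
  z
}

# -- internal validation helpers ---------------------------------------------

check_count <- function(x, label) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x))
    stop("`", label, "` must be a single integer >= 1", call. = FALSE)
  as.integer(x)
}

check_theta <- function(family, theta) {
  if (any(theta <= 0 | theta >= family$tau))
    stop("power parameter must lie in (0, ", family$tau, ") for the ",
         family$name, " family", call. = FALSE)
  invisible(theta)
}
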