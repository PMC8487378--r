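#' Pearson chi-square concordance test against a specified MaxErlB model
#'
#' Bins a sample of positive lifetimes into `bins` equal-probability
#' intervals built from the model quantile function, merges bins whose
#' expected count falls below `min_expected`, and computes the Pearson
#' statistic
#' \deqn{\chi^2_c = \sum_j (n_j - n_0 p_j)^2 / (n_0 p_j),}
#' where \eqn{n_j} is the observed count in \eqn{[t_{j-1}, t_j)},
#' \eqn{n_0} the sample size and \eqn{p_j = F(t_j) - F(t_{j-1})} the model
#' probability of the bin.  The statistic is referred to the upper-`alpha`
#' chi-square quantile on \eqn{(r - 1) - L} degrees of freedom, with `r` the
#' number of bins after merging and `L = n_estimated` the number of
#' parameters treated as estimated.
#'
#' @param x Numeric vector of positive lifetimes.
#' @inheritParams maxerlb-distribution
#' @param bins Initial number of equal-probability bins.
#' @param n_estimated Number of estimated parameters `L` subtracted from the
#'   degrees of freedom.  The classical convention counts the parameters
#'   fitted from the data; pass 4 to reproduce the published simulation
#'   checks, which subtract all four distribution parameters.
#' @param alpha Significance level of the test.
#' @param min_expected Smallest expected count allowed per bin before
#'   adjacent bins are merged.
#' @return An object of class `maxerlb_gof`: a list with the bin table
#'   (a tibble with columns `lower`, `upper`, `observed`, `prob`,
#'   `expected`), `statistic`, `df`, `alpha`, `critical` and `reject`.
#'   [tidy()] returns the bin table, [glance()] the one-row summary.
#' @examples
#' u <- rmaxerlb(2000, 2, 10, 3, 0.2, seed = 7)
#' gof <- maxerlb_gof(u, k = 2, lam = 10, n = 3, p = 0.2,
#'                    bins = 12, n_estimated = 4)
#' glance(gof)
#' @export
maxerlb_gof <- function(x, k, lam, n, p, bins = 12, n_estimated = 0,
                        alpha = 0.05, min_expected = 5) {
  pr <- check_maxerlb_params(k, lam, n, p)
  x <- as.numeric(x)
  if (!length(x) || any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be a nonempty vector of positive finite lifetimes",
         call. = FALSE)
  bins <- check_count(bins, "bins")
  ends <- qmaxerlb(seq(0, 1, length.out = bins + 1), pr$k, pr$lam, pr$n, pr$p)
  observed <- tabulate(findInterval(x, ends, rightmost.closed = FALSE),
                       nbins = bins)
  probs <- bin_probabilities(ends, pr$k, pr$lam, pr$n, pr$p)
  merged <- merge_bins(ends, observed, probs, min_expected = min_expected)
  n0 <- length(x)
  stat <- chisq_statistic(merged$observed, merged$probs, n0 = n0)
  r <- length(merged$observed)
  df <- (r - 1) - n_estimated
  if (df < 1)
    stop("degrees of freedom fell below 1 after merging; use more bins or ",
         "a smaller `n_estimated`", call. = FALSE)
  crit <- chisq_critical(df, alpha)
  structure(
    list(
      bins = tibble::tibble(
        lower = utils::head(merged$ends, -1),
        upper = utils::tail(merged$ends, -1),
        observed = merged$observed,
        prob = merged$probs,
        expected = n0 * merged$probs
      ),
      statistic = stat, df = df, alpha = alpha, critical = crit,
      reject = stat > crit, n = n0,
      params = maxerlb(pr$k, pr$lam, pr$n, pr$p)
    ),
    class = "maxerlb_gof"
  )
}

#' Model probabilities of a set of time bins
#'
#' \eqn{p_j = F(t_j) - F(t_{j-1})} for consecutive bin ends
#' \eqn{0 = t_0 < t_1 < \cdots < t_r = \infty} under a MaxErlB model.
#'
#' @param ends Strictly increasing vector of bin ends starting at 0 and
#'   ending at `Inf`.
#' @inheritParams maxerlb-distribution
#' @return Numeric vector of `length(ends) - 1` probabilities summing to 1.
#' @export
bin_probabilities <- function(ends, k, lam, n, p) {
  if (length(ends) < 2 || is.unsorted(ends, strictly = TRUE))
    stop("`ends` must be strictly increasing", call. = FALSE)
  if (ends[1] != 0 || !is.infinite(ends[length(ends)]))
    stop("`ends` must start at 0 and end at Inf so the bins span (0, Inf)",
         call. = FALSE)
  diff(pmaxerlb(ends, k, lam, n, p))
}

#' Pearson chi-square statistic from binned counts
#'
#' @param observed Integer vector of observed bin counts \eqn{n_j}.
#' @param probs Model bin probabilities \eqn{p_j}, summing to 1.
#' @param n0 Total sample size; defaults to `sum(observed)`.
#' @return The statistic \eqn{\sum_j (n_j - n_0 p_j)^2 / (n_0 p_j)}.
#' @examples
#' chisq_statistic(c(60, 40), c(0.5, 0.5))  # 4
#' @export
chisq_statistic <- function(observed, probs, n0 = sum(observed)) {
  if (length(observed) != length(probs))
    stop("`observed` and `probs` must have the same length", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must sum to 1", call. = FALSE)
  if (n0 <= 0) stop("`n0` must be positive", call. = FALSE)
  expected <- n0 * probs
  if (any(expected == 0))
    stop("zero expected count; merge bins first", call. = FALSE)
  sum((observed - expected)^2 / expected)
}

#' Merge adjacent bins until every expected count is large enough
#'
#' While any expected count \eqn{n_0 p_j} is below `min_expected`, the
#' adjacent pair of bins with the smallest combined expected count is
#' merged (counts and probabilities are summed).  Totals are conserved.
#'
#' @inheritParams chisq_statistic
#' @param ends Bin ends, one more than the number of bins.
#' @param min_expected Expected-count threshold (the classical Pearson
#'   prescription is 5).
#' @return A list with elements `ends`, `observed`, `probs`.
#' @export
merge_bins <- function(ends, observed, probs, n0 = sum(observed),
                       min_expected = 5) {
  if (length(ends) != length(observed) + 1 ||
      length(observed) != length(probs))
    stop("`ends` must have one more element than `observed`/`probs`",
         call. = FALSE)
  while (any(n0 * probs < min_expected)) {
    if (length(observed) < 2)
      stop("cannot reach the expected-count threshold with at least 2 bins",
           call. = FALSE)
    pair <- which.min(utils::head(probs, -1) + utils::tail(probs, -1))
    probs <- append(probs[-c(pair, pair + 1)], probs[pair] + probs[pair + 1],
                    after = pair - 1)
    observed <- append(observed[-c(pair, pair + 1)],
                       observed[pair] + observed[pair + 1], after = pair - 1)
    ends <- ends[-(pair + 1)]
  }
  list(ends = ends, observed = observed, probs = probs)
}

#' Upper critical value of the chi-square distribution
#'
#' The upper-`alpha` quantile on `df` degrees of freedom, e.g.
#' `chisq_critical(7)` is 14.067.
#'
#' @param df Degrees of freedom.
#' @param alpha Upper tail probability.
#' @return A single number.
#' @export
chisq_critical <- function(df, alpha = 0.05) {
  if (df < 1) stop("`df` must be at least 1", call. = FALSE)
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' @export
print.maxerlb_gof <- function(x, ...) {
  cat("Pearson chi-square concordance test against",
      sprintf("MaxErlB(%d, %g, %d, %g)\n",
              x$params$k, x$params$lam, x$params$n, x$params$p))
  cat(sprintf("  X^2 = %.4f on %d df; critical value (alpha = %g) = %.3f\n",
              x$statistic, x$df, x$alpha, x$critical))
  cat(if (x$reject) "  => reject concordance\n" else
        "  => concordance not rejected\n")
  invisible(x)
}
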