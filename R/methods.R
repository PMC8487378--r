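#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EM fit
#'
#' @param x A `maxerlb_fit` object from [maxerlb_em()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per estimated parameter
#'   (`term`, `estimate`); `glance()`: a one-row tibble with the
#'   log-likelihood, iteration count, convergence flag, sample size and the
#'   fixed shapes.
#' @export
tidy.maxerlb_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "p"), estimate = c(x$lambda, x$p))
}

#' @rdname tidy.maxerlb_fit
#' @export
glance.maxerlb_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, iterations = x$iterations, converged = x$converged,
    m = x$m, k = x$k, n = x$n, epsilon = x$epsilon
  )
}

#' Tidy a chi-square concordance test
#'
#' @param x A `maxerlb_gof` object from [maxerlb_gof()].
#' @param ... Unused.
#' @return `tidy()`: the bin table (one row per merged bin: `lower`,
#'   `upper`, `observed`, `prob`, `expected`); `glance()`: a one-row tibble
#'   with `statistic`, `df`, `critical`, `alpha`, `reject`, `n`.
#' @export
tidy.maxerlb_gof <- function(x, ...) x$bins

#' @rdname tidy.maxerlb_gof
#' @export
glance.maxerlb_gof <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, critical = x$critical,
    alpha = x$alpha, reject = x$reject, n = x$n
  )
}

#' Plot an EM fit: data histogram with the fitted density overlaid
#'
#' @param object A `maxerlb_fit` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maxerlb_fit <- function(object, bins = 30, ...) {
  df <- tibble::tibble(x = object$data)
  grid <- tibble::tibble(
    x = seq(1e-9, max(object$data) * 1.05, length.out = 512)
  )
  grid$density <- dmaxerlb(grid$x, object$k, object$lambda,
                           object$n, object$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(
      x = "lifetime", y = "density",
      title = sprintf("MaxErlB fit (k = %d, n = %d): lambda = %.4g, p = %.4g",
                      object$k, object$n, object$lambda, object$p)
    )
}

#' Plot a concordance test: observed vs expected counts per bin
#'
#' @param object A `maxerlb_gof` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maxerlb_gof <- function(object, ...) {
  b <- object$bins
  b$bin <- factor(seq_len(nrow(b)))
  long <- tibble::tibble(
    bin = rep(b$bin, 2),
    count = c(b$observed, b$expected),
    kind = rep(c("observed", "expected"), each = nrow(b))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "bin (equal model probability)", y = "count",
      title = sprintf("Pearson X^2 = %.3f on %d df (critical %.3f)",
                      object$statistic, object$df, object$critical)
    )
}
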