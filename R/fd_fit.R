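#' Construct a scaling-fit object
#'
#' All three fractal-dimension estimators in the package reduce to a log-log
#' scaling relationship between a scale variable (box size \eqn{l_B}, grid
#' size \eqn{\epsilon}, or coarse-graining interval \eqn{k}) and a measured
#' quantity (covering number \eqn{N_B}, occupied-box count, or mean curve
#' length). `fd_fit` packages the measured points together with the ordinary
#' least-squares fit of `log(y)` on `log(x)` and the resulting dimension
#' estimate, and is the common return class of [network_fd()], [matrix_fd()]
#' and [higuchi_fd()].
#'
#' @param x numeric vector of scale values (positive).
#' @param y numeric vector of measured values at each scale (positive, same
#'   length as `x`; zeros are tolerated only when the fit is degenerate).
#' @param dimension the dimension estimate. When `NULL`, it is taken as the
#'   negated OLS slope of `log(y)` on `log(x)`.
#' @param method character tag identifying the estimator (`"cbb"`,
#'   `"boxcount2d"`, `"higuchi"`, ...).
#' @param scale_name,value_name axis labels used by the print and plot
#'   methods.
#' @param details optional list of estimator-specific diagnostics.
#'
#' @return An object of class `fd_fit`: a list with elements `x`, `y`,
#'   `slope`, `intercept`, `r.squared`, `dimension`, `method`, `scale_name`,
#'   `value_name`, `details` and `call`.
#' @seealso [network_fd()], [matrix_fd()], [higuchi_fd()]
#' @export
fd_fit <- function(x, y, dimension = NULL, method = "fit",
                   scale_name = "scale", value_name = "count",
                   details = list()) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(x > 0))
  if (any(!is.finite(y)) || any(y < 0)) {
    stop_fdconn("measured values must be finite and non-negative",
                "fdconn_degenerate")
  }
  lx <- log(x)
  ly <- log(y)
  keep <- is.finite(ly)
  if (sum(keep) < 2) {
    stop_fdconn("fewer than 2 usable points for the log-log regression",
                "fdconn_degenerate")
  }
  fit <- lm(ly[keep] ~ lx[keep])
  slope <- unname(coef(fit)[2])
  if (is.na(slope)) slope <- 0  # constant scale column cannot occur; constant y can
  intercept <- unname(coef(fit)[1])
  ssr <- sum(residuals(fit)^2)
  sst <- sum((ly[keep] - mean(ly[keep]))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(
    list(
      x = x, y = y,
      slope = slope, intercept = intercept, r.squared = r2,
      dimension = if (is.null(dimension)) -slope else dimension,
      method = method,
      scale_name = scale_name, value_name = value_name,
      details = details,
      call = sys.call(-1)
    ),
    class = "fd_fit"
  )
}

#' @export
print.fd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Fractal scaling fit (%s)\n", x$method))
  cat(sprintf("  points    : %d (%s = %s .. %s)\n", length(x$x),
              x$scale_name, format(min(x$x)), format(max(x$x))))
  cat(sprintf("  slope     : %s   r^2 = %s\n",
              format(x$slope, digits = digits),
              format(x$r.squared, digits = digits)))
  cat(sprintf("  dimension : %s\n", format(x$dimension, digits = digits)))
  invisible(x)
}

#' @export
summary.fd_fit <- function(object, ...) {
  out <- data.frame(scale = object$x, value = object$y)
  names(out) <- c(object$scale_name, object$value_name)
  structure(
    list(points = out, slope = object$slope, intercept = object$intercept,
         r.squared = object$r.squared, dimension = object$dimension,
         method = object$method, details = object$details),
    class = "summary.fd_fit"
  )
}

#' @export
print.summary.fd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Fractal scaling fit (%s)\n\n", x$method))
  print(x$points, row.names = FALSE)
  cat(sprintf("\nlog-log OLS: slope %s, intercept %s, r^2 %s\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits),
              format(x$r.squared, digits = digits)))
  cat(sprintf("dimension estimate: %s\n", format(x$dimension, digits = digits)))
  invisible(x)
}

#' @export
coef.fd_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    dimension = object$dimension)
}

#' Predicted scaling values from a fitted power law
#'
#' Evaluates the fitted power law \eqn{y = e^{a} x^{b}} at new scale values.
#'
#' @param object an [fd_fit] object.
#' @param newdata numeric vector of scale values; defaults to the fitted ones.
#' @param ... unused.
#' @return numeric vector of predicted values.
#' @export
predict.fd_fit <- function(object, newdata = NULL, ...) {
  xx <- newdata %||% object$x
  exp(object$intercept + object$slope * log(xx))
}

#' @export
residuals.fd_fit <- function(object, ...) {
  log(object$y) - (object$intercept + object$slope * log(object$x))
}

#' @export
plot.fd_fit <- function(x, ...) {
  graphics::plot(log(x$x), log(x$y),
                 xlab = sprintf("log(%s)", x$scale_name),
                 ylab = sprintf("log(%s)", x$value_name),
                 main = sprintf("%s scaling (dimension %.3f)",
                                x$method, x$dimension), ...)
  graphics::abline(a = x$intercept, b = x$slope, lty = 2)
  invisible(x)
}
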