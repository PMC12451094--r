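#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("First-order decay fit: C(t) = C0 * exp(-k t)\n")
  cat(sprintf("  C0 = %s uM, k = %s /day, t_half = %s days\n",
              format(coef(x)["C0"], digits = digits),
              format(coef(x)["k"], digits = digits),
              format(x$t_half, digits = digits)))
  cat(sprintf("  RSS = %s on %d observations%s%s\n",
              format(x$rss, digits = digits), x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$k_pinned) " [k at lower bound]" else ""))
  invisible(x)
}

#' @export
print.sigmoid_fit <- function(x, digits = 4, ...) {
  cat("Sigmoidal accumulation fit: c(t) = cmax / (1 + (cmax-c0)/c0 * exp(-k t))\n")
  cat(sprintf("  c0 = %s uM, cmax = %s uM, k = %s /day\n",
              format(coef(x)["c0"], digits = digits),
              format(coef(x)["cmax"], digits = digits),
              format(coef(x)["k"], digits = digits)))
  cat(sprintf("  inflection t* = %s days, induction t_ind = %s\n",
              format(x$t_star, digits = digits),
              if (is.na(x$t_ind)) "— (none)"
              else paste(format(x$t_ind, digits = digits), "days")))
  cat(sprintf("  RSS = %s on %d observations%s\n",
              format(x$rss, digits = digits), x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  est <- coef(object)
  se <- rep(NA_real_, length(est))
  if (!is.null(object$fit)) {
    se <- tryCatch(summary(object$fit)$coefficients[, "Std. Error"],
                   error = function(e) se)
  }
  tab <- cbind(Estimate = est, `Std. Error` = se)
  dfres <- object$n_obs - length(est)
  out <- list(fit = object, coefficients = tab,
              sigma = if (dfres > 0) sqrt(object$rss / dfres) else NA_real_,
              df_residual = dfres)
  class(out) <- "summary.kinetic_fit"
  out
}

#' @export
print.summary.kinetic_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParameters:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Residual standard error: %s uM on %d degrees of freedom\n",
              format(x$sigma, digits = digits), x$df_residual))
  invisible(x)
}

model_curve <- function(object, t) {
  if (inherits(object, "decay_fit")) {
    est <- coef(object)
    decay_value(est["C0"], est["k"], t)
  } else {
    sigmoid_value(coef(object), t)
  }
}

#' Predict concentrations from a fitted kinetic model
#'
#' @param object A `decay_fit` or `sigmoid_fit`.
#' @param newdata Optional data frame with a `day` column, or numeric days;
#'   defaults to the fitted times.
#' @param ... Unused.
#' @return Predicted concentrations in µM.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$day
       else as.numeric(newdata)
  unname(model_curve(object, t))
}

#' @export
fitted.kinetic_fit <- function(object, ...) {
  unname(model_curve(object, object$data$t))
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Plot a fitted kinetic model over its data
#'
#' Observations as points, the fitted curve as a line; for sigmoid fits the
#' inflection point and the inflection tangent (whose x-axis intercept is the
#' induction time) are drawn as well.
#'
#' @param x A `decay_fit` or `sigmoid_fit`.
#' @param n Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kinetic_fit <- function(x, n = 200, ...) {
  t <- x$data$t; y <- x$data$y
  tt <- seq(min(t), max(t), length.out = n)
  graphics::plot(t, y, xlab = "storage time (days)",
                 ylab = "concentration (µM)", ...)
  graphics::lines(tt, model_curve(x, tt), col = "firebrick", lwd = 2)
  if (inherits(x, "sigmoid_fit") && is.finite(x$t_star)) {
    ip <- inflection_point(x)
    graphics::points(ip$t_star, ip$c_at, pch = 19, col = "steelblue")
    graphics::abline(a = ip$c_at - ip$slope * ip$t_star, b = ip$slope,
                     lty = 2, col = "steelblue")
    if (!is.na(x$t_ind))
      graphics::points(x$t_ind, 0, pch = 4, col = "steelblue")
  }
  invisible(x)
}

#' Simulate replicate series from a fitted kinetic model
#'
#' Draws new observations at the fitted timepoints: model curve plus i.i.d.
#' Gaussian noise with standard deviation equal to the residual standard
#' error, truncated at zero (concentrations cannot be negative).
#'
#' @param object A fitted `kinetic_fit`.
#' @param nsim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one column per simulated replicate.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  dfres <- object$n_obs - length(coef(object))
  sigma <- if (dfres > 0) sqrt(object$rss / dfres) else 0
  out <- as.data.frame(replicate(nsim, pmax(mu + stats::rnorm(length(mu), 0, sigma), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.replicate_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Replicate summary (%s, n = %d): %s, pH %s, dose %s g/L\n",
              x$model, x$n, x$analyte, format(x$pH),
              format(x$extract_dose)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
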