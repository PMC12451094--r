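#' Logistic accumulation model for lipid oxidation products
#'
#' Evaluates the sigmoidal growth model
#' \deqn{c(t) = \frac{c_{max}}{1 + \frac{c_{max}-c_0}{c_0} e^{-kt}}}
#' describing the concentration of a lipid oxidation product (hydroperoxides
#' or volatile aldehydes) during storage: it starts at `c0` at `t = 0`,
#' rises through an inflection at `cmax/2`, and saturates at `cmax`.
#'
#' @param params Numeric vector or list with elements `c0` (initial
#'   concentration, µM, `> 0`), `cmax` (plateau concentration, µM, `> c0`)
#'   and `k` (rate constant, 1/day, `> 0`).
#' @param t Time(s) in days.
#' @return Concentration(s) in µM, strictly increasing in `t`.
#' @examples
#' sigmoid_value(c(c0 = 1, cmax = 100, k = 1), t = log(99)) # cmax/2
#' @export
sigmoid_value <- function(params, t) {
  p <- as.list(params)
  c0 <- p$c0; cmax <- p$cmax; k <- p$k
  if (is.null(c0) || is.null(cmax) || is.null(k)) {
    v <- unlist(params)
    if (length(v) != 3) stop("`params` must supply c0, cmax, k", call. = FALSE)
    c0 <- v[[1]]; cmax <- v[[2]]; k <- v[[3]]
  }
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be > 0", call. = FALSE)
  if (!is.finite(cmax) || cmax <= c0) stop("cmax must be > c0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  cmax / (1 + (cmax - c0) / c0 * exp(-k * t))
}

decay_value <- function(C0, k, t) C0 * exp(-k * t)

#' Half-life of a first-order decay
#'
#' The time at which an exponentially decaying concentration has fallen to
#' half its initial value, `t_half = ln(2) / k`.
#'
#' @param k First-order rate constant in 1/day, `> 0`.
#' @return Half-life in days.
#' @examples
#' half_life(1.44) # fast pigment degradation at pH 2: ~0.48 days
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  log(2) / k
}

series_input <- function(x, value, min_points, what) {
  if (inherits(x, "kinetic_series")) {
    t <- x$day; y <- x$value
    meta <- x$meta; analyte <- x$analyte
  } else if (is.data.frame(x)) {
    if (!all(c("day", "value") %in% names(x)))
      stop("data frame input needs columns `day` and `value`", call. = FALSE)
    t <- x$day; y <- x$value
    meta <- list(sample_id = "data", pH = NA_real_, extract_dose = NA_real_,
                 replicate = 1L)
    analyte <- if ("analyte" %in% names(x)) x$analyte[1] else NA_character_
  } else {
    t <- as.numeric(x); y <- as.numeric(value)
    meta <- list(sample_id = "data", pH = NA_real_, extract_dose = NA_real_,
                 replicate = 1L)
    analyte <- NA_character_
  }
  if (length(t) != length(y) || anyNA(t) || anyNA(y))
    stop("times and values must be equal-length and complete", call. = FALSE)
  ord <- order(t); t <- t[ord]; y <- y[ord]
  if (length(unique(t)) < min_points)
    stop(sprintf("%s requires at least %d distinct timepoints", what,
                 min_points), call. = FALSE)
  if (any(y < 0)) stop("values must be non-negative", call. = FALSE)
  list(t = t, y = y, meta = meta, analyte = analyte)
}

#' Fit a first-order exponential decay to a pigment time series
#'
#' Fits `C(t) = C0 * exp(-k t)` by nonlinear least squares on the original
#' concentration scale (so zero observations are admissible), with
#' `C0 > 0` and `k >= 0` enforced by bounds. Starting values come from a
#' log-linear regression on the strictly positive observations. The
#' half-life `ln(2)/k` is attached; a series fitted at the `k = 0` boundary
#' (no detectable decay) gets `t_half = Inf` and a warning flag.
#'
#' @param x A [kinetic_series], a data frame with columns `day`/`value`, or a
#'   numeric vector of days (then supply `value`). At least 3 distinct
#'   timepoints are required, with at least one positive value.
#' @param value Numeric concentrations when `x` is a numeric day vector.
#' @return An object of class `c("decay_fit", "kinetic_fit")` with components
#'   `coefficients` (`C0`, `k`), `t_half`, `rss`, `n_obs`, `converged`,
#'   `k_pinned`, `data`, and the underlying `nls` fit in `$fit` (when one was
#'   run). Standard methods (`print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`) apply.
#' @examples
#' t <- 0:6
#' fit <- fit_decay(t, 24 * exp(-1.44 * t))
#' coef(fit); fit$t_half
#' @seealso [fit_sigmoid()], [half_life()], [aggregate_replicates()]
#' @export
fit_decay <- function(x, value = NULL) {
  s <- series_input(x, value, 3L, "decay fitting")
  t <- s$t; y <- s$y
  if (all(y == 0)) stop("degenerate series: all values zero", call. = FALSE)

  pos <- y > 0
  if (sum(pos) >= 2) {
    ll <- stats::lm(log(y[pos]) ~ t[pos])
    C0_init <- exp(unname(stats::coef(ll)[1]))
    k_init <- max(-unname(stats::coef(ll)[2]), 1e-6)
  } else {
    C0_init <- max(y); k_init <- 0.1
  }

  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ C0 * exp(-k * t), data = df,
                      start = list(C0 = C0_init, k = k_init),
                      lower = c(C0 = 1e-12, k = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(C0 = C0_init, k = k_init); rss <- sum((y - decay_value(C0_init, k_init, t))^2)
    converged <- FALSE
  } else {
    est <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  # the k = 0 boundary optimum (constant model at mean(y)) can beat a fit
  # stranded at tiny k where the RSS surface is flat
  rss0 <- sum((y - mean(y))^2)
  k_pinned <- est["k"] <= 1e-10 || rss0 <= rss * (1 + 1e-9)
  if (k_pinned) {
    est <- c(C0 = mean(y), k = 0)
    rss <- rss0
    converged <- TRUE
    warning("rate constant pinned at lower bound 0; t_half set to Inf",
            call. = FALSE)
  }
  structure(list(
    coefficients = est,
    t_half = if (k_pinned) Inf else log(2) / unname(est["k"]),
    rss = rss, n_obs = length(y), converged = isTRUE(converged),
    k_pinned = unname(k_pinned),
    data = df, meta = s$meta, analyte = s$analyte,
    fit = fit, call = match.call()
  ), class = c("decay_fit", "kinetic_fit"))
}

#' Fit a sigmoidal accumulation model to a lipid-oxidation time series
#'
#' Fits the logistic model of [sigmoid_value()] by bounded nonlinear least
#' squares with multi-start over the rate constant (default starts
#' `k = 0.05, 0.2, 0.8, 3.2, 12.8` per day); the best residual sum of
#' squares wins, ties broken towards the smallest `k`. Bounds:
#' `c0` in `(1e-6, 2 * min positive observation]`, `cmax` in
#' `[0.8, 3] * max observation`, `k > 0`. The inflection point and the
#' inflection-tangent induction time are attached via [inflection_point()]
#' and [induction_time()].
#'
#' Flat series, whose dynamic range is below twice the estimated noise floor
#' (successive-difference estimate), are flagged `converged = FALSE` and get
#' no derived statistics.
#'
#' @inheritParams fit_decay
#' @param starts Numeric vector of rate-constant starting values (1/day).
#' @return An object of class `c("sigmoid_fit", "kinetic_fit")` with
#'   `coefficients` (`c0`, `cmax`, `k`), `t_star`, `t_ind` (`NA` when no
#'   induction phase exists, reported as em dash), `rss`, `n_obs`,
#'   `converged`, `data` and `$fit`.
#' @examples
#' t <- 0:14
#' fit <- fit_sigmoid(t, sigmoid_value(c(c0 = 1, cmax = 100, k = 1), t))
#' coef(fit); fit$t_ind
#' @export
fit_sigmoid <- function(x, value = NULL,
                        starts = c(0.05, 0.2, 0.8, 3.2, 12.8)) {
  s <- series_input(x, value, 4L, "sigmoid fitting")
  t <- s$t; y <- s$y
  rng <- max(y) - min(y)
  noise_floor <- if (length(y) > 2) stats::sd(diff(y)) / sqrt(2) else 0
  flat <- rng < 2 * noise_floor || rng == 0

  ymax <- max(y)
  ypos_min <- if (any(y > 0)) min(y[y > 0]) else 1e-3
  lower <- c(c0 = 1e-6, cmax = 0.8 * ymax, k = 1e-6)
  upper <- c(c0 = 2 * ypos_min, cmax = 3 * ymax, k = 1e3)
  c0_start <- min(max(ypos_min, 1e-3), upper["c0"])
  cmax_start <- min(max(ymax, lower["cmax"] + 1e-9), upper["cmax"])
  df <- data.frame(t = t, y = y)

  best <- NULL
  for (k0 in sort(starts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ cmax / (1 + (cmax - c0) / c0 * exp(-k * t)),
                        data = df,
                        start = list(c0 = unname(c0_start),
                                     cmax = unname(cmax_start),
                                     k = k0),
                        lower = unname(lower), upper = unname(upper),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    # keep the smallest-k solution among RSS ties (relative 1e-10)
    if (is.null(best) || rss < best$rss * (1 - 1e-10) ||
        (abs(rss - best$rss) <= 1e-10 * max(best$rss, 1e-300) &&
         stats::coef(fit)["k"] < best$est["k"])) {
      best <- list(fit = fit, rss = rss, est = stats::coef(fit))
    }
  }
  if (is.null(best))
    stop("sigmoid fit failed for all starting values", call. = FALSE)

  est <- best$est
  converged <- !flat && isTRUE(best$fit$convInfo$isConv %||% TRUE)
  out <- structure(list(
    coefficients = est, rss = best$rss, n_obs = length(y),
    converged = converged, flat = flat,
    t_star = NA_real_, t_ind = NA_real_,
    data = df, meta = s$meta, analyte = s$analyte,
    fit = best$fit, call = match.call()
  ), class = c("sigmoid_fit", "kinetic_fit"))
  if (!flat) {
    ip <- inflection_point(out)
    out$t_star <- ip$t_star
    out$t_ind <- induction_time(out)
  }
  out
}

#' Inflection point of a fitted (or parametric) sigmoid
#'
#' The logistic accumulation curve has a single inflection — the moment of
#' maximal oxidation rate during the propagation phase — at
#' `t* = ln((cmax - c0)/c0) / k`, where the concentration equals `cmax/2`
#' and the slope equals `k * cmax / 4`.
#'
#' @param fit A `sigmoid_fit`, or a numeric vector/list with `c0`, `cmax`, `k`.
#' @return A list with `t_star` (days), `c_at` (µM), `slope` (µM/day) and
#'   `before_start` (`TRUE` when `t_star <= 0`, i.e. the inflection precedes
#'   the first observation, as for series that start high relative to their
#'   plateau).
#' @examples
#' inflection_point(c(c0 = 1, cmax = 100, k = 1)) # t* = ln(99)
#' @export
inflection_point <- function(fit) {
  p <- sigmoid_params(fit)
  t_star <- log((p$cmax - p$c0) / p$c0) / p$k
  list(t_star = t_star, c_at = p$cmax / 2, slope = p$k * p$cmax / 4,
       before_start = t_star <= 0)
}

#' Inflection-tangent induction time
#'
#' The induction period of a sigmoidal oxidation curve is defined by the
#' tangent construction: draw the tangent at the inflection point and take
#' its intersection with the time axis (`c = 0`). In closed form
#' `t_ind = t* - 2/k = (ln((cmax - c0)/c0) - 2) / k`. When the intercept is
#' non-positive — series that start at a concentration already high relative
#' to the plateau — no induction phase exists and `NA` is returned
#' (rendered as an em dash in reports).
#'
#' @inheritParams inflection_point
#' @return Induction time in days, or `NA_real_` when none exists.
#' @examples
#' induction_time(c(c0 = 1, cmax = 100, k = 1))   # log(99) - 2
#' induction_time(c(c0 = 67, cmax = 300, k = 4))  # NA: no induction phase
#' @export
induction_time <- function(fit) {
  p <- sigmoid_params(fit)
  t_ind <- (log((p$cmax - p$c0) / p$c0) - 2) / p$k
  if (!is.finite(t_ind) || t_ind <= 0) NA_real_ else t_ind
}

sigmoid_params <- function(fit) {
  if (inherits(fit, "sigmoid_fit")) {
    est <- stats::coef(fit)
    p <- list(c0 = unname(est["c0"]), cmax = unname(est["cmax"]),
              k = unname(est["k"]))
  } else {
    v <- unlist(fit)
    if (!is.null(names(v)) && all(c("c0", "cmax", "k") %in% names(v)))
      p <- list(c0 = unname(v["c0"]), cmax = unname(v["cmax"]),
                k = unname(v["k"]))
    else if (length(v) == 3)
      p <- list(c0 = v[[1]], cmax = v[[2]], k = v[[3]])
    else stop("cannot interpret sigmoid parameters", call. = FALSE)
  }
  if (p$c0 <= 0 || p$cmax <= p$c0 || p$k <= 0)
    stop("invalid sigmoid parameters: need cmax > c0 > 0, k > 0",
         call. = FALSE)
  p
}

#' Aggregate replicate fits into mean and standard deviation
#'
#' Averages fitted parameters and derived statistics across replicate fits of
#' the same model kind and storage condition, as replicate experiments are
#' reported: per-parameter mean ± SD. Half-lives are averaged per replicate
#' (`mean(t_half)`), which is not the same as `ln(2)/mean(k)`; both are
#' reported because the two differ whenever `k` varies between replicates
#' (Jensen gap). Induction times are averaged over the replicates for which
#' an induction phase exists (count in `n_ind`).
#'
#' @param fits List of at least two `decay_fit` or at least two `sigmoid_fit`
#'   objects sharing one condition (sample, pH, dose, analyte).
#' @return A one-row data frame of class `replicate_summary` with columns
#'   `<param>_mean` / `<param>_sd` for each parameter and derived statistic,
#'   plus `n` (number of fits) and the condition keys.
#' @examples
#' t <- 0:6
#' f1 <- fit_decay(t, 24 * exp(-1.0 * t))
#' f2 <- fit_decay(t, 24 * exp(-2.0 * t))
#' aggregate_replicates(list(f1, f2))  # mean t_half != ln(2)/mean(k)
#' @export
aggregate_replicates <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("need at least two replicate fits", call. = FALSE)
  cls <- vapply(fits, function(f) class(f)[1], character(1))
  if (length(unique(cls)) != 1)
    stop("mixed fit kinds cannot be aggregated", call. = FALSE)
  keys <- vapply(fits, condition_key, character(1))
  if (length(unique(keys)) != 1)
    stop("fits come from different conditions: ",
         paste(unique(keys), collapse = " vs "), call. = FALSE)

  stat_list <- if (cls[1] == "decay_fit") {
    list(C0 = vapply(fits, function(f) unname(coef(f)["C0"]), 0),
         k = vapply(fits, function(f) unname(coef(f)["k"]), 0),
         t_half = vapply(fits, function(f) f$t_half, 0))
  } else {
    list(c0 = vapply(fits, function(f) unname(coef(f)["c0"]), 0),
         cmax = vapply(fits, function(f) unname(coef(f)["cmax"]), 0),
         k = vapply(fits, function(f) unname(coef(f)["k"]), 0),
         t_star = vapply(fits, function(f) f$t_star, 0),
         t_ind = vapply(fits, function(f) f$t_ind, 0))
  }
  m <- fits[[1]]$meta
  out <- data.frame(sample_id = m$sample_id, pH = m$pH,
                    extract_dose = m$extract_dose,
                    analyte = fits[[1]]$analyte, model = cls[1],
                    n = length(fits), stringsAsFactors = FALSE)
  for (nm in names(stat_list)) {
    v <- stat_list[[nm]]
    ok <- is.finite(v)
    out[[paste0(nm, "_mean")]] <- if (any(ok)) mean(v[ok]) else NA_real_
    out[[paste0(nm, "_sd")]] <- if (sum(ok) > 1) stats::sd(v[ok]) else NA_real_
    if (nm == "t_ind") out$n_ind <- sum(!is.na(v))
  }
  if (cls[1] == "decay_fit")
    out$t_half_from_mean_k <- log(2) / out$k_mean
  class(out) <- c("replicate_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
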