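test_that("sigmoid_value satisfies its algebraic anchors", {
  p <- c(c0 = 1, cmax = 100, k = 1)
  expect_equal(sigmoid_value(p, 0), 1)               # c(0) = c0
  expect_equal(sigmoid_value(p, 100), 100, tolerance = 1e-9) # asymptote
  expect_equal(sigmoid_value(p, log(99)), 50)        # cmax/2 at inflection
  t <- seq(0, 20, 0.5)
  expect_true(all(diff(sigmoid_value(p, t)) > 0))    # strictly increasing
  expect_error(sigmoid_value(c(c0 = -1, cmax = 100, k = 1), 0), "c0")
  expect_error(sigmoid_value(c(c0 = 5, cmax = 5, k = 1), 0), "cmax")
  expect_error(sigmoid_value(c(c0 = 1, cmax = 100, k = 0), 0), "k")
})

test_that("half_life inverts the rate constant", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(round(half_life(1.44), 2), 0.48)
  expect_equal(half_life(2.88), half_life(1.44) / 2)  # scaling law
  expect_error(half_life(0), "k")
  expect_error(half_life(-1), "k")
})

test_that("fit_decay recovers exact model data and handles edge cases", {
  t <- 0:5
  f <- fit_decay(t, 10 * exp(-0.5 * t))
  expect_s3_class(f, "decay_fit")
  expect_equal(unname(coef(f)), c(10, 0.5), tolerance = 1e-8)
  expect_equal(f$t_half, log(2) / 0.5, tolerance = 1e-8)
  expect_true(f$converged)

  # constant series: zero-slope limit, half-life infinite
  expect_warning(fc <- fit_decay(0:4, rep(7, 5)), "pinned")
  expect_equal(unname(coef(fc)), c(7, 0))
  expect_identical(fc$t_half, Inf)

  expect_error(fit_decay(0:4, rep(0, 5)), "degenerate")
  expect_error(fit_decay(0:1, c(5, 3)), "3 distinct")
})

test_that("fit_decay finds the global optimum on seeded noisy data", {
  set.seed(101)
  t <- seq(0, 7, 1)
  reps <- lapply(1:4, function(i) pmax(24 * exp(-1.44 * t) + rnorm(8, 0, 1), 0))
  tt <- rep(t, 4); yy <- unlist(reps)
  f <- fit_decay(tt, yy)
  expect_lt(abs(unname(coef(f)["k"]) - 1.44) / 1.44, 0.10)
  oracle <- grid_decay_rss(tt, yy, c(10, 40), c(0.3, 4))
  expect_lte(f$rss, oracle["rss"] * (1 + 1e-6))
})

test_that("fit_sigmoid recovers exact and noisy logistic data", {
  t <- 0:14
  f <- fit_sigmoid(t, sigmoid_value(c(1, 100, 1), t))
  expect_equal(unname(coef(f)), c(1, 100, 1), tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)

  # high starting concentration relative to plateau: no induction phase
  f2 <- fit_sigmoid(0:9, sigmoid_value(c(c0 = 67, cmax = 300, k = 4), 0:9))
  expect_true(f2$converged)
  expect_true(is.na(f2$t_ind))

  set.seed(7)
  t10 <- seq(0, 18, 2)
  tt <- rep(t10, 4)
  yy <- pmax(sigmoid_value(c(5, 1000, 0.9), tt) + rnorm(length(tt), 0, 25), 0)
  fn <- fit_sigmoid(tt, yy)
  est <- coef(fn)
  expect_lt(abs(est["cmax"] - 1000) / 1000, 0.15)
  expect_lt(abs(est["k"] - 0.9) / 0.9, 0.15)
  expect_error(fit_sigmoid(0:2, c(1, 2, 3)), "4 distinct")
})

test_that("flat series are flagged as non-converged with no derived stats", {
  # non-monotone, flat: pure measurement jitter around a constant level
  y <- 50 + c(1, -1, 1, -1, 1, -1, 1, -1, 1)
  f <- fit_sigmoid(c(0, 1, 3, 5, 7, 10, 14, 17, 21), y)
  expect_false(f$converged)
  expect_true(is.na(f$t_star) && is.na(f$t_ind))
})

test_that("closed-form inflection and induction agree with numeric oracle", {
  ip <- inflection_point(c(c0 = 1, cmax = 100, k = 1))
  expect_equal(ip$t_star, log(99), tolerance = 1e-12)
  expect_equal(ip$c_at, 50)
  expect_equal(ip$slope, 25)
  # symmetric start: inflection exactly at t = 0
  expect_equal(inflection_point(c(c0 = 50, cmax = 100, k = 2))$t_star, 0)
  expect_true(inflection_point(c(c0 = 50, cmax = 100, k = 2))$before_start)

  expect_equal(induction_time(c(c0 = 1, cmax = 100, k = 1)), log(99) - 2,
               tolerance = 1e-12)
  # cmax/c0 = e^2 + 1 puts the tangent intercept exactly at the origin: none
  expect_true(is.na(induction_time(c(c0 = 1, cmax = exp(2) + 1, k = 1))))
  expect_true(is.na(induction_time(c(c0 = 67, cmax = 300, k = 4))))

  set.seed(42)
  n <- 1000
  c0 <- 10^runif(n, -2, 2)
  cmax <- c0 * (1 + 10^runif(n, -1, 3))
  k <- 10^runif(n, -1.3, 1.1)
  for (i in seq_len(n)) {
    num <- numeric_inflection(c0[i], cmax[i], k[i])
    ip <- inflection_point(c(c0 = c0[i], cmax = cmax[i], k = k[i]))
    scale_t <- max(abs(ip$t_star), 1 / k[i])
    expect_lt(abs(ip$t_star - num$t_star), 1e-9 * scale_t)
    expect_lt(abs(ip$c_at - num$c_at), 1e-9 * ip$c_at)
    expect_lt(abs(ip$slope - num$slope), 1e-9 * ip$slope)
    closed <- (log((cmax[i] - c0[i]) / c0[i]) - 2) / k[i]
    expect_lt(abs(closed - num$t_ind), 1e-9 * max(abs(closed), 1 / k[i]))
  }
})

test_that("tangent line at the induction time passes through zero", {
  set.seed(11)
  for (i in 1:50) {
    c0 <- runif(1, 0.1, 5)
    cmax <- c0 * exp(2) * runif(1, 1.5, 50)  # ensures t_ind > 0
    k <- runif(1, 0.1, 5)
    p <- c(c0 = c0, cmax = cmax, k = k)
    ti <- induction_time(p)
    ip <- inflection_point(p)
    tangent_at <- function(t) ip$c_at + ip$slope * (t - ip$t_star)
    expect_lt(abs(tangent_at(ti)), 1e-9 * cmax)
  }
})

test_that("increasing k shortens both induction time and half-life", {
  ks <- c(0.2, 0.5, 1, 2, 4)
  ti <- vapply(ks, function(k) induction_time(c(c0 = 1, cmax = 500, k = k)), 0)
  expect_true(all(diff(ti) < 0))
  expect_true(all(diff(half_life(ks)) < 0))
})

test_that("decay fits obey t_half * k = ln 2 by construction", {
  set.seed(5)
  for (i in 1:20) {
    t <- seq(0, 10, length.out = 8)
    y <- pmax(runif(1, 5, 50) * exp(-runif(1, 0.1, 2) * t) + rnorm(8, 0, 0.5), 0)
    f <- fit_decay(t, y)
    if (is.finite(f$t_half))
      expect_equal(f$t_half * unname(coef(f)["k"]), log(2), tolerance = 1e-12)
  }
})

test_that("aggregate_replicates reports the replicate-averaged half-life", {
  t <- 0:6
  f1 <- fit_decay(t, 24 * exp(-1.0 * t))
  f2 <- fit_decay(t, 24 * exp(-2.0 * t))
  s <- aggregate_replicates(list(f1, f2))
  expect_equal(s$k_mean, 1.5, tolerance = 1e-6)
  # mean of half-lives, not half-life of the mean rate (Jensen gap)
  expect_equal(s$t_half_mean, (log(2) / 1 + log(2) / 2) / 2, tolerance = 1e-6)
  expect_equal(s$t_half_from_mean_k, log(2) / 1.5, tolerance = 1e-6)
  expect_gt(s$t_half_mean, s$t_half_from_mean_k)

  s2 <- aggregate_replicates(list(f1, f1))
  expect_equal(s2$k_sd, 0)

  expect_error(aggregate_replicates(list(f1)), "two")
  fs <- fit_sigmoid(0:9, sigmoid_value(c(1, 100, 1), 0:9))
  expect_error(aggregate_replicates(list(f1, fs)), "mixed")
  f3 <- fit_decay(kinetic_series(t, 24 * exp(-t), "anthocyanin", pH = 3))
  f4 <- fit_decay(kinetic_series(t, 24 * exp(-t), "anthocyanin", pH = 4))
  expect_error(aggregate_replicates(list(f3, f4)), "conditions")
})

test_that("fit methods are mutually consistent", {
  t <- 0:8
  set.seed(2)
  y <- pmax(20 * exp(-0.7 * t) + rnorm(9, 0, 0.4), 0)
  f <- fit_decay(t, y)
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(predict(f, newdata = data.frame(day = t)), fitted(f))
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-10)
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(9L, 3L))
  expect_true(all(sims >= 0))
  expect_output(print(summary(f)), "Residual standard error")
})
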