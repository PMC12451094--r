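# Independent oracles used across the suite. They deliberately avoid the
# closed forms and code paths of the package: numeric differentiation for
# the inflection/tangent construction, grid search for least-squares
# optima, trapezoidal 1-nm integration for colorimetry.

sig_fun <- function(c0, cmax, k) function(t)
  cmax / (1 + (cmax - c0) / c0 * exp(-k * t))

# Richardson-extrapolated central differences
num_d1 <- function(f, t, h) {
  d <- function(h) (f(t + h) - f(t - h)) / (2 * h)
  (4 * d(h / 2) - d(h)) / 3
}
num_d2 <- function(f, t, h) {
  d <- function(h) (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  (4 * d(h / 2) - d(h)) / 3
}

# numeric inflection: bracket at the argmax of the numeric first derivative
# (robust against rounding noise in the flat tails), then root-find the
# Richardson second difference; step h balances truncation against rounding
numeric_inflection <- function(c0, cmax, k) {
  f <- sig_fun(c0, cmax, k)
  h <- 5e-3 / k
  d2 <- function(t) num_d2(f, t, h)
  span <- 40 / k
  grid <- seq(-span, span, length.out = 4001)
  d1g <- (f(grid + h) - f(grid - h)) / (2 * h)
  i <- which.max(d1g)
  stopifnot(i > 1, i < length(grid))
  lo <- grid[i - 1]; hi <- grid[i + 1]
  # widen until the second difference changes sign across the bracket
  while (sign(d2(lo)) == sign(d2(hi))) {
    w <- hi - lo; lo <- lo - w; hi <- hi + w
  }
  t_star <- stats::uniroot(d2, c(lo, hi), tol = 1e-14 * max(1, abs(hi)))$root
  slope <- num_d1(f, t_star, h)
  c_at <- f(t_star)
  list(t_star = t_star, c_at = c_at, slope = slope,
       t_ind = t_star - c_at / slope)
}

# brute-force least squares for exponential decay on a refined grid
grid_decay_rss <- function(t, y, C0_range, k_range, n = 60, passes = 3) {
  best <- c(C0 = NA, k = NA, rss = Inf)
  for (p in seq_len(passes)) {
    C0s <- seq(C0_range[1], C0_range[2], length.out = n)
    ks <- seq(k_range[1], k_range[2], length.out = n)
    for (C0 in C0s) for (k in ks) {
      rss <- sum((y - C0 * exp(-k * t))^2)
      if (rss < best["rss"]) best <- c(C0 = C0, k = k, rss = rss)
    }
    dC <- diff(C0_range) / n; dk <- diff(k_range) / n
    C0_range <- c(best["C0"] - 2 * dC, best["C0"] + 2 * dC)
    k_range <- c(max(best["k"] - 2 * dk, 0), best["k"] + 2 * dk)
  }
  best
}

# trapezoidal colorimetric integration on a 1-nm grid, written without the
# package's integration path (its own normalisation, rule and grid)
oracle_lab <- function(wl, A) {
  tab <- pigmentox::cie_tables(step = 1)
  a <- stats::approx(wl, A, xout = tab$wavelength, rule = 2)$y
  Tr <- 10^(-a)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2)
  kn <- 100 / trap(tab$illuminant * tab$ybar)
  X <- kn * trap(Tr * tab$illuminant * tab$xbar)
  Y <- kn * trap(Tr * tab$illuminant * tab$ybar)
  Z <- kn * trap(Tr * tab$illuminant * tab$zbar)
  Xn <- kn * trap(tab$illuminant * tab$xbar)
  Zn <- kn * trap(tab$illuminant * tab$zbar)
  fl <- function(t) ifelse(t > 216/24389, t^(1/3), (24389/27 * t + 16) / 116)
  c(L = 116 * fl(Y / 100) - 16,
    a = 500 * (fl(X / Xn) - fl(Y / 100)),
    b = 200 * (fl(Y / 100) - fl(Z / Zn)))
}

make_flat_wl <- function() seq(380, 780, by = 1)

toy_kinetic_csv <- function(path, shuffle = FALSE) {
  df <- expand.grid(replicate = 1:2, day = c(0, 1, 3, 7))
  df$sample_id <- "s1"; df$pH <- 2; df$extract_dose <- 0.73
  df$analyte <- "anthocyanin"
  df$value <- 24 * exp(-1.44 * df$day) + df$replicate / 10
  if (shuffle) df <- df[sample(nrow(df)), ]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
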