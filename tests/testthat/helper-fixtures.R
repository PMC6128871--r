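# Shared in-code fixtures. All spectra are generated; nothing is read from
# disk unless a test writes it first.

# triangular band of height 0.5 over 1000-1060 cm^-1 (apex 1030) on a 2 cm^-1
# grid, zero elsewhere; trapezoid area of the band is exactly 15
triangle_spectrum <- function(height = 0.5, id = "triangle") {
  w <- seq(650, 4000, by = 2)
  a <- numeric(length(w))
  rising <- w >= 1000 & w <= 1030
  falling <- w > 1030 & w <= 1060
  a[rising] <- height * (w[rising] - 1000) / 30
  a[falling] <- height * (1060 - w[falling]) / 30
  ftir_spectrum(w, a, sample_id = id)
}

# five-band organic spectrum with known centers, mild baseline, no noise
five_band_spectrum <- function(seed = NULL, noise_sd = 0, step = 2) {
  generate_spectrum(
    bands = list(band_spec(1030, 0.45, 30), band_spec(1510, 0.12, 15),
                 band_spec(1630, 0.15, 20), band_spec(2850, 0.05, 12),
                 band_spec(2920, 0.06, 14), band_spec(3400, 0.12, 200)),
    baseline = c(0.02, 0),
    noise_sd = noise_sd, grid = default_wavenumber_grid(step),
    seed = seed, sample_id = "five_band"
  )
}

# five-band spectrum with sharp V-shaped notches cut into every endpoint
# search window, so adaptive endpoints sit on unambiguous local minima that
# a mild global ramp cannot displace (used for exact-invariance properties)
notched_spectrum <- function() {
  s <- five_band_spectrum()
  w <- s$wavenumbers
  a <- s$absorbance
  for (ctr in c(920, 1130, 1460, 1560, 1740, 2780, 2880, 2990)) {
    near <- abs(w - ctr) <= 6
    a[near] <- a[near] - 0.06 * (1 - abs(w[near] - ctr) / 6)
  }
  ftir_spectrum(w, a, sample_id = "notched")
}

# brute-force simple OLS via normal equations (independent of lm)
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - slope * x - intercept
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2) / sxx)
  tstat <- slope / se_slope
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sse / sst,
       see = sqrt(sse / (n - 2)),
       p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# brute-force pooled two-sample t
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# brute-force tricube local weighted quadratic fit (loess oracle)
loess_oracle <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0, function(x0i) {
    d <- abs(x - x0i)
    h <- sort(d)[q]
    w <- pmax(0, 1 - (d / h)^3)^3
    X <- stats::poly(x - x0i, degree = degree, raw = TRUE)
    X <- cbind(1, X)
    b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    b[1L]
  }, numeric(1))
}
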