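make_composition <- function(core, depth, carb, arom = 30 - carb / 10,
                             lat = 50, temp = 28 - 0.42 * lat,
                             excluded = FALSE) {
  n <- length(depth)
  data.frame(sample_id = paste0(core, "_", seq_len(n)), material = "peat",
             site = rep_len(core, n), category = "x", depth_cm = depth,
             latitude_deg = rep_len(lat, n),
             mean_annual_temp_C = rep_len(temp, n),
             excluded = rep_len(excluded, n),
             carb_est = carb, arom_est = arom,
             stringsAsFactors = FALSE)
}

test_that("surface summary averages the sections above the depth cutoff", {
  tab <- make_composition("A", c(10, 30, 70), c(10, 20, 99))
  s <- surface_summary(tab)
  expect_identical(s$n_sections, 2L)
  expect_equal(s$mean_carb, 15)
  expect_equal(s$sd_carb, sqrt(50), tolerance = 1e-9)  # ~7.071

  one <- surface_summary(make_composition("B", 5, 42))
  expect_equal(one$mean_carb, 42)
  expect_true(is.na(one$sd_carb))

  expect_warning(deep <- surface_summary(make_composition("C", c(60, 80),
                                                          c(1, 2))),
                 "omitted")
  expect_null(deep)

  # invariant to row order; excluded rows never contribute
  tab2 <- rbind(make_composition("A", c(10, 30, 70), c(10, 20, 99)),
                make_composition("D", c(5, 45), c(50, 60)),
                make_composition("E", 20, 77, excluded = TRUE))
  perm <- tab2[sample(nrow(tab2)), ]
  s1 <- surface_summary(tab2)
  s2 <- surface_summary(perm)
  expect_equal(s1[order(s1$core_id), ], s2[order(s2$core_id), ],
               ignore_attr = TRUE)
  expect_false("E" %in% s1$core_id)
})

test_that("latitudinal regression recovers an exact linear trend", {
  lats <- c(10, 25, 40, 55, 70)
  summaries <- data.frame(core_id = letters[1:5], n_sections = 3,
                          mean_carb = 0.5 * lats + 10,
                          sd_carb = 1, mean_arom = 50 - 0.4 * lats,
                          sd_arom = 1, latitude_deg = lats,
                          mean_annual_temp_C = 28 - 0.42 * lats)
  r <- suppressWarnings(  # summary.lm flags the perfect fit
    latitudinal_regression(summaries, "mean_carb", "latitude_deg"))
  expect_equal(r$slope, 0.5, tolerance = 1e-10)
  expect_equal(r$intercept, 10, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_identical(r$n, 5L)
  summaries$latitude_deg <- 45
  expect_error(latitudinal_regression(summaries, "mean_carb",
                                      "latitude_deg"), "degenerate")
})

test_that("pooled t test matches the closed form and handles degeneracy", {
  r <- pooled_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-9)  # -1.2247
  expect_identical(r$df, 4L)
  expect_equal(r$p_value, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-9)  # 0.2879

  same <- pooled_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const_eq <- pooled_t_test(c(2, 2), c(2, 2, 2))
  expect_equal(const_eq$t, 0)
  expect_equal(const_eq$p_value, 1)
  expect_warning(const_ne <- pooled_t_test(c(2, 2), c(3, 3)), "zero pooled")
  expect_equal(const_ne$p_value, 0)

  single <- pooled_t_test(4, c(1, 2, 3))
  expect_true(is.na(single$t))
  expect_match(single$note, "n < 2")

  # swapping the groups negates t and preserves p exactly
  set.seed(12)
  a <- rnorm(8); b <- rnorm(11, 0.5)
  r1 <- pooled_t_test(a, b); r2 <- pooled_t_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_identical(r1$p_value, r2$p_value)
  o <- pooled_t_oracle(a, b)
  expect_equal(r1$t, o$t, tolerance = 1e-8)
  expect_equal(r1$p_value, o$p, tolerance = 1e-8)
})

test_that("loess depth profiles reproduce local regression exactly", {
  # degree-2 local fits are exact on globally quadratic data
  set.seed(7)
  depth <- sort(runif(30, 0, 200))
  quad <- 60 - 0.4 * depth + 8e-4 * depth^2
  prof <- loess_profile(depth, quad, at = depth)
  expect_equal(prof$fit, quad, tolerance = 1e-8)

  # constant data: flat curve, zero-width band
  const <- loess_profile(depth, rep(5, 30), at = c(10, 100, 190))
  expect_equal(const$fit, rep(5, 3), tolerance = 1e-9)
  expect_lt(max(const$upper - const$lower), 1e-8)

  # 20-point fixture against the brute-force tricube WLS oracle
  set.seed(8)
  x <- sort(runif(20, 0, 100))
  y <- 30 + 0.2 * x - 0.002 * x^2 + rnorm(20, 0, 2)
  at <- c(5, 25, 50, 75, 95)
  prof2 <- loess_profile(x, y, at = at)
  expect_equal(prof2$fit, loess_oracle(x, y, at), tolerance = 1e-8)

  # latitude grouping splits at 45 degrees, boundary counts as high
  g <- loess_profile(rep(depth, 2), c(quad, quad + 5),
                     latitude = rep(c(45, 20), each = 30), at = c(50, 100))
  expect_setequal(unique(g$group), c("high_latitude", "low_latitude"))
  expect_warning(loess_profile(1:3, 1:3, latitude = rep(10, 3)),
                 "skipped")
})

test_that("spectral PCA preprocesses to constant area and matches an eigen oracle", {
  set.seed(21)
  spectra <- lapply(1:6, function(i) five_band_spectrum(seed = i,
                                                        noise_sd = 0.004,
                                                        step = 10))
  for (i in 1:6) spectra[[i]]$sample_id <- paste0("s", i)
  p <- pca_spectra(spectra)
  areas <- apply(p$preprocessed, 1, function(a) {
    sum(diff(p$grid) * (a[-1] + a[-length(a)])) / 2
  })
  expect_equal(areas, rep(100, 6), tolerance = 1e-9, ignore_attr = TRUE)

  # variance conservation and reconstruction of the centered matrix
  centered <- scale(p$preprocessed, center = TRUE, scale = FALSE)
  expect_equal(sum(p$explained_variance),
               sum(centered^2) / (nrow(centered) - 1), tolerance = 1e-9)
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)

  # eigen-decomposition oracle on the sample covariance of a small set
  ev <- eigen(stats::cov(p$preprocessed), symmetric = TRUE)
  k <- nrow(centered) - 1
  expect_equal(p$explained_variance[1:k], ev$values[1:k], tolerance = 1e-8)
  oracle_scores <- centered %*% ev$vectors[, 1:k]
  for (j in 1:k) {
    expect_equal(abs(p$scores[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # deterministic sign convention
  for (j in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  # identical spectra: zero variance, zero scores
  same <- pca_spectra(replicate(4, five_band_spectrum(), simplify = FALSE))
  expect_equal(sum(same$explained_variance), 0, tolerance = 1e-12)
  expect_equal(max(abs(same$scores)), 0, tolerance = 1e-8)
})

test_that("external-variable vectors recover axis-aligned gradients", {
  set.seed(31)
  spectra <- lapply(1:12, function(i) five_band_spectrum(seed = i,
                                                         noise_sd = 0.01))
  for (i in 1:12) spectra[[i]]$sample_id <- paste0("s", i)
  p <- pca_spectra(spectra)
  v <- data.frame(pc1_copy = p$scores[, 1],
                  flat = rep(1, 12),
                  noise = rnorm(12))
  expect_warning(fits <- fit_external_vectors(p$scores, v, n_perm = 199,
                                              seed = 5), "constant")
  pc1 <- fits[fits$variable == "pc1_copy", ]
  expect_equal(abs(pc1$dx), 1, tolerance = 1e-8)
  expect_equal(pc1$r_squared, 1, tolerance = 1e-10)
  expect_equal(pc1$p_perm, 1 / 200)
  flat <- fits[fits$variable == "flat", ]
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_perm, 1)

  # pure-noise variables are mostly non-significant across seeded repeats
  set.seed(77)
  ps <- vapply(1:20, function(i) {
    fit_external_vectors(p$scores, data.frame(x = rnorm(12)),
                         n_perm = 199, seed = i)$p_perm
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85)

  # determinism in the seeded permutation p
  f1 <- fit_external_vectors(p$scores, v["noise"], n_perm = 199, seed = 9)
  f2 <- fit_external_vectors(p$scores, v["noise"], n_perm = 199, seed = 9)
  expect_identical(f1, f2)
})

test_that("vector fits agree with an independent ordination implementation", {
  skip_if_not_installed("vegan")
  set.seed(41)
  spectra <- lapply(1:15, function(i) five_band_spectrum(seed = i + 100,
                                                         noise_sd = 0.01))
  for (i in 1:15) spectra[[i]]$sample_id <- paste0("s", i)
  p <- pca_spectra(spectra)
  v <- data.frame(grad = p$scores[, 1] * 0.7 + p$scores[, 2] * 0.3 +
                    rnorm(15, 0, 0.05))
  mine <- fit_external_vectors(p$scores, v, n_perm = 199, seed = 3)
  ef <- vegan::envfit(p$scores[, 1:2], v, permutations = 199)
  expect_equal(mine$r_squared, unname(ef$vectors$r), tolerance = 1e-8)
  arrow <- ef$vectors$arrows[1, ]
  expect_equal(abs(c(mine$dx, mine$dy)), abs(unname(arrow)),
               tolerance = 1e-6)
})

test_that("humification indices are height ratios anchored on the carb band", {
  m <- data.frame(peak_name = c("carb", "arom15", "arom16", "aliph28",
                                "aliph29"),
                  normalized_height = rep(2e-3, 5))
  h <- humification_indices(m)
  expect_equal(h$arom_carb_ratio, 2)
  expect_equal(h$aliph_carb_ratio, 2)
  m0 <- m
  m0$normalized_height[1] <- 0
  expect_warning(h0 <- humification_indices(m0), "undefined")
  expect_true(is.na(h0$arom_carb_ratio))

  # invariant under spectrum scaling
  defs <- default_peak_definitions()
  s <- five_band_spectrum(seed = 51, noise_sd = 0.002)
  h1 <- humification_indices(measure_all(s, defs = defs))
  h2 <- humification_indices(measure_all(
    ftir_spectrum(s$wavenumbers, 5 * s$absorbance), defs = defs))
  expect_equal(h1$arom_carb_ratio, h2$arom_carb_ratio, tolerance = 1e-9)
  expect_equal(h1$aliph_carb_ratio, h2$aliph_carb_ratio, tolerance = 1e-9)
})
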