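test_that("endpoints fall on plateau minima with lowest-wavenumber ties", {
  s <- triangle_spectrum()
  left <- find_endpoint(s, c(980, 1010))
  right <- find_endpoint(s, c(1050, 1090))
  expect_equal(left$position, 980)
  expect_equal(right$position, 1060)
  expect_identical(left$method, "local_minimum")
  expect_identical(right$method, "local_minimum")
})

test_that("monotone spectra fall back to the second-derivative maximum", {
  w <- seq(650, 4000, by = 2)
  # piecewise-linear, strictly decreasing, convex kink at 1010 cm^-1
  a <- ifelse(w <= 1010, 10 - 0.002 * w, 10 - 0.002 * 1010 - 0.001 * (w - 1010))
  s <- ftir_spectrum(w, a)
  ep <- find_endpoint(s, c(1000, 1020))
  expect_equal(ep$position, 1010)
  expect_identical(ep$method, "second_derivative")
})

test_that("endpoint positions are invariant to positive scaling", {
  s <- five_band_spectrum(seed = 7, noise_sd = 0.003)
  for (win in list(c(850, 1000), c(1080, 1180), c(1535, 1590))) {
    e1 <- find_endpoint(s, win)
    e2 <- find_endpoint(ftir_spectrum(s$wavenumbers, 4.2 * s$absorbance), win)
    expect_equal(e1$position, e2$position)
    expect_identical(e1$method, e2$method)
  }
})

test_that("endpoint windows must be wide enough and inside the grid", {
  s <- triangle_spectrum()
  expect_error(find_endpoint(s, c(1000, 1001)), "fewer than 3")
  expect_error(find_endpoint(s, c(640, 700)), "edge")
  expect_error(find_endpoint(s, c(3990, 4000)), "edge")
})

test_that("baseline correction subtracts the endpoint chord", {
  w <- seq(650, 4000, by = 2)
  # affine trace with a bump: A(1000)=0.2, A(1060)=0.1, plus 0.4 bump at 1030
  base <- 0.2 - (0.1 / 60) * (w - 1000)
  bump <- ifelse(w >= 1000 & w <= 1060,
                 0.35 * (1 - abs(w - 1030) / 30), 0)
  s <- ftir_spectrum(w, base + bump)
  bc <- baseline_correct(s, 1000, 1060)
  expect_equal(bc$corrected[1L], 0)
  expect_equal(bc$corrected[length(bc$corrected)], 0)
  i1030 <- which(bc$wavenumbers == 1030)
  # raw 0.5 at 1030 against the 0.15 chord midpoint
  expect_equal(s$absorbance[w == 1030], 0.5)
  expect_equal(bc$corrected[i1030], 0.35)
})

test_that("a global linear ramp does not change the corrected segment", {
  s <- five_band_spectrum(seed = 8, noise_sd = 0.002)
  ramp <- ftir_spectrum(s$wavenumbers,
                        s$absorbance + 0.3 + 2e-4 * s$wavenumbers)
  b1 <- baseline_correct(s, 1000, 1080)
  b2 <- baseline_correct(ramp, 1000, 1080)
  expect_equal(b1$corrected, b2$corrected, tolerance = 1e-10)
  # exactly linear across the segment: corrected is identically zero
  lin <- ftir_spectrum(s$wavenumbers, 1 + 5e-4 * s$wavenumbers)
  expect_equal(baseline_correct(lin, 1000, 1080)$corrected,
               rep(0, 41), tolerance = 1e-12)
})

test_that("off-grid endpoints are refused", {
  s <- triangle_spectrum()
  expect_error(baseline_correct(s, 1000.5, 1060), "grid")
  expect_error(baseline_correct(s, 1060, 1000), "below")
})

test_that("measure_peak reports corrected and area-normalized heights", {
  s <- triangle_spectrum()  # area 15
  def <- peak_definition("carb", 1030, c(980, 1010), c(1050, 1090))
  m <- measure_peak(s, def)
  expect_equal(m$peak_position, 1030)
  expect_equal(m$corrected_height, 0.5, tolerance = 1e-9)
  expect_equal(m$normalized_height, 0.5 / 15, tolerance = 1e-9)
  expect_true(m$left_endpoint < m$peak_position &
                m$peak_position < m$right_endpoint)
  # scaling the spectrum leaves the normalized height unchanged
  m2 <- measure_peak(ftir_spectrum(s$wavenumbers, 3 * s$absorbance), def)
  expect_equal(m2$normalized_height, m$normalized_height, tolerance = 1e-10)
  expect_error(measure_peak(s, def, total_area = 0), "not positive")
})

test_that("measure_all maps over definitions and matches generator truth", {
  s <- five_band_spectrum()
  defs <- default_peak_definitions()
  expect_identical(nrow(measure_all(s, defs = list())), 0L)
  one <- measure_all(s, defs = defs["carb"])
  expect_identical(nrow(one), 1L)
  expect_equal(one$normalized_height,
               measure_peak(s, defs$carb)$normalized_height)
  all5 <- measure_all(s, defs = defs)
  expect_identical(nrow(all5), 5L)
  centers <- c(carb = 1030, arom15 = 1510, arom16 = 1630,
               aliph28 = 2850, aliph29 = 2920)
  expect_true(all(abs(all5$peak_position - centers[all5$peak_name]) <= 2))
})

test_that("normalized heights are scale-invariant and corrected heights are affine-invariant", {
  defs <- default_peak_definitions()
  for (seed in 1:5) {
    s <- five_band_spectrum(seed = seed, noise_sd = 0.003)
    m <- measure_all(s, defs = defs)
    for (c_ in c(0.5, 2, 10)) {
      mc <- measure_all(ftir_spectrum(s$wavenumbers, c_ * s$absorbance,
                                      s$sample_id), defs = defs)
      expect_equal(mc$normalized_height, m$normalized_height,
                   tolerance = 1e-10)
    }
    # endpoint containment within the search windows
    for (i in seq_len(nrow(m))) {
      d <- defs[[m$peak_name[i]]]
      expect_true(d$left_window[1] <= m$left_endpoint[i] &
                    m$left_endpoint[i] <= d$left_window[2])
      expect_true(d$right_window[1] <= m$right_endpoint[i] &
                    m$right_endpoint[i] <= d$right_window[2])
    }
  }

  # affine invariance, on a fixture whose endpoints are sharp V minima that
  # a mild global ramp cannot displace: corrected heights are unchanged and
  # normalized heights change only through the total area
  s <- notched_spectrum()
  m <- measure_all(s, defs = defs)
  ramp <- ftir_spectrum(s$wavenumbers,
                        s$absorbance + 0.15 + 1e-4 * s$wavenumbers,
                        s$sample_id)
  mr <- measure_all(ramp, defs = defs)
  expect_equal(mr$left_endpoint, m$left_endpoint)
  expect_equal(mr$right_endpoint, m$right_endpoint)
  expect_equal(mr$corrected_height, m$corrected_height, tolerance = 1e-10)
  expect_equal(mr$normalized_height,
               m$corrected_height / integrate_spectrum(ramp),
               tolerance = 1e-10)
})

test_that("endpoint method is exhaustive over monotone and dipped windows", {
  w <- seq(1000, 1078, by = 2)  # 40 points
  win <- c(1020, 1060)
  set.seed(421)
  for (i in 1:500) {
    # strictly monotone through the window: curvature only, no local minimum
    a <- cumsum(runif(length(w), 0.01, 0.2)) * sample(c(-1, 1), 1)
    ep <- find_endpoint(ftir_spectrum(w, a), win)
    expect_identical(ep$method, "second_derivative")
    # carve an interior dip: must switch to local_minimum
    j <- sample(12:30, 1)
    a2 <- a
    a2[j] <- min(a[j - 1], a[j + 1]) - 0.5
    ep2 <- find_endpoint(ftir_spectrum(w, a2), win)
    expect_identical(ep2$method, "local_minimum")
    expect_equal(ep2$position, w[j])
  }
})

test_that("silicate screen requires mineral diagnostics plus a large carb peak", {
  w <- default_wavenumber_grid()
  flat <- suppressWarnings(screen_silicate(ftir_spectrum(w, rep(0, length(w)))))
  expect_false(flat$flagged)
  expect_length(flat$evidence, 0L)

  mineral <- generate_spectrum(
    bands = list(band_spec(1030, 1.2, 30), band_spec(3695, 0.12, 8),
                 band_spec(3620, 0.12, 8), band_spec(780, 0.1, 8),
                 band_spec(3400, 0.05, 200)),
    baseline = c(0.01, 0), sample_id = "mineral")
  sc <- screen_silicate(mineral)
  expect_true(sc$flagged)
  expect_setequal(sc$evidence,
                  c("kaolinite_3695", "kaolinite_3620", "silicate_780"))

  organic <- generate_spectrum(
    bands = list(band_spec(1030, 1.2, 30), band_spec(3400, 0.05, 200)),
    baseline = c(0.01, 0), sample_id = "organic")
  expect_false(screen_silicate(organic)$flagged)
})
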