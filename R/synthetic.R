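#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their parameters and seed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default synthetic wavenumber grid
#'
#' 650 to 4000 cm^-1. Instruments at a nominal 4 cm^-1 resolution typically
#' store points every ~2 cm^-1, giving 1676 points at the default step.
#'
#' @param step Grid spacing in cm^-1 (default 2).
#' @return Ascending numeric grid.
#' @export
default_wavenumber_grid <- function(step = 2) seq(650, 4000, by = step)

#' Describe one Gaussian absorption band
#'
#' @param center Band center, cm^-1.
#' @param height Band height, absorbance (non-negative).
#' @param width Gaussian sigma, cm^-1 (positive).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, height, width) {
  if (height < 0) stop("band height must be non-negative", call. = FALSE)
  if (width <= 0) stop("band width must be positive", call. = FALSE)
  structure(list(center = center, height = height, width = width),
            class = "band_spec")
}

gaussian_band <- function(grid, center, width) {
  exp(-(grid - center)^2 / (2 * width^2))
}

#' Generate a synthetic band-mixture spectrum
#'
#' Sum of Gaussian bands plus an affine baseline plus seeded white noise on
#' the absorbance scale. Gaussian bands are the simplest shape with an
#' analytic area and are sufficient to exercise endpoint detection, baseline
#' correction and normalization; they do not emulate ATR physics.
#'
#' @param bands List of [band_spec()]s (may be empty).
#' @param baseline Length-2 `(offset, slope)`: absorbance added as
#'   `offset + slope * wavenumber`.
#' @param noise_sd Gaussian noise SD in absorbance units.
#' @param grid Wavenumber grid (default [default_wavenumber_grid()]).
#' @param seed Integer seed; same seed, same spectrum, bit for bit.
#' @param sample_id Sample identifier.
#' @return A [ftir_spectrum()].
#' @export
generate_spectrum <- function(bands = list(), baseline = c(0, 0),
                              noise_sd = 0, grid = default_wavenumber_grid(),
                              seed = NULL, sample_id = "synthetic") {
  if (length(grid) < 16L) stop("grid too short", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  a <- baseline[1L] + baseline[2L] * grid
  for (b in bands) a <- a + b$height * gaussian_band(grid, b$center, b$width)
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  ftir_spectrum(grid, a, sample_id = sample_id)
}

# The linear map tying composition (wt%) to normalized corrected peak
# heights (cm) used by all generators: height = (composition - intercept) /
# slope. Slopes sized so typical heights are a few 1e-3 cm.
#' @rdname generate_calibration_set
#' @export
ftir_linear_map <- function() {
  list(carb = list(slope = 20000, intercept = -5),
       arom = list(slope = 8000, intercept = 0))
}

# fixed band shapes for the five organic bands
organic_band_shapes <- function() {
  list(carb = list(center = 1030, width = 30),
       arom15 = list(center = 1510, width = 15),
       arom16 = list(center = 1630, width = 20),
       aliph28 = list(center = 2850, width = 12),
       aliph29 = list(center = 2920, width = 14))
}

# Build a spectrum whose measured normalized corrected heights hit the
# targets `t` (named vector, cm), given a per-sample background. Solves the
# self-consistency between raw band heights and total area: with unit band
# areas a_b and background area A_bg, A = A_bg / (1 - sum(t_b * a_b)) and
# raw heights u_b = t_b * A.
spectrum_from_targets <- function(targets, grid, background, noise_sd,
                                  seed, sample_id) {
  shapes <- organic_band_shapes()
  unit_areas <- vapply(names(targets), function(nm) {
    sh <- shapes[[nm]]
    trapz_area(grid, gaussian_band(grid, sh$center, sh$width))
  }, numeric(1))
  a_bg <- trapz_area(grid, background)
  if (a_bg <= 0)
    stop("background area must be positive", call. = FALSE)
  load <- sum(targets * unit_areas)
  if (load >= 1)
    stop("target heights too large for a positive-area spectrum",
         call. = FALSE)
  total <- a_bg / (1 - load)
  a <- background
  for (nm in names(targets)) {
    sh <- shapes[[nm]]
    a <- a + targets[[nm]] * total * gaussian_band(grid, sh$center, sh$width)
  }
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  ftir_spectrum(grid, a, sample_id = sample_id)
}

# per-sample background: broad O-H band, a variable broad shoulder under the
# aromatic region (what baseline correction exists to remove), offset + tilt
synthetic_background <- function(grid, oh_height = 0.12, shoulder_height = 0,
                                 offset = 0.02, tilt = 0) {
  oh_height * gaussian_band(grid, 3400, 200) +
    shoulder_height * gaussian_band(grid, 1600, 150) +
    offset + tilt * grid
}

#' Generate a synthetic calibration-standard set
#'
#' Emulates the structure of a wet-chemistry calibration set: `n` standards
#' with compositions drawn uniformly, normalized peak heights linear in
#' composition through [ftir_linear_map()], composition re-observed with
#' Gaussian noise, and class labels including OMG and OFF so the exclusion
#' rules are exercised. The default ranges and noise SDs are fixed by design
#' to emulate a calibration of realistic strength (see the package
#' vignette): carbohydrates U(20, 82) wt\% with sigma 9, aromatics U(8, 28)
#' wt\% with sigma 5.
#'
#' OMG standards receive a positive carbohydrate-height bias (the clay
#' coating band) and OFF standards a positive aromatic-height bias, making
#' them off-calibration for the analyte that excludes them.
#'
#' @param n Number of standards (at least `n_omg + n_off + 6`; default 58).
#' @param carb_range,arom_range Uniform composition ranges, wt\%.
#' @param carb_noise_sd,arom_noise_sd Wet-chemistry observation noise, wt\%.
#' @param n_omg,n_off Counts of OMG and OFF standards (default 4 each).
#' @param omg_carb_bias,off_arom_bias Height biases, cm.
#' @param map Height-composition map, see [ftir_linear_map()].
#' @param seed Integer seed (mandatory; generators are deterministic).
#' @return A [calibration_standards()] table with extra columns
#'   `true_carb` and `true_arom` (noise-free compositions).
#' @export
generate_calibration_set <- function(n = 58, carb_range = c(20, 82),
                                     arom_range = c(8, 28),
                                     carb_noise_sd = 9, arom_noise_sd = 5,
                                     n_omg = 4, n_off = 4,
                                     omg_carb_bias = 1.5e-3,
                                     off_arom_bias = 8e-4,
                                     map = ftir_linear_map(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n < n_omg + n_off + 6)
    stop("n must be at least n_omg + n_off + 6", call. = FALSE)
  with_seed(seed, {
    classes <- sample(c(rep_len(setdiff(standard_classes, c("OMG", "OFF")),
                                n - n_omg - n_off),
                        rep("OMG", n_omg), rep("OFF", n_off)))
    true_carb <- stats::runif(n, carb_range[1L], carb_range[2L])
    true_arom <- stats::runif(n, arom_range[1L], arom_range[2L])
    true_arom[classes == "OFF"] <-
      stats::runif(sum(classes == "OFF"), 1, 5)  # chemical pulp: lignin removed
    carb_h <- (true_carb - map$carb$intercept) / map$carb$slope
    arom_sum_h <- (true_arom - map$arom$intercept) / map$arom$slope
    # the arom15/arom16 partition varies widely between materials, so each
    # single band predicts lignin far worse than their sum
    split <- stats::runif(n, 0.15, 0.75)
    arom15_h <- split * arom_sum_h
    arom16_h <- (1 - split) * arom_sum_h
    carb_h[classes == "OMG"] <- carb_h[classes == "OMG"] + omg_carb_bias
    arom15_h[classes == "OFF"] <- arom15_h[classes == "OFF"] +
      0.5 * off_arom_bias
    arom16_h[classes == "OFF"] <- arom16_h[classes == "OFF"] +
      0.5 * off_arom_bias
    obs_carb <- pmin(100, pmax(0, true_carb + stats::rnorm(n, 0, carb_noise_sd)))
    obs_arom <- pmin(100, pmax(0, true_arom + stats::rnorm(n, 0, arom_noise_sd)))
    out <- calibration_standards(
      sample_id = sprintf("std%02d", seq_len(n)),
      standard_class = classes,
      carb_height = carb_h,
      arom15_height = arom15_h,
      arom16_height = arom16_h,
      pct_cellulose_hemicellulose = obs_carb,
      pct_klason_lignin = obs_arom
    )
    out$true_carb <- true_carb
    out$true_arom <- true_arom
    out
  })
}

#' Generate spectra realizing a standards table
#'
#' Builds one band-mixture spectrum per standard whose measured normalized
#' corrected peak heights match the table's stored heights, on top of a
#' per-sample background with a variable broad shoulder under the aromatic
#' region, an offset and a tilt. Because the shoulder, offset and tilt vary
#' between samples, raw (non-baseline-corrected) heights are contaminated
#' while corrected heights are not — the situation endpoint-chord baseline
#' correction exists to fix.
#'
#' @param standards A [calibration_standards()] table.
#' @param aliph_height Target aliphatic normalized height per band, cm.
#' @param shoulder_sd SD of the half-normal shoulder height, absorbance.
#' @param offset_range Uniform range of the baseline offset, absorbance.
#' @param tilt_sd SD of the baseline tilt, absorbance per cm^-1.
#' @param noise_sd White-noise SD, absorbance.
#' @param grid Wavenumber grid.
#' @param seed Integer seed (mandatory).
#' @return Named list of [ftir_spectrum()]s, one per standard.
#' @export
generate_standard_spectra <- function(standards, aliph_height = 3e-4,
                                      shoulder_sd = 0.12,
                                      offset_range = c(0.01, 0.04),
                                      tilt_sd = 2e-6, noise_sd = 0.002,
                                      grid = default_wavenumber_grid(),
                                      seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- nrow(standards)
  with_seed(seed, {
    sh <- abs(stats::rnorm(n, 0, shoulder_sd))
    off <- stats::runif(n, offset_range[1L], offset_range[2L])
    tilt <- stats::rnorm(n, 0, tilt_sd)
    sub_seeds <- sample.int(2^31 - 2, n)
    spectra <- lapply(seq_len(n), function(i) {
      bg <- synthetic_background(grid, shoulder_height = sh[i],
                                 offset = off[i], tilt = tilt[i])
      targets <- c(carb = standards$carb_height[i],
                   arom15 = standards$arom15_height[i],
                   arom16 = standards$arom16_height[i],
                   aliph28 = aliph_height, aliph29 = aliph_height)
      spectrum_from_targets(targets, grid, bg, noise_sd, sub_seeds[i],
                            standards$sample_id[i])
    })
    names(spectra) <- standards$sample_id
    spectra
  })
}

#' Parameters of a synthetic latitudinal transect
#'
#' Defaults emulate the structure of a pole-to-equator peatland transect:
#' core latitudes at the study sites' values (subarctic Sweden to Borneo),
#' carbohydrate content rising with latitude and falling with depth at high
#' latitudes, aromatic content falling with latitude, composition observed
#' with between-sample noise, plus a set of peat-forming plant samples.
#'
#' @param latitudes Core latitudes, degrees N (3 or more).
#' @param depths Section midpoint depths per core, cm.
#' @param carb_lat_slope Carbohydrate trend with latitude, wt\% per degree.
#' @param carb_equator Carbohydrate content at 0 deg N surface, wt\%.
#' @param arom_lat_slope,arom_equator Same for aromatics.
#' @param carb_depth_slope_highlat Carbohydrate trend with depth in cores at
#'   or above the latitude split, wt\% per cm (negative: loss with depth).
#' @param arom_depth_slope_highlat Aromatic depth trend at high latitude.
#' @param lat_split Latitude separating high from low cores (default 45).
#' @param noise_sd Between-sample composition noise, wt\%.
#' @param n_plants Number of plant samples spread over the cores' latitudes.
#' @param plant_noise_sd Composition noise for plants, wt\%.
#' @param seed Integer seed.
#' @return A `transect_params` list.
#' @export
transect_params <- function(latitudes = c(68.35, 48.29, 48.25, 47.51, 47.51,
                                          47.18, 45.41, 45.41, 35.69, 35.69,
                                          26.60, 26.52, 4.37, 4.37),
                            depths = seq(5, 195, by = 10),
                            carb_lat_slope = 0.55, carb_equator = 18,
                            arom_lat_slope = -0.45, arom_equator = 48,
                            carb_depth_slope_highlat = -0.15,
                            arom_depth_slope_highlat = 0.08,
                            lat_split = 45, noise_sd = 5,
                            n_plants = 39, plant_noise_sd = 7, seed = 1) {
  if (length(latitudes) < 3L) stop("need at least 3 cores", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(latitudes = latitudes, depths = depths,
                 carb_lat_slope = carb_lat_slope, carb_equator = carb_equator,
                 arom_lat_slope = arom_lat_slope, arom_equator = arom_equator,
                 carb_depth_slope_highlat = carb_depth_slope_highlat,
                 arom_depth_slope_highlat = arom_depth_slope_highlat,
                 lat_split = lat_split, noise_sd = noise_sd,
                 n_plants = n_plants, plant_noise_sd = plant_noise_sd,
                 seed = seed),
            class = "transect_params")
}

# noise-free composition surface of the transect
transect_truth <- function(p, lat, depth) {
  high <- lat >= p$lat_split
  depth0 <- ifelse(is.na(depth), 0, depth)
  carb <- p$carb_equator + p$carb_lat_slope * lat +
    ifelse(high, p$carb_depth_slope_highlat * depth0, 0)
  arom <- p$arom_equator + p$arom_lat_slope * lat +
    ifelse(high, p$arom_depth_slope_highlat * depth0, 0)
  list(carb = pmin(95, pmax(2, carb)), arom = pmin(95, pmax(2, arom)))
}

#' Generate a synthetic latitudinal transect
#'
#' Produces peat cores (and optionally plant samples) whose compositions
#' follow known latitudinal and depth gradients, either as a composition
#' table alone (`spectra = FALSE`, fast) or together with band-mixture
#' spectra whose normalized peak heights encode the noisy compositions
#' through [ftir_linear_map()] (`spectra = TRUE`, the full pipeline input).
#' Mean annual temperature is derived from latitude
#' (`28 - 0.42 * latitude` degrees C, an idealized surface-temperature
#' gradient).
#'
#' @param params A [transect_params()].
#' @param spectra Generate spectra as well? Default `TRUE`.
#' @param map Height-composition map ([ftir_linear_map()]).
#' @param noise_sd_absorbance Spectral white noise, absorbance.
#' @return List with `records` ([sample_records()]), `composition`
#'   (`data.frame` with `sample_id`, `true_carb`, `true_arom`, `obs_carb`,
#'   `obs_arom`), and `spectra` (named list, or `NULL`).
#' @export
generate_transect <- function(params = transect_params(), spectra = TRUE,
                              map = ftir_linear_map(),
                              noise_sd_absorbance = 0.002) {
  p <- params
  n_core <- length(p$latitudes)
  core_id <- sprintf("core%02d", seq_len(n_core))
  lat <- rep(p$latitudes, each = length(p$depths))
  depth <- rep(p$depths, times = n_core)
  site <- rep(core_id, each = length(p$depths))
  n_peat <- length(lat)

  plant_lat <- if (p$n_plants > 0)
    rep_len(p$latitudes, p$n_plants) else numeric(0)
  all_lat <- c(lat, plant_lat)
  all_depth <- c(depth, rep(NA_real_, p$n_plants))
  material <- c(rep("peat", n_peat), rep("plant", p$n_plants))
  site <- c(site, sprintf("plants_%s", rep_len(core_id, p$n_plants)))
  ids <- c(sprintf("%s_d%03d", site[seq_len(n_peat)], as.integer(depth)),
           sprintf("plant%02d", seq_len(p$n_plants)))

  truth <- transect_truth(p, all_lat, all_depth)
  with_seed(p$seed, {
    sdv <- c(rep(p$noise_sd, n_peat), rep(p$plant_noise_sd, p$n_plants))
    obs_carb <- pmin(95, pmax(2, truth$carb + stats::rnorm(length(all_lat), 0, sdv)))
    obs_arom <- pmin(95, pmax(2, truth$arom + stats::rnorm(length(all_lat), 0, sdv)))
    records <- sample_records(
      sample_id = ids, material = material, site = site,
      category = ifelse(all_lat >= p$lat_split, "high_latitude",
                        "low_latitude"),
      depth_cm = all_depth, latitude_deg = all_lat,
      mean_annual_temp_C = 28 - 0.42 * all_lat
    )
    composition <- data.frame(sample_id = ids, true_carb = truth$carb,
                              true_arom = truth$arom, obs_carb = obs_carb,
                              obs_arom = obs_arom, stringsAsFactors = FALSE)
    spec_list <- NULL
    if (spectra) {
      grid <- default_wavenumber_grid()
      n <- length(ids)
      sh <- abs(stats::rnorm(n, 0, 0.12))
      off <- stats::runif(n, 0.01, 0.04)
      tilt <- stats::rnorm(n, 0, 2e-6)
      aliph <- pmax(5e-5, 6e-4 - 4e-6 * all_lat) / 2
      sub_seeds <- sample.int(2^31 - 2, n)
      spec_list <- lapply(seq_len(n), function(i) {
        bg <- synthetic_background(grid, shoulder_height = sh[i],
                                   offset = off[i], tilt = tilt[i])
        carb_h <- (obs_carb[i] - map$carb$intercept) / map$carb$slope
        arom_h <- (obs_arom[i] - map$arom$intercept) / map$arom$slope
        targets <- c(carb = carb_h, arom15 = 0.45 * arom_h,
                     arom16 = 0.55 * arom_h,
                     aliph28 = aliph[i], aliph29 = aliph[i])
        spectrum_from_targets(targets, grid, bg, noise_sd_absorbance,
                              sub_seeds[i], ids[i])
      })
      names(spec_list) <- ids
    }
    list(records = records, composition = composition, spectra = spec_list)
  })
}
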