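#' Build a per-sample composition table
#'
#' Joins sample metadata with band measurements and applies the fitted
#' calibrations: estimated \% carbohydrates from the `carb` height,
#' estimated \% aromatics from the summed `arom15 + arom16` height, the
#' (uncalibrated) aliphatic relative abundance, and the classical
#' humification indices. One row per sample; excluded samples keep their
#' rows and flags but are dropped from downstream statistics.
#'
#' @param records A [sample_records()] table.
#' @param measurements Stacked [measure_all()] output for all samples.
#' @param carb_model,arom_model Fitted `calibration_model`s.
#' @return `data.frame` with metadata plus `carb_est`, `carb_se`,
#'   `arom_est`, `arom_se`, `aliphatic_rel_abund`, `arom_carb_ratio`,
#'   `aliph_carb_ratio`.
#' @export
build_composition_table <- function(records, measurements, carb_model,
                                    arom_model) {
  get_h <- function(id, band) {
    v <- measurements$normalized_height[measurements$sample_id == id &
                                          measurements$peak_name == band]
    if (length(v)) v[1L] else NA_real_
  }
  carb_h <- vapply(records$sample_id, get_h, numeric(1), band = "carb")
  arom_h <- vapply(records$sample_id, get_h, numeric(1), band = "arom15") +
    vapply(records$sample_id, get_h, numeric(1), band = "arom16")
  aliph_h <- vapply(records$sample_id, get_h, numeric(1), band = "aliph28") +
    vapply(records$sample_id, get_h, numeric(1), band = "aliph29")
  carb <- predict_composition(carb_model, carb_h)
  arom <- predict_composition(arom_model, arom_h)
  hi <- humification_ratios(carb_h, arom_h, aliph_h)
  out <- cbind(as.data.frame(records), data.frame(
    carb_height = carb_h,
    arom_height = arom_h,
    carb_est = carb$estimate, carb_se = carb$se,
    arom_est = arom$estimate, arom_se = arom$se,
    aliphatic_rel_abund = aliph_h,
    arom_carb_ratio = hi$arom_carb_ratio,
    aliph_carb_ratio = hi$aliph_carb_ratio
  ))
  rownames(out) <- NULL
  out
}

#' Humification indices from band measurements
#'
#' Classical FTIR humification indices: the ratios of the summed aromatic
#' (`arom15 + arom16`) and summed aliphatic (`aliph28 + aliph29`) normalized
#' heights to the carbohydrate (`carb`) normalized height. Higher ratios
#' indicate greater humification. Undefined (returned as `NA` with a
#' warning) when the carbohydrate height is not positive.
#'
#' @param measurements A [measure_all()] table for one sample.
#' @return List with `arom_carb_ratio` and `aliph_carb_ratio`.
#' @export
humification_indices <- function(measurements) {
  h <- function(b) {
    v <- measurements$normalized_height[measurements$peak_name %in% b]
    if (length(v)) sum(v) else NA_real_
  }
  humification_ratios(h("carb"), h(c("arom15", "arom16")),
                      h(c("aliph28", "aliph29")))
}

# rbind a list of data-frame rows, dropping skipped (NULL) entries
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

humification_ratios <- function(carb_h, arom_h, aliph_h) {
  bad <- !is.na(carb_h) & carb_h <= 0
  if (any(bad)) {
    warning("carb height <= 0 for ", sum(bad),
            " sample(s); humification indices undefined", call. = FALSE)
    carb_h[bad] <- NA_real_
  }
  list(arom_carb_ratio = arom_h / carb_h,
       aliph_carb_ratio = aliph_h / carb_h)
}

#' Summarize surface peat per core
#'
#' Averages estimated composition over the near-surface sections of each
#' core — those whose (midpoint) depth does not exceed `max_depth` cm — and
#' reports the mean and sample standard deviation (n - 1 denominator) per
#' core. Cores with a single qualifying section get `NA` SDs; cores with
#' none are omitted with a warning. Excluded samples never enter.
#'
#' @param composition A [build_composition_table()] table (peat rows used).
#' @param max_depth Depth cutoff in cm (default 50).
#' @param core_column Column identifying the core (default `"site"`).
#' @return `data.frame`: `core_id`, `n_sections`, `mean_carb`, `sd_carb`,
#'   `mean_arom`, `sd_arom`, `latitude_deg`, `mean_annual_temp_C`,
#'   `category`.
#' @export
surface_summary <- function(composition, max_depth = 50,
                            core_column = "site") {
  peat <- composition[composition$material == "peat" &
                        !composition$excluded, , drop = FALSE]
  cores <- unique(peat[[core_column]])
  rows <- lapply(cores, function(core) {
    sub <- peat[peat[[core_column]] == core &
                  peat$depth_cm <= max_depth, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("core ", core, " has no sections within ", max_depth,
              " cm; omitted", call. = FALSE)
      return(NULL)
    }
    n <- nrow(sub)
    data.frame(
      core_id = core,
      n_sections = n,
      mean_carb = mean(sub$carb_est),
      sd_carb = if (n > 1L) stats::sd(sub$carb_est) else NA_real_,
      mean_arom = mean(sub$arom_est),
      sd_arom = if (n > 1L) stats::sd(sub$arom_est) else NA_real_,
      latitude_deg = mean(sub$latitude_deg),
      mean_annual_temp_C = mean(sub$mean_annual_temp_C),
      category = sub$category[1L],
      stringsAsFactors = FALSE
    )
  })
  rbind_rows(rows)
}

# simple OLS report shared by the regression front-ends
ols_report <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points, got ", n, call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate design: covariate is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       slope_se = unname(sm$coefficients[2L, 2L]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2L, 4L]),
       n = n,
       see = sqrt(sum(stats::residuals(fit)^2) / (n - 2)))
}

#' Regress per-core surface composition on a site covariate
#'
#' Unweighted ordinary least squares of per-core surface means (one point
#' per core) on latitude or mean annual temperature — the latitudinal-trend
#' test for surface peat chemistry.
#'
#' @param summaries A [surface_summary()] table.
#' @param response `"mean_carb"` or `"mean_arom"`.
#' @param covariate `"latitude_deg"` or `"mean_annual_temp_C"`.
#' @return List: `slope`, `intercept`, `slope_se`, `r_squared`, `p_value`,
#'   `n`, `see`, plus the labels.
#' @export
latitudinal_regression <- function(summaries,
                                   response = c("mean_carb", "mean_arom"),
                                   covariate = c("latitude_deg",
                                                 "mean_annual_temp_C")) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  rep <- ols_report(summaries[[covariate]], summaries[[response]])
  c(rep, list(response = response, covariate = covariate))
}

#' Pooled-variance two-sample t test
#'
#' Student's unpaired two-tailed t test with pooled variance,
#' `df = n_a + n_b - 2`, for contrasts such as plant chemistry in low- vs
#' high-latitude site groups. Groups of size 1 cannot be tested and return
#' `NA` statistics with a note. Degenerate zero-variance inputs are handled
#' explicitly: equal constant groups give t = 0, p = 1; unequal means with
#' zero pooled variance give p = 0 with a warning.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `note`.
#' @export
pooled_t_test <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  base <- list(t = NA_real_, df = na + nb - 2L, p_value = NA_real_,
               mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
               note = "")
  if (na < 2L || nb < 2L) {
    base$note <- "significance not determinable (a group has n < 2)"
    return(base)
  }
  pooled_var <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      base$t <- 0; base$p_value <- 1
    } else {
      warning("zero pooled variance with unequal means; p = 0",
              call. = FALSE)
      base$t <- sign(mean(a) - mean(b)) * Inf
      base$p_value <- 0
    }
    return(base)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  base$t <- unname(tt$statistic)
  base$p_value <- tt$p.value
  base
}

#' LOESS depth profiles by latitude group
#'
#' Locally weighted polynomial regression of composition on depth,
#' fitted separately for high- and low-latitude samples (split at 45 deg N,
#' the midpoint between pole and equator; the boundary itself counts as
#' high). Defaults follow the standard smoother settings: degree-2 local
#' polynomials with tricube weights over a span of 0.75, evaluated exactly
#' (no interpolation surface), with a pointwise normal-approximation 95\%
#' confidence band.
#'
#' @param depth,value Numeric vectors (cm, wt\%).
#' @param latitude Optional latitudes; when `NULL` all points form one
#'   group `"all"`.
#' @param degree,span LOESS parameters (defaults 2 and 0.75).
#' @param split_deg Latitude split (default 45).
#' @param n_grid Points in the evaluation grid per group (default 100).
#' @param at Optional explicit depths at which to evaluate instead of the
#'   even grid.
#' @param conf Confidence level for the band (default 0.95).
#' @return `data.frame`: `group`, `depth`, `fit`, `se`, `lower`, `upper`.
#'   Groups with fewer than `degree + 2` points are skipped with a warning.
#' @export
loess_profile <- function(depth, value, latitude = NULL, degree = 2,
                          span = 0.75, split_deg = 45, n_grid = 100,
                          at = NULL, conf = 0.95) {
  ok <- is.finite(depth) & is.finite(value)
  depth <- depth[ok]; value <- value[ok]
  group <- if (is.null(latitude)) {
    rep("all", length(depth))
  } else {
    lat <- latitude[ok]
    ifelse(lat >= split_deg, "high_latitude", "low_latitude")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(unique(group), function(g) {
    d <- depth[group == g]; v <- value[group == g]
    if (length(d) < degree + 2) {
      warning("group ", g, " has fewer than ", degree + 2,
              " points; skipped", call. = FALSE)
      return(NULL)
    }
    fit <- stats::loess(v ~ d, degree = degree, span = span,
                        control = stats::loess.control(surface = "direct"))
    dd <- if (is.null(at)) seq(min(d), max(d), length.out = n_grid) else at
    pr <- stats::predict(fit, newdata = data.frame(d = dd), se = TRUE)
    data.frame(group = g, depth = dd, fit = as.numeric(pr$fit),
               se = as.numeric(pr$se.fit),
               lower = as.numeric(pr$fit - z * pr$se.fit),
               upper = as.numeric(pr$fit + z * pr$se.fit),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Principal components analysis of whole spectra
#'
#' Interpolates all spectra to a common wavenumber grid (the overlap of the
#' recorded ranges), rescales each spectrum so its total integrated area is
#' exactly `target_area` (100 by convention) — removing overall-absorbance
#' differences between samples — and runs PCA on the column-centered,
#' non-variance-scaled matrix. Loadings are orthonormal; for deterministic
#' output each component's largest-magnitude loading element is made
#' positive. Samples with non-positive area are excluded with a warning.
#'
#' @param spectra List of [ftir_spectrum()]s (3 or more).
#' @param grid_step Common-grid spacing in cm^-1; default: median spacing of
#'   the first spectrum.
#' @param target_area Area each spectrum is scaled to (default 100).
#' @return List: `scores` (samples x PCs), `loadings` (wavenumbers x PCs),
#'   `explained_variance`, `prop_variance`, `grid`, `preprocessed` matrix,
#'   `sample_ids`.
#' @export
pca_spectra <- function(spectra, grid_step = NULL, target_area = 100) {
  if (length(spectra) < 3L) stop("need at least 3 spectra", call. = FALSE)
  lapply(spectra, assert_spectrum)
  lo <- max(vapply(spectra, function(s) min(s$wavenumbers), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavenumbers), numeric(1)))
  if (hi <= lo) stop("spectra have no overlapping wavenumber range",
                     call. = FALSE)
  if (is.null(grid_step))
    grid_step <- stats::median(diff(spectra[[1L]]$wavenumbers))
  grid <- seq(lo, hi, by = grid_step)
  ids <- vapply(spectra, function(s) s$sample_id, "")
  rows <- t(vapply(spectra, function(s) {
    stats::approx(s$wavenumbers, s$absorbance, xout = grid)$y
  }, numeric(length(grid))))
  areas <- apply(rows, 1L, function(a) trapz_area(grid, a))
  keep <- areas > 0
  if (!all(keep)) {
    warning(sum(!keep), " spectrum/spectra with non-positive area excluded: ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)
    rows <- rows[keep, , drop = FALSE]
    ids <- ids[keep]
    areas <- areas[keep]
  }
  if (nrow(rows) < 3L) stop("fewer than 3 spectra left after area screen",
                            call. = FALSE)
  pre <- rows * (target_area / areas)
  pc <- stats::prcomp(pre, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading element positive per PC
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- ids
  rownames(pre) <- ids
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2,
       prop_variance = pc$sdev^2 / sum(pc$sdev^2),
       grid = grid, preprocessed = pre, sample_ids = ids)
}

#' Fit external variables to ordination scores
#'
#' Projects each external variable (depth, latitude, temperature, estimated
#' composition, ...) onto the first two principal-component axes by least
#' squares. The arrow direction is the unit coefficient vector (the gradient
#' of the variable in score space), the squared correlation measures arrow
#' length, and significance comes from a seeded permutation test that
#' shuffles the variable across samples. Variables defined on a subset of
#' samples (e.g. depth, absent for plants) are fitted on their complete
#' cases.
#'
#' @param scores Score matrix from [pca_spectra()] (first two columns used).
#' @param variables `data.frame` of numeric columns aligned with the score
#'   rows; `NA`s drop the sample for that variable only.
#' @param n_perm Number of permutations (99 or more; default 999).
#' @param seed Integer seed for the permutations (mandatory).
#' @return `data.frame`: `variable`, `dx`, `dy` (unit direction),
#'   `r_squared`, `p_perm`, `n`. Constant variables get r^2 = 0, p = 1 and
#'   a warning.
#' @export
fit_external_vectors <- function(scores, variables, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory for the permutation test",
                          call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be at least 99", call. = FALSE)
  S <- as.matrix(scores)[, 1:2, drop = FALSE]
  rows <- lapply(names(variables), function(nm) {
    v <- as.numeric(variables[[nm]])
    ok <- is.finite(v)
    vv <- v[ok]; SS <- S[ok, , drop = FALSE]
    n <- length(vv)
    if (n < 3L || stats::var(vv) == 0) {
      warning("variable ", nm, " is constant or near-empty; direction ",
              "undefined", call. = FALSE)
      return(data.frame(variable = nm, dx = NA_real_, dy = NA_real_,
                        r_squared = 0, p_perm = 1, n = n,
                        stringsAsFactors = FALSE))
    }
    X <- cbind(1, SS)
    Q <- qr.Q(qr(X))
    r2_of <- function(y) {
      fitted <- Q %*% crossprod(Q, y)
      ssr <- sum((fitted - mean(y))^2)
      sst <- sum((y - mean(y))^2)
      ssr / sst
    }
    b <- qr.solve(X, vv)[2:3]
    r2 <- r2_of(vv)
    perm_ge <- with_seed(seed, {
      sum(vapply(seq_len(n_perm),
                 function(i) r2_of(sample(vv)), numeric(1)) >= r2)
    })
    data.frame(variable = nm,
               dx = b[1L] / sqrt(sum(b^2)), dy = b[2L] / sqrt(sum(b^2)),
               r_squared = r2,
               p_perm = (1 + perm_ge) / (n_perm + 1),
               n = n, stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
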