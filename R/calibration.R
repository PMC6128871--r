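#' @keywords internal
standard_classes <- c("hardwood", "softwood", "leaves_grasses", "needles",
                      "OCC", "ONP", "OMG", "OFF")

#' Assemble a calibration-standards table
#'
#' Calibration standards are plant and paper materials with wet-chemistry
#' reference values: \% cellulose + hemicellulose (acid hydrolysis) for the
#' carbohydrate calibration and \% Klason lignin (acid-insoluble residue
#' minus ash; includes tannins, other polyphenols and char) for the aromatic
#' calibration. Heights are normalized corrected peak heights in cm.
#'
#' @param sample_id Character vector.
#' @param standard_class One of `hardwood`, `softwood`, `leaves_grasses`,
#'   `needles`, `OCC` (old corrugated cardboard), `ONP` (old newsprint),
#'   `OMG` (old magazines), `OFF` (office paper).
#' @param carb_height,arom15_height,arom16_height Normalized corrected peak
#'   heights (cm).
#' @param pct_cellulose_hemicellulose,pct_klason_lignin Wet-chemistry
#'   composition in weight percent, each in \[0, 100\].
#' @return A validated `data.frame`.
#' @export
calibration_standards <- function(sample_id, standard_class, carb_height,
                                  arom15_height, arom16_height,
                                  pct_cellulose_hemicellulose,
                                  pct_klason_lignin) {
  df <- data.frame(sample_id = as.character(sample_id),
                   standard_class = as.character(standard_class),
                   carb_height = as.numeric(carb_height),
                   arom15_height = as.numeric(arom15_height),
                   arom16_height = as.numeric(arom16_height),
                   pct_cellulose_hemicellulose =
                     as.numeric(pct_cellulose_hemicellulose),
                   pct_klason_lignin = as.numeric(pct_klason_lignin),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$standard_class), standard_classes)
  if (length(bad))
    stop("unknown standard class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (col in c("pct_cellulose_hemicellulose", "pct_klason_lignin")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v < 0 | v > 100))
      stop(col, " must lie in [0, 100]", call. = FALSE)
  }
  hts <- c(df$carb_height, df$arom15_height, df$arom16_height)
  if (any(!is.finite(hts)))
    stop("non-finite peak heights", call. = FALSE)
  if (any(hts < 0))
    warning("negative normalized peak heights in standards", call. = FALSE)
  df
}

#' Select the standards entering a calibration
#'
#' The carbohydrate calibration omits the OMG (old magazine) standards,
#' whose clay paper coating produces a mineral band overlapping the
#' carbohydrate peak; the aromatic calibration omits the OFF (office paper)
#' standards, a chemical pulp with most lignin removed. Row order is
#' preserved.
#'
#' @param standards A [calibration_standards()] table.
#' @param analyte `"carbohydrates"` or `"aromatics"`.
#' @return The filtered table.
#' @export
select_standards <- function(standards,
                             analyte = c("carbohydrates", "aromatics")) {
  analyte <- match.arg(analyte)
  bad <- setdiff(unique(standards$standard_class), standard_classes)
  if (length(bad))
    stop("unknown standard class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  drop <- if (analyte == "carbohydrates") "OMG" else "OFF"
  standards[standards$standard_class != drop, , drop = FALSE]
}

#' Fit a linear calibration of composition on peak height
#'
#' Ordinary least squares of wet-chemistry composition (wt\%) on normalized
#' corrected peak height (cm). The standard error of the y-estimate,
#' `see = sqrt(SSE / (n - 2))`, is carried as the per-sample prediction
#' uncertainty of the calibration.
#'
#' @param x Normalized heights (cm).
#' @param y Composition (wt\%).
#' @param analyte,predictor Labels recorded in the model.
#' @return A `calibration_model` list: `analyte`, `predictor`, `slope`
#'   (wt\% per cm), `intercept` (wt\%), `r_squared`, `p_value` (two-sided
#'   slope t-test), `n`, `see` (wt\%).
#' @export
fit_calibration <- function(x, y, analyte = "carbohydrates",
                            predictor = "carb") {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 standards, got ", n, call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate design: predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  sse <- sum(stats::residuals(fit)^2)
  structure(list(
    analyte = analyte,
    predictor = predictor,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2L, 4L]),
    n = n,
    see = sqrt(sse / (n - 2))
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s ~ %s: slope %.4g, intercept %.4g\n  R^2 = %.3f, p = %.3g, n = %d, SEE = %.3g wt%%\n",
    x$analyte, x$predictor, x$slope, x$intercept, x$r_squared, x$p_value,
    x$n, x$see))
  invisible(x)
}

#' Fit an analyte calibration from a standards table
#'
#' Applies the analyte's exclusion rule ([select_standards()]) and fits the
#' analyte's predictor: the `carb` height for carbohydrates against
#' \% cellulose + hemicellulose, or the summed `arom15 + arom16` height for
#' aromatics against \% Klason lignin. The sum is a single predictor, not a
#' two-covariate fit.
#'
#' @param standards A [calibration_standards()] table.
#' @param analyte `"carbohydrates"` or `"aromatics"`.
#' @return A `calibration_model`.
#' @export
calibrate_analyte <- function(standards,
                              analyte = c("carbohydrates", "aromatics")) {
  analyte <- match.arg(analyte)
  sel <- select_standards(standards, analyte)
  if (analyte == "carbohydrates") {
    fit_calibration(sel$carb_height, sel$pct_cellulose_hemicellulose,
                    analyte, "carb")
  } else {
    fit_calibration(sel$arom15_height + sel$arom16_height,
                    sel$pct_klason_lignin, analyte, "arom15_plus_arom16")
  }
}

#' Compare candidate aromatic predictors
#'
#' Fits \% Klason lignin against the `arom15` height, the `arom16` height,
#' and their sum (on the OFF-excluded standard set), and ranks the three
#' models by R^2, descending. Ties keep the listed order (arom15, arom16,
#' sum). The winner is the predictor used for aromatic estimation.
#'
#' @param standards A [calibration_standards()] table.
#' @return List with `models` (ranked list of `calibration_model`s) and
#'   `winner` (predictor label of the best model).
#' @export
compare_aromatic_predictors <- function(standards) {
  sel <- select_standards(standards, "aromatics")
  xs <- list(arom15 = sel$arom15_height,
             arom16 = sel$arom16_height,
             arom15_plus_arom16 = sel$arom15_height + sel$arom16_height)
  models <- mapply(function(x, nm) {
    fit_calibration(x, sel$pct_klason_lignin, "aromatics", nm)
  }, xs, names(xs), SIMPLIFY = FALSE)
  r2 <- vapply(models, `[[`, numeric(1), "r_squared")
  ord <- order(-r2)  # stable: ties keep listed order
  models <- models[ord]
  list(models = models, winner = models[[1L]]$predictor)
}

#' Predict composition from a fitted calibration
#'
#' `estimate = slope * height + intercept`; the attached standard error is
#' the calibration's constant standard error of the y-estimate, used as the
#' per-sample uncertainty. Estimates outside \[0, 100\] wt\% are returned
#' unclipped with a warning — clipping would silently bias cross-sample
#' comparisons.
#'
#' @param model A `calibration_model`.
#' @param height Normalized corrected peak height(s), cm.
#' @return `data.frame` with columns `estimate` and `se` (wt\%).
#' @export
predict_composition <- function(model, height) {
  if (!inherits(model, "calibration_model"))
    stop("model must be a calibration_model", call. = FALSE)
  est <- model$slope * height + model$intercept
  out_of_range <- is.finite(est) & (est < 0 | est > 100)
  if (any(out_of_range))
    warning(sum(out_of_range), " ", model$analyte,
            " estimate(s) outside [0, 100] wt%; returned unclipped",
            call. = FALSE)
  data.frame(estimate = est, se = rep(model$see, length(est)))
}
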