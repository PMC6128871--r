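#' Assemble a pipeline run configuration
#'
#' The configuration collects everything a full run needs: inputs (a
#' calibration-standards table, sample spectra, sample metadata), the peak
#' config, the analysis options, the mandatory seed, and a declarative
#' exclusion list (sample id -> reason) so that sample omissions — fresh
#' wood fragments, silicate-bearing sections — are auditable and
#' reproducible rather than hard-coded.
#'
#' @param standards [calibration_standards()] table, or path to a CSV with
#'   the same columns.
#' @param spectra Named list of [ftir_spectrum()]s, or path to a workbook
#'   readable by [read_spectra_table()].
#' @param records [sample_records()] table, or path to a CSV.
#' @param out_dir Output directory for the report bundle.
#' @param peak_config Path to the peak-definition YAML.
#' @param exclusions Named character vector: `sample_id = reason`.
#' @param seed Integer seed (mandatory; drives the permutation tests).
#' @param n_perm Permutations for external-vector fits.
#' @param surface_max_depth_cm,latitude_split_deg,loess_degree,loess_span
#'   Analysis options.
#' @param flag_silicates Run the advisory silicate screen?
#' @return A `peatspec_config` list.
#' @export
run_config <- function(standards, spectra, records, out_dir,
                       peak_config = default_peak_config(),
                       exclusions = character(0), seed,
                       n_perm = 999, surface_max_depth_cm = 50,
                       latitude_split_deg = 45, loess_degree = 2,
                       loess_span = 0.75, flag_silicates = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  for (inp in list(standards, spectra, records)) {
    if (is.character(inp) && !file.exists(inp))
      stop("input path does not exist: ", inp, call. = FALSE)
  }
  if (!file.exists(peak_config))
    stop("peak config does not exist: ", peak_config, call. = FALSE)
  structure(list(standards = standards, spectra = spectra, records = records,
                 out_dir = out_dir, peak_config = peak_config,
                 exclusions = exclusions, seed = seed, n_perm = n_perm,
                 surface_max_depth_cm = surface_max_depth_cm,
                 latitude_split_deg = latitude_split_deg,
                 loess_degree = loess_degree, loess_span = loess_span,
                 flag_silicates = flag_silicates),
            class = "peatspec_config")
}

load_input <- function(x, loader) if (is.character(x)) loader(x) else x

#' Run the full measurement-to-report pipeline
#'
#' Executes the complete workflow: measure every spectrum (adaptive
#' endpoints, baseline correction, area normalization), screen for silicate
#' interference, fit the carbohydrate calibration and select the best
#' aromatic predictor, estimate per-sample composition, and run the
#' downstream statistics (surface summaries, latitudinal and temperature
#' regressions, plant-peat latitude contrasts, LOESS depth profiles, PCA
#' with permutation-tested external vectors). Writes one CSV per result
#' table plus a JSON manifest into `config$out_dir`. Outputs are staged and
#' moved only on success, so a failed run leaves no partial bundle; a stage
#' failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "peatspec_config"))
    stop("config must come from run_config()", call. = FALSE)
  stage <- "load_inputs"
  res <- tryCatch({
    standards <- load_input(config$standards, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE))
    spectra <- load_input(config$spectra, function(p)
      read_spectra_table(p)$spectra)
    records <- load_input(config$records, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE))
    if (!inherits(records, "peat_sample_records"))
      records <- sample_records(
        records$sample_id, records$material, records$site, records$category,
        records$depth_cm, records$latitude_deg, records$mean_annual_temp_C,
        if ("exclusion_reason" %in% names(records))
          records$exclusion_reason else NA_character_)
    for (id in names(config$exclusions)) {
      i <- which(records$sample_id == id)
      if (!length(i)) stop("exclusion list names unknown sample '", id, "'")
      records$excluded[i] <- TRUE
      records$exclusion_reason[i] <- config$exclusions[[id]]
    }
    missing_spec <- setdiff(records$sample_id, names(spectra))
    if (length(missing_spec))
      stop("no spectrum for sample(s): ",
           paste(utils::head(missing_spec, 5), collapse = ", "))

    stage <- "measure"
    cfg <- read_peak_definitions(config$peak_config)
    measurements <- do.call(rbind, c(lapply(records$sample_id, function(id) {
      measure_all(spectra[[id]], defs = cfg$peaks)
    }), list(make.row.names = FALSE)))

    stage <- "screen"
    silicate <- NULL
    if (isTRUE(config$flag_silicates)) {
      silicate <- do.call(rbind, c(lapply(records$sample_id, function(id) {
        sc <- screen_silicate(spectra[[id]],
                              measurements[measurements$sample_id == id, ],
                              config = cfg)
        data.frame(sample_id = id, silicate_flagged = sc$flagged,
                   evidence = paste(sc$evidence, collapse = ";"),
                   stringsAsFactors = FALSE)
      }), list(make.row.names = FALSE)))
    }

    stage <- "calibrate"
    standards <- calibration_standards(
      standards$sample_id, standards$standard_class, standards$carb_height,
      standards$arom15_height, standards$arom16_height,
      standards$pct_cellulose_hemicellulose, standards$pct_klason_lignin)
    carb_model <- calibrate_analyte(standards, "carbohydrates")
    arom_cmp <- compare_aromatic_predictors(standards)
    # prediction always uses the summed-peak model (the sum is the single
    # x-variable of the aromatic calibration); the ranking is reported
    arom_model <- calibrate_analyte(standards, "aromatics")

    stage <- "predict"
    composition <- build_composition_table(records, measurements,
                                           carb_model, arom_model)

    stage <- "analyze"
    included <- composition[!composition$excluded, , drop = FALSE]
    peat <- included[included$material == "peat", , drop = FALSE]
    plants <- included[included$material == "plant", , drop = FALSE]
    surface <- surface_summary(peat,
                               max_depth = config$surface_max_depth_cm)
    combos <- expand.grid(response = c("mean_carb", "mean_arom"),
                          covariate = c("latitude_deg",
                                        "mean_annual_temp_C"),
                          stringsAsFactors = FALSE)
    regressions <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      as.data.frame(latitudinal_regression(
        surface, combos$response[i], combos$covariate[i]))))
    rownames(regressions) <- NULL

    contrast_set <- if (nrow(plants) >= 4L) plants else
      peat[peat$depth_cm <= config$surface_max_depth_cm, , drop = FALSE]
    lowlat <- contrast_set$latitude_deg < config$latitude_split_deg
    t_tests <- do.call(rbind, lapply(c("carb_est", "arom_est"), function(v) {
      tt <- pooled_t_test(contrast_set[[v]][lowlat],
                          contrast_set[[v]][!lowlat])
      data.frame(variable = v, group_a = "low_latitude",
                 group_b = "high_latitude", t = tt$t, df = tt$df,
                 p_value = tt$p_value, n_a = tt$n_a, n_b = tt$n_b,
                 stringsAsFactors = FALSE)
    }))

    loess_curves <- do.call(rbind, lapply(
      c(carb_est = "carb_est", arom_est = "arom_est"), function(v) {
        cbind(variable = v,
              loess_profile(peat$depth_cm, peat[[v]], peat$latitude_deg,
                            degree = config$loess_degree,
                            span = config$loess_span,
                            split_deg = config$latitude_split_deg))
      }))
    rownames(loess_curves) <- NULL

    stage <- "ordination"
    inc_ids <- included$sample_id
    pca <- pca_spectra(spectra[inc_ids])
    vars <- data.frame(
      depth = ifelse(included$material == "peat", included$depth_cm, NA),
      latitude = ifelse(included$material == "peat",
                        included$latitude_deg, NA),
      temperature = ifelse(included$material == "peat",
                           included$mean_annual_temp_C, NA),
      carbohydrates_est = included$carb_est,
      aromatics_est = included$arom_est,
      aliphatic_rel_abund = included$aliphatic_rel_abund)
    vectors <- fit_external_vectors(pca$scores, vars,
                                    n_perm = config$n_perm,
                                    seed = config$seed)

    stage <- "report"
    manifest <- list(
      package = "peatspec",
      version = as.character(utils::packageVersion("peatspec")),
      seed = config$seed,
      n_perm = config$n_perm,
      peak_config = basename(config$peak_config),
      n_input = nrow(records),
      n_included = sum(!records$excluded),
      n_excluded = sum(records$excluded),
      exclusions = as.list(stats::setNames(
        records$exclusion_reason[records$excluded],
        records$sample_id[records$excluded])),
      n_peat = sum(included$material == "peat"),
      n_plant = sum(included$material == "plant"),
      n_pca = length(pca$sample_ids),
      aromatic_predictor = arom_cmp$winner,
      calibration = list(
        carbohydrates = unclass(carb_model),
        aromatics = unclass(arom_model))
    )
    list(measurements = measurements, silicate = silicate,
         standards = standards, carb_model = carb_model,
         arom_model = arom_model, aromatic_comparison = arom_cmp,
         composition = composition, surface = surface,
         regressions = regressions, t_tests = t_tests,
         loess_curves = loess_curves, pca = pca, vectors = vectors,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  staging <- file.path(tempfile("peatspec_run_"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(staging, name), row.names = FALSE)
  wr(res$measurements, "measurements.csv")
  if (!is.null(res$silicate)) wr(res$silicate, "silicate_flags.csv")
  wr(res$composition, "composition.csv")
  wr(res$surface, "surface_summary.csv")
  wr(res$regressions, "regressions.csv")
  wr(res$t_tests, "t_tests.csv")
  wr(res$loess_curves, "loess_curves.csv")
  wr(data.frame(sample_id = rownames(res$pca$scores),
                res$pca$scores[, 1:min(5, ncol(res$pca$scores))]),
     "pca_scores.csv")
  wr(data.frame(wavenumber = res$pca$grid,
                res$pca$loadings[, 1:min(5, ncol(res$pca$loadings))]),
     "pca_loadings.csv")
  wr(res$vectors, "vector_fits.csv")
  jsonlite::write_json(res$manifest,
                       file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  invisible(res)
}
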