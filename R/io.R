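#' Read a single FTIR spectrum from disk
#'
#' Two dialects are supported. `"two_column_csv"` is a plain CSV/TSV with a
#' wavenumber column and an absorbance (or \%T) column; extra columns are
#' ignored. `"workbook_sheet"` reads one named sample row out of a
#' multi-sample workbook (see [read_spectra_table()]).
#'
#' Rows may appear in any order (instrument exports usually run high to low
#' wavenumber); the returned spectrum is always canonical ascending.
#'
#' @param path File path.
#' @param dialect `"two_column_csv"` or `"workbook_sheet"`.
#' @param sample_id Sample identifier. For the workbook dialect this selects
#'   the row; for two-column files it defaults to the file name.
#' @param mode `"absorbance"` (default) or `"percent_transmittance"`. \%T
#'   input is converted to absorbance on load.
#' @param layout Workbook layout description, see [workbook_layout()].
#' @param sep Field separator for the CSV dialect (default `,`).
#' @return A [ftir_spectrum()].
#' @export
read_spectrum <- function(path,
                          dialect = c("two_column_csv", "workbook_sheet"),
                          sample_id = NULL,
                          mode = c("absorbance", "percent_transmittance"),
                          layout = workbook_layout(),
                          sep = ",") {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "two_column_csv") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 2L)
      stop("two-column dialect needs at least 2 columns in ", path,
           call. = FALSE)
    w <- df[[1L]]
    a <- df[[2L]]
    for (col in list(w, a)) {
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1L]
        stop("non-numeric cell in ", path, " at data row ",
             if (is.na(bad)) "?" else bad, call. = FALSE)
      }
    }
    if (anyNA(w) || anyNA(a)) {
      bad <- which(is.na(w) | is.na(a))[1L]
      stop("missing value in ", path, " at data row ", bad, call. = FALSE)
    }
    if (anyDuplicated(w)) {
      bad <- which(duplicated(w))[1L]
      stop("duplicate wavenumber in ", path, " at data row ", bad,
           " (", w[bad], " cm^-1)", call. = FALSE)
    }
    if (is.null(sample_id))
      sample_id <- tools::file_path_sans_ext(basename(path))
    s <- ftir_spectrum(w, a, sample_id = sample_id)
  } else {
    tbl <- read_spectra_table(path, layout = layout, sep = sep)
    if (is.null(sample_id)) {
      if (length(tbl$spectra) != 1L)
        stop("workbook has ", length(tbl$spectra),
             " samples; supply sample_id", call. = FALSE)
      s <- tbl$spectra[[1L]]
    } else {
      hit <- vapply(tbl$spectra, function(x) x$sample_id, "") == sample_id
      if (!any(hit)) stop("sample_id '", sample_id, "' not in ", path,
                          call. = FALSE)
      s <- tbl$spectra[[which(hit)[1L]]]
    }
  }
  if (mode == "percent_transmittance") s <- transmittance_to_absorbance(s)
  s
}

#' Write a spectrum as a two-column CSV
#'
#' @param s A [ftir_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  assert_spectrum(s)
  df <- data.frame(`wavenumber_cm-1` = s$wavenumbers,
                   absorbance = s$absorbance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Describe the layout of a multi-sample spectral workbook
#'
#' Multi-sample workbooks hold one row per sample: a block of metadata
#' columns followed by one column per wavenumber, with the wavenumber value
#' in the column header. The exact layout varies between exports, so it is
#' configurable: `id_column` names the sample identifier column and
#' `meta_columns` lists further metadata columns to carry along (missing ones
#' are ignored). Every remaining column whose header parses as a number is
#' taken as a wavenumber.
#'
#' @param id_column Name of the sample-id column (default `"sample_id"`).
#' @param meta_columns Character vector of metadata column names.
#' @return A list usable as the `layout` argument of [read_spectra_table()].
#' @export
workbook_layout <- function(id_column = "sample_id",
                            meta_columns = c("material", "site", "category",
                                             "depth_cm", "latitude_deg",
                                             "mean_annual_temp_C",
                                             "standard_class",
                                             "pct_cellulose_hemicellulose",
                                             "pct_klason_lignin")) {
  list(id_column = id_column, meta_columns = meta_columns)
}

#' Read a multi-sample spectral workbook
#'
#' Reads a samples-by-wavenumbers table (wide CSV, or an XLSX sheet when the
#' readxl package is installed) into a list of [ftir_spectrum()] objects plus
#' a metadata data frame. See [workbook_layout()] for the column conventions.
#'
#' @param path CSV or XLSX path.
#' @param layout A [workbook_layout()].
#' @param sheet Sheet name or index for XLSX input.
#' @param mode `"absorbance"` or `"percent_transmittance"`.
#' @param sep Field separator for CSV input.
#' @return List with `spectra` (named list of spectra) and `metadata`
#'   (data frame, one row per sample).
#' @export
read_spectra_table <- function(path, layout = workbook_layout(), sheet = 1,
                               mode = c("absorbance", "percent_transmittance"),
                               sep = ",") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading ", ext, " workbooks requires the readxl package",
           call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                        check.names = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!layout$id_column %in% names(df))
    stop("workbook ", path, " lacks id column '", layout$id_column, "'",
         call. = FALSE)
  headers <- names(df)
  wn <- suppressWarnings(as.numeric(headers))
  spec_cols <- which(!is.na(wn))
  if (length(spec_cols) < 16L)
    stop("workbook ", path, " has only ", length(spec_cols),
         " wavenumber columns", call. = FALSE)
  meta_cols <- intersect(c(layout$id_column, layout$meta_columns), headers)
  metadata <- df[, meta_cols, drop = FALSE]
  names(metadata)[names(metadata) == layout$id_column] <- "sample_id"
  metadata$sample_id <- as.character(metadata$sample_id)

  spectra <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- as.numeric(df[i, spec_cols])
    if (anyNA(vals))
      stop("non-numeric or missing spectral cell for sample '",
           metadata$sample_id[i], "' in ", path, call. = FALSE)
    s <- ftir_spectrum(wn[spec_cols], vals, sample_id = metadata$sample_id[i])
    if (mode == "percent_transmittance") s <- transmittance_to_absorbance(s)
    spectra[[i]] <- s
  }
  names(spectra) <- metadata$sample_id
  list(spectra = spectra, metadata = metadata)
}

#' Build a validated sample-metadata table
#'
#' One row per sample: material class (peat, plant or calibration standard),
#' site and category labels, depth below the peat surface for peat sections,
#' latitude, mean annual temperature, and an auditable exclusion flag.
#' Exclusions (e.g. silicate interference, or core sections of fresh wood
#' fragments that obscure the humification signal) are recorded with their
#' reason and retained in the table; statistics drop them downstream.
#'
#' @param sample_id Character vector.
#' @param material `"peat"`, `"plant"` or `"standard"` per sample.
#' @param site,category Character labels (recycled).
#' @param depth_cm Section midpoint depth in cm for peat samples; must be
#'   `NA` for plants and standards and present, non-negative, for peat.
#' @param latitude_deg,mean_annual_temp_C Site covariates (recycled).
#' @param exclusion_reason `NA`/empty for included samples; a non-empty
#'   reason marks the sample excluded.
#' @return A `data.frame` with class `peat_sample_records`; column
#'   `excluded` is derived from `exclusion_reason`.
#' @export
sample_records <- function(sample_id, material, site = NA_character_,
                           category = NA_character_, depth_cm = NA_real_,
                           latitude_deg = NA_real_,
                           mean_annual_temp_C = NA_real_,
                           exclusion_reason = NA_character_) {
  n <- length(sample_id)
  material <- rep_len(as.character(material), n)
  ok <- material %in% c("peat", "plant", "standard")
  if (!all(ok))
    stop("unknown material '", material[!ok][1L], "'", call. = FALSE)
  depth_cm <- rep_len(as.numeric(depth_cm), n)
  if (any(material == "peat" & is.na(depth_cm)))
    stop("peat samples need depth_cm", call. = FALSE)
  if (any(material != "peat" & !is.na(depth_cm)))
    stop("depth_cm must be absent for non-peat samples", call. = FALSE)
  if (any(depth_cm < 0, na.rm = TRUE))
    stop("negative depth_cm", call. = FALSE)
  exclusion_reason <- rep_len(as.character(exclusion_reason), n)
  exclusion_reason[!is.na(exclusion_reason) &
                     !nzchar(exclusion_reason)] <- NA_character_
  df <- data.frame(
    sample_id = as.character(sample_id),
    material = material,
    site = rep_len(as.character(site), n),
    category = rep_len(as.character(category), n),
    depth_cm = depth_cm,
    latitude_deg = rep_len(as.numeric(latitude_deg), n),
    mean_annual_temp_C = rep_len(as.numeric(mean_annual_temp_C), n),
    excluded = !is.na(exclusion_reason),
    exclusion_reason = exclusion_reason,
    stringsAsFactors = FALSE
  )
  class(df) <- c("peat_sample_records", "data.frame")
  df
}
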