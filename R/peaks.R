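#' Define a spectral band and its endpoint search windows
#'
#' A band is quantified between two endpoints found adaptively per sample:
#' the left (lower-wavenumber) endpoint is searched inside `left_window`, the
#' right endpoint inside `right_window`. The nominal position is only a
#' label; the exact peak position is located per sample between the resolved
#' endpoints.
#'
#' @param name Band name, e.g. `"carb"`, `"arom15"`.
#' @param nominal_position Nominal band position in cm^-1 (strictly between
#'   the two windows).
#' @param left_window,right_window Closed cm^-1 intervals, `left_window`
#'   entirely below `right_window`.
#' @return A `peak_definition` list.
#' @export
peak_definition <- function(name, nominal_position, left_window, right_window) {
  left_window <- sort(as.numeric(left_window))
  right_window <- sort(as.numeric(right_window))
  if (length(left_window) != 2L || length(right_window) != 2L)
    stop("windows must be length-2 intervals", call. = FALSE)
  if (left_window[2L] >= right_window[1L])
    stop("left_window must lie entirely below right_window for band ", name,
         call. = FALSE)
  if (!(nominal_position > left_window[2L] &&
        nominal_position < right_window[1L]))
    stop("nominal position ", nominal_position,
         " not strictly between the windows for band ", name, call. = FALSE)
  structure(list(name = as.character(name),
                 nominal_position = as.numeric(nominal_position),
                 left_window = left_window,
                 right_window = right_window),
            class = "peak_definition")
}

#' Load peak definitions from a YAML config
#'
#' The config carries, per band, the nominal position and the two endpoint
#' search windows, plus the silicate-screen thresholds and diagnostic mineral
#' bands. The file shipped with the package defines the five standard organic
#' bands: `carb` (~1030 cm^-1, polysaccharides), `arom15` (~1510) and
#' `arom16` (~1630, aromatic ring stretches), `aliph28` (~2850) and `aliph29`
#' (~2920, aliphatic C-H).
#'
#' @param path YAML file; defaults to the packaged config.
#' @return List with `peaks` (named list of [peak_definition()]), `silicate`
#'   (list with `thresholds` and `bands`).
#' @export
read_peak_definitions <- function(path = default_peak_config()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$peaks)) stop("config lacks a 'peaks' section", call. = FALSE)
  parse_block <- function(block) {
    defs <- lapply(names(block), function(nm) {
      b <- block[[nm]]
      peak_definition(nm, b$nominal, b$left_window, b$right_window)
    })
    names(defs) <- names(block)
    defs
  }
  out <- list(peaks = parse_block(cfg$peaks), silicate = NULL)
  if (!is.null(cfg$silicate)) {
    out$silicate <- list(
      thresholds = cfg$silicate$thresholds,
      bands = parse_block(cfg$silicate$bands)
    )
  }
  out
}

#' @rdname read_peak_definitions
#' @export
default_peak_config <- function() {
  system.file("extdata", "peaks.yml", package = "peatspec", mustWork = TRUE)
}

#' @rdname read_peak_definitions
#' @export
default_peak_definitions <- function() read_peak_definitions()$peaks

# indices of grid points inside a closed window, with fp tolerance
window_indices <- function(s, window) {
  w <- s$wavenumbers
  eps <- 1e-8 * max(abs(window))
  which(w >= window[1L] - eps & w <= window[2L] + eps)
}

# odd-width centered moving average; width 1 is the identity
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) stop("smoothing width must be odd", call. = FALSE)
  k <- (width - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Locate a peak endpoint inside a search window
#'
#' Endpoints are found per sample because band positions shift with sample
#' chemistry. The primary rule takes the local minima of the full spectrum
#' that fall inside the window (a point no higher than both neighbors;
#' plateaus count) and returns the one with the smallest absorbance, breaking
#' ties toward the lowest wavenumber. When the spectrum is monotone through
#' the window and no local minimum exists, the fallback returns the point
#' maximizing the discrete second derivative — the point of strongest upward
#' curvature, where the band shoulder flattens into baseline.
#'
#' @param s A [ftir_spectrum()].
#' @param window Closed cm^-1 interval containing at least 3 grid points and
#'   not touching the first or last sample of the spectrum.
#' @param smooth_width Odd moving-average width applied to the trace before
#'   the second-derivative fallback; 1 (default) disables smoothing.
#' @return List with `position` (cm^-1), `method` (`"local_minimum"` or
#'   `"second_derivative"`), and `index` into the grid.
#' @export
find_endpoint <- function(s, window, smooth_width = 1L) {
  assert_spectrum(s)
  idx <- window_indices(s, window)
  n <- length(s$wavenumbers)
  if (length(idx) < 3L)
    stop("endpoint window [", window[1L], ", ", window[2L],
         "] contains fewer than 3 grid points", call. = FALSE)
  if (min(idx) <= 1L || max(idx) >= n)
    stop("endpoint window touches the edge of the spectrum", call. = FALSE)
  a <- s$absorbance
  is_min <- a[idx] <= a[idx - 1L] & a[idx] <= a[idx + 1L]
  if (any(is_min)) {
    cand <- idx[is_min]
    pick <- cand[which.min(a[cand])]  # ties: which.min takes the first,
                                      # i.e. the lowest wavenumber
    return(list(position = s$wavenumbers[pick], method = "local_minimum",
                index = pick))
  }
  asm <- moving_average(a, smooth_width)
  h1 <- s$wavenumbers[idx] - s$wavenumbers[idx - 1L]
  h2 <- s$wavenumbers[idx + 1L] - s$wavenumbers[idx]
  d2 <- 2 * ((asm[idx + 1L] - asm[idx]) / h2 -
               (asm[idx] - asm[idx - 1L]) / h1) / (h1 + h2)
  pick <- idx[which.max(d2)]
  list(position = s$wavenumbers[pick], method = "second_derivative",
       index = pick)
}

#' Baseline-correct a spectral segment between two endpoints
#'
#' Subtracts the chord (straight baseline) drawn between the absorbances at
#' the two endpoints from every grid point in `[left, right]`. The corrected
#' values are exactly zero at both endpoints, and any affine component of the
#' spectrum is absorbed by the chord.
#'
#' @param s A [ftir_spectrum()].
#' @param left,right Endpoint wavenumbers; must coincide with grid points
#'   (no silent interpolation).
#' @return List with `wavenumbers` and `corrected` absorbances over the
#'   segment, plus `indices` into the spectrum grid.
#' @export
baseline_correct <- function(s, left, right) {
  assert_spectrum(s)
  if (!(left < right)) stop("left endpoint must be below right", call. = FALSE)
  w <- s$wavenumbers
  eps <- 1e-8 * max(abs(w))
  il <- which(abs(w - left) <= eps)
  ir <- which(abs(w - right) <= eps)
  if (length(il) != 1L || length(ir) != 1L)
    stop("endpoints must lie exactly on the wavenumber grid (",
         left, ", ", right, ")", call. = FALSE)
  seg <- il:ir
  al <- s$absorbance[il]; ar <- s$absorbance[ir]
  chord <- al + (ar - al) * (w[seg] - w[il]) / (w[ir] - w[il])
  corrected <- s$absorbance[seg] - chord
  corrected[1L] <- 0
  corrected[length(corrected)] <- 0
  list(wavenumbers = w[seg], corrected = corrected, indices = seg)
}

#' Measure one band in one spectrum
#'
#' Resolves both endpoints with [find_endpoint()], baseline-corrects the
#' segment between them, takes the peak position as the interior argmax of
#' the corrected absorbance (ties toward the lowest wavenumber), and divides
#' the corrected height by the total integrated spectral area to give the
#' normalized corrected peak height — the method's core statistic, with
#' units of cm (absorbance / (absorbance * cm^-1)).
#'
#' @param s A [ftir_spectrum()].
#' @param def A [peak_definition()].
#' @param total_area Total integrated area from [integrate_spectrum()];
#'   computed if missing. Must be positive — normalization is refused
#'   otherwise.
#' @param smooth_width Passed to [find_endpoint()].
#' @return One-row `data.frame`: `peak_name`, `left_endpoint`,
#'   `right_endpoint`, `left_method`, `right_method`, `peak_position`,
#'   `raw_height`, `corrected_height`, `normalized_height`.
#' @export
measure_peak <- function(s, def, total_area = integrate_spectrum(s),
                         smooth_width = 1L) {
  assert_spectrum(s)
  if (!inherits(def, "peak_definition"))
    stop("def must be a peak_definition", call. = FALSE)
  if (!is.finite(total_area) || total_area <= 0)
    stop("total area ", signif(total_area, 6),
         " is not positive; refusing to normalize band ", def$name,
         call. = FALSE)
  lep <- find_endpoint(s, def$left_window, smooth_width)
  rep_ <- find_endpoint(s, def$right_window, smooth_width)
  bc <- baseline_correct(s, lep$position, rep_$position)
  m <- length(bc$corrected)
  if (m < 3L)
    stop("no interior points between endpoints for band ", def$name,
         call. = FALSE)
  interior <- 2:(m - 1L)
  pk <- interior[which.max(bc$corrected[interior])]  # first max = lowest cm^-1
  data.frame(
    peak_name = def$name,
    left_endpoint = lep$position,
    right_endpoint = rep_$position,
    left_method = lep$method,
    right_method = rep_$method,
    peak_position = bc$wavenumbers[pk],
    raw_height = s$absorbance[bc$indices[pk]],
    corrected_height = bc$corrected[pk],
    normalized_height = bc$corrected[pk] / total_area,
    stringsAsFactors = FALSE
  )
}

#' Measure a set of bands in one spectrum
#'
#' @param s A [ftir_spectrum()].
#' @param defs List of [peak_definition()]s (default: the packaged five
#'   organic bands).
#' @param total_area Total integrated area; computed once if missing.
#' @param smooth_width Passed to [find_endpoint()].
#' @return `data.frame` with one row per band, prefixed by `sample_id`.
#' @seealso [aliphatic_relative_abundance()], [humification_indices()]
#' @export
measure_all <- function(s, defs = default_peak_definitions(),
                        total_area = integrate_spectrum(s),
                        smooth_width = 1L) {
  assert_spectrum(s)
  if (length(defs) == 0L) {
    return(data.frame(sample_id = character(0), peak_name = character(0),
                      left_endpoint = numeric(0), right_endpoint = numeric(0),
                      left_method = character(0), right_method = character(0),
                      peak_position = numeric(0), raw_height = numeric(0),
                      corrected_height = numeric(0),
                      normalized_height = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(defs, measure_peak, s = s, total_area = total_area,
                 smooth_width = smooth_width)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cbind(sample_id = s$sample_id, out, stringsAsFactors = FALSE)
}

#' Aliphatic relative abundance
#'
#' Sum of the normalized corrected heights of the two aliphatic C-H bands
#' (~2850 and ~2920 cm^-1). Aliphatics are not calibrated against wet
#' chemistry; their area-normalized heights are reported as relative
#' abundances for cross-sample comparison.
#'
#' @param measurements Measurement table from [measure_all()].
#' @param bands Names of the aliphatic bands.
#' @return Numeric scalar (cm), or `NA` if the bands are absent.
#' @export
aliphatic_relative_abundance <- function(measurements,
                                         bands = c("aliph28", "aliph29")) {
  rows <- measurements$peak_name %in% bands
  if (!any(rows)) return(NA_real_)
  sum(measurements$normalized_height[rows])
}

#' Screen a spectrum for silicate mineral interference
#'
#' Silicates produce a large band overlapping the carbohydrate peak at
#' ~1030 cm^-1, inflating apparent carbohydrate content. The screen flags a
#' spectrum when diagnostic mineral bands are present — kaolinite doublet at
#' 3695 and 3620 cm^-1 (both required), and/or the 780 cm^-1 silicate band —
#' AND the ~1030 cm^-1 peak is large. The flag is advisory: exclusion is a
#' metadata decision, never automatic deletion.
#'
#' @param s A [ftir_spectrum()].
#' @param measurements Optional [measure_all()] table containing a `carb`
#'   row; measured if absent.
#' @param config Parsed config from [read_peak_definitions()] providing the
#'   diagnostic bands and thresholds (`presence`, `carb_large`, both in cm of
#'   normalized height).
#' @param smooth_width Passed to [find_endpoint()].
#' @return List with `flagged` (logical) and `evidence` (character vector of
#'   diagnostic band names that fired).
#' @export
screen_silicate <- function(s, measurements = NULL,
                            config = read_peak_definitions(),
                            smooth_width = 1L) {
  assert_spectrum(s)
  sil <- config$silicate
  if (is.null(sil)) stop("config has no silicate section", call. = FALSE)
  thr <- sil$thresholds
  total_area <- integrate_spectrum(s)
  if (total_area <= 0) {
    warning("non-positive area; silicate screen skipped", call. = FALSE)
    return(list(flagged = FALSE, evidence = character(0)))
  }
  band_height <- function(def) {
    if (min(def$left_window) < min(s$wavenumbers) ||
        max(def$right_window) > max(s$wavenumbers)) {
      warning("diagnostic region for ", def$name,
              " outside the recorded range; treated as absent", call. = FALSE)
      return(NA_real_)
    }
    measure_peak(s, def, total_area = total_area,
                 smooth_width = smooth_width)$normalized_height
  }
  hts <- vapply(sil$bands, band_height, numeric(1))
  present <- !is.na(hts) & hts > thr$presence
  evidence <- names(hts)[present]
  kaol <- all(c("kaolinite_3695", "kaolinite_3620") %in% evidence)
  s780 <- "silicate_780" %in% evidence
  if (is.null(measurements) || !"carb" %in% measurements$peak_name) {
    carb <- measure_peak(s, read_peak_definitions()$peaks$carb,
                         total_area = total_area,
                         smooth_width = smooth_width)$normalized_height
  } else {
    carb <- measurements$normalized_height[measurements$peak_name == "carb"][1L]
  }
  flagged <- (kaol || s780) && carb > thr$carb_large
  list(flagged = flagged, evidence = evidence)
}
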