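#' FTIR spectrum and spectrum-series containers
#'
#' A `spectrum` is an absorbance trace on a strictly monotone wavenumber
#' grid (stored ascending); a `spectrum_series` is a time-ordered
#' collection of spectra sharing one grid, as produced by repeated
#' acquisition during a proteolysis run. Processing operations
#' ([subtract_reference()], [baseline_correct()], [normalize_area()],
#' [difference_series()], [band_timecourse()]) require the grid to span
#' at least the 1375-1725 cm^-1 analysis window.
#'
#' @param wavenumber wavenumber grid, cm^-1, strictly monotone.
#' @param absorbance absorbance values, AU, same length as `wavenumber`
#'   (for a series: a matrix with one column per time point).
#' @param t_min acquisition time(s), min; for a series, strictly
#'   increasing and of length `ncol(absorbance)`.
#' @param label free-text identifier.
#' @return An object of class `spectrum` or `spectrum_series`.
#' @export
spectrum <- function(wavenumber, absorbance, t_min = NA_real_, label = NULL) {
  .check_grid(wavenumber)
  if (!is.numeric(absorbance) || length(absorbance) != length(wavenumber) ||
      anyNA(absorbance))
    ck_invalid("'absorbance' must be numeric, NA-free, same length as the grid")
  o <- order(wavenumber)
  structure(list(wavenumber = as.numeric(wavenumber[o]),
                 absorbance = as.numeric(absorbance[o]),
                 t_min = t_min, label = label),
            class = "spectrum")
}

#' @rdname spectrum
#' @export
spectrum_series <- function(wavenumber, absorbance, t_min, label = NULL) {
  .check_grid(wavenumber)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumber))
    ck_invalid("'absorbance' must have one row per wavenumber")
  if (anyNA(absorbance)) ck_invalid("'absorbance' must be NA-free")
  if (length(t_min) != ncol(absorbance))
    ck_invalid("'t_min' must have one entry per spectrum")
  if (is.unsorted(t_min, strictly = TRUE))
    ck_invalid("'t_min' must be strictly increasing")
  o <- order(wavenumber)
  structure(list(wavenumber = as.numeric(wavenumber[o]),
                 absorbance = absorbance[o, , drop = FALSE],
                 t_min = as.numeric(t_min), label = label),
            class = "spectrum_series")
}

.check_grid <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2L ||
      anyNA(wavenumber) || any(!is.finite(wavenumber)))
    ck_invalid("'wavenumber' must be a finite numeric grid")
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0)))
    ck_invalid("'wavenumber' must be strictly monotone")
  invisible(wavenumber)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum%s: %d points, %g-%g cm^-1%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (is.na(x$t_min)) "" else sprintf(", t = %g min", x$t_min)))
  invisible(x)
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("FTIR series%s: %d spectra (t = %g-%g min), %d points, %g-%g cm^-1\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              ncol(x$absorbance), min(x$t_min), max(x$t_min),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# apply a per-spectrum function over a series, keeping metadata
.series_map <- function(series, f) {
  cols <- lapply(seq_along(series$t_min), function(i)
    f(spectrum(series$wavenumber, series$absorbance[, i],
               t_min = series$t_min[i], label = series$label)))
  spectrum_series(cols[[1L]]$wavenumber,
                  vapply(cols, `[[`, numeric(length(cols[[1L]]$wavenumber)),
                         "absorbance"),
                  series$t_min, label = series$label)
}

.same_grid <- function(a, b) {
  length(a) == length(b) && all(a == b)
}

#' Subtract an enzyme reference spectrum
#'
#' Removes the spectral contribution of the enzyme solution from each
#' reaction-mixture spectrum by pointwise subtraction. The grids must be
#' identical; no implicit resampling is performed (use [regrid()]
#' first if needed).
#'
#' @param mixture a `spectrum` or `spectrum_series` of the reaction mix.
#' @param reference the enzyme-solution `spectrum`.
#' @return Same class as `mixture`, with the reference label recorded in
#'   the `reference` attribute.
#' @export
subtract_reference <- function(mixture, reference) {
  if (!inherits(reference, "spectrum"))
    ck_invalid("'reference' must be a spectrum")
  wn <- if (inherits(mixture, "spectrum_series")) mixture$wavenumber
        else if (inherits(mixture, "spectrum")) mixture$wavenumber
        else ck_invalid("'mixture' must be a spectrum or spectrum_series")
  if (!.same_grid(wn, reference$wavenumber))
    ck_stop("wavenumber grids differ; regrid() the reference explicitly",
            "casekin_grid_mismatch")
  out <- if (inherits(mixture, "spectrum_series")) {
    spectrum_series(mixture$wavenumber,
                    mixture$absorbance - reference$absorbance,
                    mixture$t_min, label = mixture$label)
  } else {
    spectrum(mixture$wavenumber, mixture$absorbance - reference$absorbance,
             t_min = mixture$t_min, label = mixture$label)
  }
  attr(out, "reference") <- if (is.null(reference$label)) "unnamed reference"
                            else reference$label
  out
}

#' Two-anchor linear baseline correction
#'
#' Subtracts the straight line through the spectrum's values at the two
#' anchor wavenumbers (by default 1725 and 1375 cm^-1, flanking the amide
#' and carboxylate bands) and returns only the window between the
#' anchors. The anchor points themselves are appended to the output grid
#' (by linear interpolation before subtraction), so the corrected
#' spectrum is exactly zero at both anchors.
#'
#' @param s a `spectrum` or `spectrum_series` spanning both anchors.
#' @param anchors two wavenumbers, cm^-1.
#' @return The baseline-corrected window, same class as the input.
#' @export
baseline_correct <- function(s, anchors = c(1725, 1375)) {
  if (inherits(s, "spectrum_series"))
    return(.series_map(s, function(sp) baseline_correct(sp, anchors)))
  if (!inherits(s, "spectrum")) ck_invalid("'s' must be a spectrum")
  if (length(anchors) != 2L || anyNA(anchors))
    ck_invalid("'anchors' must be two wavenumbers")
  lo <- min(anchors); hi <- max(anchors)
  if (lo < min(s$wavenumber) || hi > max(s$wavenumber))
    ck_stop(sprintf("anchors (%g, %g) outside grid span [%g, %g]",
                    lo, hi, min(s$wavenumber), max(s$wavenumber)),
            "casekin_out_of_range")
  a_lo <- stats::approx(s$wavenumber, s$absorbance, xout = lo)$y
  a_hi <- stats::approx(s$wavenumber, s$absorbance, xout = hi)$y
  keep <- s$wavenumber > lo & s$wavenumber < hi
  wn <- c(lo, s$wavenumber[keep], hi)
  ab <- c(a_lo, s$absorbance[keep], a_hi)
  line <- a_lo + (wn - lo) * (a_hi - a_lo) / (hi - lo)
  spectrum(wn, ab - line, t_min = s$t_min, label = s$label)
}

# signed trapezoidal integral over the full stored grid
.trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Equal-area normalization
#'
#' Scales a baseline-corrected spectrum so that its signed trapezoidal
#' integral over the analysis window equals `target_area` (1 AU cm^-1 by
#' default; any common constant gives the same difference-spectrum
#' shapes up to scale). Spectra whose window area is not positive cannot
#' be normalized and raise an error rather than silently flipping sign.
#'
#' @param s a `spectrum` or `spectrum_series` (typically the output of
#'   [baseline_correct()], whose grid is the window itself).
#' @param window wavenumber bounds of the integration window, cm^-1.
#' @param target_area desired window area, AU cm^-1.
#' @return Normalized object of the same class.
#' @export
normalize_area <- function(s, window = c(1375, 1725), target_area = 1) {
  if (inherits(s, "spectrum_series"))
    return(.series_map(s, function(sp) normalize_area(sp, window, target_area)))
  if (!inherits(s, "spectrum")) ck_invalid("'s' must be a spectrum")
  stopifnot_scalar_number(target_area, "target_area", positive = TRUE)
  lo <- min(window); hi <- max(window)
  if (lo < min(s$wavenumber) || hi > max(s$wavenumber))
    ck_stop("integration window outside grid span", "casekin_out_of_range")
  sel <- s$wavenumber >= lo & s$wavenumber <= hi
  area <- .trapz(s$wavenumber[sel], s$absorbance[sel])
  if (!is.finite(area) || area <= 0)
    ck_stop(sprintf("window area %.3g is not positive; cannot normalize", area),
            "casekin_normalization_impossible")
  spectrum(s$wavenumber, s$absorbance * target_area / area,
           t_min = s$t_min, label = s$label)
}

#' Difference spectra relative to the first time point
#'
#' Subtracts the first recorded spectrum (conventionally t = 1 min) from
#' every spectrum of a fully preprocessed series, so that structure loss
#' appears as negative and product growth as positive bands. The first
#' difference spectrum is identically zero by construction.
#'
#' @param series a preprocessed `spectrum_series`.
#' @return A `spectrum_series` of difference spectra.
#' @export
difference_series <- function(series) {
  if (!inherits(series, "spectrum_series"))
    ck_stop("'series' must be a non-empty spectrum_series",
            "casekin_empty_input")
  spectrum_series(series$wavenumber,
                  series$absorbance - series$absorbance[, 1L],
                  series$t_min, label = series$label)
}

#' Band intensity time course from difference spectra
#'
#' Reads the difference-spectrum intensity at one band position as a
#' function of time, linearly interpolating between the two neighbouring
#' grid points so the result does not depend on whether the nominal band
#' centre falls on the acquisition grid.
#'
#' @param diff_series a `spectrum_series` of difference spectra.
#' @param band_cm1 band position, cm^-1 (e.g. 1633 beta-sheet, 1650
#'   alpha-helix, 1593/1405 free carboxylates).
#' @return A `band_trace`: data.frame with columns `t_min`, `delta_abs`
#'   and the band position as attribute `band_cm1`.
#' @export
band_timecourse <- function(diff_series, band_cm1) {
  if (!inherits(diff_series, "spectrum_series"))
    ck_invalid("'diff_series' must be a spectrum_series")
  stopifnot_scalar_number(band_cm1, "band_cm1")
  wn <- diff_series$wavenumber
  if (band_cm1 < min(wn) || band_cm1 > max(wn))
    ck_stop(sprintf("band %g cm^-1 outside window [%g, %g]",
                    band_cm1, min(wn), max(wn)), "casekin_out_of_range")
  vals <- apply(diff_series$absorbance, 2L, function(a)
    stats::approx(wn, a, xout = band_cm1)$y)
  structure(data.frame(t_min = diff_series$t_min, delta_abs = vals),
            band_cm1 = band_cm1, class = c("band_trace", "data.frame"))
}

#' @export
print.band_trace <- function(x, ...) {
  cat(sprintf("Band trace at %g cm^-1, %d time points (t = %g-%g min)\n",
              attr(x, "band_cm1"), nrow(x), min(x$t_min), max(x$t_min)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Full FTIR processing chain for a reaction series
#'
#' Applies, in order: enzyme-reference subtraction, two-anchor baseline
#' correction, equal-area normalization, differencing against the first
#' spectrum, and band read-off. The order matters (normalizing before
#' baseline correction gives different results) and is enforced here.
#'
#' @param raw_series the as-recorded `spectrum_series` of the reaction
#'   mixture.
#' @param enzyme_reference the enzyme-solution `spectrum` on the same grid.
#' @param bands band positions to extract, cm^-1.
#' @param anchors,target_area passed to [baseline_correct()] and
#'   [normalize_area()].
#' @return List with elements `traces` (named list of `band_trace`, one
#'   per band), `difference` (the difference `spectrum_series`) and
#'   `processed` (the normalized series before differencing).
#' @export
process_reaction_series <- function(raw_series, enzyme_reference,
                                    bands = c(1633, 1650, 1593),
                                    anchors = c(1725, 1375),
                                    target_area = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ck_stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
              class(e)[1L])
    })
  }
  s1 <- stage("subtract_reference",
              subtract_reference(raw_series, enzyme_reference))
  s2 <- stage("baseline_correct", baseline_correct(s1, anchors))
  s3 <- stage("normalize_area",
              normalize_area(s2, window = sort(anchors), target_area))
  dd <- stage("difference_series", difference_series(s3))
  traces <- lapply(bands, function(b)
    stage("band_timecourse", band_timecourse(dd, b)))
  names(traces) <- as.character(bands)
  list(traces = traces, difference = dd, processed = s3)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation onto `new_wavenumber`. Series operations never
#' resample implicitly; call this explicitly when grids differ.
#'
#' @param s a `spectrum` or `spectrum_series`.
#' @param new_wavenumber target grid, cm^-1, within the current span.
#' @return Object of the same class on the new grid.
#' @export
regrid <- function(s, new_wavenumber) {
  .check_grid(new_wavenumber)
  if (inherits(s, "spectrum_series"))
    return(.series_map(s, function(sp) regrid(sp, new_wavenumber)))
  if (!inherits(s, "spectrum")) ck_invalid("'s' must be a spectrum")
  if (min(new_wavenumber) < min(s$wavenumber) ||
      max(new_wavenumber) > max(s$wavenumber))
    ck_stop("new grid extends beyond the recorded span",
            "casekin_out_of_range")
  spectrum(new_wavenumber,
           stats::approx(s$wavenumber, s$absorbance,
                         xout = sort(new_wavenumber))$y,
           t_min = s$t_min, label = s$label)
}
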