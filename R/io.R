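#' Delimited-text input and output
#'
#' Plain-CSV readers and writers for the package's tabular interchange
#' formats: kinetic trajectories (`t_s, S, X, Y, N, Z`), peak-time
#' observation tables (`E0_mg_per_L, tmax_s`), wide spectral series
#' (first column `wavenumber_cm1`, remaining columns `t_<minutes>`),
#' band traces (`t_min, delta_abs`) and particle tables
#' (`height_nm, diameter_nm`).
#'
#' @param x object to write.
#' @param path file path.
#' @name casekin_io
NULL

#' @rdname casekin_io
#' @export
write_trajectory_csv <- function(x, path) {
  if (!inherits(x, "kinetic_trajectory"))
    ck_invalid("'x' must be a kinetic_trajectory")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname casekin_io
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "S", "X", "Y", "N")
  if (!all(need %in% names(d)))
    ck_invalid(sprintf("trajectory CSV must have columns %s",
                       paste(need, collapse = ", ")))
  if (is.null(d$Z)) d$Z <- 0
  structure(d[c("t_s", "S", "X", "Y", "N", "Z")],
            class = c("kinetic_trajectory", "data.frame"))
}

#' @rdname casekin_io
#' @export
write_tmax_csv <- function(x, path) {
  obs <- .as_tmax_observations(x)
  utils::write.csv(data.frame(E0_mg_per_L = obs$E0, tmax_s = obs$tmax),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname casekin_io
#' @export
read_tmax_csv <- function(path) .as_tmax_observations(utils::read.csv(path))

#' @rdname casekin_io
#' @export
write_series_csv <- function(x, path) {
  if (!inherits(x, "spectrum_series"))
    ck_invalid("'x' must be a spectrum_series")
  d <- data.frame(wavenumber_cm1 = x$wavenumber)
  for (i in seq_along(x$t_min))
    d[[sprintf("t_%g", x$t_min[i])]] <- x$absorbance[, i]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname casekin_io
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "wavenumber_cm1")
    ck_invalid("first column of a series CSV must be 'wavenumber_cm1'")
  tc <- grep("^t_", names(d), value = TRUE)
  if (!length(tc)) ck_invalid("series CSV needs time columns named t_<minutes>")
  t_min <- as.numeric(sub("^t_", "", tc))
  o <- order(t_min)
  spectrum_series(d$wavenumber_cm1, as.matrix(d[tc[o]]), t_min[o])
}

#' @rdname casekin_io
#' @export
write_band_trace_csv <- function(x, path) {
  if (!inherits(x, "band_trace")) ck_invalid("'x' must be a band_trace")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname casekin_io
#' @export
read_particles_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("height_nm", "diameter_nm") %in% names(d)))
    ck_invalid("particle CSV must have columns height_nm, diameter_nm")
  particle_ensemble(d$height_nm, d$diameter_nm)
}

#' @rdname casekin_io
#' @export
write_particles_csv <- function(x, path) {
  if (!inherits(x, "particle_ensemble"))
    ck_invalid("'x' must be a particle_ensemble")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
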