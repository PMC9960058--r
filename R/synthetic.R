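#' Synthetic peak-time observations
#'
#' Emulates the light-scattering determination of the nanoparticle peak
#' time at several enzyme concentrations: for each `E0` the exact model
#' `t_max` is computed from the rate constants and then perturbed by
#' multiplicative lognormal noise (`sdlog = sigma`), mimicking the
#' 1-2 min timing resolution of continuous scattering records. The
#' generating `k2` is recorded as the `true_k2` attribute so recovery by
#' [fit_k2()] can be scored without re-deriving it.
#'
#' @param rates a [rate_constants()] object (the generating truth).
#' @param E0 enzyme concentrations, mg/L.
#' @param sigma lognormal noise scale (0 gives exact observations).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `E0`, `tmax` and attributes `true_k2`,
#'   `sigma`.
#' @export
gen_tmax_dataset <- function(rates, E0 = c(0.125, 0.25, 0.5, 1),
                             sigma = 0, seed = NULL) {
  if (!inherits(rates, "rate_constants"))
    ck_invalid("'rates' must be a rate_constants object")
  if (!is.numeric(E0) || !length(E0) || any(E0 <= 0))
    ck_invalid("'E0' must be positive concentrations")
  stopifnot_scalar_number(sigma, "sigma", nonnegative = TRUE)
  if (!is.null(seed)) set.seed(seed)
  tm <- vapply(E0, function(e) tmax(proteolysis_model(rates, e)), numeric(1))
  if (sigma > 0) tm <- tm * exp(stats::rnorm(length(tm), 0, sigma))
  structure(data.frame(E0 = E0, tmax = tm),
            true_k2 = rates$k2, sigma = sigma)
}

#' Synthetic FTIR spectral time series with recorded truth
#'
#' Forward model for a proteolysis FTIR run: Gaussian bands at the
#' beta-sheet (1633 cm^-1), alpha-helix (1650 cm^-1) and free-carboxylate
#' (1593, 1405 cm^-1) positions whose amplitudes follow the kinetic
#' model — structure bands track the retained-structure signal
#' (`S+X/2+Y` by default, with a residual offset for structure that
#' survives complete digestion) and carboxylate bands track the product
#' fraction `N(t)` — on a 4 cm^-1 grid over 1300-1800 cm^-1. Each
#' noiseless spectrum is scaled to a common window area (mirroring the
#' roughly conserved total amide + carboxylate intensity of real runs),
#' then a linear baseline, a broad enzyme-solution profile and white
#' noise are added.
#'
#' The returned `truth` table holds, per band and time, the
#' difference-spectrum value an ideal (noise-free) processing chain
#' would read off after anchor-line correction and normalization to unit
#' window area. It is computed directly from the forward model's own
#' arithmetic, independently of the processing functions, so pipeline
#' output can be scored against it.
#'
#' @param traj a `kinetic_trajectory` covering the requested times.
#' @param times_min acquisition times, min (first is the reference).
#' @param bands data.frame with columns `center`, `sigma` (cm^-1),
#'   `amplitude` (AU) and `kind` (`"structure"` or `"product"`).
#' @param coupling retention hypothesis driving the structure bands.
#' @param residual_offset fraction of the structure-band amplitude that
#'   never decays (residual order in the digest).
#' @param window_area raw window area each noiseless spectrum is scaled
#'   to, AU cm^-1.
#' @param baseline `c(offset, slope)`: linear baseline `offset +
#'   slope * (wavenumber - 1300)`, AU.
#' @param enzyme_amplitude peak absorbance of the broad enzyme profile
#'   (Gaussian, centre 1550 cm^-1, sigma 90 cm^-1), AU.
#' @param noise_sd white-noise standard deviation per point, AU.
#' @param wavenumber acquisition grid, cm^-1.
#' @param anchors baseline anchor wavenumbers used for the truth
#'   bookkeeping (must match the downstream processing call).
#' @param seed optional integer seed.
#' @return List with `series` (raw `spectrum_series`), `enzyme`
#'   (reference `spectrum`), `truth` (data.frame `band_cm1`, `t_min`,
#'   `delta_abs`) and `params`.
#' @export
gen_ftir_series <- function(traj,
                            times_min = c(1, seq(5, 90, by = 5)),
                            bands = default_ftir_bands(),
                            coupling = c("S+X/2+Y", "S+Y"),
                            residual_offset = 0.1,
                            window_area = 25,
                            baseline = c(0.02, 1e-4),
                            enzyme_amplitude = 0.05,
                            noise_sd = 0.002,
                            wavenumber = seq(1300, 1800, by = 4),
                            anchors = c(1725, 1375),
                            seed = NULL) {
  if (!inherits(traj, "kinetic_trajectory"))
    ck_invalid("'traj' must be a kinetic_trajectory")
  coupling <- match.arg(coupling)
  if (!is.null(seed)) set.seed(seed)
  t_s <- times_min * 60
  if (min(t_s) < min(traj$t_s) || max(t_s) > max(traj$t_s))
    ck_stop("requested times fall outside the trajectory grid",
            "casekin_out_of_range")
  at <- function(col) stats::approx(traj$t_s, traj[[col]], xout = t_s)$y
  u <- switch(coupling,
              "S+Y" = at("S") + at("Y"),
              "S+X/2+Y" = at("S") + at("X") / 2 + at("Y"))
  v <- at("N")

  amp <- function(b, i) {
    if (bands$kind[b] == "structure")
      bands$amplitude[b] * (residual_offset + (1 - residual_offset) * u[i])
    else bands$amplitude[b] * v[i]
  }
  nb <- nrow(bands); nt <- length(times_min); nw <- length(wavenumber)
  shapes <- vapply(seq_len(nb), function(b)
    exp(-(wavenumber - bands$center[b])^2 / (2 * bands$sigma[b]^2)),
    numeric(nw))
  B <- vapply(seq_len(nt), function(i)
    as.numeric(shapes %*% vapply(seq_len(nb), amp, numeric(1), i = i)),
    numeric(nw))

  # scale each noiseless spectrum to a common raw window area
  for (i in seq_len(nt)) {
    ar <- .window_area(wavenumber, B[, i], anchors)
    B[, i] <- B[, i] * window_area / ar
  }

  truth_vals <- vapply(seq_len(nt), function(i)
    .ideal_band_readoff(wavenumber, B[, i], bands$center, anchors),
    numeric(nb))
  truth <- data.frame(
    band_cm1 = rep(bands$center, times = nt),
    t_min = rep(times_min, each = nb),
    delta_abs = as.numeric(truth_vals - truth_vals[, 1L]))

  base <- baseline[1] + baseline[2] * (wavenumber - 1300)
  enz <- enzyme_amplitude * exp(-(wavenumber - 1550)^2 / (2 * 90^2))
  raw <- B + base + enz
  if (noise_sd > 0)
    raw <- raw + matrix(stats::rnorm(nw * nt, 0, noise_sd), nw, nt)

  list(series = spectrum_series(wavenumber, raw, times_min,
                                label = "synthetic reaction mixture"),
       enzyme = spectrum(wavenumber, enz, label = "synthetic enzyme reference"),
       truth = truth,
       params = list(coupling = coupling, residual_offset = residual_offset,
                     window_area = window_area, baseline = baseline,
                     enzyme_amplitude = enzyme_amplitude, noise_sd = noise_sd,
                     bands = bands, anchors = anchors))
}

#' @rdname gen_ftir_series
#' @export
default_ftir_bands <- function() {
  data.frame(center = c(1633, 1650, 1593, 1405),
             sigma = c(12, 12, 12, 12),
             amplitude = c(1.0, 0.8, 0.5, 0.35),
             kind = c("structure", "structure", "product", "product"))
}

# forward-model bookkeeping mirroring the processing arithmetic:
# anchor-line subtraction on the window {lo, interior grid, hi}, signed
# trapezoidal area, normalization to unit area, linear read-off
.window_points <- function(wn, ab, anchors) {
  lo <- min(anchors); hi <- max(anchors)
  a_lo <- stats::approx(wn, ab, xout = lo)$y
  a_hi <- stats::approx(wn, ab, xout = hi)$y
  keep <- wn > lo & wn < hi
  x <- c(lo, wn[keep], hi)
  y <- c(a_lo, ab[keep], a_hi)
  list(x = x, y = y - (a_lo + (x - lo) * (a_hi - a_lo) / (hi - lo)))
}

.window_area <- function(wn, ab, anchors) {
  w <- .window_points(wn, ab, anchors)
  .trapz(w$x, w$y)
}

.ideal_band_readoff <- function(wn, ab, band_cm1, anchors) {
  w <- .window_points(wn, ab, anchors)
  area <- .trapz(w$x, w$y)
  stats::approx(w$x, w$y / area, xout = band_cm1)$y
}

#' Synthetic AFM particle ensemble
#'
#' Draws particle heights from a Gaussian mixture and diameters from a
#' Gaussian, truncated at zero by resampling (so the distribution shape
#' near its body is unchanged, with no atom at the truncation point).
#' Defaults reproduce the structure of a heat-stopped digest: a bimodal
#' height distribution (components at 0.8 and 3.8 nm) with diameters
#' around 58 +/- 12 nm. Set `height_means = 1`, `height_sds = 0.3`,
#' `height_weights = 1` for an inhibitor-stopped, unimodal sample.
#'
#' @param n number of particles.
#' @param height_means,height_sds,height_weights Gaussian-mixture
#'   parameters for heights, nm (weights must sum to 1).
#' @param diameter_mean,diameter_sd diameter distribution, nm.
#' @param label sample identifier.
#' @param seed optional integer seed.
#' @return A [particle_ensemble()] with generator parameters in the
#'   `truth` attribute.
#' @export
gen_particle_ensemble <- function(n = 500,
                                  height_means = c(0.8, 3.8),
                                  height_sds = c(0.2, 0.6),
                                  height_weights = c(0.4, 0.6),
                                  diameter_mean = 58, diameter_sd = 12,
                                  label = NULL, seed = NULL) {
  if (length(height_means) != length(height_sds) ||
      length(height_means) != length(height_weights))
    ck_config_error("height mixture parameters must have equal lengths",
                    key = "height_means")
  if (abs(sum(height_weights) - 1) > 1e-9 || any(height_weights < 0))
    ck_config_error("height_weights must be non-negative and sum to 1",
                    key = "height_weights")
  if (any(height_sds <= 0) || diameter_sd <= 0)
    ck_config_error("all standard deviations must be positive", key = "sds")
  if (n < 0) ck_invalid("'n' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(structure(particle_ensemble(numeric(0), numeric(0), label = label),
                     truth = NULL))
  comp <- sample.int(length(height_weights), n, replace = TRUE,
                     prob = height_weights)
  H <- .rnorm_pos(n, height_means[comp], height_sds[comp])
  D <- .rnorm_pos(n, diameter_mean, diameter_sd)
  ens <- suppressWarnings(particle_ensemble(H, D, label = label))
  attr(ens, "truth") <- list(height_means = height_means,
                             height_sds = height_sds,
                             height_weights = height_weights,
                             diameter_mean = diameter_mean,
                             diameter_sd = diameter_sd, n = n)
  ens
}

# truncated-normal draws by resampling negatives
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad),
                           if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}
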