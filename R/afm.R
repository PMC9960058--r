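#' Nanoparticle ensembles measured by atomic force microscopy
#'
#' Particles dried on mica flatten, so each is characterized by its
#' height `H` and diameter `D` (both nm) from surface sections. An
#' ensemble is a table of such records plus a sample label. Particles
#' with `H > D` are admitted with a warning, since they contradict the
#' flattened-droplet geometry expected after adsorption and drying.
#'
#' @param height_nm particle heights, nm (> 0).
#' @param diameter_nm particle diameters, nm (> 0), same length.
#' @param label sample identifier.
#' @return Object of class `particle_ensemble` (a data.frame with
#'   columns `height_nm`, `diameter_nm`).
#' @export
particle_ensemble <- function(height_nm, diameter_nm, label = NULL) {
  if (length(height_nm) != length(diameter_nm))
    ck_invalid("'height_nm' and 'diameter_nm' must have equal length")
  if (length(height_nm)) {
    if (anyNA(height_nm) || anyNA(diameter_nm) ||
        any(height_nm <= 0) || any(diameter_nm <= 0))
      ck_invalid("heights and diameters must be positive and NA-free")
    if (any(height_nm > diameter_nm))
      ck_warn(sprintf("%d particle(s) have H > D, unexpected for flattened particles",
                      sum(height_nm > diameter_nm)))
  }
  structure(data.frame(height_nm = as.numeric(height_nm),
                       diameter_nm = as.numeric(diameter_nm)),
            label = label, class = c("particle_ensemble", "data.frame"))
}

#' @export
print.particle_ensemble <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("AFM particle ensemble%s: n = %d\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"), nrow(x)))
  if (nrow(x) >= 2L) {
    s <- summary(x)
    cat(sprintf("  height   %.2f +/- %.2f nm\n", s$mean_H, s$sd_H))
    cat(sprintf("  diameter %.1f +/- %.1f nm\n", s$mean_D, s$sd_D))
  }
  invisible(x)
}

#' Summary statistics of a particle ensemble
#'
#' Arithmetic means and sample standard deviations of particle height
#' and diameter. With a single particle the sd is undefined and reported
#' as 0 with `sd_defined = FALSE`.
#'
#' @param object a [particle_ensemble()].
#' @param ... unused.
#' @return List with `n`, `mean_H`, `sd_H`, `mean_D`, `sd_D`,
#'   `sd_defined`.
#' @export
summary.particle_ensemble <- function(object, ...) {
  if (nrow(object) == 0L)
    ck_stop("empty ensemble: no particles to summarize", "casekin_empty_input")
  one <- nrow(object) == 1L
  structure(list(
    n = nrow(object),
    mean_H = mean(object$height_nm),
    sd_H = if (one) 0 else stats::sd(object$height_nm),
    mean_D = mean(object$diameter_nm),
    sd_D = if (one) 0 else stats::sd(object$diameter_nm),
    sd_defined = !one,
    label = attr(object, "label")), class = "particle_summary")
}

#' @export
print.particle_summary <- function(x, ...) {
  cat(sprintf("n = %d particles%s\n", x$n,
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  cat(sprintf("  mean height   %.2f +/- %.2f nm\n", x$mean_H, x$sd_H))
  cat(sprintf("  mean diameter %.1f +/- %.1f nm\n", x$mean_D, x$sd_D))
  if (!x$sd_defined) cat("  (single particle: sd undefined, reported as 0)\n")
  invisible(x)
}

#' Histogram of particle sizes with mode detection
#'
#' Bins one size dimension at a fixed bin width and locates modes as
#' local maxima of the 3-bin moving-average-smoothed counts. The dried
#' nanoparticle height distributions are diagnostic: heat-stopped
#' samples show a bimodal height distribution while inhibitor-stopped
#' ones are unimodal, so a transparent, auditable mode detector is
#' preferred over kernel density estimation here.
#'
#' @param ens a [particle_ensemble()].
#' @param bin_width_nm bin width, nm (default 0.2, suited to heights;
#'   use ~5 for diameters).
#' @param dimension `"height"` or `"diameter"`.
#' @param min_count_frac modes whose smoothed count falls below this
#'   fraction of the dominant smoothed peak are discarded; this
#'   suppresses Poisson-noise bumps in sparsely populated bins while
#'   keeping any genuine secondary population.
#' @return List of class `size_histogram`: `breaks`, `counts`, `mids`,
#'   `smoothed`, `modes_nm` (bin midpoints of detected modes),
#'   `bin_width_nm`, `dimension`.
#' @export
height_histogram <- function(ens, bin_width_nm = 0.2,
                             dimension = c("height", "diameter"),
                             min_count_frac = 0.05) {
  dimension <- match.arg(dimension)
  if (!inherits(ens, "particle_ensemble") || nrow(ens) == 0L)
    ck_stop("'ens' must be a non-empty particle_ensemble",
            "casekin_empty_input")
  stopifnot_scalar_number(bin_width_nm, "bin_width_nm", positive = TRUE)
  x <- if (dimension == "height") ens$height_nm else ens$diameter_nm
  rng <- range(x)
  if (bin_width_nm >= diff(rng) + bin_width_nm * 1e-9 && diff(rng) > 0)
    ck_warn("bin width spans the whole data range; single-bin histogram")
  breaks <- seq(floor(rng[1] / bin_width_nm) * bin_width_nm,
                rng[2] + bin_width_nm, by = bin_width_nm)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  n <- length(h$counts)
  if (n < 3L) {
    sm <- as.numeric(h$counts)
  } else {
    sm <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
    sm[1L] <- mean(h$counts[1:2])
    sm[n] <- mean(h$counts[(n - 1L):n])
    sm <- as.numeric(sm)
  }
  modes <- .local_maxima(sm)
  modes <- modes[sm[modes] >= min_count_frac * max(sm)]
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 smoothed = sm, modes_nm = h$mids[modes],
                 bin_width_nm = bin_width_nm, dimension = dimension,
                 n = length(x)),
            class = "size_histogram")
}

# indices of strict local maxima of a smoothed count vector; plateaus
# count once, at their first bin
.local_maxima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  keep <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left_ok <- i == 1L || y[i - 1L] < y[i]
    right_ok <- j == n || y[j + 1L] < y[i]
    if (left_ok && right_ok && y[i] > 0) keep <- c(keep, i)
    i <- j + 1L
  }
  keep
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("%s histogram: %d particles, bin %g nm, %d bins\n",
              x$dimension, x$n, x$bin_width_nm, length(x$counts)))
  cat(sprintf("  detected mode(s) at %s nm\n",
              paste(signif(x$modes_nm, 3), collapse = ", ")))
  invisible(x)
}

#' @export
plot.size_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = signif(x$mids, 3), space = 0,
                    xlab = sprintf("%s, nm", x$dimension), ylab = "count", ...)
  invisible(x)
}

#' Per-particle volume under a geometric model
#'
#' The dried particles flatten on mica, so a geometric model is needed
#' to turn (H, D) into a volume. Two are provided: a spherical cap of
#' height `H` and basal diameter `D`, `V = (pi H / 6) (3 (D/2)^2 + H^2)`
#' (the default), and a half ellipsoid with semi-axes `D/2, D/2, H`,
#' `V = (2/3) pi (D/2)^2 H`. Published mean volumes of such ensembles
#' are model-dependent; only the volume-to-radius conversion
#' ([sphere_equivalent_radius()]) is model-free.
#'
#' @param height_nm particle height(s), nm.
#' @param diameter_nm particle diameter(s), nm.
#' @param model `"spherical_cap"` or `"half_ellipsoid"`.
#' @return Volume(s), nm^3.
#' @export
particle_volume <- function(height_nm, diameter_nm,
                            model = c("spherical_cap", "half_ellipsoid")) {
  model <- match.arg(model)
  if (any(height_nm <= 0) || any(diameter_nm <= 0))
    ck_invalid("heights and diameters must be positive")
  r <- diameter_nm / 2
  switch(model,
         spherical_cap = pi * height_nm / 6 * (3 * r^2 + height_nm^2),
         half_ellipsoid = 2 / 3 * pi * r^2 * height_nm)
}

#' Sphere-equivalent radius of a particle volume
#'
#' Radius of the sphere with the same volume,
#' `r = (3 V / (4 pi))^(1/3)`. Used to express flattened-particle
#' volumes as equivalent solution-phase particle radii.
#'
#' @param volume_nm3 volume(s), nm^3, positive.
#' @return Radius (nm).
#' @export
sphere_equivalent_radius <- function(volume_nm3) {
  if (!is.numeric(volume_nm3) || any(!is.finite(volume_nm3)) ||
      any(volume_nm3 <= 0))
    ck_invalid("'volume_nm3' must be positive and finite")
  (3 * volume_nm3 / (4 * pi))^(1 / 3)
}
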