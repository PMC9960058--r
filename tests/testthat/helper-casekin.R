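# Rate constants determined from light-scattering data: effective rates
# k1*E0 = 0.0066, k2 = 0.0015, k3*E0 = 0.0002 s^-1 at E0 = 0.25 mg/L.
paper_rc <- function(ka = 0) {
  rate_constants(k1E0 = 0.0066, k2 = 0.0015, k3E0 = 2e-4, E0 = 0.25, ka = ka)
}

paper_model <- function(E0 = 0.25) proteolysis_model(paper_rc(), E0)

# Independent fixed-step classical Runge-Kutta (RK4) integrator for the
# chain ODEs. Deliberately shares no code with the package (which uses
# the closed form and an adaptive lsoda solver).
rk4_chain <- function(a, b, cc, times, ka = 0, dt = NULL) {
  if (is.null(dt)) dt <- min(0.02 / max(a, b, cc), diff(times))
  rhs <- function(y) c(-a * y[1],
                       a * y[1] - b * y[2],
                       b * y[2] - (cc + ka) * y[3],
                       cc * y[3],
                       ka * y[3])
  out <- matrix(NA_real_, length(times), 5)
  y <- c(1, 0, 0, 0, 0)
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  colnames(out) <- c("S", "X", "Y", "N", "Z")
  out
}

# log-uniform random rate triple in [1e-5, 1e-1] s^-1 with all pairwise
# relative gaps above 1e-3 (the closed form is only claimed away from
# the confluent limit)
random_rates <- function() {
  repeat {
    r <- 10^stats::runif(3, -5, -1)
    gaps <- abs(outer(r, r, "-")) / outer(r, r, "+")
    if (min(gaps[lower.tri(gaps)]) > 1e-3) return(r)
  }
}

# model with prescribed effective rates at E0 = 1
model_from_effective <- function(a, b, cc) {
  proteolysis_model(rate_constants(k1 = a, k2 = b, k3 = cc), E0 = 1)
}

gaussian_band <- function(wn, center, sigma, amplitude = 1) {
  amplitude * exp(-(wn - center)^2 / (2 * sigma^2))
}
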