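#' Fit the enzyme-independent rearrangement rate constant k2
#'
#' Estimates `k2` from observed peak times of the nanoparticle signal at
#' one or more enzyme concentrations, holding `k1` and `k3` fixed at
#' their independently determined values. For a candidate `k2`, the model
#' peak time at each `E0` is the root of the transcendental `dY/dt = 0`
#' condition (see [tmax()]); the estimate minimizes the sum of squared
#' residuals between observed and model peak times. The minimization is a
#' bounded 1-D search on `log(k2)` over `[1e-6, 1]` s^-1
#' ([stats::optimize()]), which is reliable because the residual surface
#' is smooth and unimodal in practice.
#'
#' @param observations data.frame with columns `E0` (mg/L) and `tmax` (s)
#'   — the column names `E0_mg_per_L` / `tmax_s` used by the CSV I/O
#'   helpers are also accepted.
#' @param k1 fixed first-stage rate coefficient, s^-1 per (mg/L).
#' @param k3 fixed third-stage rate coefficient, s^-1 per (mg/L).
#' @param interval search bounds for `k2`, s^-1.
#' @return An object of class `k2_fit` with components `k2`, `k1`, `k3`,
#'   `observations`, `fitted`, `residuals`, `ssr`, and the usual
#'   [coef()], [fitted()], [residuals()], [predict()], [print()] and
#'   [summary()] methods.
#' @examples
#' rc <- rate_constants(k1 = 0.0264, k2 = 0.0015, k3 = 8e-4)
#' obs <- gen_tmax_dataset(rc, E0 = c(0.125, 0.25, 0.5, 1), sigma = 0)
#' fit <- fit_k2(obs, k1 = 0.0264, k3 = 8e-4)
#' coef(fit)
#' @export
fit_k2 <- function(observations, k1, k3, interval = c(1e-6, 1)) {
  obs <- .as_tmax_observations(observations)
  stopifnot_scalar_number(k1, "k1", positive = TRUE)
  stopifnot_scalar_number(k3, "k3", positive = TRUE)
  if (!is.numeric(interval) || length(interval) != 2L || any(interval <= 0) ||
      interval[1] >= interval[2])
    ck_invalid("'interval' must be positive increasing bounds for k2")
  if (length(unique(obs$E0)) == 1L && nrow(obs) > 1L &&
      stats::sd(obs$tmax) > 0)
    ck_warn("all observations share one E0 with differing tmax; returning the least-squares optimum over replicates")

  pred <- function(k2, E0) {
    rc <- rate_constants(k1 = k1, k2 = k2, k3 = k3)
    vapply(E0, function(e) tmax(proteolysis_model(rc, e)), numeric(1))
  }
  ssr <- function(logk2) {
    p <- tryCatch(pred(exp(logk2), obs$E0), error = function(e) NULL)
    if (is.null(p)) return(.Machine$double.xmax)
    sum((obs$tmax - p)^2)
  }
  opt <- stats::optimize(ssr, interval = log(interval), tol = 1e-10)
  k2_hat <- exp(opt$minimum)
  fit_vals <- pred(k2_hat, obs$E0)
  structure(
    list(k2 = k2_hat, k1 = k1, k3 = k3,
         observations = obs, fitted = fit_vals,
         residuals = obs$tmax - fit_vals,
         ssr = sum((obs$tmax - fit_vals)^2),
         interval = interval, n = nrow(obs)),
    class = "k2_fit")
}

.as_tmax_observations <- function(observations) {
  if (!is.data.frame(observations) || nrow(observations) < 1L)
    ck_stop("'observations' must be a non-empty data.frame",
            "casekin_empty_input")
  nm <- names(observations)
  e_col <- intersect(c("E0", "E0_mg_per_L"), nm)[1]
  t_col <- intersect(c("tmax", "tmax_s"), nm)[1]
  if (is.na(e_col) || is.na(t_col))
    ck_invalid("'observations' needs columns E0 (or E0_mg_per_L) and tmax (or tmax_s)")
  obs <- data.frame(E0 = as.numeric(observations[[e_col]]),
                    tmax = as.numeric(observations[[t_col]]))
  if (any(!is.finite(obs$E0)) || any(obs$E0 <= 0))
    ck_invalid("all E0 must be positive and finite")
  if (any(!is.finite(obs$tmax)) || any(obs$tmax <= 0))
    ck_invalid("all tmax must be positive and finite")
  obs
}

#' @export
coef.k2_fit <- function(object, ...) c(k2 = object$k2)

#' @export
fitted.k2_fit <- function(object, ...) object$fitted

#' @export
residuals.k2_fit <- function(object, ...) object$residuals

#' Predict peak times at new enzyme concentrations
#'
#' @param object a [fit_k2()] result.
#' @param newdata data.frame with an `E0` (or `E0_mg_per_L`) column;
#'   defaults to the fitted observations.
#' @param ... unused.
#' @return Numeric vector of model `t_max` values, s.
#' @export
predict.k2_fit <- function(object, newdata = NULL, ...) {
  E0 <- if (is.null(newdata)) object$observations$E0
        else {
          nm <- intersect(c("E0", "E0_mg_per_L"), names(newdata))[1]
          if (is.na(nm)) ck_invalid("'newdata' needs an E0 column")
          as.numeric(newdata[[nm]])
        }
  rc <- rate_constants(k1 = object$k1, k2 = object$k2, k3 = object$k3)
  vapply(E0, function(e) tmax(proteolysis_model(rc, e)), numeric(1))
}

#' @export
print.k2_fit <- function(x, ...) {
  cat("Rearrangement rate constant fitted from nanoparticle peak times\n")
  cat(sprintf("  k2 = %.6g s^-1  (k1 = %g, k3 = %g s^-1 per mg/L, fixed)\n",
              x$k2, x$k1, x$k3))
  cat(sprintf("  %d observation(s), residual sum of squares %.4g s^2\n",
              x$n, x$ssr))
  invisible(x)
}

#' @export
summary.k2_fit <- function(object, ...) {
  out <- object
  out$table <- data.frame(E0_mg_per_L = object$observations$E0,
                          tmax_obs_s = object$observations$tmax,
                          tmax_fit_s = object$fitted,
                          residual_s = object$residuals)
  out$rmse <- sqrt(mean(object$residuals^2))
  class(out) <- "summary.k2_fit"
  out
}

#' @export
print.summary.k2_fit <- function(x, ...) {
  print.k2_fit(x)
  cat(sprintf("  RMSE = %.4g s\n\nPer-observation residuals:\n", x$rmse))
  print(x$table, row.names = FALSE)
  invisible(x)
}
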