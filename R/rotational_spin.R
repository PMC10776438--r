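## Rotational correlation analysis and the spin-rotational relaxation
## feasibility arithmetic for superoxide-containing radical pairs.

# Physical constants (CODATA): free-electron g-factor and electron
# gyromagnetic ratio magnitude (rad s^-1 T^-1).
G_E <- 2.00231930
GAMMA_E <- 1.7608596e11

#' Second-rank orientational autocorrelation function
#'
#' `C(tau) = < P2(u(t) . u(t + tau)) >` averaged over all time origins,
#' where P2 is the second Legendre polynomial -- the autocorrelation of
#' `(3 cos^2 theta(t) - 1)/2` with theta the angle the bond vector subtends
#' with its orientation at the time origin. `C(0) = 1` for unit vectors.
#'
#' @param u n x 3 matrix of unit vectors (rows are time-ordered
#'   orientations at uniform spacing).
#' @param max_lag maximum lag in steps.
#' @param dt time per step (ps); taken from `attr(u, "dt")` when present.
#' @return A `rotational_acf` data.frame with columns `lag` (ps) and `C`.
#' @export
p2_autocorrelation <- function(u, max_lag = NULL, dt = NULL) {
  u <- as.matrix(u)
  if (nrow(u) < 2L) stop_ib("need at least 2 orientations")
  nrm <- row_norms(u)
  if (any(abs(nrm - 1) > 1e-6)) stop_ib("orientations must be unit vectors")
  dt <- dt %||% attr(u, "dt") %||% 1
  if (is.null(max_lag)) max_lag <- min(nrow(u) - 1L, 1000L)
  C <- cpp_p2_acf(u, as.integer(max_lag))
  out <- data.frame(lag = (seq_along(C) - 1L) * dt, C = C)
  class(out) <- c("rotational_acf", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Estimate the rotational correlation time tau2
#'
#' Two estimators of the characteristic decay time of the P2
#' autocorrelation: `"fit"` -- least-squares mono-exponential
#' `C(t) = exp(-t / tau2)` restricted to lags where `C > exp(-2)`; and
#' `"integral"` -- trapezoidal integral of C up to its first non-positive
#' value (or the window end). Both are always computed; `method` selects the
#' headline value.
#'
#' @param acf a `rotational_acf` from [p2_autocorrelation()].
#' @param method `"fit"` or `"integral"`.
#' @return list with `tau2` (ps), `se` (fit standard error or `NA`),
#'   `method`, `tau2_fit`, `tau2_integral`.
#' @export
estimate_tau2 <- function(acf, method = c("fit", "integral")) {
  method <- match.arg(method)
  lag <- acf$lag
  C <- acf$C
  if (min(C) > exp(-1))
    stop_ib("no decay within window: C never falls below 1/e")
  # integral estimate up to the first non-positive C
  zero <- which(C <= 0)
  iend <- if (length(zero)) zero[1L] else length(C)
  tau_int <- sum(diff(lag[1:iend]) * (C[1:iend][-1L] + C[1:iend][-iend]) / 2)
  # mono-exponential fit on the early decay
  keep <- which(C > exp(-2))
  keep <- seq_len(max(keep))  # contiguous early window
  dfit <- data.frame(t = lag[keep], C = C[keep])
  slope <- stats::coef(stats::lm(log(pmax(C, 1e-12)) ~ 0 + t, data = dfit))
  tau0 <- max(-1 / slope, 2 * attr(acf, "dt") %||% 1, na.rm = TRUE)
  fit <- tryCatch(
    stats::nls(C ~ exp(-t / tau), data = dfit, start = list(tau = tau0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # nls rejects zero-residual (exact) inputs; the log-linear fit is exact there
    tau_fit <- unname(-1 / slope)
    se <- NA_real_
  } else {
    tau_fit <- stats::coef(fit)[["tau"]]
    se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                   error = function(e) NA_real_)
  }
  list(tau2 = if (method == "fit") tau_fit else tau_int, se = se,
       method = method, tau2_fit = tau_fit, tau2_integral = tau_int)
}

#' Build a g-tensor object
#'
#' Principal values of the electron g-interaction matrix of the radical.
#'
#' @param g11,g22,g33 principal values (dimensionless), each > 1.9.
#' @return An object of class `"g_tensor"`.
#' @export
g_tensor <- function(g11, g22, g33) {
  g <- c(g11, g22, g33)
  if (any(!is.finite(g)) || any(g <= 1.9))
    stop_ib("g-tensor principal values must be finite and > 1.9")
  structure(list(g = g, g_e = G_E), class = "g_tensor")
}

#' g-anisotropy measure
#'
#' `Delta g^2 = sum_i (g_ii - g_e)^2`, the summed squared deviation of the
#' principal g-values from the free-electron g-factor. It measures how far
#' the orbital angular momentum is from fully quenched and scales the
#' spin-rotational relaxation rate.
#'
#' @param g a [g_tensor()] or numeric vector of 3 principal values.
#' @return Delta g squared (dimensionless).
#' @export
delta_g_squared <- function(g) {
  if (inherits(g, "g_tensor")) g <- g$g
  if (length(g) != 3L || any(!is.finite(g)))
    stop_ib("need 3 finite principal g-values")
  sum((g - G_E)^2)
}

#' Spin-rotational relaxation time
#'
#' For isotropic rotational diffusion the electron-spin relaxation rate via
#' the spin-rotational mechanism is `1/T = Delta g^2 / (9 tau2)`, so
#' `T = 9 tau2 / Delta g^2`.
#'
#' @param tau2 rotational correlation time.
#' @param delta_g2 g-anisotropy `Delta g^2` (> 0).
#' @param tau2_unit unit of `tau2`: `"ps"` (default) or `"ns"`.
#' @return Relaxation time T in ns.
#' @export
spin_relaxation_time <- function(tau2, delta_g2, tau2_unit = c("ps", "ns")) {
  tau2_unit <- match.arg(tau2_unit)
  check_number(tau2, "tau2", lower = 0, strict = TRUE)
  check_number(delta_g2, "delta_g2", lower = 0, strict = TRUE)
  tau2_ps <- if (tau2_unit == "ns") tau2 * 1000 else tau2
  9 * tau2_ps / delta_g2 / 1000
}

#' Larmor (spin-precession) timescale
#'
#' `tau_s = (|gamma_e| B / (2 pi))^(-1)`: the period of free electron-spin
#' precession in an applied magnetic field B. In the geomagnetic field
#' (50 microtesla) this is about 710 ns.
#'
#' @param B magnetic field (Tesla), > 0.
#' @return tau_s in ns.
#' @export
larmor_timescale <- function(B) {
  check_number(B, "B", lower = 0, strict = TRUE)
  2 * pi / (GAMMA_E * B) * 1e9
}

#' Radical-pair magnetosensitivity feasibility assessment
#'
#' Compares the spin-rotational relaxation time T against the spin
#' precession timescale tau_s in the applied field. When relaxation is much
#' faster than precession (`tau_s / T >> 1`) the spin correlation is lost
#' before any field effect can develop and magnetosensitivity is
#' suppressed.
#'
#' @param tau2 rotational correlation time (ps).
#' @param delta_g2 g-anisotropy.
#' @param B magnetic field (Tesla).
#' @param thresholds length-2 numeric: ratios above `thresholds[1]` are
#'   `"suppressed"`, below `thresholds[2]` `"feasible"`, otherwise
#'   `"marginal"`.
#' @return An object of class `"spin_feasibility"`: list with `tau2_ps`,
#'   `delta_g2`, `T_ns`, `B_T`, `tau_s_ns`, `ratio` (tau_s / T), `verdict`.
#' @export
feasibility_assessment <- function(tau2, delta_g2, B,
                                   thresholds = c(suppressed = 10,
                                                  feasible = 1)) {
  T_ns <- spin_relaxation_time(tau2, delta_g2)
  tau_s <- larmor_timescale(B)
  ratio <- tau_s / T_ns
  verdict <- if (ratio > thresholds[[1L]]) "suppressed"
  else if (ratio < thresholds[[2L]]) "feasible"
  else "marginal"
  structure(list(tau2_ps = tau2, delta_g2 = delta_g2, T_ns = T_ns, B_T = B,
                 tau_s_ns = tau_s, ratio = ratio, verdict = verdict),
            class = "spin_feasibility")
}

#' @export
print.spin_feasibility <- function(x, ...) {
  cat(sprintf(
    "<spin_feasibility> tau2 = %.4g ps, dg2 = %.4g -> T = %.4g ns; B = %.3g T -> tau_s = %.4g ns\n  tau_s / T = %.3g: %s\n",
    x$tau2_ps, x$delta_g2, x$T_ns, x$B_T, x$tau_s_ns, x$ratio, x$verdict))
  invisible(x)
}

#' First-order viscosity scaling of binding dynamics
#'
#' Stokes-Einstein-Debye projection: both the rotational correlation time
#' and the binding time scale linearly with the (micro-)viscosity. A
#' first-order model for asking how binding dynamics would shift in a more
#' viscous cellular environment.
#'
#' @param tau2 rotational correlation time (any unit).
#' @param t_b binding time (any unit).
#' @param factor viscosity multiplier (> 0).
#' @return list with `tau2` and `t_b` scaled.
#' @export
viscosity_scaling <- function(tau2, t_b, factor) {
  check_number(factor, "factor", lower = 0, strict = TRUE)
  list(tau2 = factor * tau2, t_b = factor * t_b)
}
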