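# Post-processing metrics: pulse amplitudes, cranio-spinal pressure
# differences, longitudinal impedance, Reynolds number.

#' Pulse amplitude of a trace
#'
#' Half the peak-to-peak excursion over the analysis window:
#' `(max - min) / 2`. Applied to pressures (mmHg) or flows (ml/s).
#'
#' @param trace Numeric vector.
#' @param times_s Optional time vector; with `window_s` it restricts the
#'   analysis window (default: whole trace).
#' @param window_s Optional length-2 window `[t0, t1]`.
#' @return The pulse amplitude.
#' @examples
#' pulse_amplitude(sin(seq(0, 2 * pi, length.out = 200))) # ~1
#' @export
pulse_amplitude <- function(trace, times_s = NULL, window_s = NULL) {
  if (length(trace) == 0L) stop("trace must be non-empty")
  if (!is.null(window_s)) {
    if (is.null(times_s)) stop("window_s requires times_s")
    keep <- times_s >= window_s[1L] & times_s <= window_s[2L]
    trace <- trace[keep]
    if (length(trace) == 0L) stop("analysis window contains no samples")
  }
  (max(trace) - min(trace)) / 2
}

#' Pointwise pressure difference between two traces
#'
#' @param P_upstream,P_downstream Aligned numeric pressure traces (mmHg).
#' @param times_s Optional time vector used to restrict the extrema to
#'   `window_s`.
#' @param window_s Optional length-2 analysis window.
#' @return A list with `dP` (the pointwise difference), `max` and `min`
#'   (extrema over the window).
#' @export
pressure_difference <- function(P_upstream, P_downstream,
                                times_s = NULL, window_s = NULL) {
  if (length(P_upstream) != length(P_downstream)) {
    stop("pressure traces are misaligned (different lengths)")
  }
  dP <- P_upstream - P_downstream
  d <- dP
  if (!is.null(window_s)) {
    if (is.null(times_s)) stop("window_s requires times_s")
    d <- dP[times_s >= window_s[1L] & times_s <= window_s[2L]]
    if (length(d) == 0L) stop("analysis window contains no samples")
  }
  list(dP = dP, max = max(d), min = min(d))
}

#' Longitudinal impedance of a conduit
#'
#' Frequency-domain obstruction-severity index: both the pressure-difference
#' and flow traces are Fourier-transformed over whole cycles, the impedance
#' modulus `|dP_k / Q_k|` is formed at the harmonics falling inside the
#' frequency band, and the band is summarised either as the mean modulus
#' (default) or as the trapezoid-free band integral `sum |Z_k| df`. Harmonics
#' whose flow magnitude falls below `q_floor` are excluded with a warning
#' (the ratio is not meaningful there).
#'
#' @param dP Pressure-difference trace (mmHg), sampled uniformly over an
#'   integer number of cycles.
#' @param Q Flow trace (ml/s) on the same grid.
#' @param dt_s Sampling interval (s).
#' @param band_Hz Length-2 frequency band, default `c(1, 8)` Hz.
#' @param method `"mean"` (default) or `"integral"`.
#' @param q_floor Flow-magnitude exclusion floor (default 1e-12 ml/s).
#' @return A list with `LI` (band summary, mmHg.s/ml), `freq_Hz`,
#'   `modulus` (per retained harmonic), and `excluded` (count).
#' @examples
#' t <- seq(0, 4 - 0.01, by = 0.01)
#' q <- sin(2 * pi * t)
#' longitudinal_impedance(5 * q, q, 0.01)$LI # 5 (pure resistor)
#' @export
longitudinal_impedance <- function(dP, Q, dt_s, band_Hz = c(1, 8),
                                   method = c("mean", "integral"),
                                   q_floor = 1e-12) {
  method <- match.arg(method)
  n <- length(dP)
  if (length(Q) != n) stop("dP and Q must share the same grid")
  if (n < 4L) stop("traces too short for spectral analysis")
  f <- seq(0, n - 1L) / (n * dt_s)
  half <- seq(2L, floor(n / 2) + 1L) # drop DC, keep up to Nyquist
  in_band <- half[f[half] >= band_Hz[1L] & f[half] <= band_Hz[2L]]
  if (length(in_band) == 0L) stop("no harmonics inside the requested band")
  dPk <- stats::fft(dP)[in_band]
  Qk <- stats::fft(Q)[in_band]
  ok <- Mod(Qk) / n >= q_floor
  if (any(!ok)) {
    warning(sprintf("%d harmonic(s) excluded: flow magnitude below floor",
                    sum(!ok)))
  }
  if (!any(ok)) stop("all harmonics in band have negligible flow")
  z <- Mod(dPk[ok] / Qk[ok])
  li <- if (method == "mean") mean(z) else sum(z) * (1 / (n * dt_s))
  list(LI = li, freq_Hz = f[in_band][ok], modulus = z, excluded = sum(!ok))
}

#' Reynolds number
#'
#' `Re = rho v D / mu` for a conduit of diameter `D` at sectional velocity
#' `v`. At the aqueduct's peak systolic velocity (0.13 m/s, 2 mm diameter)
#' this is ~259: firmly laminar.
#'
#' @param v_m_s Velocity (m/s), >= 0.
#' @param D_m Diameter (m), > 0.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(0.13, 0.002)
#' @export
reynolds_number <- function(v_m_s, D_m, fluid = fluid_properties()) {
  if (any(v_m_s < 0)) stop("velocity must be non-negative")
  if (D_m <= 0) stop("diameter must be positive")
  fluid$rho_kg_m3 * v_m_s * D_m / fluid$mu_kg_ms
}

#' Summary metrics of a simulation
#'
#' Convenience report over a simulation result: per-node mean and
#' peak-to-peak pressures, pulse amplitudes, cranio-spinal pressure
#' difference extrema, and the longitudinal impedance of the trans-foramen
#' pathway.
#'
#' @param sim A `csf_simulation` from [simulate_network()].
#' @param window_s Analysis window, default the last cardiac cycle.
#' @param period_s Cardiac period (s), default 1.
#' @param band_Hz Impedance band, default `c(1, 8)` Hz.
#' @return A list of class `csf_metrics`.
#' @export
metrics_report <- function(sim, window_s = NULL, period_s = 1,
                           band_Hz = c(1, 8)) {
  stopifnot(inherits(sim, "csf_simulation"))
  t <- sim$times_s
  if (is.null(window_s)) window_s <- c(max(t) - period_s, max(t))
  keep <- t >= window_s[1L] & t <= window_s[2L]
  dts <- unique(round(diff(t), 12))
  li <- if (length(dts) == 1L) {
    n_keep <- sum(t >= max(t) - 4 * period_s + dts[1L] / 2)
    idx <- seq(length(t) - n_keep + 1L, length(t))
    longitudinal_impedance(sim$P_IC[idx] - sim$P_SP[idx],
                           sim$Q_FM_ml_s[idx], dts[1L], band_Hz = band_Hz)
  } else {
    NULL # mixed timestep (cough refinement): spectral analysis not defined
  }
  dp <- pressure_difference(sim$P_IC, sim$P_SP, t, window_s)
  structure(list(
    mean_P_IC = mean(sim$P_IC[keep]), mean_P_SP = mean(sim$P_SP[keep]),
    pp_P_IC = diff(range(sim$P_IC[keep])), pp_P_SP = diff(range(sim$P_SP[keep])),
    pulse_amplitude_IC = pulse_amplitude(sim$P_IC, t, window_s),
    pulse_amplitude_SP = pulse_amplitude(sim$P_SP, t, window_s),
    peak_dP_pos = dp$max, peak_dP_neg = dp$min,
    LI_mmHg_s_ml = if (is.null(li)) NA_real_ else li$LI,
    window_s = window_s
  ), class = "csf_metrics")
}

#' @export
print.csf_metrics <- function(x, ...) {
  cat("<csf_metrics>\n")
  cat(sprintf("  mean P: IC %.3f / SP %.3f mmHg\n", x$mean_P_IC, x$mean_P_SP))
  cat(sprintf("  pulse amplitude: IC %.3f / SP %.3f mmHg\n",
              x$pulse_amplitude_IC, x$pulse_amplitude_SP))
  cat(sprintf("  dP extrema: [%.3f, %.3f] mmHg\n", x$peak_dP_neg, x$peak_dP_pos))
  cat(sprintf("  longitudinal impedance: %.4g mmHg.s/ml\n", x$LI_mmHg_s_ml))
  invisible(x)
}
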