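#' Periodic volumetric flow waveform
#'
#' Container for a uniformly sampled volumetric flow curve over one cardiac
#' cycle. Times span `[0, period_s)`; flows are in ml/s with the caudal /
#' ventral direction positive (cranial / dorsal negative).
#'
#' @param times_s Numeric vector of sample times in seconds, uniformly spaced,
#'   starting at 0 and strictly inside one period.
#' @param flows_ml_s Numeric vector of flows (ml/s), same length as `times_s`.
#' @param period_s Cycle duration in seconds. Defaults to `n * dt`, the span
#'   implied by the uniform grid.
#'
#' @return An object of class `flow_waveform`: a list with elements
#'   `times_s`, `flows_ml_s`, `period_s`.
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' wf <- flow_waveform(t, sin(2 * pi * t))
#' mean(wf$flows_ml_s)
#' @export
flow_waveform <- function(times_s, flows_ml_s, period_s = NULL) {
  times_s <- as.numeric(times_s)
  flows_ml_s <- as.numeric(flows_ml_s)
  n <- length(times_s)
  if (n < 2L) stop("a flow_waveform needs at least 2 samples")
  if (length(flows_ml_s) != n) {
    stop("times_s and flows_ml_s must have the same length")
  }
  if (any(!is.finite(times_s)) || any(!is.finite(flows_ml_s))) {
    stop("flow_waveform arrays must be finite")
  }
  dt <- diff(times_s)
  if (any(dt <= 0)) stop("times_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-10 * max(dt)) {
    stop("times_s must be uniformly spaced")
  }
  if (abs(times_s[1L]) > 1e-12) stop("times_s must start at 0")
  if (is.null(period_s)) period_s <- n * dt[1L]
  if (period_s <= 0) stop("period_s must be positive")
  if (times_s[n] >= period_s) stop("times_s must lie inside [0, period_s)")
  structure(
    list(times_s = times_s, flows_ml_s = flows_ml_s, period_s = period_s),
    class = "flow_waveform"
  )
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %d samples over %.4g s; mean %.4g, range [%.4g, %.4g] ml/s\n",
    length(x$times_s), x$period_s, mean(x$flows_ml_s),
    min(x$flows_ml_s), max(x$flows_ml_s)
  ))
  invisible(x)
}

#' @export
as.data.frame.flow_waveform <- function(x, ...) {
  data.frame(time_s = x$times_s, flow_ml_s = x$flows_ml_s)
}

#' Periodic interpolator for a flow waveform
#'
#' Returns a function of time (s) that evaluates the waveform with periodic
#' extension, using monotone cubic Hermite interpolation between samples.
#'
#' @param wf A [flow_waveform()].
#' @return A vectorised function `f(t)` in ml/s.
#' @export
waveform_function <- function(wf) {
  stopifnot(inherits(wf, "flow_waveform"))
  t_closed <- c(wf$times_s, wf$period_s)
  y_closed <- c(wf$flows_ml_s, wf$flows_ml_s[1L])
  f <- stats::splinefun(t_closed, y_closed, method = "monoH.FC")
  period <- wf$period_s
  function(t) f(t %% period)
}

#' Geometric configuration of the craniospinal model
#'
#' Areas and volumes used to turn measured flows into boundary signals.
#' `A_lv_m2` is back-solved from the production-velocity relation
#' (0.4 ml/min over the patch giving 1.14e-5 m/s); `V_spinal_m3` is
#' back-solved so the default cough source peaks at 50.46 ml/s. `V_basilar_m3`
#' and `A_canal_m2` are order-of-magnitude configuration values, not measured
#' claims.
#'
#' @param A_lv_m2 Inlet patch area on the lateral ventricles (m^2).
#' @param V_basilar_m3 Volume of the CSF region anterior to the brainstem (m^3).
#' @param V_spinal_m3 Volume of the spinal source compartment (m^3).
#' @param A_canal_m2 Spinal-canal cross-section at the porous disc (m^2).
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(A_lv_m2 = 5.85e-4,
                            V_basilar_m3 = 1e-5,
                            V_spinal_m3 = 5.575625e-6,
                            A_canal_m2 = 1.5e-4) {
  vals <- c(A_lv_m2, V_basilar_m3, V_spinal_m3, A_canal_m2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry values must be strictly positive")
  }
  structure(
    list(A_lv_m2 = A_lv_m2, V_basilar_m3 = V_basilar_m3,
         V_spinal_m3 = V_spinal_m3, A_canal_m2 = A_canal_m2),
    class = "geometry_config"
  )
}

#' CSF fluid properties
#'
#' CSF is modelled as water at body temperature: density 998.2 kg/m^3,
#' dynamic viscosity 0.001003 kg/(m.s).
#'
#' @param rho_kg_m3 Density (kg/m^3).
#' @param mu_kg_ms Dynamic viscosity (kg/(m.s)).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho_kg_m3 = 998.2, mu_kg_ms = 0.001003) {
  if (!is.finite(rho_kg_m3) || rho_kg_m3 <= 0) stop("rho must be positive")
  if (!is.finite(mu_kg_ms) || mu_kg_ms <= 0) stop("mu must be positive")
  structure(list(rho_kg_m3 = rho_kg_m3, mu_kg_ms = mu_kg_ms),
            class = "fluid_properties")
}

#' Preprocess a raw cardiac-gated PC-MRI flow series
#'
#' Applies the standard preprocessing chain to a raw cardiac-gated series
#' (typically 30 samples per cycle): the time axis is rescaled to a one-second
#' beat, the series is closed periodically (equal flow at 0 s and 1 s) and
#' interpolated with a monotone piecewise-cubic Hermite polynomial (PCHIP) to
#' `target_n` points, smoothed with a centred moving average of odd width
#' applied with periodic wrap, and finally mean-subtracted so the net flow per
#' cycle is zero (CSF production is below the PC-MRI detection level, so the
#' measured cycle must balance).
#'
#' @param raw Numeric vector of raw flow samples (ml/s) over one cycle,
#'   assumed uniformly spaced; at least 8 samples.
#' @param target_n Number of output samples per cycle (default 100).
#' @param ma_width Width of the moving-average filter; must be odd (default 7).
#' @return A [flow_waveform()] with `target_n` samples on a 1 s beat,
#'   zero-mean to numerical precision.
#' @examples
#' raw <- sin(2 * pi * (0:29) / 30) + 0.3
#' wf <- preprocess_pcmri(raw)
#' abs(mean(wf$flows_ml_s)) < 1e-10
#' @export
preprocess_pcmri <- function(raw, target_n = 100L, ma_width = 7L) {
  raw <- as.numeric(raw)
  n <- length(raw)
  if (n < 8L) stop("raw series must have at least 8 samples")
  if (any(!is.finite(raw))) stop("raw series must be finite")
  target_n <- as.integer(target_n)
  ma_width <- as.integer(ma_width)
  if (target_n < n) stop("target_n must be at least the raw sample count")
  if (ma_width < 1L || ma_width %% 2L == 0L) {
    stop("ma_width must be a positive odd integer (no symmetric centre otherwise)")
  }
  # rescale to a 1 s beat and close the cycle: flow at t = 1 equals flow at 0
  t_raw <- seq(0, 1, length.out = n + 1L)
  f <- stats::splinefun(t_raw, c(raw, raw[1L]), method = "monoH.FC")
  tt <- seq(0L, target_n - 1L) / target_n
  y <- f(tt)
  if (ma_width > 1L) {
    y <- as.numeric(stats::filter(y, rep(1 / ma_width, ma_width),
                                  sides = 2, circular = TRUE))
  }
  y <- y - mean(y)
  flow_waveform(tt, y, period_s = 1)
}

#' CSF production velocity at the ventricular inlet
#'
#' Converts a volumetric CSF production rate (choroid plexus, nominally
#' 0.4 ml/min, i.e. 576 ml/day) into the constant inlet velocity imposed on
#' the lateral-ventricle patch: `v = Q / A_lv`.
#'
#' @param rate_ml_min Production rate in ml/min (default 0.4).
#' @param geom A [geometry_config()].
#' @return Velocity in m/s.
#' @examples
#' production_velocity() # ~1.14e-5 m/s
#' @export
production_velocity <- function(rate_ml_min = 0.4, geom = geometry_config()) {
  if (!is.finite(rate_ml_min) || rate_ml_min < 0) {
    stop("rate_ml_min must be non-negative")
  }
  (rate_ml_min / 60) * 1e-6 / geom$A_lv_m2
}

#' Ventricular inlet velocity waveform
#'
#' By conservation of mass the instantaneous inflow at the lateral ventricles
#' equals the flow through the cerebral aqueduct, so the imposed inlet
#' velocity is `v_lv(t) = Q_aq(t) / A_lv`, pointwise.
#'
#' @param q_aq Preprocessed aqueduct [flow_waveform()] (zero mean).
#' @param geom A [geometry_config()].
#' @return A list with `times_s` and `velocity_m_s`.
#' @export
derive_lv_velocity <- function(q_aq, geom = geometry_config()) {
  stopifnot(inherits(q_aq, "flow_waveform"))
  list(times_s = q_aq$times_s,
       velocity_m_s = q_aq$flows_ml_s * 1e-6 / geom$A_lv_m2)
}

#' Basilar volumetric source term
#'
#' The spinal SAS flow reflects both the aqueductal flow and the arterial
#' volume changes near the basilar artery, with 2/3 of the basilar-driven flow
#' directed spinally (the compliance split of 1/3 intracranial : 2/3 spinal):
#' `Q_sas = (2/3) (Q_basilar + Q_aq)`. Inverting gives the volumetric mass
#' source imposed anterior to the brainstem,
#' `S_basilar(t) = ((3/2) Q_sas(t) - Q_aq(t)) / V_basilar * rho`.
#'
#' @param q_sas,q_aq Preprocessed [flow_waveform()]s on the same time grid.
#' @param geom A [geometry_config()].
#' @param fluid A [fluid_properties()].
#' @return A list with `source_kg_m3_s` (numeric vector on the shared grid)
#'   and `q_basilar` (a [flow_waveform()] of `(3/2) Q_sas - Q_aq` in ml/s).
#' @export
derive_basilar_source <- function(q_sas, q_aq, geom = geometry_config(),
                                  fluid = fluid_properties()) {
  stopifnot(inherits(q_sas, "flow_waveform"), inherits(q_aq, "flow_waveform"))
  if (length(q_sas$times_s) != length(q_aq$times_s) ||
      max(abs(q_sas$times_s - q_aq$times_s)) > 1e-12 ||
      abs(q_sas$period_s - q_aq$period_s) > 1e-12) {
    stop("q_sas and q_aq must share the same time grid")
  }
  q_bas <- 1.5 * q_sas$flows_ml_s - q_aq$flows_ml_s # ml/s
  s <- q_bas * 1e-6 / geom$V_basilar_m3 * fluid$rho_kg_m3
  list(
    source_kg_m3_s = s,
    q_basilar = flow_waveform(q_sas$times_s, q_bas, q_sas$period_s)
  )
}
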