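# Synthetic cardiac-gated waveform generator. The shape is a truncated
# Fourier series: downstream processing only needs periodicity, a dominant
# systolic caudal peak with diastolic reversal, and a nonzero offset, and a
# Fourier ground truth is exactly recoverable by FFT in tests.

#' Parameters for a synthetic cardiac-gated flow waveform
#'
#' Describes a PC-MRI-like volumetric flow series over one cardiac cycle as a
#' truncated Fourier series plus constant offset and optional i.i.d. Gaussian
#' sampling noise:
#' `Q(t_k) = offset + sum_h a_h sin(2 pi h t_k / T + phi_h) + eps_k`.
#'
#' Default phases place the systolic caudal peak at 15% of the cycle
#' (R-wave-gated acquisitions show peak CSF flow early in the cycle) with a
#' diastolic reversal.
#'
#' @param period_s Cardiac period in seconds (default 1).
#' @param n_samples Samples per cycle (default 30, the usual retrospective
#'   gating resolution); at least 8.
#' @param harmonic_amplitudes Amplitudes a_h in ml/s, one per harmonic.
#' @param harmonic_phases Phases phi_h in radians, same length.
#' @param offset_ml_s Constant bias in ml/s (PC-MRI baseline offset plus any
#'   net flow below detection).
#' @param noise_sd_ml_s Standard deviation of Gaussian sampling noise (ml/s).
#' @param seed Optional integer seed; with a seed the series is reproducible
#'   bit for bit.
#' @return An object of class `cardiac_waveform_params`.
#' @seealso [generate_cardiac_waveforms()]
#' @export
cardiac_waveform_params <- function(period_s = 1,
                                    n_samples = 30L,
                                    harmonic_amplitudes = c(0.30, 0.08, 0.03),
                                    harmonic_phases =
                                      pi / 2 - 2 * pi * seq_along(harmonic_amplitudes) * 0.15,
                                    offset_ml_s = 0.007,
                                    noise_sd_ml_s = 0,
                                    seed = NULL) {
  if (!is.finite(period_s) || period_s <= 0) stop("period_s must be positive")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 8L) stop("n_samples must be at least 8")
  if (length(harmonic_phases) != length(harmonic_amplitudes)) {
    stop("harmonic_phases must match harmonic_amplitudes in length")
  }
  if (!is.finite(noise_sd_ml_s) || noise_sd_ml_s < 0) {
    stop("noise_sd_ml_s must be non-negative")
  }
  if (any(harmonic_amplitudes < 0)) stop("harmonic amplitudes must be >= 0")
  if (length(harmonic_amplitudes) >= n_samples / 2) {
    stop("harmonic count must stay below the Nyquist limit of the grid")
  }
  structure(
    list(period_s = period_s, n_samples = n_samples,
         harmonic_amplitudes = as.numeric(harmonic_amplitudes),
         harmonic_phases = as.numeric(harmonic_phases),
         offset_ml_s = offset_ml_s, noise_sd_ml_s = noise_sd_ml_s,
         seed = seed),
    class = "cardiac_waveform_params"
  )
}

#' Default parameters for the spinal SAS measurement plane
#'
#' The fundamental amplitude (2.46 ml/s) is sized so that the pulsatile
#' volume excursion of the derived 0D inflow `(3/2) Q_sas` is about 1.2 ml
#' per cycle, which puts the calibrated total compliance near the
#' 0.2965 ml/mmHg scale at a 4 mmHg pulse pressure; the positive-lobe stroke
#' volume is then about 0.8 ml. These are order-of-magnitude choices for a
#' plausible subject, not a reproduction of any measured curve.
#'
#' @inheritParams cardiac_waveform_params
#' @param ... Passed on to [cardiac_waveform_params()].
#' @return A `cardiac_waveform_params` object.
#' @export
sas_waveform_params <- function(harmonic_amplitudes = c(2.46, 0.62, 0.20),
                                offset_ml_s = 0.05, ...) {
  cardiac_waveform_params(harmonic_amplitudes = harmonic_amplitudes,
                          offset_ml_s = offset_ml_s, ...)
}

.eval_fourier <- function(params, t) {
  q <- rep(params$offset_ml_s, length(t))
  for (h in seq_along(params$harmonic_amplitudes)) {
    q <- q + params$harmonic_amplitudes[h] *
      sin(2 * pi * h * t / params$period_s + params$harmonic_phases[h])
  }
  q
}

.generate_one <- function(params) {
  t <- (seq_len(params$n_samples) - 1L) * params$period_s / params$n_samples
  q <- .eval_fourier(params, t)
  if (params$noise_sd_ml_s > 0) {
    q <- q + stats::rnorm(params$n_samples, sd = params$noise_sd_ml_s)
  }
  list(times_s = t, flows_ml_s = q)
}

#' Generate synthetic aqueduct and spinal-SAS flow series
#'
#' Produces a pair of raw cardiac-gated flow series (positive = caudal) for
#' the two measurement planes, together with the exact ground truth used to
#' build them, so recovery can be asserted downstream. Defaults give an
#' aqueduct systolic peak of ~0.4 ml/s and a SAS stroke volume of ~0.8 ml.
#'
#' @param params_aq Parameters for the cerebral-aqueduct plane
#'   ([cardiac_waveform_params()] defaults).
#' @param params_sas Parameters for the spinal SAS plane at vertebral level C2
#'   ([sas_waveform_params()] defaults).
#' @param seed Optional integer seed applied before any noise is drawn;
#'   overrides per-plane seeds.
#' @return A list of class `csf_synth` with `raw_aq`, `raw_sas` (numeric
#'   vectors, ml/s), `times_aq_s`, `times_sas_s`, and `truth` (both parameter
#'   sets).
#' @examples
#' syn <- generate_cardiac_waveforms(seed = 1)
#' range(syn$raw_aq)
#' @export
generate_cardiac_waveforms <- function(params_aq = cardiac_waveform_params(),
                                       params_sas = sas_waveform_params(),
                                       seed = NULL) {
  stopifnot(inherits(params_aq, "cardiac_waveform_params"),
            inherits(params_sas, "cardiac_waveform_params"))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  } else if (!is.null(params_aq$seed)) {
    set.seed(as.integer(params_aq$seed))
  }
  aq <- .generate_one(params_aq)
  if (is.null(seed) && !is.null(params_sas$seed)) {
    set.seed(as.integer(params_sas$seed))
  }
  sas <- .generate_one(params_sas)
  structure(
    list(raw_aq = aq$flows_ml_s, raw_sas = sas$flows_ml_s,
         times_aq_s = aq$times_s, times_sas_s = sas$times_s,
         truth = list(aq = params_aq, sas = params_sas)),
    class = "csf_synth"
  )
}

#' Synthetic cough volumetric inflow
#'
#' Evaluates the cough source term (see [cough_source()]) as a volumetric
#' inflow `Q(t) = S_cough(t) V_spinal / rho` on a supplied time grid. With the
#' default [cough_spec()] the peak inflow is 50.46 ml/s.
#'
#' @param spec A [cough_spec()].
#' @param t_grid Non-empty, non-decreasing time grid in seconds (covering the
#'   cough, e.g. `[0, 4]` s).
#' @return Numeric vector of inflows (ml/s) on `t_grid`.
#' @export
generate_cough_inflow <- function(spec = cough_spec(), t_grid) {
  if (length(t_grid) == 0L) stop("t_grid must be non-empty")
  if (any(diff(t_grid) < 0)) stop("t_grid must be non-decreasing")
  cough_inflow(t_grid, spec)
}
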