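# Resistive and 2-element windkessel outlets, the single-node 0D model,
# and the calibration routines (compliance, cough amplitude).

#' Outlet boundary-condition specification
#'
#' CSF leaves the model through four outlets: absorption through the
#' interstitium and spinal pathways (2-element windkessel: resistance plus
#' buffering compliance) and through the lymphatics and arachnoid villi (pure
#' resistors). A resistive outlet obeys `Q = (P - P_ext)/R`; a windkessel
#' outlet obeys `Q = (P - P_ext)/R + C dP/dt`.
#'
#' @param name Outlet label: `"interstitium"`, `"spinal"`, `"lymphatic"`,
#'   `"arachnoid_villi"` or `"custom"`.
#' @param kind `"resistive"` or `"windkessel2"`.
#' @param R Resistance in mmHg.s/ml, > 0.
#' @param C Compliance in ml/mmHg; must be 0 for resistive outlets.
#' @param P_ext Downstream (external) pressure in mmHg, default 0.
#' @return An object of class `outlet_spec`.
#' @export
outlet_spec <- function(name = c("interstitium", "spinal", "lymphatic",
                                 "arachnoid_villi", "custom"),
                        kind = c("resistive", "windkessel2"),
                        R, C = 0, P_ext = 0) {
  name <- match.arg(name)
  kind <- match.arg(kind)
  if (!is.finite(R) || R <= 0) stop("R must be strictly positive")
  if (!is.finite(C) || C < 0) stop("C must be non-negative")
  if (kind == "resistive" && C != 0) {
    stop("a resistive outlet must have C = 0")
  }
  structure(list(name = name, kind = kind, R = R, C = C, P_ext = P_ext),
            class = "outlet_spec")
}

#' Default outlet set
#'
#' The four outlets with their calibrated parameters: resistances 7500
#' (interstitium), 7500 (spinal), 5000 (lymphatic) and 5000 (arachnoid villi)
#' mmHg.s/ml; windkessel compliances 0.0988 (interstitium) and 0.1977
#' (spinal) ml/mmHg, the 1:2 intracranial:spinal buffering split.
#'
#' @return A named list of [outlet_spec()] objects.
#' @examples
#' sapply(default_outlets(), function(o) o$R)
#' @export
default_outlets <- function() {
  list(
    interstitium = outlet_spec("interstitium", "windkessel2", R = 7500, C = 0.0988),
    spinal = outlet_spec("spinal", "windkessel2", R = 7500, C = 0.1977),
    lymphatic = outlet_spec("lymphatic", "resistive", R = 5000),
    arachnoid_villi = outlet_spec("arachnoid_villi", "resistive", R = 5000)
  )
}

#' Calibration targets for the 0D model
#'
#' @param P_mean_mmHg Target mean intracranial pressure (default 10 mmHg,
#'   inside the physiological 7-15 mmHg range).
#' @param dP_pp_mmHg Target peak-to-peak pressure pulse (default 4 mmHg).
#' @param tol_pp_mmHg Maximum deviation of the achieved peak-to-peak pressure
#'   from target (default 0.01 mmHg).
#' @param compliance_split Length-2 ratio of intracranial (interstitium) to
#'   spinal compliance, default `c(1, 2)`.
#' @return An object of class `calibration_target`.
#' @export
calibration_target <- function(P_mean_mmHg = 10, dP_pp_mmHg = 4,
                               tol_pp_mmHg = 0.01, compliance_split = c(1, 2)) {
  if (P_mean_mmHg <= 0 || dP_pp_mmHg <= 0 || tol_pp_mmHg <= 0) {
    stop("calibration targets must be positive")
  }
  if (tol_pp_mmHg >= dP_pp_mmHg) stop("tol_pp must be smaller than dP_pp")
  if (length(compliance_split) != 2L || any(compliance_split <= 0)) {
    stop("compliance_split must be two positive numbers")
  }
  structure(
    list(P_mean_mmHg = P_mean_mmHg, dP_pp_mmHg = dP_pp_mmHg,
         tol_pp_mmHg = tol_pp_mmHg, compliance_split = compliance_split),
    class = "calibration_target"
  )
}

#' One implicit windkessel step
#'
#' Backward-Euler discretisation of the 2-element windkessel law: given the
#' outflow `Q_n` at the new time level and the previous outlet pressure,
#'
#' `P_n = (Q_n R + P_prev C R / dt) / (1 + C R / dt) + P_ext-terms`
#'
#' For `C = 0` this reduces to the resistive law `P = Q R + P_ext`; for
#' `dt -> Inf` the compliance term vanishes and the same resistive limit is
#' recovered.
#'
#' @param spec An [outlet_spec()].
#' @param Q_n Outward flow at the new time level (ml/s).
#' @param P_prev Outlet pressure at the previous time level (mmHg).
#' @param dt Timestep (s), > 0.
#' @return New outlet pressure `P_n` (mmHg).
#' @examples
#' step_windkessel(outlet_spec("lymphatic", "resistive", R = 5000), 0.002, 10, 0.01)
#' @export
step_windkessel <- function(spec, Q_n, P_prev, dt) {
  stopifnot(inherits(spec, "outlet_spec"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be strictly positive")
  a <- spec$C * spec$R / dt
  (Q_n * spec$R + (P_prev - spec$P_ext) * a) / (1 + a) + spec$P_ext
}

#' Steady mean pressure of a single-node outlet network
#'
#' At steady state the compliances carry no flow, so the node pressure is set
#' by the parallel resistance: `P = Q_in / sum(1/R_i) + P_ext` (for a common
#' external pressure; mixed `P_ext` values are combined conductance-weighted).
#' With the four default outlets (parallel resistance 1500 mmHg.s/ml) and the
#' production rate 0.4 ml/min this gives the 10 mmHg target mean.
#'
#' @param outlets List of [outlet_spec()]s sharing one node.
#' @param Q_in Constant inflow (ml/s), >= 0.
#' @return Node pressure in mmHg.
#' @examples
#' steady_mean_pressure(default_outlets(), 0.4 / 60) # 10 mmHg
#' @export
steady_mean_pressure <- function(outlets, Q_in) {
  if (length(outlets) == 0L) stop("outlet list must not be empty")
  stopifnot(all(vapply(outlets, inherits, logical(1), "outlet_spec")))
  if (!is.finite(Q_in) || Q_in < 0) stop("Q_in must be non-negative")
  g <- vapply(outlets, function(o) 1 / o$R, numeric(1))
  pe <- vapply(outlets, function(o) o$P_ext, numeric(1))
  (Q_in + sum(pe * g)) / sum(g)
}

# time grid with an optional refined window (e.g. dt 0.01 s refined to
# 0.001 s during the cough); returns step end-times, excluding t = 0
.time_grid <- function(duration_s, dt_s, dt_fine_s = NULL, fine_window_s = NULL) {
  if (duration_s <= 0 || dt_s <= 0) stop("duration and dt must be positive")
  if (is.null(dt_fine_s) || is.null(fine_window_s)) {
    return(seq(dt_s, duration_s, by = dt_s))
  }
  if (dt_fine_s > dt_s) stop("dt_fine_s must not exceed dt_s")
  w0 <- max(fine_window_s[1L], 0)
  w1 <- min(fine_window_s[2L], duration_s)
  if (w1 <= w0) stop("fine window must lie inside the run and be non-empty")
  t1 <- if (w0 > 0) seq(dt_s, w0, by = dt_s) else numeric(0)
  t2 <- seq(w0 + dt_fine_s, w1, by = dt_fine_s)
  t3 <- if (w1 < duration_s) seq(w1 + dt_s, duration_s, by = dt_s) else numeric(0)
  c(t1, t2, t3)
}

.as_inflow_function <- function(inflow) {
  if (is.function(inflow)) return(inflow)
  if (inherits(inflow, "flow_waveform")) return(waveform_function(inflow))
  if (is.numeric(inflow) && length(inflow) == 1L) {
    return(function(t) rep(inflow, length(t)))
  }
  stop("inflow must be a function of time, a flow_waveform, or a scalar")
}

#' Build a total-inflow function for the single-node 0D model
#'
#' The 0D inflow combines constant CSF production with the pulsatile arterial
#' inflow. Since the ventricular inflow equals the aqueductal flow and the
#' basilar source contributes `(3/2) Q_sas - Q_aq`, the total pulsatile
#' inflow reduces to `(3/2) Q_sas(t)`.
#'
#' @param q_sas Preprocessed spinal-SAS [flow_waveform()] (or `NULL` for
#'   production only).
#' @param production_ml_s Constant production inflow (ml/s), default
#'   0.4 ml/min.
#' @param cough Optional function of time giving an additional inflow (ml/s),
#'   e.g. a scaled [cough_inflow()].
#' @return A function `Q(t)` in ml/s.
#' @export
node_inflow <- function(q_sas = NULL, production_ml_s = 0.4 / 60, cough = NULL) {
  puls <- if (is.null(q_sas)) {
    function(t) rep(0, length(t))
  } else {
    f <- waveform_function(q_sas)
    function(t) 1.5 * f(t)
  }
  function(t) {
    q <- production_ml_s + puls(t)
    if (!is.null(cough)) q <- q + cough(t)
    q
  }
}

#' Run the single-node 0D windkessel model
#'
#' All outlets share one pressure node. Because every discretised outlet law
#' is linear in the new nodal pressure, the implicit balance
#' `Q_in(t_n) = sum_i Q_i(P_n)` is solved in closed form each step:
#'
#' `P_n = (Q_in + sum C_i/dt P_{n-1} + sum P_ext,i/R_i) / (sum 1/R_i + sum C_i/dt)`
#'
#' @param outlets List of [outlet_spec()]s.
#' @param inflow Total inflow: a function of time (ml/s), a
#'   [flow_waveform()] (extended periodically), or a scalar.
#' @param duration_s Run length (s).
#' @param dt_s Timestep (s), default 0.01.
#' @param P_init Initial nodal pressure (mmHg), default 10 (the target mean).
#' @param dt_fine_s,fine_window_s Optional refined timestep and its window
#'   (e.g. 0.001 s during a cough).
#' @return An object of class `csf_trace`: list with `times_s` (including
#'   t = 0), `P_mmHg`, `Q_in_ml_s`, and `Q_out_ml_s` (matrix, one column per
#'   outlet).
#' @examples
#' tr <- run_single_node_0d(default_outlets(), 0.4 / 60, duration_s = 2)
#' tail(tr$P_mmHg, 1)
#' @export
run_single_node_0d <- function(outlets, inflow, duration_s, dt_s = 0.01,
                               P_init = 10, dt_fine_s = NULL,
                               fine_window_s = NULL) {
  stopifnot(length(outlets) > 0,
            all(vapply(outlets, inherits, logical(1), "outlet_spec")))
  qfun <- .as_inflow_function(inflow)
  tg <- .time_grid(duration_s, dt_s, dt_fine_s, fine_window_s)
  nt <- length(tg)
  g <- vapply(outlets, function(o) 1 / o$R, numeric(1))
  cc <- vapply(outlets, function(o) o$C, numeric(1))
  pe <- vapply(outlets, function(o) o$P_ext, numeric(1))
  P <- numeric(nt + 1L)
  Qin <- numeric(nt + 1L)
  Qout <- matrix(0, nt + 1L, length(outlets),
                 dimnames = list(NULL, names(outlets)))
  P[1L] <- P_init
  Qin[1L] <- qfun(0)
  Qout[1L, ] <- (P_init - pe) * g
  t_prev <- 0
  for (k in seq_len(nt)) {
    dt <- tg[k] - t_prev
    q <- qfun(tg[k])
    p_new <- (q + sum(cc) / dt * P[k] + sum(pe * g)) / (sum(g) + sum(cc) / dt)
    if (!is.finite(p_new)) {
      stop(sprintf("0D solve diverged (non-finite pressure) at step %d, t = %.4f s",
                   k, tg[k]))
    }
    P[k + 1L] <- p_new
    Qin[k + 1L] <- q
    Qout[k + 1L, ] <- (p_new - pe) * g + cc * (p_new - P[k]) / dt
    t_prev <- tg[k]
  }
  structure(
    list(times_s = c(0, tg), P_mmHg = P, Q_in_ml_s = Qin, Q_out_ml_s = Qout,
         outlets = outlets),
    class = "csf_trace"
  )
}

#' @export
print.csf_trace <- function(x, ...) {
  cat(sprintf(
    "<csf_trace> %d steps over %.3g s; P in [%.3f, %.3f] mmHg (mean %.3f)\n",
    length(x$times_s) - 1L, max(x$times_s), min(x$P_mmHg), max(x$P_mmHg),
    mean(x$P_mmHg)
  ))
  invisible(x)
}

# indices of the last full cycle of a trace (used for calibration / metrics)
.last_cycle <- function(times, period) {
  t_end <- max(times)
  which(times >= t_end - period - 1e-12 & times <= t_end + 1e-12)
}

#' Calibrate windkessel compliances to a target pulse pressure
#'
#' Scales the total compliance, split between the interstitium and spinal
#' windkessels in the target's ratio (default 1:2), until the peak-to-peak
#' nodal pressure over the last of `n_cycles` simulated cardiac cycles
#' matches the target pulse pressure within its tolerance. The peak-to-peak
#' pressure is monotone decreasing in the total compliance, so the root is
#' bracketed by bound expansion and then bisected.
#'
#' @param outlets List of [outlet_spec()]s (the windkessel members are
#'   rescaled; resistances are kept).
#' @param inflow Total inflow as in [run_single_node_0d()]; must have
#'   pulsatile content, otherwise calibration fails.
#' @param target A [calibration_target()].
#' @param period_s Cardiac period (s), default 1.
#' @param n_cycles Cycles simulated per evaluation (default 4).
#' @param dt_s Timestep (s), default 0.01.
#' @param max_iter Bisection iteration cap (default 200).
#' @return A list with `C_interstitium`, `C_spinal`, `C_total`,
#'   `achieved_pp`, `iterations`, and `outlets` (the updated outlet list).
#' @export
calibrate_compliances <- function(outlets, inflow,
                                  target = calibration_target(),
                                  period_s = 1, n_cycles = 4L, dt_s = 0.01,
                                  max_iter = 200L) {
  stopifnot(inherits(target, "calibration_target"))
  if (!all(c("interstitium", "spinal") %in% names(outlets))) {
    stop("outlets must contain named 'interstitium' and 'spinal' entries")
  }
  split <- target$compliance_split / sum(target$compliance_split)
  with_C <- function(C_total) {
    out <- outlets
    out$interstitium$C <- C_total * split[1L]
    out$interstitium$kind <- "windkessel2"
    out$spinal$C <- C_total * split[2L]
    out$spinal$kind <- "windkessel2"
    out
  }
  pp_of <- function(C_total) {
    tr <- run_single_node_0d(with_C(C_total), inflow,
                             duration_s = n_cycles * period_s, dt_s = dt_s,
                             P_init = target$P_mean_mmHg)
    idx <- .last_cycle(tr$times_s, period_s)
    diff(range(tr$P_mmHg[idx]))
  }
  # bracket: pp decreases with C_total; need pp(lo) >= target >= pp(hi)
  lo <- 1e-3
  hi <- 1
  n_eval <- 0L
  pp_lo <- pp_of(lo)
  if (pp_lo < target$dP_pp_mmHg) {
    for (i in 1:20) {
      lo <- lo / 4
      pp_lo <- pp_of(lo)
      n_eval <- n_eval + 1L
      if (pp_lo >= target$dP_pp_mmHg) break
    }
    if (pp_lo < target$dP_pp_mmHg) {
      stop("calibration failure: inflow pulsatility too weak to reach the ",
           "target pulse pressure at any admissible compliance")
    }
  }
  pp_hi <- pp_of(hi)
  while (pp_hi > target$dP_pp_mmHg) {
    hi <- hi * 4
    pp_hi <- pp_of(hi)
    n_eval <- n_eval + 1L
    if (hi > 1e6) stop("calibration failure: target not bracketable")
  }
  achieved <- NA_real_
  mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    achieved <- pp_of(mid)
    n_eval <- n_eval + 1L
    if (abs(achieved - target$dP_pp_mmHg) <= target$tol_pp_mmHg) break
    if (achieved > target$dP_pp_mmHg) lo <- mid else hi <- mid
    if (it == max_iter) stop("calibration failure: bisection did not converge")
  }
  list(
    C_interstitium = mid * split[1L],
    C_spinal = mid * split[2L],
    C_total = mid,
    achieved_pp = achieved,
    iterations = n_eval,
    outlets = with_C(mid)
  )
}

#' Pressure rise caused by a cough transient
#'
#' Measures the peak pressure during/after the cough against a baseline. The
#' reference against which the roughly 35 mmHg cough peak is quoted in the
#' literature is the mean intracranial pressure; in a short transient run the
#' calibration target mean (default 10 mmHg) is the faithful stand-in for it,
#' because the pre-cough cycle rides a compliance transient slightly above
#' the target. Alternative baselines are available: the mean or the minimum
#' of the cardiac cycle immediately preceding cough onset.
#'
#' @param trace A `csf_trace` from [run_single_node_0d()].
#' @param onset_s Cough onset time (s); the peak is searched from here on.
#' @param baseline `"target_mean"` (default), `"precough_cycle_mean"`, or
#'   `"precough_min"`.
#' @param target_mean_mmHg Baseline value for `"target_mean"` (default 10).
#' @param period_s Cardiac period (s), default 1.
#' @return Rise in mmHg (peak pressure minus baseline).
#' @export
cough_pressure_rise <- function(trace, onset_s,
                                baseline = c("target_mean",
                                             "precough_cycle_mean",
                                             "precough_min"),
                                target_mean_mmHg = 10, period_s = 1) {
  baseline <- match.arg(baseline)
  t <- trace$times_s
  p <- trace$P_mmHg
  peak <- max(p[t >= onset_s])
  pre <- p[t >= onset_s - period_s & t < onset_s]
  base <- switch(baseline,
    target_mean = target_mean_mmHg,
    precough_cycle_mean = mean(pre),
    precough_min = min(pre)
  )
  peak - base
}

#' Select the cough amplitude reaching a target pressure rise
#'
#' Finds the smallest scaling of a cough inflow template such that the peak
#' nodal pressure exceeds the baseline by at least `target_rise_mmHg`, with
#' the cardiac pulsation superimposed. The rise is monotone increasing in the
#' scaling, so the threshold is located by bound expansion plus bisection;
#' the returned scaling achieves a rise in
#' `[target, target + resolution of the bisection]`.
#'
#' @param outlets Calibrated [outlet_spec()] list.
#' @param cardiac_inflow Total cardiac inflow as in [run_single_node_0d()]
#'   (production plus pulsatile part, no cough).
#' @param cough_template Function of time: the unscaled cough inflow (ml/s).
#' @param target_rise_mmHg Required rise (default 35 mmHg).
#' @param baseline,target_mean_mmHg Passed to [cough_pressure_rise()].
#' @param duration_s,dt_s,dt_fine_s,fine_window_s Simulation controls;
#'   defaults 4 s, 0.01 s, 0.001 s in `[1.5, 2.5]` s.
#' @param onset_s Cough onset used for the rise measurement (default 1.5 s).
#' @param tol Relative bisection resolution on the scaling (default 1e-4).
#' @return A list with `scaling`, `achieved_rise_mmHg`, and `peak_inflow_ml_s`
#'   (the peak of the scaled template).
#' @export
select_cough_amplitude <- function(outlets, cardiac_inflow, cough_template,
                                   target_rise_mmHg = 35,
                                   baseline = "target_mean",
                                   target_mean_mmHg = 10,
                                   duration_s = 4, dt_s = 0.01,
                                   dt_fine_s = 0.001,
                                   fine_window_s = c(1.5, 2.5),
                                   onset_s = 1.5, tol = 1e-4) {
  if (target_rise_mmHg < 0) stop("target_rise_mmHg must be non-negative")
  qfun <- .as_inflow_function(cardiac_inflow)
  rise_of <- function(s) {
    tr <- run_single_node_0d(
      outlets, function(t) qfun(t) + s * cough_template(t),
      duration_s = duration_s, dt_s = dt_s, P_init = target_mean_mmHg,
      dt_fine_s = dt_fine_s, fine_window_s = fine_window_s
    )
    cough_pressure_rise(tr, onset_s, baseline = baseline,
                        target_mean_mmHg = target_mean_mmHg)
  }
  r0 <- rise_of(0)
  if (r0 >= target_rise_mmHg) {
    return(list(scaling = 0, achieved_rise_mmHg = r0, peak_inflow_ml_s = 0))
  }
  lo <- 0
  hi <- 1
  r_hi <- rise_of(hi)
  n_exp <- 0L
  while (r_hi < target_rise_mmHg) {
    if (r_hi <= r0 - 1e-9) {
      stop("non-monotone cough response; cannot select an amplitude")
    }
    lo <- hi
    hi <- hi * 2
    r_hi <- rise_of(hi)
    n_exp <- n_exp + 1L
    if (n_exp > 60L) stop("cough amplitude selection failed to bracket the target")
  }
  while (hi - lo > tol * hi) {
    mid <- 0.5 * (lo + hi)
    if (rise_of(mid) >= target_rise_mmHg) hi <- mid else lo <- mid
  }
  tt <- seq(0, duration_s, by = 1e-3)
  list(
    scaling = hi,
    achieved_rise_mmHg = rise_of(hi),
    peak_inflow_ml_s = max(hi * cough_template(tt))
  )
}
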