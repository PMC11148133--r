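# Two-compartment (intracranial / spinal) transient network: the lumped
# stand-in for the 3D CFD domain, with a monolithic exact solver and the
# semi-implicit outlet-coupling algorithm (perturbation-Jacobian
# quasi-Newton) as an alternative route to the same solution.

#' Simulation controls
#'
#' @param duration_s Run length (s), default 4 (four cardiac cycles).
#' @param dt_s Base timestep (s), default 0.01.
#' @param dt_cough_s Refined timestep used inside the cough window (s),
#'   default 0.001; must not exceed `dt_s`.
#' @param cough_window_s Length-2 window for the refined timestep, default
#'   `c(1.5, 2.5)` (the cough means 1.88/2.13 s plus ~5 sigma margins).
#' @param solver `"monolithic"` (exact 2x2 solve per step) or `"coupled"`
#'   (the outlet-coupling algorithm).
#' @param refine Logical: apply the refined timestep window (default TRUE
#'   when a cough is present; set FALSE for cough-free runs).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 4, dt_s = 0.01, dt_cough_s = 0.001,
                              cough_window_s = c(1.5, 2.5),
                              solver = c("monolithic", "coupled"),
                              refine = TRUE) {
  solver <- match.arg(solver)
  if (dt_cough_s > dt_s) stop("dt_cough_s must not exceed dt_s")
  if (length(cough_window_s) != 2L || cough_window_s[1L] >= cough_window_s[2L]) {
    stop("cough_window_s must be an increasing pair")
  }
  if (isTRUE(refine) &&
      (cough_window_s[1L] < 0 || cough_window_s[2L] > duration_s)) {
    stop("cough window must lie inside the run duration")
  }
  structure(
    list(duration_s = duration_s, dt_s = dt_s, dt_cough_s = dt_cough_s,
         cough_window_s = cough_window_s, solver = solver, refine = refine),
    class = "simulation_config"
  )
}

#' Outlet-coupling algorithm controls
#'
#' The flow solver and the windkessel outlets are coupled semi-implicitly:
#' each timestep is divided into coupling iterations; during the first
#' `jacobian_iters` iterations a Jacobian is estimated column by column from
#' finite differences, using a pressure perturbation that decreases over the
#' schedule from 1 to 1e-2 Pa (so the flow residual decreases over the
#' iterations); afterwards the Jacobian is frozen (optionally Broyden-
#' refreshed) and quasi-Newton steps are taken until the largest flow
#' residual drops below `residual_factor` times the current lymphatic
#' outflow.
#'
#' @param perturbation_Pa Decreasing positive schedule of pressure
#'   perturbations in Pa; default log-spaced from 1 to 1e-2 over
#'   `jacobian_iters` entries.
#' @param jacobian_iters Coupling iterations spent building the Jacobian
#'   (default 4).
#' @param residual_factor Convergence factor applied to the lymphatic
#'   volumetric outflow (default 1e-3).
#' @param max_coupling_iters Iteration cap per timestep (default 50).
#' @param broyden Logical; apply Broyden rank-one updates to the frozen
#'   Jacobian (default FALSE).
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(perturbation_Pa = 10^seq(0, -2, length.out = jacobian_iters),
                            jacobian_iters = 4L,
                            residual_factor = 1e-3,
                            max_coupling_iters = 50L,
                            broyden = FALSE) {
  jacobian_iters <- as.integer(jacobian_iters)
  if (jacobian_iters < 2L) stop("jacobian_iters must be at least 2")
  if (length(perturbation_Pa) == 0L || any(!is.finite(perturbation_Pa)) ||
      any(perturbation_Pa <= 0)) {
    stop("perturbation schedule must be positive (a 0 Pa perturbation is a configuration error)")
  }
  if (any(diff(perturbation_Pa) > 0)) {
    stop("perturbation schedule must be non-increasing")
  }
  if (residual_factor <= 0) stop("residual_factor must be positive")
  structure(
    list(perturbation_Pa = perturbation_Pa, jacobian_iters = jacobian_iters,
         residual_factor = residual_factor,
         max_coupling_iters = as.integer(max_coupling_iters),
         broyden = isTRUE(broyden)),
    class = "coupling_config"
  )
}

#' Build the two-compartment craniospinal network
#'
#' Lumps the CSF space into an intracranial node (IC) and a spinal node (SP)
#' joined by the trans-foramen-magnum resistance from
#' [foramen_resistance()]. The interstitium windkessel and the two resistive
#' outlets (lymphatic, arachnoid villi) attach to IC; the spinal windkessel
#' attaches to SP, reproducing the 1:2 intracranial:spinal buffering split.
#' The ventricles are not a separate node: the ventricular system carries no
#' compliance, so aqueductal flow passes straight through to IC.
#'
#' @param outlets The four named [outlet_spec()]s (see [default_outlets()]).
#' @param geom A [geometry_config()].
#' @param fluid A [fluid_properties()].
#' @param case An [obstruction_case()].
#' @param R_open Baseline open-foramen resistance (mmHg.s/ml), default 0.05.
#' @return An object of class `csf_network`.
#' @examples
#' net <- build_network(case = obstruction_case("OBS-3"))
#' net$R_FM
#' @export
build_network <- function(outlets = default_outlets(),
                          geom = geometry_config(),
                          fluid = fluid_properties(),
                          case = obstruction_case("control"),
                          R_open = 0.05) {
  needed <- c("interstitium", "spinal", "lymphatic", "arachnoid_villi")
  if (!setequal(names(outlets), needed) || anyDuplicated(names(outlets))) {
    stop("outlets must be exactly: ", paste(needed, collapse = ", "))
  }
  stopifnot(all(vapply(outlets, inherits, logical(1), "outlet_spec")))
  R_FM <- foramen_resistance(case, geom, fluid, R_open = R_open)
  if (!is.finite(R_FM) || R_FM <= 0) {
    stop("trans-foramen resistance must be strictly positive; use R_open > 0")
  }
  attach <- c(interstitium = "IC", lymphatic = "IC", arachnoid_villi = "IC",
              spinal = "SP")
  structure(
    list(outlets = outlets[needed], attach = attach, R_FM = R_FM,
         case = case, geom = geom, fluid = fluid, R_open = R_open),
    class = "csf_network"
  )
}

#' @export
print.csf_network <- function(x, ...) {
  cat(sprintf("<csf_network> case %s; R_FM = %.4g mmHg.s/ml\n",
              x$case$name, x$R_FM))
  invisible(x)
}

# per-node aggregates: conductance, compliance, P_ext-weighted conductance
.node_coeffs <- function(model) {
  nodes <- c("IC", "SP")
  g <- c(IC = 0, SP = 0)
  cc <- c(IC = 0, SP = 0)
  gpe <- c(IC = 0, SP = 0)
  for (nm in names(model$outlets)) {
    o <- model$outlets[[nm]]
    nd <- model$attach[[nm]]
    g[nd] <- g[nd] + 1 / o$R
    cc[nd] <- cc[nd] + o$C
    gpe[nd] <- gpe[nd] + o$P_ext / o$R
  }
  list(g = g, cc = cc, gpe = gpe, nodes = nodes)
}

# exact backward-Euler solve of the 2-node system for one step
.monolithic_step <- function(model, q_ic, q_sp, P_prev, dt, co = NULL) {
  if (is.null(co)) co <- .node_coeffs(model)
  k <- 1 / model$R_FM
  a1 <- co$g[["IC"]] + co$cc[["IC"]] / dt + k
  a2 <- co$g[["SP"]] + co$cc[["SP"]] / dt + k
  b1 <- q_ic + co$cc[["IC"]] / dt * P_prev[["IC"]] + co$gpe[["IC"]]
  b2 <- q_sp + co$cc[["SP"]] / dt * P_prev[["SP"]] + co$gpe[["SP"]]
  det <- a1 * a2 - k * k
  P_ic <- (b1 * a2 + b2 * k) / det
  P_sp <- (b2 * a1 + b1 * k) / det
  c(IC = P_ic, SP = P_sp)
}

# outlet flows at the new pressures (resistive + storage parts)
.outlet_flows <- function(model, P_new, P_prev, dt) {
  vapply(names(model$outlets), function(nm) {
    o <- model$outlets[[nm]]
    nd <- model$attach[[nm]]
    (P_new[[nd]] - o$P_ext) / o$R + o$C * (P_new[[nd]] - P_prev[[nd]]) / dt
  }, numeric(1))
}

#' One timestep of the outlet-coupling algorithm
#'
#' Treats the nodal flow solver as a black box whose unknowns are the outlet
#' (nodal) pressures. The residual at a proposed pressure pair is the
#' difference between the flow the domain pushes out of each node (inflows
#' minus the trans-foramen exchange at the proposed pressures) and the flow
#' the windkessel laws accept at those pressures. During the first
#' `jacobian_iters` coupling iterations the Jacobian is assembled column by
#' column from finite differences with the decreasing perturbation schedule;
#' subsequent iterations take quasi-Newton steps with the (frozen or
#' Broyden-updated) Jacobian. For this linear problem the frozen Jacobian is
#' exact, so convergence follows in one Newton step.
#'
#' @param model A [build_network()] model.
#' @param inputs_at_t List with scalar inflows `q_ic`, `q_sp` (ml/s) at the
#'   new time level.
#' @param P_prev Named numeric `c(IC =, SP =)`: pressures at the previous
#'   time level (mmHg).
#' @param dt Timestep (s).
#' @param coupling A [coupling_config()].
#' @return List with `P` (named pressures), `Q_out` (named outlet flows),
#'   `iterations`, `residual` (final max abs residual, ml/s), and
#'   `converged`.
#' @export
coupled_solve_step <- function(model, inputs_at_t, P_prev, dt,
                               coupling = coupling_config()) {
  stopifnot(inherits(model, "csf_network"), inherits(coupling, "coupling_config"))
  co <- .node_coeffs(model)
  k <- 1 / model$R_FM
  q <- c(IC = inputs_at_t$q_ic, SP = inputs_at_t$q_sp)
  lym_R <- model$outlets$lymphatic$R

  residual <- function(P) {
    dom <- c(IC = q[["IC"]] - k * (P[["IC"]] - P[["SP"]]),
             SP = q[["SP"]] + k * (P[["IC"]] - P[["SP"]]))
    wk <- c(IC = co$g[["IC"]] * P[["IC"]] - co$gpe[["IC"]] +
              co$cc[["IC"]] * (P[["IC"]] - P_prev[["IC"]]) / dt,
            SP = co$g[["SP"]] * P[["SP"]] - co$gpe[["SP"]] +
              co$cc[["SP"]] * (P[["SP"]] - P_prev[["SP"]]) / dt)
    dom - wk
  }

  sched_mmHg <- coupling$perturbation_Pa / .mmHg_Pa
  P <- P_prev
  r <- residual(P)
  J <- matrix(NA_real_, 2, 2)
  iters <- 0L
  converged <- FALSE
  tol_of <- function(P) {
    coupling$residual_factor * max(abs(P[["IC"]] / lym_R), 1e-9)
  }
  repeat {
    if (max(abs(r)) < tol_of(P)) {
      converged <- TRUE
      break
    }
    if (iters >= coupling$max_coupling_iters) break
    iters <- iters + 1L
    if (iters <= coupling$jacobian_iters) {
      # Jacobian-building iteration: perturb one unknown with the scheduled
      # amplitude, refreshing columns cyclically over the schedule
      col <- ((iters - 1L) %% 2L) + 1L
      d <- sched_mmHg[min(iters, length(sched_mmHg))]
      Pp <- P
      Pp[col] <- Pp[col] + d
      J[, col] <- (residual(Pp) - r) / d
      if (!anyNA(J)) {
        step <- tryCatch(solve(J, -r), error = function(e) NULL)
        if (!is.null(step)) P <- P + step
        r <- residual(P)
      }
    } else {
      r_old <- r
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      P <- P + step
      r <- residual(P)
      if (coupling$broyden) {
        # rank-one secant refresh: J <- J + (dr - J dp) dp^T / (dp^T dp)
        dr <- r - r_old
        J <- J + ((dr - J %*% step) %*% t(step)) / sum(step * step)
      }
    }
  }
  list(P = P, Q_out = .outlet_flows(model, P, P_prev, dt),
       iterations = iters, residual = max(abs(r)), converged = converged)
}

#' Simulate the two-compartment craniospinal network
#'
#' Semi-implicit (backward-Euler) time integration of the two-node model.
#' Each step balances, at the new time level, the nodal inflows against the
#' discretised outlet laws and the trans-foramen exchange
#' `(P_IC - P_SP) / R_FM` (positive caudal). The monolithic mode solves the
#' resulting 2x2 linear system exactly; the coupled mode reaches the same
#' solution through [coupled_solve_step()]. The timestep switches from
#' `dt_s` to `dt_cough_s` inside the cough window when `refine` is set.
#'
#' @param model A [build_network()] model.
#' @param inputs List with `q_ic` and (optionally) `q_sp`: functions of time
#'   (ml/s), [flow_waveform()]s, or scalars. `q_ic` is the intracranial
#'   inflow (production + aqueduct-driven + basilar source volume flux);
#'   `q_sp` is the spinal inflow (cough).
#' @param config A [simulation_config()].
#' @param coupling A [coupling_config()] (coupled mode only).
#' @param P_init Named or scalar initial pressure(s) (mmHg), default 10.
#' @return An object of class `csf_simulation`: list with `times_s`, `P_IC`,
#'   `P_SP` (mmHg), `Q_FM_ml_s` (trans-foramen flow, positive caudal),
#'   `Q_out_ml_s` (matrix, one column per outlet), `Q_in_IC_ml_s`,
#'   `Q_in_SP_ml_s`, `coupling_iters`, `coupling_residuals`,
#'   `n_unconverged`, plus the model and config.
#' @export
simulate_network <- function(model, inputs, config = simulation_config(),
                             coupling = coupling_config(), P_init = 10) {
  stopifnot(inherits(model, "csf_network"), inherits(config, "simulation_config"))
  q_ic <- .as_inflow_function(inputs$q_ic)
  q_sp <- if (is.null(inputs$q_sp)) function(t) rep(0, length(t)) else
    .as_inflow_function(inputs$q_sp)
  if (length(P_init) == 1L) P_init <- c(IC = unname(P_init), SP = unname(P_init))
  tg <- if (isTRUE(config$refine)) {
    .time_grid(config$duration_s, config$dt_s, config$dt_cough_s,
               config$cough_window_s)
  } else {
    .time_grid(config$duration_s, config$dt_s)
  }
  nt <- length(tg)
  co <- .node_coeffs(model)
  P_IC <- numeric(nt + 1L)
  P_SP <- numeric(nt + 1L)
  Qfm <- numeric(nt + 1L)
  Qout <- matrix(0, nt + 1L, length(model$outlets),
                 dimnames = list(NULL, names(model$outlets)))
  Qi <- numeric(nt + 1L)
  Qs <- numeric(nt + 1L)
  it_counts <- integer(nt + 1L)
  resids <- numeric(nt + 1L)
  P_IC[1L] <- P_init[["IC"]]
  P_SP[1L] <- P_init[["SP"]]
  Qfm[1L] <- (P_init[["IC"]] - P_init[["SP"]]) / model$R_FM
  Qi[1L] <- q_ic(0)
  Qs[1L] <- q_sp(0)
  n_unconv <- 0L
  P_prev <- P_init
  t_prev <- 0
  for (n in seq_len(nt)) {
    dt <- tg[n] - t_prev
    qi <- q_ic(tg[n])
    qs <- q_sp(tg[n])
    if (config$solver == "monolithic") {
      P_new <- .monolithic_step(model, qi, qs, P_prev, dt, co)
      Qout[n + 1L, ] <- .outlet_flows(model, P_new, P_prev, dt)
    } else {
      st <- coupled_solve_step(model, list(q_ic = qi, q_sp = qs), P_prev, dt,
                               coupling)
      P_new <- st$P
      Qout[n + 1L, ] <- st$Q_out
      it_counts[n + 1L] <- st$iterations
      resids[n + 1L] <- st$residual
      if (!st$converged) n_unconv <- n_unconv + 1L
    }
    if (any(!is.finite(P_new))) {
      stop(sprintf("network solve diverged at step %d, t = %.4f s", n, tg[n]))
    }
    P_IC[n + 1L] <- P_new[["IC"]]
    P_SP[n + 1L] <- P_new[["SP"]]
    Qfm[n + 1L] <- (P_new[["IC"]] - P_new[["SP"]]) / model$R_FM
    Qi[n + 1L] <- qi
    Qs[n + 1L] <- qs
    P_prev <- P_new
    t_prev <- tg[n]
  }
  if (n_unconv > 0L) {
    warning(sprintf("%d of %d coupling steps did not meet the convergence criterion",
                    n_unconv, nt))
  }
  structure(
    list(times_s = c(0, tg), P_IC = P_IC, P_SP = P_SP, Q_FM_ml_s = Qfm,
         Q_out_ml_s = Qout, Q_in_IC_ml_s = Qi, Q_in_SP_ml_s = Qs,
         coupling_iters = it_counts, coupling_residuals = resids,
         n_unconverged = n_unconv, model = model, config = config),
    class = "csf_simulation"
  )
}

#' @export
print.csf_simulation <- function(x, ...) {
  cat(sprintf(
    "<csf_simulation> case %s, %s solver, %d steps over %.3g s\n  P_IC in [%.3f, %.3f], P_SP in [%.3f, %.3f] mmHg\n",
    x$model$case$name, x$config$solver, length(x$times_s) - 1L, max(x$times_s),
    min(x$P_IC), max(x$P_IC), min(x$P_SP), max(x$P_SP)
  ))
  invisible(x)
}

#' @export
as.data.frame.csf_simulation <- function(x, ...) {
  data.frame(time_s = x$times_s, P_IC_mmHg = x$P_IC, P_SP_mmHg = x$P_SP,
             Q_FM_ml_s = x$Q_FM_ml_s, x$Q_out_ml_s,
             Q_in_IC_ml_s = x$Q_in_IC_ml_s, Q_in_SP_ml_s = x$Q_in_SP_ml_s)
}
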