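test_that("implicit windkessel step matches its closed form and limits", {
  res <- outlet_spec("lymphatic", "resistive", R = 5000)
  expect_equal(step_windkessel(res, 0.002, 10, 0.01), 10) # pure resistor

  wk <- outlet_spec("custom", "windkessel2", R = 5000, C = 0.1)
  expect_equal(step_windkessel(wk, 0.01, 10, 0.01), 500050 / 50001)

  # dt -> Inf and C -> 0 both recover the resistive law to machine precision
  expect_equal(step_windkessel(wk, 0.01, 123, 1e15), 0.01 * 5000,
               tolerance = 1e-12)
  wk0 <- outlet_spec("custom", "windkessel2", R = 5000, C = 0)
  expect_identical(step_windkessel(wk0, 0.01, 123, 0.01), 50)

  # constant flow held for t >> RC relaxes to Q R
  P <- 0
  for (i in 1:5000) P <- step_windkessel(wk, 0.002, P, 1) # 5000 s >> RC = 500 s
  expect_equal(P, 10, tolerance = 1e-4)

  expect_error(step_windkessel(wk, 0.01, 10, 0), "positive")
})

test_that("steady mean pressure is the parallel-resistance solution", {
  expect_equal(steady_mean_pressure(default_outlets(), 0.4 / 60), 10)
  one <- list(outlet_spec("custom", "resistive", R = 1234))
  expect_equal(steady_mean_pressure(one, 0.01), 12.34)
  pext <- list(outlet_spec("custom", "resistive", R = 1000, P_ext = 3))
  expect_equal(steady_mean_pressure(pext, 0), 3)
  expect_error(steady_mean_pressure(list(), 1), "empty")
})

test_that("steady pressure is invariant under splitting a resistor in two", {
  base <- list(a = outlet_spec("custom", "resistive", R = 4000),
               b = outlet_spec("custom", "resistive", R = 6000))
  split <- list(a1 = outlet_spec("custom", "resistive", R = 8000),
                a2 = outlet_spec("custom", "resistive", R = 8000),
                b = outlet_spec("custom", "resistive", R = 6000))
  q <- 0.0123
  expect_equal(steady_mean_pressure(base, q), steady_mean_pressure(split, q),
               tolerance = 1e-14)
})

test_that("single-node model holds steady states and the RC decay law", {
  out <- default_outlets()
  tr0 <- run_single_node_0d(out, 0, duration_s = 2, P_init = 0)
  expect_close(tr0$P_mmHg, rep(0, length(tr0$P_mmHg)), tol = 1e-14)

  # production only, initialised off-target, relaxes to the analytic mean
  tr <- run_single_node_0d(out, 0.4 / 60, duration_s = 3000, dt_s = 1,
                           P_init = 14)
  expect_equal(tail(tr$P_mmHg, 1), 10, tolerance = 1e-2)

  # zero inflow decay follows exp(-t / (R_parallel C_total)) with the
  # published values: tau = 1500 * 0.2965 = 444.75 s
  tau <- 1500 * (0.0988 + 0.1977)
  trd <- run_single_node_0d(out, 0, duration_s = 4, dt_s = 0.01, P_init = 10)
  expect_close(trd$P_mmHg / (10 * exp(-trd$times_s / tau)), 1, tol = 1e-3)
})

test_that("single-node runs conserve volume to 1e-6 ml", {
  syn <- synth_pair()
  out <- default_outlets()
  for (inflow in list(node_inflow(syn$q_sas),
                      node_inflow(syn$q_sas,
                                  cough = function(t) cough_inflow(t)))) {
    tr <- run_single_node_0d(out, inflow, duration_s = 4, dt_s = 0.01,
                             P_init = 10, dt_fine_s = 0.001,
                             fine_window_s = c(1.5, 2.5))
    dt <- diff(tr$times_s)
    g <- vapply(out, function(o) 1 / o$R, numeric(1))
    cc <- vapply(out, function(o) o$C, numeric(1))
    p <- tr$P_mmHg[-1]
    vin <- sum(tr$Q_in_ml_s[-1] * dt)
    vout <- sum((p * sum(g)) * dt)
    stored <- sum(cc) * (tail(tr$P_mmHg, 1) - tr$P_mmHg[1])
    expect_lte(abs(vin - vout - stored), 1e-6)
  }
})

test_that("compliance calibration hits the target pulse pressure", {
  syn <- synth_pair()
  cal <- calibrate_compliances(default_outlets(), node_inflow(syn$q_sas))
  expect_lte(abs(cal$achieved_pp - 4), 0.01)
  expect_equal(cal$C_spinal / cal$C_interstitium, 2, tolerance = 1e-12)
  expect_equal(cal$C_interstitium + cal$C_spinal, cal$C_total)
})

test_that("calibration recovers a known compliance across a grid", {
  syn <- synth_pair()
  inflow <- node_inflow(syn$q_sas)
  out <- default_outlets()
  for (C_star in c(0.05, 0.15, 0.2965, 0.6, 1.2)) {
    out$interstitium$C <- C_star / 3
    out$spinal$C <- 2 * C_star / 3
    tr <- run_single_node_0d(out, inflow, duration_s = 4, P_init = 10)
    idx <- tr$times_s >= 3
    pp_star <- diff(range(tr$P_mmHg[idx]))
    cal <- calibrate_compliances(
      default_outlets(), inflow,
      calibration_target(dP_pp_mmHg = pp_star, tol_pp_mmHg = pp_star / 500)
    )
    expect_equal(cal$C_total, C_star, tolerance = 0.01)
  }
})

test_that("calibration fails explicitly on a pulseless inflow", {
  expect_error(calibrate_compliances(default_outlets(), 0.4 / 60),
               "calibration failure")
})

test_that("cough amplitude selection satisfies its bisection contract", {
  syn <- synth_pair()
  cal <- calibrate_compliances(default_outlets(), node_inflow(syn$q_sas))
  template <- function(t) cough_inflow(t)

  zero <- select_cough_amplitude(cal$outlets, node_inflow(syn$q_sas), template,
                                 target_rise_mmHg = 0)
  expect_identical(zero$scaling, 0)

  sel <- select_cough_amplitude(cal$outlets, node_inflow(syn$q_sas), template,
                                target_rise_mmHg = 35)
  expect_gte(sel$achieved_rise_mmHg, 35)
  # smallest-scaling contract: 0.1% below the selection falls short
  tr <- run_single_node_0d(
    cal$outlets,
    function(t) node_inflow(syn$q_sas)(t) + 0.999 * sel$scaling * template(t),
    duration_s = 4, dt_s = 0.01, P_init = 10,
    dt_fine_s = 0.001, fine_window_s = c(1.5, 2.5)
  )
  expect_lt(cough_pressure_rise(tr, 1.5), 35)
  # selected peak inflow sits in the published regime (~50 ml/s)
  expect_gt(sel$peak_inflow_ml_s, 35)
  expect_lt(sel$peak_inflow_ml_s, 70)
})

test_that("outlet and target constructors validate", {
  expect_error(outlet_spec("custom", "resistive", R = 0), "positive")
  expect_error(outlet_spec("custom", "resistive", R = 100, C = 0.1), "C = 0")
  expect_error(calibration_target(tol_pp_mmHg = 5), "smaller")
})
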