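test_that("network construction wires the four outlets and the foramen", {
  net <- build_network(case = obstruction_case("control"), R_open = 0.05)
  expect_equal(net$R_FM, 0.05)
  expect_equal(unname(net$attach[c("interstitium", "spinal")]), c("IC", "SP"))

  net3 <- build_network(case = obstruction_case("OBS-3"), R_open = 0.05)
  expect_gte(net3$R_FM / net$R_FM, 100)

  out <- default_outlets()
  out$spinal <- NULL
  expect_error(build_network(out), "exactly")
})

test_that("zero inputs from a zero state stay identically zero", {
  net <- build_network()
  sim <- simulate_network(net, list(q_ic = 0, q_sp = 0),
                          simulation_config(duration_s = 1, refine = FALSE),
                          P_init = 0)
  expect_close(sim$P_IC, rep(0, length(sim$P_IC)), tol = 1e-14)
  expect_close(sim$P_SP, rep(0, length(sim$P_SP)), tol = 1e-14)
})

test_that("a cough against an open foramen peaks in both compartments alike", {
  syn <- synth_pair()
  net <- build_network(case = obstruction_case("control"))
  sim <- simulate_network(
    net,
    list(q_ic = node_inflow(syn$q_sas), q_sp = function(t) cough_inflow(t)),
    simulation_config(), P_init = 10
  )
  pk_ic <- max(sim$P_IC)
  pk_sp <- max(sim$P_SP)
  expect_lte(abs(pk_ic - pk_sp) / pk_sp, 0.05)
  # a single pressure peak: both traces crest inside the cough window
  expect_gte(sim$times_s[which.max(sim$P_IC)], 1.5)
  expect_lte(sim$times_s[which.max(sim$P_IC)], 2.5)
  expect_gt(pk_ic, 40)
})

test_that("severe obstruction decouples the compartments (amplitude shift)", {
  syn <- synth_pair()
  inputs <- list(q_ic = node_inflow(syn$q_sas))
  cfg <- simulation_config(refine = FALSE)
  amp <- function(case) {
    sim <- simulate_network(build_network(case = obstruction_case(case)),
                            inputs, cfg, P_init = 10)
    win <- c(3, 4)
    c(ic = pulse_amplitude(sim$P_IC, sim$times_s, win),
      sp = pulse_amplitude(sim$P_SP, sim$times_s, win))
  }
  a_ctl <- amp("control")
  a_obs <- amp("OBS-3")
  expect_gt(a_obs[["ic"]], a_ctl[["ic"]])
  expect_lt(a_obs[["sp"]], a_ctl[["sp"]])
})

test_that("decoupling is monotone over a four-decade foramen sweep", {
  syn <- synth_pair()
  inputs <- list(q_ic = node_inflow(syn$q_sas))
  cfg <- simulation_config(refine = FALSE)
  r_fm <- 0.05 * 10^(0:4)
  amps <- sapply(r_fm, function(r) {
    net <- build_network(R_open = r) # control case: R_FM = R_open
    sim <- simulate_network(net, inputs, cfg, P_init = 10)
    win <- c(3, 4)
    c(ic = pulse_amplitude(sim$P_IC, sim$times_s, win),
      sp = pulse_amplitude(sim$P_SP, sim$times_s, win))
  })
  # SP amplitude decays exactly monotonically; the IC amplitude trend is
  # monotone up to a ~1% overshoot of its decoupled plateau near the
  # crossover resistance (a two-node frequency-response effect)
  expect_true(all(diff(amps["sp", ]) <= 1e-12))
  expect_true(all(diff(amps["ic", ]) >= -0.02 * amps["ic", -1]))
  expect_gt(amps["ic", ncol(amps)], 2 * amps["ic", 1])
})

test_that("coupled and monolithic solvers agree to 1e-6 mmHg", {
  syn <- synth_pair()
  inputs <- list(q_ic = node_inflow(syn$q_sas),
                 q_sp = function(t) cough_inflow(t))
  net <- build_network(case = obstruction_case("OBS-2"))
  mono <- simulate_network(net, inputs, simulation_config(solver = "monolithic"),
                           P_init = 10)
  coup <- simulate_network(net, inputs, simulation_config(solver = "coupled"),
                           P_init = 10)
  expect_equal(coup$n_unconverged, 0L)
  expect_lte(max(abs(coup$P_IC - mono$P_IC)), 1e-6)
  expect_lte(max(abs(coup$P_SP - mono$P_SP)), 1e-6)
})

test_that("one coupled step converges fast and matches the exact solve", {
  net <- build_network(case = obstruction_case("OBS-1"))
  prev <- c(IC = 10.2, SP = 9.9)
  st <- coupled_solve_step(net, list(q_ic = 0.05, q_sp = -0.01), prev, 0.01)
  expect_true(st$converged)
  expect_lte(st$iterations, coupling_config()$jacobian_iters + 1L)
  exact <- csfdyn:::.monolithic_step(net, 0.05, -0.01, prev, 0.01)
  expect_lte(max(abs(st$P - exact)), 1e-6)
})

test_that("a zero pressure perturbation is a configuration error", {
  expect_error(coupling_config(perturbation_Pa = c(1, 0)), "positive")
  expect_error(coupling_config(perturbation_Pa = c(0.01, 1)), "non-increasing")
})

test_that("network runs conserve volume to 1e-6 ml", {
  syn <- synth_pair()
  net <- build_network(case = obstruction_case("OBS-2"))
  sim <- simulate_network(
    net,
    list(q_ic = node_inflow(syn$q_sas), q_sp = function(t) cough_inflow(t)),
    simulation_config(), P_init = 10
  )
  dt <- diff(sim$times_s)
  out <- net$outlets
  p_node <- cbind(IC = sim$P_IC, SP = sim$P_SP)[-1, ]
  vout <- 0
  stored <- 0
  for (nm in names(out)) {
    nd <- net$attach[[nm]]
    vout <- vout + sum((p_node[, nd] - out[[nm]]$P_ext) / out[[nm]]$R * dt)
    stored <- stored + out[[nm]]$C *
      (tail(if (nd == "IC") sim$P_IC else sim$P_SP, 1) -
         (if (nd == "IC") sim$P_IC else sim$P_SP)[1])
  }
  vin <- sum((sim$Q_in_IC_ml_s[-1] + sim$Q_in_SP_ml_s[-1]) * dt)
  expect_lte(abs(vin - vout - stored), 1e-6)
})

test_that("the nearly-open two-node model matches the merged single node", {
  syn <- synth_pair()
  inflow <- node_inflow(syn$q_sas)
  net <- build_network(R_open = 1e-7)
  sim <- simulate_network(net, list(q_ic = inflow),
                          simulation_config(refine = FALSE), P_init = 10)
  tr <- run_single_node_0d(default_outlets(), inflow, duration_s = 4,
                           dt_s = 0.01, P_init = 10)
  expect_lte(max(abs(sim$P_IC - tr$P_mmHg)), 1e-6)
  expect_lte(max(abs(sim$P_SP - tr$P_mmHg)), 1e-6)
})

test_that("halving the timestep moves peak pressures by less than 0.5%", {
  syn <- synth_pair()
  net <- build_network()
  inputs <- list(q_ic = node_inflow(syn$q_sas),
                 q_sp = function(t) cough_inflow(t))
  peaks <- function(dt) {
    sim <- simulate_network(
      net, inputs,
      simulation_config(dt_s = dt, dt_cough_s = dt / 10), P_init = 10
    )
    c(max(sim$P_IC), max(sim$P_SP))
  }
  p1 <- peaks(0.01)
  p2 <- peaks(0.005)
  expect_true(all(abs(p1 - p2) / p2 < 0.005))
})
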