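test_that("traces decay exponentially and accumulate across spikes", {
  sp <- stdp_params()
  dt <- 0.5
  ps <- init_plastic_state(2, 2)
  ps <- stdp_trace_step(ps, c(TRUE, FALSE), c(FALSE, FALSE), sp, dt)
  expect_equal(ps$A_E, c(sp$A0, 0))
  for (k in 1:30) ps <- stdp_trace_step(ps, c(FALSE, FALSE),
                                        c(FALSE, FALSE), sp, dt)
  # 15 ms = tau_STDP: e-fold, exact Euler form
  expect_equal(ps$A_E[1], sp$A0 * (1 - dt / sp$tau_STDP)^30)
  expect_equal(ps$A_E[1], sp$A0 * exp(-1), tolerance = 0.02)

  # two spikes one step apart accumulate (all-to-all rule)
  ps2 <- init_plastic_state(1, 1)
  ps2 <- stdp_trace_step(ps2, TRUE, FALSE, sp, dt)
  ps2 <- stdp_trace_step(ps2, TRUE, FALSE, sp, dt)
  expect_equal(ps2$A_E, sp$A0 * (1 - dt / sp$tau_STDP) + sp$A0)
})

test_that("isolated spike pairs follow the exponential pair rule", {
  sp <- stdp_params()
  dt <- 0.5
  # the spike-step increment lands after that step's update, so a lag of n
  # steps sees n - 1 trace decays
  euler_kernel <- function(lag) (1 - dt / sp$tau_STDP)^(round(abs(lag) / dt) - 1)
  for (lag in c(1, 5, 15, 30)) {
    # pre before post potentiates by eta * A0 * exp(-lag/tau)
    expect_equal(pair_update(lag), sp$eta * sp$A0 * euler_kernel(lag))
    expect_equal(pair_update(lag), sp$eta * sp$A0 * exp(-lag / sp$tau_STDP),
                 tolerance = 0.05)
    # post before pre depresses by the mirror amount
    expect_equal(pair_update(-lag), -sp$eta * sp$A0 * euler_kernel(lag))
  }
  # far outside the window: negligible interaction
  expect_lt(abs(pair_update(150)), 1e-3 * sp$eta)
})

test_that("coincident pre/post spikes produce no interaction", {
  sp <- stdp_params()
  ps <- init_plastic_state(1, 1)
  ps <- stdp_weight_update(ps, TRUE, TRUE, sp)  # traces still zero
  expect_equal(ps$Wp_EI[1, 1], 1)
})

test_that("plastic fractions are clamped at zero", {
  sp <- stdp_params(eta = 0.9)
  ps <- init_plastic_state(1, 1)
  ps$A_I <- 5                                   # large post trace
  ps <- stdp_weight_update(ps, TRUE, FALSE, sp) # depression 4.5 > 1
  expect_equal(ps$Wp_EI[1, 1], 0)
})

test_that("average E-to-I weight is the mean incoming effective weight", {
  W <- build_connectivity(tiny_spec(10))
  expect_equal(average_ei_weight(W$W_EI, matrix(1, 10, 10)), 100)
  expect_equal(average_ei_weight(W$W_EI, matrix(0, 10, 10)), 0)
  expect_equal(average_ei_weight(W$W_EI, matrix(1.3, 10, 10)), 130)
  expect_error(average_ei_weight(W$W_EI, matrix(1, 10, 9)), "shape")
})
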