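test_that("membrane update reproduces hand-computed slopes and equilibria", {
  p <- neuron_params()
  st <- init_state(3, p)

  # at the leak reversal with no conductances the potential is stationary
  st0 <- membrane_step(st, rep(0, 3), p)
  expect_equal(st0$V, rep(p$E_L, 3))

  # 200 pA into 100 pF: dV/dt = 2 mV/ms
  st1 <- membrane_step(st, rep(200, 3), p)
  expect_equal(st1$V, rep(p$E_L + 2 * p$dt, 3))

  # g_L = 4 nS balanced by an effective 4 nS excitatory conductance pulls V
  # to the midpoint of E_L and E_E = (E_L + E_E)/2 = -28.5 mV
  st2 <- init_state(1, p)
  st2$g_E <- 4 / p$f_max
  for (i in 1:2000) st2 <- membrane_step(st2, 0, p)
  expect_equal(st2$V, (p$E_L + p$E_E) / 2, tolerance = 1e-8)

  expect_error(membrane_step(st, numeric(2), p), "length")
  stbad <- st; stbad$V[2] <- NaN
  expect_error(membrane_step(stbad, rep(0, 3), p, step = 7L), "step 7")
})

test_that("spike sampling follows the exponential rate law and refractoriness", {
  p <- neuron_params()
  st <- init_state(2, p)

  # vanishing rate at strongly hyperpolarized V
  st$V <- rep(-200, 2)
  expect_equal(spike_probability(st$V, st$phi, p), rep(0, 2), tolerance = 1e-12)

  # probability saturates instead of overflowing
  expect_equal(spike_probability(1e4, -55, p), 1)

  # a neuron that spiked 2 ms ago cannot spike regardless of V
  st$V <- rep(100, 2)
  st$t_last_spike <- c(8, 0)
  set.seed(1)
  m <- sample_spikes(st, p, t = 10)   # gaps: 2 ms and 10 ms
  expect_false(m[1])
  expect_true(m[2])
})

test_that("empirical rate at V = phi matches f0 over a long run", {
  p <- neuron_params()
  n <- 50
  steps <- 4e3                       # 50 x 4e3 = 2e5 neuron-steps
  st <- init_state(n, p)
  st$V <- st$phi                     # held at threshold: f = f0 = 2 Hz
  set.seed(42)
  spikes <- 0
  for (k in seq_len(steps)) {
    m <- sample_spikes(st, p, t = k * p$dt)
    spikes <- spikes + sum(m)
    st$t_last_spike[m] <- k * p$dt
  }
  total_s <- n * steps * p$dt / 1000
  # refractory loss at 2 Hz is ~1%: compare against thinned expectation
  p_step <- -expm1(-p$f0 * 1e-3 * p$dt)
  expected <- p_step * n * steps
  se <- sqrt(expected)
  expect_lt(abs(spikes - expected), 3 * se)
  expect_equal(spikes / total_s, p$f0, tolerance = 0.1)
})

test_that("spike reset averages to 40 mV then hyperpolarizes by 20 mV", {
  p <- neuron_params()
  st <- init_state(2, p)
  st$V <- c(-50, 40)
  st <- apply_spike_reset(st, c(TRUE, TRUE), p, t = 5)
  expect_equal(st$V, c(-5, 40))      # (40 + V)/2; 40 is its fixed point
  expect_equal(st$phi, rep(p$phi0 + p$delta_phi, 2))
  expect_equal(st$t_last_spike, c(5, 5))
  st <- resolve_spike_reset(st)
  expect_equal(st$V, c(-50 - 20, 40 - 20))

  # non-spikers are untouched
  st2 <- init_state(2, p)
  st2 <- apply_spike_reset(st2, c(FALSE, FALSE), p, t = 5)
  expect_equal(st2$V, rep(p$E_L, 2))
  expect_equal(st2$phi, rep(p$phi0, 2))
})

test_that("threshold relaxes exponentially toward phi0", {
  p <- neuron_params()
  st <- init_state(1, p)
  expect_equal(threshold_step(st, p)$phi, p$phi0)  # equilibrium

  st$phi <- -50
  phis <- numeric(200)
  for (k in 1:200) { st <- threshold_step(st, p); phis[k] <- st$phi }
  # 100 ms = one time constant: -55 + 5/e, within Euler error O(dt/tau)
  expect_equal(phis[200], p$phi0 + 5 * exp(-1), tolerance = 0.005)
  expect_true(all(diff(phis) < 0))   # monotone from above
})

test_that("conductances decay exponentially and increments are normalized", {
  p <- neuron_params()
  st <- init_state(1, p)
  st$g_E <- 10
  for (k in 1:30) st <- conductance_step(st, 0, 0, FALSE, p)
  # 15 ms = tau_syn: e-fold decay within Euler error
  expect_equal(st$g_E, 10 * exp(-1), tolerance = 10 * exp(-1) * 0.02)
  expect_equal(st$g_E, 10 * (1 - p$dt / p$tau_syn)^30)  # exact Euler form

  # own spike: sAHP increment delta_K / tau_K = 40/5000 nS
  st2 <- init_state(1, p)
  st2 <- conductance_step(st2, 0, 0, TRUE, p)
  expect_equal(st2$g_K, 40 / 5000)

  # synaptic delivery: syn_gain * W / tau_syn on top of the decayed value
  st3 <- init_state(1, p)
  st3 <- conductance_step(st3, 6, 3, FALSE, p)
  expect_equal(st3$g_E, p$syn_gain * 6 / p$tau_syn)
  expect_equal(st3$g_I, p$syn_gain * 3 / p$tau_syn)

  expect_error(conductance_step(st, -1, 0, FALSE, p), "negative")
})

test_that("chloride relaxes to equilibrium and sets the Nernst reversal", {
  p <- neuron_params()

  # equal concentrations: no gradient, E_Cl = 0
  expect_equal(nernst_potential(p$Cl_out, p), 0)
  # equilibrium concentrations: -26.7 ln(110/6) = -77.66 mV
  expect_equal(nernst_potential(6, p), -26.7 * log(110 / 6))
  expect_equal(nernst_potential(6, p), -77.657, tolerance = 1e-4)
  # base-10 flag
  p10 <- neuron_params(nernst_log = "base10")
  expect_equal(nernst_potential(6, p10), -26.7 * log10(110 / 6))

  # strictly decreasing in the concentration ratio
  cls <- seq(2, 100, by = 1)
  expect_true(all(diff(nernst_potential(cls, p)) > 0))  # E_Cl rises as Cl_in rises

  # with I_Cl = 0 a perturbed concentration relaxes back to 6 mM
  st <- init_state(1, p)
  st$Cl_in <- 20
  st$g_I <- 0
  for (k in 1:2e4) st <- chloride_step(st, p)  # 10 s = 2 tau_Cl
  expect_equal(st$Cl_in, p$Cl_in_eq + 14 * exp(-2), tolerance = 1e-3)
  expect_equal(st$E_Cl, nernst_potential(st$Cl_in, p))

  # depolarized neuron with open GABA channels loads chloride
  st2 <- init_state(1, p)
  st2$V <- -20; st2$g_I <- 10
  st2 <- chloride_step(st2, p)
  expect_gt(st2$Cl_in, p$Cl_in_eq)
})
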