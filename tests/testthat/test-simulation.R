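test_that("compiled engine matches the pure-R reference loop bit for bit", {
  proto <- ftsts_protocol("inverted-standard", onset = 100, duration = 120,
                          train_offset = -0.5, overlap_fraction = 0.3)
  light <- build_light_schedule("increase", onset = 250, duration = 60)
  cfg <- tiny_config(n = 15, duration = 400, seed = 11, protocols = proto,
                     light = light)
  a <- run_simulation(cfg)
  b <- ftsts:::sim_core_r(cfg)
  expect_identical(a$raster, b$raster)
  expect_identical(a$state_E$V, b$state_E$V)
  expect_identical(a$state_I$Cl_in, b$state_I$Cl_in)
  expect_identical(a$state_E$phi, b$state_E$phi)
  expect_equal(a$Wp_EE, b$Wp_EE, tolerance = 1e-14)
  expect_equal(a$Wp_EI, b$Wp_EI, tolerance = 1e-14)
  expect_equal(a$weights$avg_w_EI_nS, b$weights$avg_w_EI_nS,
               tolerance = 1e-12)
})

test_that("a run is bit-reproducible from its seed", {
  cfg <- tiny_config(n = 12, duration = 300, seed = 5)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$raster, b$raster)
  expect_identical(a$Wp_EI, b$Wp_EI)
  cfg2 <- tiny_config(n = 12, duration = 300, seed = 6)
  expect_false(identical(run_simulation(cfg2)$raster, a$raster))
})

test_that("no neuron ever violates the refractory period", {
  cfg <- tiny_config(n = 15, duration = 400, seed = 3)
  sim <- run_simulation(cfg)
  gaps <- tapply(sim$raster$time_ms, sim$raster$neuron_id,
                 function(t) if (length(t) > 1) min(diff(t)) else Inf)
  expect_true(all(gaps >= cfg$neuron$tau_ref))
})

test_that("with plasticity off the average weight is exactly conserved", {
  proto <- ftsts_protocol("standard", onset = 50, duration = 120)
  cfg <- tiny_config(n = 15, duration = 300, seed = 2, protocols = proto,
                     stdp = stdp_params(eta = 1e-12))
  cfg$stdp$eta <- 0
  sim <- run_simulation(cfg)
  expect_true(all(sim$weights$avg_w_EI_nS == sim$weights$avg_w_EI_nS[1]))
  expect_true(all(sim$Wp_EI == 1))
})

test_that("an input-free network stays near the spontaneous rate", {
  cfg <- simulation_config(duration = 4000, seed = 8,
                           connectivity = connectivity_spec(N_E = 100,
                                                            N_I = 100),
                           seizure = NULL)
  sim <- run_simulation(cfg)
  # 200 neurons x 4 s x f0 exp((E_L - phi0)/beta) ~ 0.53 Hz => ~420 spikes;
  # allow generous slack for recurrent excitation, but no runaway
  expect_lt(nrow(sim$raster), 5 * 420)
  expect_gt(nrow(sim$raster), 420 / 5)
  # and no network-wide synchronous event: no 100 ms bin recruits everyone
  bins <- table(cut(sim$raster$time_ms, seq(0, 4000, 100)))
  expect_lt(max(bins), 100)
})

test_that("the seizure input targets the configured window and neurons", {
  cfg <- tiny_config(n = 20)
  sz <- cfg$seizure
  expect_equal(seizure_input(cfg, sz$start - 1), rep(0, 20))
  mid <- seizure_input(cfg, sz$start + 1)
  expect_equal(mid[sz$targets], rep(sz$amplitude, length(sz$targets)))
  expect_equal(sum(mid != 0), length(sz$targets))
  expect_equal(seizure_input(cfg, sz$start + sz$duration), rep(0, 20))
})

test_that("efficacy rate is the weight change per second over the window", {
  cfg <- tiny_config(n = 10, duration = 300, seed = 4)
  sim <- run_simulation(cfg)
  w <- sim$weights
  manual <- (w$avg_w_EI_nS[w$time_ms == 300] -
               w$avg_w_EI_nS[w$time_ms == 100]) / 0.2
  expect_equal(efficacy_rate(sim, c(100, 300)), manual)
  expect_error(efficacy_rate(sim, c(101, 300)), "not sampled")
  # constant weight: rate 0
  cfg$stdp$eta <- 0
  expect_equal(efficacy_rate(run_simulation(cfg), c(0, 300)), 0)
})

test_that("configuration validation rejects inconsistent windows", {
  expect_error(simulation_config(duration = 1000,
                                 connectivity = tiny_spec(10),
                                 seizure = list(amplitude = 200, start = 500,
                                                duration = 1000,
                                                targets = 1:5)),
               "seizure window")
  expect_error(tiny_config(duration = 500,
                           protocols = ftsts_protocol(onset = 400,
                                                      duration = 5000)),
               "stimulation window")
  expect_error(simulation_config(duration = 1000,
                                 connectivity = tiny_spec(10),
                                 seizure = list(amplitude = 1, start = 0,
                                                duration = 10,
                                                targets = c(1, 99))),
               "out of range")
})
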