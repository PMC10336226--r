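test_that("activation variables keep the inactivation identity and limits", {
  for (opsin in c("chronos", "chrimson")) {
    p <- chr_params(opsin)
    for (W in c(1e-3, 0.0023, 0.0308, 0.11, 0.5, 5)) {
      v <- chr_activation_vars(W, p)
      expect_equal(v$A_inact1 + v$A_inact2 + v$A_persist, 1)
    }
  }
  p <- chr_params("chronos")
  # strong light: tau_act -> tau_act0 = 0.74 ms
  expect_equal(chr_activation_vars(1e3, p)$tau_act, 0.74, tolerance = 1e-6)
  # vanishing light: A_act -> a0 = 1
  expect_equal(chr_activation_vars(1e-8, p)$A_act, 1, tolerance = 1e-9)
})

test_that("the conductance waveform rises, saturates, and decays", {
  p <- chr_params("chronos")
  pulse <- list(t_on = 0, t_off = 400, W_light = 0.0308)
  v <- chr_activation_vars(pulse$W_light, p)
  # zero at the delayed opening
  expect_equal(chr_conductance(v$d, pulse, p), 0)
  # sustained light: F -> A_act * A_persist
  expect_equal(chr_conductance(400, pulse, p), v$A_act * v$A_persist,
               tolerance = 5e-3)
  # bounded by the activation amplitude throughout
  Fs <- chr_conductance(seq(0, 400, by = 0.5), pulse, p)
  expect_true(all(Fs >= 0 & Fs <= v$A_act))
  # off-decay: e-fold after tau_off = 3.6 ms
  F_off <- chr_conductance(pulse$t_off, pulse, p)
  expect_equal(chr_conductance(pulse$t_off + 3.6, pulse, p),
               F_off * exp(-1))
})

test_that("Chronos closes faster than Chrimson", {
  pulse <- list(t_on = 0, t_off = 5)
  for (W in c(0.0308)) {
    pulse$W_light <- W
    f1 <- chr_conductance(c(5, 15), pulse, chr_params("chronos"))
    f2 <- chr_conductance(c(5, 15), pulse, chr_params("chrimson"))
    expect_lt(f1[2] / f1[1], f2[2] / f2[1])  # faster relative decay
  }
  expect_lt(chr_params("chronos")$tau_off, chr_params("chrimson")$tau_off)
})

test_that("photocurrent follows I = -g F (V - V_rev)", {
  p <- chr_params("chronos")
  expect_equal(chr_current(0, 0.7, p), 0)          # at reversal
  expect_equal(chr_current(-60, 0.5, p), -294 * 0.5 * (-60))  # +8820 pA
  expect_equal(chr_current(-60, 0, p), 0)
  expect_error(chr_current(-60, -0.1, p), "F")
})

test_that("light schedules encode opsin placement and the blue lead", {
  inc <- build_light_schedule("increase", onset = 100, duration = 60)
  expect_equal(inc$opsin_E$opsin, "chronos")
  expect_equal(inc$opsin_I$opsin, "chrimson")
  expect_equal(inc$blue_target, "E")
  dec <- build_light_schedule("decrease", onset = 100, duration = 60)
  expect_equal(dec$opsin_I$opsin, "chronos")
  expect_equal(dec$blue_target, "I")
  # every blue flash leads its red partner by exactly 2 ms
  n <- nrow(dec$red)
  expect_equal(dec$red$t_on[seq_len(n)] - dec$blue$t_on[seq_len(n)],
               rep(2, n))
  # empty schedule
  none <- build_light_schedule("increase", onset = 0, duration = 0.5)
  expect_equal(nrow(none$blue), 0)
  expect_equal(light_waveform(none$blue, seq(0, 10, 0.5), chr_params()),
               rep(0, 21))
})

test_that("rasterized waveforms superpose single-flash responses", {
  p <- chr_params("chronos")
  tg <- seq(0, 100, by = 0.5)
  one <- data.frame(t_on = 10, t_off = 11)
  Fw <- light_waveform(one, tg, p)
  direct <- chr_conductance(pmax(tg, 10), list(t_on = 10, t_off = 11), p)
  direct[tg < 10] <- 0
  expect_equal(Fw, pmin(direct, 1), tolerance = 1e-12)
  # two distant flashes: tails add
  two <- data.frame(t_on = c(10, 50), t_off = c(11, 51))
  F2 <- light_waveform(two, tg, p)
  expect_equal(F2[tg < 50], Fw[tg < 50], tolerance = 1e-9)
  expect_gt(F2[tg == 50.5], 0)
})
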