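grid_ms <- function(to, dt = 0.5) seq(0, to - dt, by = dt)

test_that("pulse trains are charge balanced with the documented geometry", {
  dt <- 0.5
  tr <- pulse_train_spec(amplitude = 2, width = 1, inter_pulse_interval = 10,
                         polarity = 1L, onset = 0, duration = 60)
  w <- build_pulse_train(tr, grid_ms(60))
  expect_equal(sum(w) * dt, 0)                       # zero net charge
  expect_equal(w[1:2], c(-2, -2))                    # polarity +1: -A first
  expect_equal(w[3:4], c(2, 2))                      # then +A
  expect_equal(w[5:24], rep(0, 20))                  # 10 ms gap
  tr$polarity <- -1L
  w2 <- build_pulse_train(tr, grid_ms(60))
  expect_equal(w2, -w)                               # polarity flips the pulse
  expect_equal(w2[1], 2)                             # -1 begins positive

  # a window that cuts a pulse pair mid-way emits only whole pairs
  tr3 <- pulse_train_spec(onset = 0, duration = 13)
  w3 <- build_pulse_train(tr3, grid_ms(13))
  expect_equal(sum(w3) * dt, 0)
  expect_equal(sum(w3 != 0), 4)                      # one complete pair only
})

test_that("train offsets are periodic in the pulse cycle", {
  tr <- pulse_train_spec(width = 1, inter_pulse_interval = 10,
                         onset = 24, duration = 96)
  tg <- grid_ms(240)
  # W=1, T=10: the cycle is 12 ms, so offsets 0 and 12 are identical
  expect_identical(build_pulse_train(tr, tg, offset = 0),
                   build_pulse_train(tr, tg, offset = 12))
  expect_identical(build_pulse_train(tr, tg, offset = -1),
                   build_pulse_train(tr, tg, offset = 11))
  # and a half-cycle offset is not
  expect_false(identical(build_pulse_train(tr, tg, offset = 0),
                         build_pulse_train(tr, tg, offset = 6)))
})

test_that("waveforms must align to the integration grid", {
  tr <- pulse_train_spec(width = 0.3)
  expect_error(build_pulse_train(tr, grid_ms(12)), "not an integer multiple")
})

test_that("the four protocol names map to their polarity pairs", {
  pol <- list("standard" = c(1, -1), "inverted-standard" = c(-1, 1),
              "mirrored" = c(1, 1), "inverted-mirrored" = c(-1, -1))
  for (nm in names(pol)) {
    p <- ftsts_protocol(nm)
    expect_equal(c(p$a_E, p$a_I), pol[[nm]])
    # and the reverse lookup recovers the name
    expect_equal(ftsts_protocol(a_E = pol[[nm]][1], a_I = pol[[nm]][2])$name,
                 nm)
  }
  expect_equal(ftsts_protocol("standard")$period, 12)
})

test_that("mirrored protocol with zero offset drives both populations alike", {
  p <- ftsts_protocol("mirrored", onset = 0, duration = 48, train_offset = 0)
  w <- protocol_waveforms(p, grid_ms(48))
  expect_identical(w$wave_E, w$wave_I)
  # the train-offset delays the inhibitory train
  p2 <- ftsts_protocol("mirrored", onset = 12, duration = 24,
                       train_offset = 2)
  w2 <- protocol_waveforms(p2, grid_ms(48))
  iE <- which(w2$wave_E != 0)[1]
  iI <- which(w2$wave_I != 0)[1]
  expect_equal((iI - iE) * 0.5, 2)
})

test_that("stimulation routing is deterministic and sized by the fraction", {
  p <- ftsts_protocol("inverted-standard", overlap_fraction = 0.8)
  set.seed(99)
  r1 <- route_stimulation(p, 500, 500)
  expect_equal(sum(r1$cross_E), floor(0.8 * 500))
  expect_equal(sum(r1$cross_I), 400)
  set.seed(99)
  r2 <- route_stimulation(p, 500, 500)
  expect_identical(r1, r2)
  p0 <- ftsts_protocol("inverted-standard", overlap_fraction = 0)
  expect_equal(sum(route_stimulation(p0, 100, 100)$cross_E), 0)
})
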