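test_that("puff waveforms hit the requested duration and volume", {
  cases <- list(
    list(kind = "short_puff", dur = 2.43, shape = "half_sine"),
    list(kind = "long_puff", dur = 5.0, shape = "half_sine"),
    list(kind = "post_puff", dur = 1.34, shape = "triangular")
  )
  for (cs in cases) {
    for (V in c(30e-6, 55e-6, 80e-6)) {
      w <- build_puff(cs$kind, cs$dur, V, cs$shape)
      expect_equal(max(w$times), cs$dur, tolerance = 1e-12)
      expect_equal(waveform_volume(w), V, tolerance = 1e-9)
      expect_true(all(w$flow >= 0))
    }
  }
  expect_error(build_puff("short_puff", -1, 55e-6),
               class = "vapedose_invalid_argument")
  expect_error(build_puff("short_puff", 2.43, 0),
               class = "vapedose_invalid_argument")
})

test_that("half-sine peak flow follows the closed form pi*V/(2T)", {
  for (T in c(1.8, 2.43, 5.0)) {
    V <- 55e-6
    w <- build_puff("custom", T, V, "half_sine")
    expect_equal(max(w$flow), pi * V / (2 * T), tolerance = 1e-4)
  }
  # exhalation variant of the same closed form
  e <- build_exhalation(1e-4, 2.5)
  expect_equal(max(abs(e$flow)), pi * 1e-4 / (2 * 2.5), tolerance = 1e-4)
})

test_that("exhalation is negative-signed with matching volume", {
  e <- build_exhalation(55e-6, 1.8)
  expect_equal(max(e$times), 1.8, tolerance = 1e-12)
  expect_true(all(e$flow <= 0))
  expect_equal(abs(waveform_volume(e)), 55e-6, tolerance = 1e-9)
  expect_error(build_exhalation(0, 1.8), class = "vapedose_invalid_argument")
})

test_that("nasal cycle is periodic, balanced, and meters the minute volume", {
  cyc <- build_nasal_cycle(minute_volume = 6e-3, period = 4)
  one <- sample_cycle(cyc, 0, 4)
  expect_equal(waveform_volume(one), 0, tolerance = 1e-9 * cyc$peak_flow * 4)

  # three full periods -> exactly three inhalation phases
  w <- sample_cycle(cyc, 0, 12)
  pos <- w$flow > 1e-12
  starts <- sum(diff(c(FALSE, pos)) == 1)
  expect_identical(starts, 3L)

  # inhaled volume over one minute matches the minute volume within 1%
  w60 <- sample_cycle(cyc, 0, 60)
  inhaled <- trapz_pos(w60)
  expect_equal(inhaled, 6e-3, tolerance = 0.01)

  # shift by one period reproduces the flow bit-exactly
  a <- sample_cycle(cyc, 0, 8)
  b <- sample_cycle(cyc, 4, 12)
  expect_identical(a$flow, b$flow)

  expect_error(sample_cycle(cyc, 0, 0.001, dt = 0.01),
               class = "vapedose_invalid_argument")
})

test_that("waveform volume integrates constants and cancels symmetric pairs", {
  w <- flow_waveform(seq(0, 2, 0.1), rep(3e-5, 21))
  expect_equal(waveform_volume(w), 3e-5 * 2, tolerance = 1e-12)
  p <- build_puff("custom", 2, 55e-6)
  e <- build_exhalation(55e-6, 2)
  both <- concat_waveforms(p, e)
  expect_equal(waveform_volume(both), 0, tolerance = 1e-9 * 55e-6)
})
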