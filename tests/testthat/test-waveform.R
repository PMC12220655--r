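test_that("stroke volume and dimensionless stroke length match the clinical values", {
  # physiological waveform: V_s = 0.823 mL against the 1.875 mL segment volume
  wf <- harmonic_waveform(pi * 0.823, period = 1)
  se <- stroke_volume_and_epsilon(wf, 1.875)
  expect_equal(se$V_s, 0.823, tolerance = 1e-4)
  expect_equal(se$epsilon, 0.439, tolerance = 1e-3)
  # scaled by the small factor 0.00763 used for the small-stroke validation
  se2 <- stroke_volume_and_epsilon(scale_waveform(wf, 0.00763), 1.875)
  expect_equal(se2$epsilon, 0.00335, tolerance = 1e-3)
})

test_that("a sine waveform has stroke volume Q0 T / pi", {
  # analytic quadrature: V_s = 0.5 * integral |Q0 sin(2 pi t / T)| dt = Q0 T / pi
  for (Q0 in c(0.5, 2.585)) {
    for (Tper in c(1, 0.8)) {
      wf <- harmonic_waveform(Q0, Tper)
      expect_equal(stroke_volume_and_epsilon(wf, 1)$V_s, Q0 * Tper / pi,
                   tolerance = 1e-5)
    }
  }
})

test_that("waveform validation rejects degenerate input", {
  expect_error(flow_waveform(numeric(0), numeric(0), 1), "empty")
  expect_error(flow_waveform(c(0, 0.2, 0.1), 1:3, 1), "increasing")
  expect_error(stroke_volume_and_epsilon(harmonic_waveform(1, 1), -1),
               "positive")
})

test_that("the cycle mean is reported, not forced to zero", {
  wf <- harmonic_waveform(1, 1, Q_mean = 0.3)
  expect_equal(csfdrift:::waveform_mean(wf), 0.3, tolerance = 1e-6)
})

test_that("linear interpolation reproduces the tabulated in-vitro diffusivity", {
  # interpolating the bench measurements 3.323e-2 cm^2/s (0.5 mL) and
  # 5.858e-2 cm^2/s (1 mL) at the physiological stroke volume 0.823 mL
  kH <- linear_interpolate(0.823, 0.5, 3.323e-2, 1.0, 5.858e-2)
  expect_equal(kH, 4.960e-2, tolerance = 1e-3)
})
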