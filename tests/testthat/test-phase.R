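test_that("moving average matches hand-computed values and shrinks at edges", {
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  x <- rnorm(50)
  sm <- moving_average(x, 7)
  # interior sample: plain centered mean
  expect_equal(sm[25], mean(x[22:28]))
  # edge: truncated window, no padding
  expect_equal(sm[1], mean(x[1:4]))
  expect_error(moving_average(c(1, NA, 2), 3), "finite")
  expect_error(moving_average(1:10, 4), "odd")
})

test_that("circular phase encoding hits the cardinal points and round-trips", {
  enc <- phase_to_cartesian(c(0, 25, 50, 75))
  expect_equal(enc$y_sin, c(0, 1, 0, -1), tolerance = 1e-12)
  expect_equal(enc$y_cos, c(1, 0, -1, 0), tolerance = 1e-12)
  # decoding exercises the negative-angle wrap branch
  expect_equal(cartesian_to_phase(0, 1), 0)
  expect_equal(cartesian_to_phase(-1, 0), 75)
  # exhaustive integer grid round-trip
  p <- 0:99
  dec <- cartesian_to_phase(phase_to_cartesian(p))
  expect_equal(dec, as.numeric(p), tolerance = 1e-12)
  # values outside [0,100] are reduced modulo 100
  expect_equal(phase_to_cartesian(125), phase_to_cartesian(25))
  expect_error(cartesian_to_phase(0, 0), "undefined phase")
  expect_error(phase_to_cartesian(NaN), "finite")
})

test_that("phase labels ramp 0 -> 100 between pressure peaks", {
  # clean pulse train: pulses every 10 samples
  t <- 0:59
  pressure <- exp(3 * (cos(2 * pi * (t %% 10) / 10) - 1))
  lab <- derive_phase_labels(pressure, smooth_window = 3,
                             min_peak_distance = 5, min_prominence = 0.05)
  peaks <- which(lab$phase == 0)
  expect_true(length(peaks) >= 4)
  # midpoint of a 0->100 ramp
  mid <- peaks[1] + 5L
  expect_equal(lab$phase[mid], 50)
  expect_true(lab$valid[mid])
  # before first / after last peak: invalid
  if (peaks[1] > 1) expect_false(any(lab$valid[seq_len(peaks[1] - 1)]))
  last_peak <- max(peaks)
  if (last_peak < length(pressure)) {
    expect_false(any(lab$valid[(last_peak + 1):length(pressure)]))
  }
  # ramps are non-decreasing within strides and < 100 before the next peak
  expect_true(all(lab$phase[lab$valid] < 100))
})

test_that("degenerate pressure inputs fail loudly", {
  expect_error(derive_phase_labels(rep(1, 200)), "insufficient strides")
  expect_error(derive_phase_labels(c(rep(0, 100), Inf, rep(0, 99))), "finite")
  expect_error(derive_phase_labels(rep(0, 5), smooth_window = 15), "shorter")
})

test_that("the four bins follow the printed integer boundaries", {
  expect_equal(as.character(assign_phase_bin(15)), "pre-stance")
  expect_equal(as.character(assign_phase_bin(45)), "post-stance")
  expect_equal(as.character(assign_phase_bin(100)), "post-swing")
  expect_equal(as.character(assign_phase_bin(30)), "pre-stance")
  expect_equal(as.character(assign_phase_bin(30.5)), "post-stance")
  expect_equal(as.character(assign_phase_bin(0)), "pre-stance")
  expect_equal(as.character(assign_phase_bin(80)), "pre-swing")
  # partition: every value in [0,100] maps to exactly one bin
  grid <- seq(0, 100, by = 0.25)
  bins <- assign_phase_bin(grid)
  expect_false(anyNA(bins))
  expect_error(assign_phase_bin(101), "0, 100")
})

test_that("downsampling decimates with the rate factor and preserves signal", {
  x <- rnorm(2000)
  y <- downsample_channel(x, 2000, 100)
  expect_length(y, 100)
  # DC passes the low-pass untouched
  expect_equal(downsample_channel(rep(3.5, 400), 400, 100), rep(3.5, 100),
               tolerance = 1e-9)
  # a sinusoid well below the output Nyquist survives with < 1% amplitude error
  t <- seq(0, 4, length.out = 4000)
  s <- sin(2 * pi * 10 * t) # 10 Hz at 1000 Hz input
  y <- downsample_channel(s, 1000, 100)
  ref <- s[seq(1, by = 10, length.out = 400)]
  interior <- 50:350
  expect_lt(max(abs(y[interior] - ref[interior])), 0.01)
  expect_error(downsample_channel(x, 150, 100), "integer multiple")
})
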