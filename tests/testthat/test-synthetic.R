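test_that("jitter-free generation has exact stride boundaries and length", {
  spec <- synthetic_spec(n_strides = 5, stride_len_mean = 100,
                         stride_len_jitter = 0, seed = 3)
  gen <- generate_recording(spec)
  expect_equal(n_samples(gen$recording), 500)
  ph <- gen$phase$phase
  # stride boundaries every 100 samples (0-based 0, 100, 200, ...)
  expect_equal(ph[201], 0) # 0-based sample 200
  expect_equal(ph[251], 50) # mid-stride
  # foot pressure peaks exactly at stride starts
  fp <- gen$recording$foot_pressure
  expect_equal(which.max(fp[151:250]), 50 + 1) # peak at 0-based 200
})

test_that("generation is deterministic under a fixed seed", {
  spec <- synthetic_spec(n_strides = 4, stride_len_jitter = 0.1, seed = 9)
  g1 <- generate_recording(spec)
  g2 <- generate_recording(spec)
  expect_identical(g1$recording$signals, g2$recording$signals)
  expect_identical(g1$phase, g2$phase)
})

test_that("invalid spec fields are rejected by name", {
  expect_error(synthetic_spec(n_strides = 1), "n_strides")
  expect_error(synthetic_spec(5, stride_len_mean = 5), "stride_len_mean")
  expect_error(synthetic_spec(5, stride_len_jitter = 1), "stride_len_jitter")
  ch <- default_channel_spec()
  ch$snr[1] <- -1
  expect_error(synthetic_spec(5, channels = ch), "snr")
  expect_error(synthetic_spec(5, channels = ch[0, ]), "empty")
  ch2 <- default_channel_spec()
  ch2$kind[2] <- "mystery"
  expect_error(synthetic_spec(5, channels = ch2), "kind")
})

test_that("noise channels carry no phase information", {
  ch <- tibble::tibble(name = c("kin", "pure_noise"),
                       modality = c("IMU", "EMG"),
                       kind = c("kinematic-sinusoid", "noise"),
                       phase_offset = c(0, 0), snr = c(0, 0))
  spec <- synthetic_spec(n_strides = 50, stride_len_mean = 100,
                         channels = ch, seed = 21)
  gen <- generate_recording(spec)
  ph <- gen$phase$phase
  noise <- gen$recording$signals$pure_noise
  expect_lt(abs(cor(noise, sin(2 * pi * ph / 100))), 0.1)
  expect_lt(abs(cor(noise, ph)), 0.1)
  # the informative channel, by contrast, is strongly phase-locked
  expect_gt(abs(cor(gen$recording$signals$kin, sin(2 * pi * ph / 100))), 0.8)
})

test_that("informative channels share mutual information with phase, noise does not", {
  ch <- attribution_channels()
  spec <- synthetic_spec(n_strides = 30, stride_len_mean = 100,
                         channels = ch, seed = 5)
  gen <- generate_recording(spec)
  binned_mi <- function(x, y, nb = 8) {
    bx <- cut(x, breaks = nb, labels = FALSE)
    by <- cut(y, breaks = nb, labels = FALSE)
    p <- table(bx, by) / length(x)
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
    s
  }
  ph <- gen$phase$phase
  mi <- vapply(gen$recording$signals, function(x) binned_mi(x, ph), numeric(1))
  expect_gt(min(mi[c("kin_a", "kin_b", "stretch_a")]), 0.3)
  expect_lt(max(mi[c("noise_a", "noise_b", "noise_c")]), 0.05)
})

test_that("pressure-derived labels agree with ground truth on clean data", {
  spec <- synthetic_spec(n_strides = 10, stride_len_mean = 100,
                         stride_len_jitter = 0, seed = 7)
  gen <- generate_recording(spec)
  lab <- derive_phase_labels(gen$recording$foot_pressure)
  ok <- lab$valid
  err <- circular_phase_distance(lab$phase[ok], gen$phase$phase[ok])
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("generate_dataset composes generation, labelling and windowing", {
  ds <- tiny_dataset(n_strides = 21)
  expect_equal(n_windows(ds), 2001) # T - L + 1 with T = 2100
  expect_equal(attr(ds, "label_source"), "ground_truth")
  spec <- synthetic_spec(n_strides = 6, stride_len_jitter = 0, seed = 2)
  ds_gt <- generate_dataset(spec, 100, 5, labels = "ground_truth")
  ds_pr <- generate_dataset(spec, 100, 5, labels = "pressure")
  common <- intersect(ds_gt$end_index, ds_pr$end_index)
  d <- circular_phase_distance(
    ds_gt$phase[match(common, ds_gt$end_index)],
    ds_pr$phase[match(common, ds_pr$end_index)])
  expect_lt(max(d), 2)
})
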