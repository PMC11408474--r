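interp_model <- function(M = 3, N = 2, h = 2, d = 16, L = 50,
                         per_channel_tokens = TRUE, seed = 1) {
  ptt_model(ptt_config(n_channels = M, window_len = L, patch_len = 10,
                       embed_dim = d, n_heads = h, n_layers = N, dropout = 0,
                       per_channel_tokens = per_channel_tokens), seed)
}

interp_ds <- function(M = 3, L = 50, K = 8, seed = 2) {
  nm <- paste0("ch", seq_len(M))
  sig <- as.data.frame(setNames(lapply(seq_len(M), function(i) {
    set.seed(seed + i); rnorm(L + K - 1)
  }), nm))
  rec <- gait_recording(sig, 100, setNames(rep("IMU", M), nm))
  make_windows(rec, runif(L + K - 1, 0, 100), L, 1)
}

test_that("channel weights are stochastic and respect symmetry", {
  # single channel: weight exactly 1
  ds1 <- interp_ds(M = 1)
  rep1 <- channel_weights(interp_model(M = 1), ds1)
  expect_equal(rep1$mean_weight, 1, tolerance = 1e-9)
  # identical channel content + shared token: uniform 1/M
  M <- 4
  nm <- paste0("ch", 1:M)
  base <- rnorm(60)
  rec <- gait_recording(as.data.frame(setNames(replicate(M, base,
                                                         simplify = FALSE), nm)),
                        100, setNames(rep("IMU", M), nm))
  ds <- make_windows(rec, runif(60, 0, 100), 50, 1)
  m <- interp_model(M = M, per_channel_tokens = FALSE)
  rep_u <- channel_weights(m, ds)
  expect_equal(rep_u$mean_weight, rep(1 / M, M), tolerance = 1e-9)
  # weights always sum to one
  rep_g <- channel_weights(interp_model(M = 3), interp_ds(M = 3))
  expect_equal(sum(rep_g$mean_weight), 1, tolerance = 1e-6)
  expect_error(channel_weights(interp_model(M = 3), interp_ds(M = 3)[0]),
               "empty")
})

test_that("window-averaged weights equal the mean of per-window weights", {
  m <- interp_model(M = 3)
  ds <- interp_ds(M = 3, K = 2)
  rep2 <- channel_weights(m, ds)
  per_win <- sapply(1:2, function(k) {
    tr <- ptt_forward(ds$windows[, , k], m)
    colMeans(tr$cross_attention)
  })
  expect_equal(rep2$mean_weight, rowMeans(per_win), tolerance = 1e-9)
})

test_that("attention scope averages the requested layer/head set", {
  m <- interp_model(M = 2, N = 3, h = 2)
  w <- matrix(rnorm(2 * 50), 2)
  tr <- ptt_forward(w, m, capture = TRUE)
  # a single layer+head equals that head's raw attention
  sc1 <- attention_scope(tr, layers = 2, heads = 1)
  expect_equal(sc1$maps[[1]], tr$encoder_attention[[1]][[2]][1, , ])
  # rows of any averaged map are stochastic
  sc <- attention_scope(m, w)
  for (mp in sc$maps) {
    expect_equal(rowSums(mp), rep(1, nrow(mp)), tolerance = 1e-4)
  }
  # default selection: last 3 layers, capped heads
  expect_equal(sc$layers_used, 1:3)
  expect_equal(sc$heads_used, 1:2)
  # union of two layers averages elementwise
  sA <- attention_scope(tr, layers = 2, heads = 1:2)
  sB <- attention_scope(tr, layers = 3, heads = 1:2)
  sAB <- attention_scope(tr, layers = 2:3, heads = 1:2)
  expect_equal(sAB$maps[[2]], (sA$maps[[2]] + sB$maps[[2]]) / 2,
               tolerance = 1e-12)
  expect_error(attention_scope(tr, layers = 9), "out of range")
  tr_nocap <- ptt_forward(w, m)
  expect_error(attention_scope(tr_nocap), "no trace")
})

test_that("top-k selection ranks within modality with lexicographic ties", {
  rep_tbl <- tibble::tibble(
    channel = c("a", "b", "c"),
    modality = "IMU",
    mean_weight = c(0.5, 0.3, 0.2),
    sd_weight = 0
  )
  sel <- select_top_channels(rep_tbl, c(IMU = 2))
  expect_equal(sel$selected, c("a", "b"))
  # exact ties resolve by name, stable under row permutation
  tie <- tibble::tibble(channel = c("zeta", "beta", "alpha"),
                        modality = "EMG",
                        mean_weight = c(0.4, 0.3, 0.3), sd_weight = 0)
  s1 <- select_top_channels(tie, c(EMG = 2))
  s2 <- select_top_channels(tie[c(3, 1, 2), ], c(EMG = 2))
  expect_equal(s1$selected, c("zeta", "alpha"))
  expect_equal(s2$selected, s1$selected)
  # idempotent: reselecting from the selection changes nothing
  sub <- tie[tie$channel %in% s1$selected, ]
  expect_equal(select_top_channels(sub, c(EMG = 2))$selected, s1$selected)
  expect_error(select_top_channels(tie, c(EMG = 7)), "EMG")
  expect_error(select_top_channels(tie, c(IMU = 1)), "IMU")
})

test_that("the four fused sources follow the composition arithmetic", {
  reg <- standard_channel_registry()
  expect_equal(nrow(reg), 34)
  set.seed(9)
  rep_tbl <- tibble::tibble(channel = reg$channel, modality = reg$modality,
                            mean_weight = runif(34), sd_weight = 0)
  rep_tbl$mean_weight <- rep_tbl$mean_weight / sum(rep_tbl$mean_weight)
  specs <- build_fused_source_specs(rep_tbl)
  expect_named(specs, c("IMU+EMG", "Stretch+EMG", "IMU+Stretch",
                        "IMU+Stretch+EMG"))
  for (s in specs) {
    expect_length(s$selected, 16)
    expect_false(anyDuplicated(s$selected) > 0)
    expect_true(all(s$selected %in% rep_tbl$channel))
  }
  # stretch channels always ride along in the stretch-bearing configs
  stretch <- reg$channel[reg$modality == "STRETCH"]
  for (nm in c("Stretch+EMG", "IMU+Stretch", "IMU+Stretch+EMG")) {
    expect_true(all(stretch %in% specs[[nm]]$selected))
  }
  # modality composition counts
  mod_of <- setNames(reg$modality, reg$channel)
  comp <- function(sel) table(factor(mod_of[sel$selected],
                                     levels = c("IMU", "STRETCH", "EMG")))
  expect_equal(as.numeric(comp(specs[["IMU+EMG"]])), c(8, 0, 8))
  expect_equal(as.numeric(comp(specs[["Stretch+EMG"]])), c(0, 2, 14))
  expect_equal(as.numeric(comp(specs[["IMU+Stretch"]])), c(14, 2, 0))
  expect_equal(as.numeric(comp(specs[["IMU+Stretch+EMG"]])), c(7, 2, 7))
  expect_error(build_fused_source_specs(rep_tbl[rep_tbl$modality != "EMG", ]),
               "missing modality")
})
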