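# Finite-difference validation of every hand-written backward pass.

test_that("transformer gradients match finite differences", {
  set.seed(7)
  cfg <- ptt_config(n_channels = 2, window_len = 20, patch_len = 5,
                    embed_dim = 8, n_heads = 2, n_layers = 2, dropout = 0)
  m <- ptt_model(cfg, seed = 7)
  B <- 3
  Xb <- array(rnorm(2 * 20 * B), dim = c(2, 20, B))
  labels <- matrix(rnorm(B * 2), B, 2)
  lossfn <- function(v) {
    p <- gaitphase:::params_unflatten(m$params, v)
    fw <- gaitphase:::ptt_forward_batch(Xb, p, cfg)
    mean((fw$Y - labels)^2)
  }
  v0 <- gaitphase:::params_flatten(m$params)
  fw <- gaitphase:::ptt_forward_batch(Xb, m$params, cfg)
  dY <- 2 * (fw$Y - labels) / length(fw$Y)
  gv <- gaitphase:::params_flatten(
    gaitphase:::ptt_backward_batch(dY, m$params, cfg, fw$cache))
  expect_length(gv, length(v0))
  idx <- sort(sample(length(v0), 80))
  num <- numeric_grad(lossfn, v0, idx)
  expect_lt(max(abs(num - gv[idx])), 1e-6)
})

test_that("baseline gradients match finite differences for every family", {
  set.seed(1)
  M <- 3; L <- 40; B <- 3
  Xb <- array(rnorm(M * L * B), dim = c(M, L, B))
  labels <- matrix(rnorm(B * 2), B, 2)
  for (fam in c("CNN", "LSTM", "GRU", "CNN+LSTM", "CNN+GRU")) {
    spec <- baseline_spec(fam, hidden_dim = 6, n_recurrent_blocks = 2,
                          n_cnn_blocks = 2)
    mod <- build_baseline(spec, M, L, seed = 3)
    lossfn <- function(v) {
      p <- gaitphase:::params_unflatten(mod$params, v)
      fw <- gaitphase:::baseline_forward_batch(Xb, p, mod$config)
      mean((fw$Y - labels)^2)
    }
    v0 <- gaitphase:::params_flatten(mod$params)
    fw <- gaitphase:::baseline_forward_batch(Xb, mod$params, mod$config)
    dY <- 2 * (fw$Y - labels) / length(fw$Y)
    g <- gaitphase:::reorder_like(
      mod$params,
      gaitphase:::baseline_backward_batch(dY, mod$params, mod$config, fw$cache))
    gv <- gaitphase:::params_flatten(g)
    idx <- sort(sample(length(v0), min(50, length(v0))))
    num <- numeric_grad(lossfn, v0, idx)
    expect_lt(max(abs(num - gv[idx])), 1e-6, label = fam)
  }
})

test_that("layer norm backward matches finite differences", {
  set.seed(9)
  x <- matrix(rnorm(12), 3, 4)
  gamma <- runif(4, 0.5, 1.5)
  beta <- rnorm(4)
  dy <- matrix(rnorm(12), 3, 4)
  fw <- gaitphase:::layernorm_fwd(x, gamma, beta)
  bw <- gaitphase:::layernorm_bwd(fw, gamma, dy)
  f <- function(xv) {
    sum(gaitphase:::layernorm_fwd(matrix(xv, 3, 4), gamma, beta)$out * dy)
  }
  num <- numeric_grad(f, as.vector(x), seq_along(x))
  expect_lt(max(abs(num - as.vector(bw$dx))), 1e-6)
})

test_that("the GELU derivative is consistent with its primal", {
  x <- seq(-4, 4, length.out = 41)
  num <- (gaitphase:::gelu(x + 1e-6) - gaitphase:::gelu(x - 1e-6)) / 2e-6
  expect_lt(max(abs(num - gaitphase:::gelu_grad(x))), 1e-6)
})
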