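# Independent oracles: scalar nested-loop implementations of the attention
# arithmetic, kept deliberately free of the package's vectorised code paths.

mat_mul_loop <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
      out[i, j] <- s
    }
  }
  out
}

softmax_loop <- function(v) {
  m <- max(v)
  e <- exp(v - m)
  e / sum(e)
}

# multi-head self-attention + output projection, all scalar loops
oracle_mha <- function(x, W_q, W_k, W_v, W_o, h, scale) {
  S <- nrow(x)
  d <- ncol(x)
  dk <- d %/% h
  Q <- mat_mul_loop(x, W_q)
  K <- mat_mul_loop(x, W_k)
  V <- mat_mul_loop(x, W_v)
  concat <- matrix(0, S, d)
  attn <- array(0, dim = c(h, S, S))
  for (j in seq_len(h)) {
    cols <- ((j - 1) * dk + 1):(j * dk)
    for (s1 in seq_len(S)) {
      logits <- numeric(S)
      for (s2 in seq_len(S)) {
        acc <- 0
        for (k in cols) acc <- acc + Q[s1, k] * K[s2, k]
        logits[s2] <- acc / scale
      }
      w <- softmax_loop(logits)
      attn[j, s1, ] <- w
      for (k in cols) {
        acc <- 0
        for (s2 in seq_len(S)) acc <- acc + w[s2] * V[s2, k]
        concat[s1, k] <- acc
      }
    }
  }
  list(out = mat_mul_loop(concat, W_o), attention = attn)
}

# single-query cross-attention over M key/value rows
oracle_cross <- function(T_prime, T_tokens, W_q, W_k, W_v, W_o, h, scale) {
  M <- nrow(T_tokens)
  d <- ncol(T_tokens)
  dk <- d %/% h
  q <- mat_mul_loop(matrix(T_prime, 1), W_q)
  K <- mat_mul_loop(T_tokens, W_k)
  V <- mat_mul_loop(T_tokens, W_v)
  concat <- numeric(d)
  weights <- matrix(0, h, M)
  for (j in seq_len(h)) {
    cols <- ((j - 1) * dk + 1):(j * dk)
    logits <- numeric(M)
    for (m in seq_len(M)) {
      acc <- 0
      for (k in cols) acc <- acc + q[1, k] * K[m, k]
      logits[m] <- acc / scale
    }
    w <- softmax_loop(logits)
    weights[j, ] <- w
    for (k in cols) {
      acc <- 0
      for (m in seq_len(M)) acc <- acc + w[m] * V[m, k]
      concat[k] <- acc
    }
  }
  list(feature = as.numeric(mat_mul_loop(matrix(concat, 1), W_o)),
       weights = weights)
}

# central finite-difference gradient of f at v for the given indices
numeric_grad <- function(f, v, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + eps
    vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, numeric(1))
}

# small noise-free synthetic dataset used across tests
tiny_dataset <- function(n_strides = 5, channels = NULL, seed = 11,
                         window_len = 100, stride = 1) {
  ch <- channels
  if (is.null(ch)) {
    ch <- default_channel_spec()
    ch$snr <- 0
  }
  spec <- synthetic_spec(n_strides = n_strides, stride_len_mean = 100,
                         stride_len_jitter = 0, channels = ch, seed = seed)
  generate_dataset(spec, window_len, stride, labels = "ground_truth")
}

# channel table for the attribution task: informative vs pure-noise channels
attribution_channels <- function() {
  tibble::tibble(
    name = c("kin_a", "kin_b", "stretch_a", "noise_a", "noise_b", "noise_c"),
    modality = c("IMU", "IMU", "STRETCH", "EMG", "EMG", "EMG"),
    kind = c("kinematic-sinusoid", "kinematic-sinusoid", "stretch-ramp",
             "noise", "noise", "noise"),
    phase_offset = c(0, 30, 0, 0, 0, 0),
    snr = c(0, 0, 0, 0, 0, 0)
  )
}
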