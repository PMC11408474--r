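#' Baseline model families
#'
#' Classical time-series regressors used as comparison points for the patch
#' transformer, all sharing its forward contract: an `M x L` window in, a
#' two-component (sin, cos) phase prediction out.
#'
#' * `"CNN"` — a dual-branch 1-D convolutional stack (kernel sizes 5 and 3),
#'   each branch `n_cnn_blocks` conv/ReLU/average-pool blocks, global average
#'   pooling, linear head.
#' * `"LSTM"` / `"GRU"` — `n_recurrent_blocks` stacked recurrent layers of
#'   width `hidden_dim`; the final hidden state feeds a linear head.
#' * `"CNN+LSTM"` / `"CNN+GRU"` — three conv blocks feeding three recurrent
#'   blocks.
#'
#' @param family One of `"CNN"`, `"LSTM"`, `"GRU"`, `"CNN+LSTM"`,
#'   `"CNN+GRU"`.
#' @param hidden_dim Recurrent hidden width (default 128, the publication
#'   setting) and convolutional filter count.
#' @param n_recurrent_blocks Stacked recurrent layers for the pure recurrent
#'   families (default 4).
#' @param n_cnn_blocks Convolution blocks per branch for the CNN family
#'   (default 3).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(family = c("CNN", "LSTM", "GRU", "CNN+LSTM", "CNN+GRU"),
                          hidden_dim = 128L, n_recurrent_blocks = 4L,
                          n_cnn_blocks = 3L) {
  family <- match.arg(family)
  if (hidden_dim < 1L || n_recurrent_blocks < 1L || n_cnn_blocks < 1L) {
    abort("baseline_spec: all dimensions must be positive")
  }
  structure(list(family = family, hidden_dim = as.integer(hidden_dim),
                 n_recurrent_blocks = as.integer(n_recurrent_blocks),
                 n_cnn_blocks = as.integer(n_cnn_blocks)),
            class = "baseline_spec")
}

# output length of a valid conv + pool-by-2 block chain
conv_chain_len <- function(T_in, kernel, n_blocks) {
  for (b in seq_len(n_blocks)) T_in <- (T_in - kernel + 1L) %/% 2L
  T_in
}

init_conv_stack <- function(n_blocks, c_in, filters, kernel) {
  lapply(seq_len(n_blocks), function(b) {
    cin <- if (b == 1L) c_in else filters
    list(W = array(runif(filters * cin * kernel, -1, 1) / sqrt(cin * kernel),
                   dim = c(filters, cin, kernel)),
         b = numeric(filters))
  })
}

init_recurrent_stack <- function(n_blocks, c_in, hid, gates) {
  lapply(seq_len(n_blocks), function(l) {
    cin <- if (l == 1L) c_in else hid
    list(W = init_linear(cin, gates * hid),
         U = init_linear(hid, gates * hid),
         b = numeric(gates * hid))
  })
}

#' Build a baseline model
#'
#' @param spec A [baseline_spec()].
#' @param n_channels,window_len Input window shape `M x L`.
#' @param seed Integer seed for weight initialisation.
#' @return A `baseline_model` (also inherits `gait_model`) with elements
#'   `family`, `config`, `params`.
#' @export
build_baseline <- function(spec, n_channels, window_len, seed = 1L) {
  stopifnot(inherits(spec, "baseline_spec"))
  local_seed(seed)
  M <- as.integer(n_channels)
  L <- as.integer(window_len)
  hid <- spec$hidden_dim
  cfg <- c(spec[c("family", "hidden_dim", "n_recurrent_blocks",
                  "n_cnn_blocks")],
           list(n_channels = M, window_len = L))
  params <- switch(
    spec$family,
    "CNN" = {
      kernels <- c(5L, 3L)
      for (k in kernels) {
        if (conv_chain_len(L, k, spec$n_cnn_blocks) < 1L) {
          abort("window too short for the convolutional stack")
        }
      }
      list(branches = lapply(kernels, function(k) {
             init_conv_stack(spec$n_cnn_blocks, M, hid, k)
           }),
           head = list(W = init_linear(2L * hid, 2L), b = numeric(2L)))
    },
    "LSTM" = list(rnn = init_recurrent_stack(spec$n_recurrent_blocks, M, hid, 4L),
                  head = list(W = init_linear(hid, 2L), b = numeric(2L))),
    "GRU" = list(rnn = init_recurrent_stack(spec$n_recurrent_blocks, M, hid, 3L),
                 head = list(W = init_linear(hid, 2L), b = numeric(2L))),
    "CNN+LSTM" = ,
    "CNN+GRU" = {
      if (conv_chain_len(L, 5L, 3L) < 1L) {
        abort("window too short for the convolutional stack")
      }
      gates <- if (spec$family == "CNN+LSTM") 4L else 3L
      list(convs = init_conv_stack(3L, M, hid, 5L),
           rnn = init_recurrent_stack(3L, hid, hid, gates),
           head = list(W = init_linear(hid, 2L), b = numeric(2L)))
    }
  )
  cfg$kernels <- if (spec$family == "CNN") c(5L, 3L) else 5L
  structure(list(family = spec$family, config = cfg, params = params),
            class = c("baseline_model", "gait_model"))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s, M=%d L=%d, hidden=%d (%s params)%s\n",
              x$family, x$config$n_channels, x$config$window_len,
              x$config$hidden_dim,
              format(length(params_flatten(x$params)), big.mark = ","),
              if (is.null(x$history)) "" else " [trained]"))
  invisible(x)
}

# ---- 1-D convolution over arrays (C_in, T, B) -----------------------------

conv1d_fwd <- function(X, W, b) {
  dims <- dim(X)
  C <- dims[1]; T_in <- dims[2]; B <- dims[3]
  K <- dim(W)[3]
  T_out <- T_in - K + 1L
  X2 <- matrix(X, C, T_in * B)
  Y2 <- matrix(0, dim(W)[1], T_out * B)
  for (k in seq_len(K)) {
    idx <- as.vector(outer(k:(k + T_out - 1L), (0:(B - 1L)) * T_in, `+`))
    Y2 <- Y2 + matrix(W[, , k], dim(W)[1]) %*% X2[, idx, drop = FALSE]
  }
  Y2 <- Y2 + b
  array(Y2, dim = c(dim(W)[1], T_out, B))
}

conv1d_bwd <- function(X, W, dY) {
  dims <- dim(X)
  C <- dims[1]; T_in <- dims[2]; B <- dims[3]
  K <- dim(W)[3]
  T_out <- dim(dY)[2]
  X2 <- matrix(X, C, T_in * B)
  dY2 <- matrix(dY, dim(W)[1], T_out * B)
  dX2 <- matrix(0, C, T_in * B)
  dW <- array(0, dim = dim(W))
  for (k in seq_len(K)) {
    idx <- as.vector(outer(k:(k + T_out - 1L), (0:(B - 1L)) * T_in, `+`))
    dW[, , k] <- dY2 %*% t(X2[, idx, drop = FALSE])
    dX2[, idx] <- dX2[, idx] + t(matrix(W[, , k], dim(W)[1])) %*% dY2
  }
  list(dX = array(dX2, dim = dims), dW = dW, db = rowSums(dY2))
}

pool2_fwd <- function(X) {
  T_in <- dim(X)[2]
  T_out <- T_in %/% 2L
  (X[, 2L * seq_len(T_out) - 1L, , drop = FALSE] +
     X[, 2L * seq_len(T_out), , drop = FALSE]) / 2
}

pool2_bwd <- function(dY, T_in) {
  dims <- dim(dY)
  dX <- array(0, dim = c(dims[1], T_in, dims[3]))
  T_out <- dims[2]
  dX[, 2L * seq_len(T_out) - 1L, ] <- dY / 2
  dX[, 2L * seq_len(T_out), ] <- dY / 2
  dX
}

conv_stack_fwd <- function(X, convs) {
  caches <- vector("list", length(convs))
  for (b in seq_along(convs)) {
    Z <- conv1d_fwd(X, convs[[b]]$W, convs[[b]]$b)
    A <- Z; A[A < 0] <- 0
    P <- pool2_fwd(A)
    caches[[b]] <- list(X = X, Z = Z, T_pre_pool = dim(A)[2])
    X <- P
  }
  list(out = X, caches = caches)
}

conv_stack_bwd <- function(dOut, convs, caches) {
  grads <- vector("list", length(convs))
  for (b in rev(seq_along(convs))) {
    cc <- caches[[b]]
    dA <- pool2_bwd(dOut, cc$T_pre_pool)
    dZ <- dA * (cc$Z > 0)
    cb <- conv1d_bwd(cc$X, convs[[b]]$W, dZ)
    grads[[b]] <- list(W = cb$dW, b = cb$db)
    dOut <- cb$dX
  }
  list(grads = grads, dX = dOut)
}

# ---- recurrent layers over arrays (C, T, B) -------------------------------

lstm_layer_fwd <- function(X, lp) {
  Tn <- dim(X)[2]; B <- dim(X)[3]
  H <- ncol(lp$U)
  hid <- H %/% 4L
  h <- matrix(0, B, hid); cst <- matrix(0, B, hid)
  Hs <- array(0, dim = c(B, hid, Tn))
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- t(matrix(X[, t, ], dim(X)[1], B))
    G <- xt %*% lp$W + h %*% lp$U + rep(lp$b, each = B)
    i <- sigmoid(G[, 1:hid, drop = FALSE])
    f <- sigmoid(G[, hid + 1:hid, drop = FALSE])
    g <- tanh(G[, 2L * hid + 1:hid, drop = FALSE])
    o <- sigmoid(G[, 3L * hid + 1:hid, drop = FALSE])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cst,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; cst <- c_new
    Hs[, , t] <- h
  }
  list(Hs = Hs, cache = cache)
}

lstm_layer_bwd <- function(dHs, lp, cache) {
  Tn <- dim(dHs)[3]; B <- dim(dHs)[1]
  hid <- dim(dHs)[2]
  dW <- lp$W * 0; dU <- lp$U * 0; db <- lp$b * 0
  dh_next <- matrix(0, B, hid); dc_next <- matrix(0, B, hid)
  dX <- array(0, dim = c(nrow(lp$W), Tn, B))
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dHs[, , t] + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + t(cc$xt) %*% dG
    dU <- dU + t(cc$h_prev) %*% dG
    db <- db + colSums(dG)
    dh_next <- dG %*% t(lp$U)
    dX[, t, ] <- t(dG %*% t(lp$W))
  }
  list(grads = list(W = dW, U = dU, b = db), dX = dX)
}

gru_layer_fwd <- function(X, lp) {
  Tn <- dim(X)[2]; B <- dim(X)[3]
  hid <- ncol(lp$U) %/% 3L
  h <- matrix(0, B, hid)
  Hs <- array(0, dim = c(B, hid, Tn))
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- t(matrix(X[, t, ], dim(X)[1], B))
    Gx <- xt %*% lp$W + rep(lp$b, each = B)
    Gh <- h %*% lp$U
    z <- sigmoid(Gx[, 1:hid, drop = FALSE] + Gh[, 1:hid, drop = FALSE])
    r <- sigmoid(Gx[, hid + 1:hid, drop = FALSE] + Gh[, hid + 1:hid, drop = FALSE])
    hn_h <- Gh[, 2L * hid + 1:hid, drop = FALSE]
    n <- tanh(Gx[, 2L * hid + 1:hid, drop = FALSE] + r * hn_h)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, n = n, hn_h = hn_h)
    h <- h_new
    Hs[, , t] <- h
  }
  list(Hs = Hs, cache = cache)
}

gru_layer_bwd <- function(dHs, lp, cache) {
  Tn <- dim(dHs)[3]; B <- dim(dHs)[1]
  hid <- dim(dHs)[2]
  dW <- lp$W * 0; dU <- lp$U * 0; db <- lp$b * 0
  dh_next <- matrix(0, B, hid)
  dX <- array(0, dim = c(nrow(lp$W), Tn, B))
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dHs[, , t] + dh_next
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    dn_pre <- dn * (1 - cc$n^2)
    dr <- dn_pre * cc$hn_h
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    dGx <- cbind(dz_pre, dr_pre, dn_pre)
    dGh <- cbind(dz_pre, dr_pre, dn_pre * cc$r)
    dW <- dW + t(cc$xt) %*% dGx
    db <- db + colSums(dGx)
    dU <- dU + t(cc$h_prev) %*% dGh
    dh_prev <- dh_prev + dGh %*% t(lp$U)
    dh_next <- dh_prev
    dX[, t, ] <- t(dGx %*% t(lp$W))
  }
  list(grads = list(W = dW, U = dU, b = db), dX = dX)
}

rnn_stack_fwd <- function(X, layers, kind) {
  fwd <- if (kind == "lstm") lstm_layer_fwd else gru_layer_fwd
  caches <- vector("list", length(layers))
  Hs <- NULL
  for (l in seq_along(layers)) {
    res <- fwd(X, layers[[l]])
    caches[[l]] <- res$cache
    Hs <- res$Hs
    X <- aperm(Hs, c(2L, 3L, 1L)) # (hid, T, B) feeds the next layer
  }
  list(Hs = Hs, caches = caches)
}

rnn_stack_bwd <- function(dHs_top, layers, caches, kind) {
  bwd <- if (kind == "lstm") lstm_layer_bwd else gru_layer_bwd
  grads <- vector("list", length(layers))
  dHs <- dHs_top
  dX <- NULL
  for (l in rev(seq_along(layers))) {
    res <- bwd(dHs, layers[[l]], caches[[l]])
    grads[[l]] <- res$grads
    dX <- res$dX # (C, T, B)
    if (l > 1L) dHs <- aperm(dX, c(3L, 1L, 2L)) # back to (B, hid, T)
  }
  list(grads = grads, dX = dX)
}

# ---- family-level batched forward/backward --------------------------------

baseline_forward_batch <- function(Xb, params, config, training = FALSE) {
  B <- dim(Xb)[3]
  fam <- config$family
  if (fam == "CNN") {
    b1 <- conv_stack_fwd(Xb, params$branches[[1]])
    b2 <- conv_stack_fwd(Xb, params$branches[[2]])
    g1 <- t(apply(b1$out, c(1L, 3L), mean))  # B x F
    g2 <- t(apply(b2$out, c(1L, 3L), mean))
    feat <- cbind(g1, g2)
    Y <- feat %*% params$head$W + rep(params$head$b, each = B)
    list(Y = Y, cache = list(b1 = b1, b2 = b2, feat = feat, B = B))
  } else if (fam %in% c("LSTM", "GRU")) {
    kind <- tolower(fam)
    rs <- rnn_stack_fwd(Xb, params$rnn, kind)
    Tn <- dim(rs$Hs)[3]
    h_last <- rs$Hs[, , Tn, drop = FALSE][, , 1L]
    if (is.null(dim(h_last))) h_last <- matrix(h_last, nrow = B)
    Y <- h_last %*% params$head$W + rep(params$head$b, each = B)
    list(Y = Y, cache = list(rs = rs, h_last = h_last, Tn = Tn, B = B))
  } else { # CNN+LSTM / CNN+GRU
    kind <- if (fam == "CNN+LSTM") "lstm" else "gru"
    cs <- conv_stack_fwd(Xb, params$convs)
    rs <- rnn_stack_fwd(cs$out, params$rnn, kind)
    Tn <- dim(rs$Hs)[3]
    h_last <- rs$Hs[, , Tn, drop = FALSE][, , 1L]
    if (is.null(dim(h_last))) h_last <- matrix(h_last, nrow = B)
    Y <- h_last %*% params$head$W + rep(params$head$b, each = B)
    list(Y = Y, cache = list(cs = cs, rs = rs, h_last = h_last, Tn = Tn, B = B))
  }
}

baseline_backward_batch <- function(dY, params, config, cache) {
  fam <- config$family
  B <- cache$B
  if (fam == "CNN") {
    g <- list(branches = vector("list", 2L), head = list())
    g$head$W <- t(cache$feat) %*% dY
    g$head$b <- colSums(dY)
    dfeat <- dY %*% t(params$head$W)
    Fh <- ncol(dfeat) %/% 2L
    for (br in 1:2) {
      out <- cache[[c("b1", "b2")[br]]]$out
      T_out <- dim(out)[2]
      dg <- dfeat[, ((br - 1L) * Fh + 1L):(br * Fh), drop = FALSE]
      dout <- aperm(array(rep(t(dg) / T_out, times = T_out),
                          dim = c(Fh, B, T_out)), c(1L, 3L, 2L))
      cb <- conv_stack_bwd(dout, params$branches[[br]],
                           cache[[c("b1", "b2")[br]]]$caches)
      g$branches[[br]] <- cb$grads
    }
    g
  } else if (fam %in% c("LSTM", "GRU")) {
    kind <- tolower(fam)
    g <- list(rnn = NULL, head = list())
    g$head$W <- t(cache$h_last) %*% dY
    g$head$b <- colSums(dY)
    dh_last <- dY %*% t(params$head$W)
    dHs <- array(0, dim = dim(cache$rs$Hs))
    dHs[, , cache$Tn] <- dh_last
    rb <- rnn_stack_bwd(dHs, params$rnn, cache$rs$caches, kind)
    g$rnn <- rb$grads
    g
  } else {
    kind <- if (fam == "CNN+LSTM") "lstm" else "gru"
    g <- list(convs = NULL, rnn = NULL, head = list())
    g$head$W <- t(cache$h_last) %*% dY
    g$head$b <- colSums(dY)
    dh_last <- dY %*% t(params$head$W)
    dHs <- array(0, dim = dim(cache$rs$Hs))
    dHs[, , cache$Tn] <- dh_last
    rb <- rnn_stack_bwd(dHs, params$rnn, cache$rs$caches, kind)
    g$rnn <- rb$grads
    cb <- conv_stack_bwd(rb$dX, params$convs, cache$cs$caches)
    g$convs <- cb$grads
    g
  }
}
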