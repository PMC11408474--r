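# Vectorised batch forward/backward for the patch transformer.
#
# Layout convention: a batch of B windows (each M channels x L steps) becomes
# one big activation matrix of (S * M * B) rows by d columns, where
# S = L/patch_len + 1 sequence positions. Rows are grouped by sequence
# (channel i of window b), ordered channel-fastest, position s varying within
# a block. All linear maps are then single large matrix products; only the
# S x S attention kernels loop over sequences and heads.
# Gradient correctness is pinned by finite-difference tests and agreement
# with the reference single-window forward (model-forward.R).

drop_mask <- function(nr, nc, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(x, m) if (is.null(m)) x else x * m

ptt_embed_batch <- function(Xb, params, config) {
  dims <- dim(Xb)
  M <- dims[1]; L <- dims[2]; B <- dims[3]
  P <- config$patch_len
  nP <- config$n_patches
  S <- config$seq_len
  d <- config$embed_dim
  nseq <- M * B
  PM <- t(matrix(aperm(Xb, c(2L, 1L, 3L)), nrow = P))
  proj <- PM %*% params$W_t + rep(params$b_t, each = nrow(PM))
  H <- matrix(0, S * nseq, d)
  idx_tok <- seq.int(1L, by = S, length.out = nseq)
  tok_idx <- if (config$per_channel_tokens) rep_len(seq_len(M), nseq) else rep(1L, nseq)
  H[idx_tok, ] <- params$tokens[tok_idx, , drop = FALSE] +
    rep(params$P_t[1L, ], each = nseq)
  H[-idx_tok, ] <- proj + params$P_t[rep(2:S, times = nseq), , drop = FALSE]
  list(H = H, PM = PM, idx_tok = idx_tok, tok_idx = tok_idx,
       nseq = nseq, S = S)
}

ptt_encoder_layer_batch <- function(H, lp, config, nseq, training) {
  S <- config$seq_len
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  Q <- H %*% lp$W_q
  K <- H %*% lp$W_k
  V <- H %*% lp$W_v
  att <- .attn_fwd(Q, K, V, S, h, scale)
  A <- att$A # cube S x (S*h) x nseq; head j in columns (j-1)*S+1 .. j*S
  O <- att$O
  mha <- O %*% lp$W_o
  m1 <- drop_mask(nrow(H), ncol(H), config$dropout, training)
  r1 <- H + apply_mask(mha, m1)
  ln1 <- layernorm_fwd(r1, lp$ln1_gamma, lp$ln1_beta)
  a <- ln1$out
  pre <- a %*% lp$W_1 + rep(lp$b_1, each = nrow(a))
  hid <- gelu(pre)
  ffn <- hid %*% lp$W_2 + rep(lp$b_2, each = nrow(a))
  m2 <- drop_mask(nrow(H), ncol(H), config$dropout, training)
  r2 <- a + apply_mask(ffn, m2)
  ln2 <- layernorm_fwd(r2, lp$ln2_gamma, lp$ln2_beta)
  if (any(!is.finite(ln2$out))) abort("encoder layer: non-finite activations")
  list(out = ln2$out,
       cache = list(H = H, Q = Q, K = K, V = V, A = A, O = O,
                    m1 = m1, ln1 = ln1, a = a, pre = pre, hid = hid,
                    m2 = m2, ln2 = ln2))
}

ptt_encoder_layer_batch_bwd <- function(dOut, lp, config, cache, nseq) {
  S <- config$seq_len
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  g <- list()
  l2 <- layernorm_bwd(cache$ln2, lp$ln2_gamma, dOut)
  g$ln2_gamma <- l2$dgamma; g$ln2_beta <- l2$dbeta
  dr2 <- l2$dx
  da <- dr2
  dffn <- apply_mask(dr2, cache$m2)
  g$W_2 <- t(cache$hid) %*% dffn
  g$b_2 <- colSums(dffn)
  dhid <- dffn %*% t(lp$W_2)
  dpre <- dhid * gelu_grad(cache$pre)
  g$W_1 <- t(cache$a) %*% dpre
  g$b_1 <- colSums(dpre)
  da <- da + dpre %*% t(lp$W_1)
  l1 <- layernorm_bwd(cache$ln1, lp$ln1_gamma, da)
  g$ln1_gamma <- l1$dgamma; g$ln1_beta <- l1$dbeta
  dr1 <- l1$dx
  dH <- dr1
  dmha <- apply_mask(dr1, cache$m1)
  g$W_o <- t(cache$O) %*% dmha
  dO <- dmha %*% t(lp$W_o)
  datt <- .attn_bwd(dO, cache$Q, cache$K, cache$V, cache$A, S, h, scale)
  dQ <- datt$dQ
  dK <- datt$dK
  dV <- datt$dV
  g$W_q <- t(cache$H) %*% dQ
  g$W_k <- t(cache$H) %*% dK
  g$W_v <- t(cache$H) %*% dV
  dH <- dH + dQ %*% t(lp$W_q) + dK %*% t(lp$W_k) + dV %*% t(lp$W_v)
  list(dH = dH, grads = g)
}

ptt_cross_batch <- function(Tok, params, config, B) {
  cp <- params$cross
  M <- nrow(Tok) %/% B
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  q <- matrix(cp$T_prime, 1L) %*% cp$W_q
  K <- Tok %*% cp$W_k
  V <- Tok %*% cp$W_v
  W <- array(0, dim = c(M, B, h))
  F0 <- matrix(0, B, config$embed_dim)
  grp <- rep(seq_len(B), each = M)
  for (j in seq_len(h)) {
    cols <- head_cols(j, dk)
    logits <- matrix(K[, cols, drop = FALSE] %*% q[1L, cols] / scale, M, B)
    logits <- logits - rep(apply(logits, 2L, max), each = M)
    e <- exp(logits)
    Wj <- e / rep(colSums(e), each = M)
    W[, , j] <- Wj
    F0[, cols] <- rowsum(V[, cols, drop = FALSE] * as.vector(Wj), grp)
  }
  Feat <- F0 %*% cp$W_o
  list(Feat = Feat, cache = list(Tok = Tok, q = q, K = K, V = V, W = W,
                                 F0 = F0, M = M, B = B))
}

ptt_cross_batch_bwd <- function(dFeat, params, config, cache) {
  cp <- params$cross
  M <- cache$M; B <- cache$B
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  g <- list()
  g$W_o <- t(cache$F0) %*% dFeat
  dF0 <- dFeat %*% t(cp$W_o)
  dK <- matrix(0, M * B, config$embed_dim)
  dV <- matrix(0, M * B, config$embed_dim)
  dq <- matrix(0, 1L, config$embed_dim)
  expand <- rep(seq_len(B), each = M)
  for (j in seq_len(h)) {
    cols <- head_cols(j, dk)
    Wj <- cache$W[, , j]
    wv <- as.vector(Wj)
    dFh <- dF0[, cols, drop = FALSE]
    dWV <- dFh[expand, , drop = FALSE]
    dV[, cols] <- dWV * wv
    dw <- matrix(rowSums(dWV * cache$V[, cols, drop = FALSE]), M, B)
    dlog <- Wj * (dw - rep(colSums(Wj * dw), each = M))
    dlv <- as.vector(dlog) / scale
    dq[1L, cols] <- colSums(cache$K[, cols, drop = FALSE] * dlv)
    dK[, cols] <- dlv %o% cache$q[1L, cols]
  }
  g$W_k <- t(cache$Tok) %*% dK
  g$W_v <- t(cache$Tok) %*% dV
  g$W_q <- t(matrix(cp$T_prime, 1L)) %*% dq
  g$T_prime <- as.numeric(dq %*% t(cp$W_q))
  dTok <- dK %*% t(cp$W_k) + dV %*% t(cp$W_v)
  list(dTok = dTok, grads = g)
}

# full batch forward. Xb: array M x L x B (already normalised).
ptt_forward_batch <- function(Xb, params, config, training = FALSE) {
  B <- dim(Xb)[3]
  emb <- ptt_embed_batch(Xb, params, config)
  H <- emb$H
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    res <- ptt_encoder_layer_batch(H, params$layers[[l]], config,
                                   emb$nseq, training)
    H <- res$out
    layer_caches[[l]] <- res$cache
  }
  Tok <- H[emb$idx_tok, , drop = FALSE]
  ca <- ptt_cross_batch(Tok, params, config, B)
  hd <- params$head
  pre <- ca$Feat %*% hd$W_1 + rep(hd$b_1, each = B)
  hid <- gelu(pre)
  Y <- hid %*% hd$W_2 + rep(hd$b_2, each = B)
  list(Y = Y,
       cross_weights = ca$cache$W, # M x B x h
       cache = list(emb = emb, layers = layer_caches, cross = ca$cache,
                    Feat = ca$Feat, pre = pre, hid = hid, B = B))
}

ptt_backward_batch <- function(dY, params, config, cache) {
  hd <- params$head
  B <- cache$B
  g <- list()
  g$head <- list()
  g$head$W_2 <- t(cache$hid) %*% dY
  g$head$b_2 <- colSums(dY)
  dhid <- dY %*% t(hd$W_2)
  dpre <- dhid * gelu_grad(cache$pre)
  g$head$W_1 <- t(cache$Feat) %*% dpre
  g$head$b_1 <- colSums(dpre)
  dFeat <- dpre %*% t(hd$W_1)
  cb <- ptt_cross_batch_bwd(dFeat, params, config, cache$cross)
  g$cross <- cb$grads
  emb <- cache$emb
  dH <- matrix(0, emb$S * emb$nseq, config$embed_dim)
  dH[emb$idx_tok, ] <- cb$dTok
  for (l in rev(seq_len(config$n_layers))) {
    lb <- ptt_encoder_layer_batch_bwd(dH, params$layers[[l]], config,
                                      cache$layers[[l]], emb$nseq)
    dH <- lb$dH
    g$layers[[l]] <- lb$grads
  }
  if (config$n_layers == 0L) g$layers <- list()
  dtok_rows <- dH[emb$idx_tok, , drop = FALSE]
  n_tok <- nrow(params$tokens)
  g$tokens <- rowsum(dtok_rows, emb$tok_idx)
  if (nrow(g$tokens) < n_tok) { # channels absent from tok_idx (never happens)
    full <- matrix(0, n_tok, config$embed_dim)
    full[as.integer(rownames(g$tokens)), ] <- g$tokens
    g$tokens <- full
  }
  dimnames(g$tokens) <- NULL
  dproj <- dH[-emb$idx_tok, , drop = FALSE]
  g$P_t <- rbind(colSums(dtok_rows),
                 rowsum(dproj, rep(2:emb$S, times = emb$nseq))[, , drop = FALSE])
  dimnames(g$P_t) <- NULL
  g$W_t <- t(emb$PM) %*% dproj
  g$b_t <- colSums(dproj)
  # mirror the parameter tree's field order exactly (Adam pairs by position)
  reorder_like(params, g)
}

reorder_like <- function(ref, x) {
  if (!is.list(ref)) return(x)
  nm <- names(ref)
  out <- if (is.null(nm)) x else x[nm]
  for (i in seq_along(ref)) out[[i]] <- reorder_like(ref[[i]], out[[i]])
  names(out) <- nm
  out
}

# evaluation-mode prediction over a dataset, optionally keeping the
# cross-attention channel weights per window
ptt_predict_internal <- function(model, dataset, batch_size = 128L,
                                 keep_weights = FALSE) {
  K <- n_windows(dataset)
  Y <- matrix(0, K, 2L)
  h <- model$config$n_heads
  M <- model$config$n_channels
  Wts <- if (keep_weights) array(0, dim = c(M, K, h)) else NULL
  starts <- seq.int(1L, K, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, K)
    Xb <- normalise_windows(dataset$windows[, , idx, drop = FALSE], model$norm)
    fw <- ptt_forward_batch(Xb, model$params, model$config, training = FALSE)
    Y[idx, ] <- fw$Y
    if (keep_weights) Wts[, idx, ] <- fw$cross_weights
  }
  list(Y = Y, weights = Wts)
}

normalise_windows <- function(Xb, norm) {
  if (is.null(norm)) return(Xb)
  (Xb - norm$mu) / norm$sd # recycles over the channel (first) dimension
}
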