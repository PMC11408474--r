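# Reference (single-window) forward pass of the patch transformer.
# These functions define the model's semantics operation by operation; the
# vectorised batch implementation used for training (model-batch.R) is
# required by the tests to agree with them to near machine precision.

attn_scale <- function(config) {
  if (config$scale_by_full_d) sqrt(config$embed_dim)
  else sqrt(config$embed_dim / config$n_heads)
}

head_cols <- function(j, dk) ((j - 1L) * dk + 1L):(j * dk)

#' Patch-embed one channel's window
#'
#' Cuts a length-L series into `L / patch_len` contiguous non-overlapping
#' patches, projects each patch with the shared linear map, prepends the
#' channel's learnable token, and adds the positional table row-wise (the
#' token receives row 1).
#'
#' @param series Numeric vector of length `config$window_len`.
#' @param channel_index Which channel's learnable token to prepend.
#' @param params,config Model parameters and [ptt_config()].
#' @return A `(L/patch_len + 1) x embed_dim` matrix.
#' @export
patch_embed <- function(series, channel_index, params, config) {
  if (length(series) != config$window_len) {
    abort("patch_embed: series length must equal window_len")
  }
  P <- config$patch_len
  patches <- matrix(series, nrow = P)      # column r = patch r
  proj <- t(patches) %*% params$W_t +
    rep(params$b_t, each = config$n_patches)
  tok_i <- if (config$per_channel_tokens) channel_index else 1L
  rbind(params$tokens[tok_i, ], proj) + params$P_t
}

multi_head_attention <- function(x, W_q, W_k, W_v, W_o, config,
                                 capture_attention = FALSE) {
  S <- nrow(x)
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  Q <- x %*% W_q
  K <- x %*% W_k
  V <- x %*% W_v
  out <- matrix(0, S, config$embed_dim)
  attn <- if (capture_attention) array(0, dim = c(h, S, S)) else NULL
  for (j in seq_len(h)) {
    cols <- head_cols(j, dk)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / scale)
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    if (capture_attention) attn[j, , ] <- A
  }
  list(out = out %*% W_o, attention = attn)
}

#' One post-norm transformer encoder layer
#'
#' Residual wiring follows the printed post-norm form:
#' `a = LayerNorm(x + MultiHead(x, x, x))`, then
#' `out = LayerNorm(a + FFN(a))` with `FFN(z) = GELU(z W1 + b1) W2 + b2`.
#' Attention logits are scaled by `sqrt(d/h)` (or `sqrt(d)` when
#' `scale_by_full_d` is set).
#'
#' @param x `S x d` input matrix (token row first).
#' @param layer_params One element of `params$layers`.
#' @param config A [ptt_config()].
#' @param capture_attention Keep the per-head attention matrices?
#' @return List with `out` (`S x d`) and `attention` (`h x S x S` array or
#'   `NULL`).
#' @export
encoder_layer <- function(x, layer_params, config, capture_attention = FALSE) {
  if (nrow(x) < 1L) abort("encoder_layer: empty input")
  lp <- layer_params
  mha <- multi_head_attention(x, lp$W_q, lp$W_k, lp$W_v, lp$W_o, config,
                              capture_attention)
  a <- layernorm_fwd(x + mha$out, lp$ln1_gamma, lp$ln1_beta)$out
  ffn <- gelu(a %*% lp$W_1 + rep(lp$b_1, each = nrow(a))) %*% lp$W_2 +
    rep(lp$b_2, each = nrow(a))
  out <- layernorm_fwd(a + ffn, lp$ln2_gamma, lp$ln2_beta)$out
  if (any(!is.finite(out))) abort("encoder_layer: non-finite activations")
  list(out = out, attention = mha$attention)
}

#' Encode one embedded channel and extract its token
#'
#' Applies the N encoder layers to a patch-embedded channel and returns the
#' encoded channel token (row 1), which summarises the channel's window.
#'
#' @param embedded Output of [patch_embed()].
#' @param params,config Model parameters and config.
#' @param capture_attention Keep per-layer attention matrices?
#' @return List with `token` (length-d vector) and `attention` (list of
#'   per-layer `h x S x S` arrays, or `NULL`).
#' @export
encode_channel <- function(embedded, params, config,
                           capture_attention = FALSE) {
  x <- embedded
  attn <- if (capture_attention) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    res <- encoder_layer(x, params$layers[[l]], config, capture_attention)
    x <- res$out
    if (capture_attention) attn[[l]] <- res$attention
  }
  list(token = x[1L, ], attention = attn)
}

#' Pool channel tokens with cross-attention
#'
#' The learnable global time-series token queries the M encoded channel
#' tokens with dot-product attention; the per-head softmax rows over channels
#' are the model's channel-importance weights, and the head-concatenated,
#' output-projected result is the fused feature vector.
#'
#' @param T_tokens `M x d` matrix of encoded channel tokens.
#' @param params,config Model parameters and config.
#' @return List with `feature` (length-d vector) and `weights`
#'   (`n_heads x M` matrix; every row sums to 1).
#' @export
cross_attend <- function(T_tokens, params, config) {
  M <- nrow(T_tokens)
  if (is.null(M) || M < 1L) abort("cross_attend: need at least one channel token")
  cp <- params$cross
  h <- config$n_heads
  dk <- config$embed_dim %/% h
  scale <- attn_scale(config)
  q <- matrix(cp$T_prime, 1L) %*% cp$W_q
  K <- T_tokens %*% cp$W_k
  V <- T_tokens %*% cp$W_v
  weights <- matrix(0, h, M)
  feat <- numeric(config$embed_dim)
  for (j in seq_len(h)) {
    cols <- head_cols(j, dk)
    w <- softmax_rows(q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / scale)
    weights[j, ] <- w
    feat[cols] <- w %*% V[, cols, drop = FALSE]
  }
  list(feature = as.numeric(matrix(feat, 1L) %*% cp$W_o), weights = weights)
}

mlp_head <- function(feature, head) {
  hid <- gelu(matrix(feature, 1L) %*% head$W_1 + matrix(head$b_1, 1L))
  as.numeric(hid %*% head$W_2 + matrix(head$b_2, 1L))
}

#' Full forward pass over one window
#'
#' Patch-embeds and encodes every channel independently, collects the encoded
#' channel tokens, pools them with the global cross-attention token and maps
#' the fused feature through the prediction MLP to the two-component
#' (sin, cos) output. Evaluation mode: dropout is never applied here, so the
#' result is deterministic.
#'
#' @param window `M x L` numeric matrix (channels in model order).
#' @param model A [ptt_model()] (or pass `params`/`config` explicitly).
#' @param capture Keep encoder self-attention matrices for
#'   [attention_scope()]?
#' @param params,config Optional explicit parameter set / config.
#' @return A `ptt_trace`: list with `y_pred` (length 2), `phase_pred`,
#'   `channel_tokens` (`M x d`), `cross_attention` (`n_heads x M`), and
#'   `encoder_attention` (per-channel list of per-layer `h x S x S` arrays
#'   when `capture = TRUE`).
#' @export
ptt_forward <- function(window, model = NULL, capture = FALSE,
                        params = model$params, config = model$config) {
  if (!is.matrix(window) || nrow(window) != config$n_channels ||
      ncol(window) != config$window_len) {
    abort("ptt_forward: window must be an n_channels x window_len matrix")
  }
  M <- config$n_channels
  tokens <- matrix(0, M, config$embed_dim)
  enc_attn <- if (capture) vector("list", M) else NULL
  for (i in seq_len(M)) {
    emb <- patch_embed(window[i, ], i, params, config)
    enc <- encode_channel(emb, params, config, capture_attention = capture)
    tokens[i, ] <- enc$token
    if (capture) enc_attn[[i]] <- enc$attention
  }
  ca <- cross_attend(tokens, params, config)
  y <- mlp_head(ca$feature, params$head)
  structure(
    list(y_pred = y,
         phase_pred = cartesian_to_phase(y[1], y[2]),
         channel_tokens = tokens,
         cross_attention = ca$weights,
         encoder_attention = enc_attn),
    class = "ptt_trace"
  )
}
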