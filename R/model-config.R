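#' Configuration of the channel-token patch transformer
#'
#' Hyper-parameters of the interpretable patch transformer: each sensor
#' channel's window is cut into non-overlapping patches of `patch_len` steps,
#' linearly embedded into `embed_dim` dimensions, prefixed with a learnable
#' per-channel token and encoded by `n_layers` post-norm transformer layers;
#' a learnable global token then pools the per-channel tokens through
#' cross-attention, whose softmax weights are the channel-importance scores,
#' and a small MLP maps the pooled feature to the two-component (sin, cos)
#' phase prediction.
#'
#' The publication-scale configuration is `embed_dim = 768`, `n_heads = 12`,
#' `n_layers = 6`, `patch_len = 10`; reduced configurations (e.g.
#' `embed_dim = 64`, `n_layers = 2`, `n_heads = 4`) train on a CPU in
#' minutes and are used throughout the package's tests.
#'
#' @param n_channels Number of input channels M.
#' @param window_len Window length L in time steps; must be a multiple of
#'   `patch_len`.
#' @param patch_len Patch length (default 10 steps).
#' @param embed_dim Embedding width d; must be a multiple of `n_heads`.
#' @param n_heads Attention heads h (per-head width `d / h`).
#' @param n_layers Encoder depth N (0 is allowed for degenerate testing
#'   configurations and reduces the encoder to the identity).
#' @param ffn_dim Feed-forward hidden width (default `4 * embed_dim`).
#' @param head_hidden Hidden width of the prediction MLP (default
#'   `embed_dim`).
#' @param dropout Dropout rate applied to the attention and feed-forward
#'   sub-layer outputs during training (default 0.1; never active at
#'   evaluation time).
#' @param scale_by_full_d If `TRUE`, attention logits are scaled by
#'   `sqrt(d)` instead of the standard per-head `sqrt(d/h)`.
#' @param per_channel_tokens If `TRUE` (default) each channel gets its own
#'   learnable token so that channel identity survives the shared patch
#'   projection; if `FALSE` a single token is shared.
#' @return A `ptt_config` list.
#' @export
ptt_config <- function(n_channels, window_len = 100L, patch_len = 10L,
                       embed_dim = 64L, n_heads = 4L, n_layers = 2L,
                       ffn_dim = 4L * embed_dim, head_hidden = embed_dim,
                       dropout = 0.1, scale_by_full_d = FALSE,
                       per_channel_tokens = TRUE) {
  cfg <- list(n_channels = as.integer(n_channels),
              window_len = as.integer(window_len),
              patch_len = as.integer(patch_len),
              embed_dim = as.integer(embed_dim),
              n_heads = as.integer(n_heads),
              n_layers = as.integer(n_layers),
              ffn_dim = as.integer(ffn_dim),
              head_hidden = as.integer(head_hidden),
              dropout = dropout,
              scale_by_full_d = isTRUE(scale_by_full_d),
              per_channel_tokens = isTRUE(per_channel_tokens))
  with(cfg, {
    if (n_channels < 1L) abort("n_channels must be >= 1")
    if (window_len %% patch_len != 0L) {
      abort("window_len must be a multiple of patch_len")
    }
    if (embed_dim %% n_heads != 0L) {
      abort("embed_dim must be a multiple of n_heads")
    }
    if (n_layers < 0L) abort("n_layers must be >= 0")
    if (min(patch_len, embed_dim, n_heads, ffn_dim, head_hidden) < 1L) {
      abort("all dimensions must be >= 1")
    }
    if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  })
  cfg$n_patches <- cfg$window_len %/% cfg$patch_len
  cfg$seq_len <- cfg$n_patches + 1L # + channel token
  structure(cfg, class = "ptt_config")
}

init_encoder_layer <- function(d, ffn) {
  list(W_q = init_linear(d, d), W_k = init_linear(d, d),
       W_v = init_linear(d, d), W_o = init_linear(d, d),
       W_1 = init_linear(d, ffn), b_1 = numeric(ffn),
       W_2 = init_linear(ffn, d), b_2 = numeric(d),
       ln1_gamma = rep(1, d), ln1_beta = numeric(d),
       ln2_gamma = rep(1, d), ln2_beta = numeric(d))
}

ptt_init_params <- function(config) {
  d <- config$embed_dim
  n_tok <- if (config$per_channel_tokens) config$n_channels else 1L
  list(
    W_t = init_linear(config$patch_len, d),
    b_t = numeric(d),
    tokens = matrix(trunc_normal(n_tok * d), n_tok, d),
    P_t = matrix(trunc_normal(config$seq_len * d), config$seq_len, d),
    layers = lapply(seq_len(config$n_layers), function(i) {
      init_encoder_layer(d, config$ffn_dim)
    }),
    cross = list(W_q = init_linear(d, d), W_k = init_linear(d, d),
                 W_v = init_linear(d, d), W_o = init_linear(d, d),
                 T_prime = trunc_normal(d)),
    head = list(W_1 = init_linear(d, config$head_hidden),
                b_1 = numeric(config$head_hidden),
                W_2 = init_linear(config$head_hidden, 2L),
                b_2 = numeric(2L))
  )
}

#' Create an (untrained) patch-transformer model
#'
#' @param config A [ptt_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `ptt_model`: list with `config` and `params` (all learnable
#'   weights: patch projection, per-channel tokens, positional table,
#'   encoder layers, cross-attention block with its global query token, and
#'   the prediction MLP).
#' @examples
#' m <- ptt_model(ptt_config(n_channels = 2, embed_dim = 16, n_heads = 2,
#'                           n_layers = 1), seed = 1)
#' @export
ptt_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ptt_config"))
  local_seed(seed)
  structure(list(config = config, params = ptt_init_params(config)),
            class = c("ptt_model", "gait_model"))
}

#' @export
print.ptt_model <- function(x, ...) {
  cfg <- x$config
  np <- length(params_flatten(x$params))
  cat(sprintf(
    "<ptt_model> M=%d L=%d P=%d d=%d heads=%d layers=%d (%s params)%s\n",
    cfg$n_channels, cfg$window_len, cfg$patch_len, cfg$embed_dim,
    cfg$n_heads, cfg$n_layers, format(np, big.mark = ","),
    if (is.null(x$history)) "" else " [trained]"))
  invisible(x)
}

# run code under a temporary RNG state derived from `seed`
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(NULL)
}
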