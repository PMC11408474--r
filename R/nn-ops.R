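# Shared numerical primitives for the hand-implemented networks.
# All backward passes in this package are written against these definitions
# and validated by finite-difference tests (see tests/testthat/test-gradients.R).

# GELU, tanh approximation (the standard transformer formulation):
# 0.5 * x * (1 + tanh(sqrt(2/pi) * (x + 0.044715 x^3)))
GELU_C <- sqrt(2 / pi)
gelu <- function(x) 0.5 * x * (1 + tanh(GELU_C * (x + 0.044715 * x * x * x)))
gelu_grad <- function(x) {
  t <- tanh(GELU_C * (x + 0.044715 * x * x * x))
  0.5 * (1 + t) + 0.5 * x * (1 - t * t) * GELU_C * (1 + 3 * 0.044715 * x * x)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax of a matrix (numerically stabilised)
softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

# backward of row-wise softmax: given A = softmax(S) and dA, return dS
softmax_rows_grad <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

LN_EPS <- 1e-5

# layer norm across columns of a row-major activation matrix.
# returns the output plus the per-row statistics needed for backprop.
layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * istd
  list(out = sweep(xhat, 2L, gamma, `*`) + rep(beta, each = nrow(x)),
       xhat = xhat, istd = istd)
}

layernorm_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, gamma, `*`)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- initialisation -------------------------------------------------------

# truncated normal (+-2 sd) used for learnable tokens / embeddings
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, sd = sd)
  while (any(bad <- abs(x) > 2 * sd)) x[bad] <- rnorm(sum(bad), sd = sd)
  x
}

# uniform fan-in initialisation for a linear map (rows = inputs)
init_linear <- function(n_in, n_out) {
  b <- 1 / sqrt(n_in)
  matrix(runif(n_in * n_out, -b, b), n_in, n_out)
}

# ---- parameter-tree utilities --------------------------------------------

# apply f elementwise over two parallel nested lists of numeric arrays
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

map_params <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, map_params, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

params_check_finite <- function(p) {
  ok <- TRUE
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else if (any(!is.finite(x))) ok <<- FALSE
    invisible(NULL)
  }
  walk(p)
  ok
}

# flatten a parameter tree to a single numeric vector (and back); used by
# the finite-difference gradient tests
params_flatten <- function(p) {
  unlist(p, use.names = FALSE)
}

params_unflatten <- function(template, v) {
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rebuild)
      names(out) <- names(x)
      out
    } else {
      n <- length(x)
      out <- v[(i + 1L):(i + n)]
      i <<- i + n
      dim(out) <- dim(x)
      out
    }
  }
  rebuild(template)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = map_params(params, function(x) x * 0),
       v = map_params(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, `-`)
  list(params = params, state = state)
}
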