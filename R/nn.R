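# Building blocks for the decoder: batch normalization, ELU, average
# pooling, inverted dropout, softmax cross-entropy, and Adam with a max-norm
# projection.  Activations flow as base-R arrays (channels x time x batch);
# the temporal convolutions call the compiled primitives in src/conv.cpp.
# The input gradient of a "same"-padded cross-correlation is the
# cross-correlation of the output gradient with the reversed kernel at the
# mirrored center, which is what tconv_dx exploits.

tconv <- function(x, K, center, depthwise) {
  nx_tconv(x, K, as.integer(center), depthwise)
}

tconv_dx <- function(dy, K, center, depthwise) {
  L <- ncol(K)
  nx_tconv(dy, K[, L:1, drop = FALSE], as.integer(L - 1L - center), depthwise)
}

tconv_kgrad <- function(x, dy, center, L, depthwise) {
  nx_tconv_kgrad(x, dy, as.integer(center), as.integer(L), depthwise)
}

# --- batch normalization ---------------------------------------------------
# "global": one statistic over the entire activation array (used per temporal
# map).  "row": one statistic per first-dimension index of a cube (used for
# the separable stage, one per map).  Training mode uses batch statistics and
# updates running statistics with momentum `mom`; evaluation mode applies the
# running statistics as a fixed per-map affine map.

bn_global_fwd <- function(x, gamma, beta, rm, rv, mom, eps, training) {
  if (training) {
    mo <- nx_bn_moments(x)
    mu <- mo[1]
    v <- mo[2]
    rm <- (1 - mom) * rm + mom * mu
    rv <- (1 - mom) * rv + mom * v
  } else {
    mu <- rm
    v <- rv
  }
  istd <- 1 / sqrt(v + eps)
  fw <- nx_bn_fwd(x, gamma, beta, mu, istd)
  list(y = fw$y,
       cache = list(xhat = fw$xhat, istd = istd, training = training),
       rm = rm, rv = rv)
}

bn_global_bwd <- function(dy, cache, gamma) {
  nx_bn_bwd(dy, cache$xhat, gamma, cache$istd, cache$training)
}

bn_row_fwd <- function(x, gamma, beta, rm, rv, mom, eps, training) {
  # x: C x T x B cube; statistics per first-dimension index
  if (training) {
    mu <- rowMeans(x, dims = 1)
    v <- rowMeans(x^2, dims = 1) - mu^2
    rm <- (1 - mom) * rm + mom * mu
    rv <- (1 - mom) * rv + mom * v
  } else {
    mu <- rm
    v <- rv
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * istd          # length-C vectors recycle along dim 1
  list(y = gamma * xhat + beta,
       cache = list(xhat = xhat, istd = istd, training = training),
       rm = rm, rv = rv)
}

bn_row_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  n <- prod(dim(xhat)[2:3])
  dgamma <- rowSums(dy * xhat, dims = 1)
  dbeta <- rowSums(dy, dims = 1)
  dxhat <- dy * gamma
  if (cache$training) {
    s1 <- rowSums(dxhat, dims = 1)
    s2 <- rowSums(dxhat * xhat, dims = 1)
    dx <- (cache$istd / n) * (n * dxhat - s1 - xhat * s2)
  } else {
    dx <- dxhat * cache$istd
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- activation / pooling / dropout ---------------------------------------

elu_fwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- expm1(x[neg])
  y
}

elu_bwd <- function(dy, y) {
  d <- dy
  neg <- y < 0
  d[neg] <- dy[neg] * (y[neg] + 1)
  d
}

pool_mat_fwd <- function(x, k) {
  # x: T x B matrix; truncating average pooling over time
  Tp <- nrow(x) %/% k
  xt <- x[seq_len(Tp * k), , drop = FALSE]
  dim(xt) <- c(k, Tp, ncol(x))
  colMeans(xt)
}

pool_mat_bwd <- function(dy, k, T_orig) {
  Tp <- nrow(dy)
  dx <- matrix(0, T_orig, ncol(dy))
  dx[seq_len(Tp * k), ] <- dy[rep(seq_len(Tp), each = k), , drop = FALSE] / k
  dx
}

pool_cube_fwd <- function(x, k) {
  d <- dim(x)
  Tp <- d[2] %/% k
  xt <- x[, seq_len(Tp * k), , drop = FALSE]
  xa <- aperm(xt, c(2, 1, 3))
  dim(xa) <- c(k, Tp, d[1], d[3])
  aperm(colMeans(xa), c(2, 1, 3))
}

pool_cube_bwd <- function(dy, k, T_orig) {
  d <- dim(dy)
  dya <- aperm(dy, c(2, 1, 3))
  dxa <- dya[rep(seq_len(d[2]), each = k), , , drop = FALSE] / k
  dx <- array(0, dim = c(d[1], T_orig, d[3]))
  dx[, seq_len(d[2] * k), ] <- aperm(dxa, c(2, 1, 3))
  dx
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

cross_entropy <- function(probs, y_onehot, eps = 1e-12) {
  -mean(colSums(y_onehot * log(probs + eps)))
}

# --- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

maxnorm_project_rows <- function(w, maxnorm) {
  norms <- sqrt(rowSums(w^2))
  scale <- pmin(1, maxnorm / pmax(norms, .Machine$double.eps))
  w * scale
}
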