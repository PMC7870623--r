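# Minimal convolutional-network engine.
#
# Tensors are plain R arrays with dim = c(H, W, N, C); trainable parameters
# live in a flat named list `par` (names like "b1.u1.w"), batch-norm running
# statistics in a parallel list `stats`.  The C++ kernels in src/ provide the
# convolution / pooling primitives; everything else (ELU, batch norm, dropout,
# dense head, Adam, losses) is vectorized R.  The design goal is a small,
# auditable engine whose gradients are verified by finite differences in the
# test suite, not a general framework.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' @useDynLib kneeage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- elementwise layers ----------------------------------------------------

elu_fwd <- function(x) .cpp_elu_fwd(x)

elu_bwd <- function(y, dy) .cpp_elu_bwd(y, dy)

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- batch norm (per channel over H, W, N) ---------------------------------

bn_fwd <- function(x, gamma, beta, rm, rv, train) {
  if (!train) {
    return(list(y = .cpp_bn_eval(x, gamma, beta, rm, rv), cache = NULL,
                newstats = NULL))
  }
  f <- .cpp_bn_fwd(x, gamma, beta)
  list(y = f$y,
       cache = list(xhat = f$xhat, var = f$var),
       newstats = list(rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * f$mu,
                       rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * f$var))
}

bn_bwd <- function(cache, gamma, dy) {
  b <- .cpp_bn_bwd(cache$xhat, dy, gamma, cache$var)
  list(dx = b$dx, dgamma = b$dgamma, dbeta = b$dbeta)
}

# ---- dropout ---------------------------------------------------------------

# Channel ("spatial") dropout: whole feature maps are dropped per sample,
# mirroring kernels being dropped rather than single pixels.
dropout_channel_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  dm <- dim(x)
  mask <- matrix((stats::runif(dm[3] * dm[4]) >= p) / (1 - p), dm[3], dm[4])
  list(y = .cpp_scale_nc(x, mask), mask = mask)
}

dropout_channel_bwd <- function(mask, dy) {
  if (is.null(mask)) return(dy)
  .cpp_scale_nc(dy, mask)
}

# Element dropout on an N x F feature matrix (dense head).
dropout_dense_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

# ---- conv / pool / dense wrappers -----------------------------------------

conv_fwd <- function(x, w, b) .cpp_conv2d_fwd(x, w, b)
conv_bwd <- function(x, w, dy) .cpp_conv2d_bwd(x, w, dy)

pool_fwd <- function(x) .cpp_maxpool2_fwd(x)
pool_bwd <- function(argmax, dy, in_dim) .cpp_maxpool2_bwd(argmax, dy, in_dim)

gap_fwd <- function(x) {
  dm <- dim(x)
  matrix(colMeans(matrix(x, nrow = dm[1] * dm[2])), dm[3], dm[4])
}

gap_bwd <- function(dy, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  array(rep(as.numeric(dy), each = hw) / hw, in_dim)
}

dense_fwd <- function(x, w, b) sweep(x %*% w, 2, b, `+`)

# ---- conv-elu-bn-dropout unit ---------------------------------------------

unit_fwd <- function(par, stats, prefix, x, p_drop, train) {
  w <- par[[paste0(prefix, ".w")]]
  b <- par[[paste0(prefix, ".b")]]
  z <- conv_fwd(x, w, b)
  a <- elu_fwd(z)
  bn <- bn_fwd(a, par[[paste0(prefix, ".gamma")]], par[[paste0(prefix, ".beta")]],
               stats[[paste0(prefix, ".rm")]], stats[[paste0(prefix, ".rv")]], train)
  do <- dropout_channel_fwd(bn$y, p_drop, train)
  list(y = do$y,
       cache = list(x = x, a = a, bn = bn$cache, mask = do$mask),
       newstats = bn$newstats)
}

unit_bwd <- function(par, prefix, cache, dy) {
  dy <- dropout_channel_bwd(cache$mask, dy)
  bnb <- bn_bwd(cache$bn, par[[paste0(prefix, ".gamma")]], dy)
  dz <- elu_bwd(cache$a, bnb$dx)
  cb <- conv_bwd(cache$x, par[[paste0(prefix, ".w")]], dz)
  grads <- list(cb$dw, cb$db, bnb$dgamma, bnb$dbeta)
  names(grads) <- paste0(prefix, c(".w", ".b", ".gamma", ".beta"))
  list(dx = cb$dx, grads = grads)
}

# ---- parameter initialization ---------------------------------------------

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

init_unit <- function(par, stats, prefix, cin, cout, k = 3) {
  par[[paste0(prefix, ".w")]] <- he_conv(k, cin, cout)
  par[[paste0(prefix, ".b")]] <- numeric(cout)
  par[[paste0(prefix, ".gamma")]] <- rep(1, cout)
  par[[paste0(prefix, ".beta")]] <- numeric(cout)
  stats[[paste0(prefix, ".rm")]] <- numeric(cout)
  stats[[paste0(prefix, ".rv")]] <- rep(1, cout)
  list(par = par, stats = stats)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    par[[k]] <- par[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(par = par, state = state)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (k in names(g)) {
    acc[[k]] <- if (is.null(acc[[k]])) g[[k]] else acc[[k]] + g[[k]]
  }
  acc
}

# ---- losses ----------------------------------------------------------------

# Mean squared error and its gradient w.r.t. predictions.
mse_loss_grad <- function(y, yhat) {
  n <- length(y)
  r <- yhat - y
  list(loss = mean(r^2), grad = 2 * r / n)
}

# Binary cross-entropy + soft Dice on logits; targets in {0,1}.
seg_loss_grad <- function(logits, target, smooth = 1) {
  p <- sigmoid(logits)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  npix <- length(p)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  dbce_dz <- (p - target) / npix
  sp <- sum(p); sg <- sum(target); spg <- sum(p * target)
  denom <- sp + sg + smooth
  dice <- (2 * spg + smooth) / denom
  # d(1-dice)/dp = (2*spg+smooth)/denom^2 - 2*target/denom ; chain p(1-p)
  ddice_dp <- (2 * spg + smooth) / denom^2 - 2 * target / denom
  dz <- dbce_dz + ddice_dp * p * (1 - p)
  list(loss = bce + (1 - dice), grad = array(dz, dim(logits)),
       bce = bce, dice = dice)
}
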