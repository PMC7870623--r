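# The network engine is hand-written, so its gradients are verified against
# finite differences and its primitives against naive R reference
# implementations.

num_grad <- function(f, x, i, eps = 1e-6) {
  x1 <- x; x1[i] <- x1[i] + eps
  x2 <- x; x2[i] <- x2[i] - eps
  (f(x1) - f(x2)) / (2 * eps)
}

test_that("convolution matches a naive R reference", {
  set.seed(1)
  H <- 7; W <- 6; N <- 2; Cin <- 3; Cout <- 2; k <- 3
  x <- array(rnorm(H * W * N * Cin), c(H, W, N, Cin))
  w <- array(rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
  b <- rnorm(Cout)
  y <- kneeage:::conv_fwd(x, w, b)
  ref <- array(0, c(H, W, N, Cout))
  for (n in 1:N) for (co in 1:Cout) for (i in 1:H) for (j in 1:W) {
    acc <- b[co]
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      ii <- i + ki - 2; jj <- j + kj - 2
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, n, ci] * w[ki, kj, ci, co]
    }
    ref[i, j, n, co] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  loss <- function(x, w, b) sum(sin(kneeage:::conv_fwd(x, w, b)))
  y <- kneeage:::conv_fwd(x, w, b)
  g <- kneeage:::conv_bwd(x, w, array(cos(y), dim(y)))
  for (i in sample(length(x), 6)) {
    expect_equal(g$dx[i], num_grad(function(a) loss(a, w, b), x, i),
                 tolerance = 1e-6)
  }
  for (i in sample(length(w), 6)) {
    expect_equal(g$dw[i], num_grad(function(a) loss(x, a, b), w, i),
                 tolerance = 1e-6)
  }
  expect_equal(g$db[1], num_grad(function(a) loss(x, w, a), b, 1),
               tolerance = 1e-6)
})

test_that("max-pooling halves dimensions and routes gradients to argmax", {
  set.seed(3)
  x <- array(rnorm(6 * 4 * 2 * 2), c(6, 4, 2, 2))
  pf <- kneeage:::pool_fwd(x)
  expect_equal(dim(pf$y), c(3, 2, 2, 2))
  for (n in 1:2) for (c in 1:2) for (i in 1:3) for (j in 1:2) {
    expect_equal(pf$y[i, j, n, c],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), n, c]))
  }
  dy <- array(rnorm(length(pf$y)), dim(pf$y))
  dx <- kneeage:::pool_bwd(pf$argmax, dy, dim(x))
  expect_equal(sum(dx != 0), length(dy))
  expect_equal(sum(dx), sum(dy))
})

test_that("transposed convolution is the exact adjoint upsampler", {
  set.seed(4)
  x <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  w <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  b <- rnorm(3)
  y <- kneeage:::.cpp_convt2_fwd(x, w, b)
  expect_equal(dim(y), c(6, 6, 2, 3))
  # reference: each input pixel paints a 2x2 block
  ref <- array(0, c(6, 6, 2, 3))
  for (n in 1:2) for (co in 1:3) {
    ref[, , n, co] <- b[co]
    for (ci in 1:2) for (i in 1:3) for (j in 1:3) {
      for (ki in 1:2) for (kj in 1:2) {
        ref[2 * i - 2 + ki, 2 * j - 2 + kj, n, co] <-
          ref[2 * i - 2 + ki, 2 * j - 2 + kj, n, co] +
          x[i, j, n, ci] * w[ki, kj, ci, co]
      }
    }
  }
  expect_equal(y, ref, tolerance = 1e-12)
  # gradient check
  loss <- function(x, w, b) sum(sin(kneeage:::.cpp_convt2_fwd(x, w, b)))
  g <- kneeage:::.cpp_convt2_bwd(x, w, array(cos(y), dim(y)))
  for (i in sample(length(x), 5)) {
    expect_equal(g$dx[i], num_grad(function(a) loss(a, w, b), x, i),
                 tolerance = 1e-6)
  }
  for (i in sample(length(w), 5)) {
    expect_equal(g$dw[i], num_grad(function(a) loss(x, a, b), w, i),
                 tolerance = 1e-6)
  }
})

test_that("batch normalization normalizes and backpropagates correctly", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 3 * 2, mean = 3, sd = 2), c(4, 4, 3, 2))
  gamma <- c(1.5, 0.7); beta <- c(0.2, -0.1)
  f <- kneeage:::bn_fwd(x, gamma, beta, rm = c(0, 0), rv = c(1, 1),
                        train = TRUE)
  for (c in 1:2) {
    xh <- f$cache$xhat[, , , c]
    expect_lt(abs(mean(xh)), 1e-8)
    expect_equal(stats::sd(as.numeric(xh)) *
                   sqrt((length(xh) - 1) / length(xh)), 1, tolerance = 1e-3)
  }
  loss_of <- function(x) {
    ff <- kneeage:::bn_fwd(x, gamma, beta, c(0, 0), c(1, 1), TRUE)
    sum(sin(ff$y))
  }
  g <- kneeage:::bn_bwd(f$cache, gamma, array(cos(f$y), dim(f$y)))
  for (i in sample(length(x), 8)) {
    expect_equal(g$dx[i], num_grad(loss_of, x, i), tolerance = 1e-5)
  }
})

test_that("whole-network gradients match finite differences", {
  set.seed(6)
  spec <- agenet_spec(input_px = 8, n_blocks = 2, base_channels = 2,
                      block_dropout = 0, head_dropout = 0)
  m <- build_agenet2d(spec, seed = 3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  y <- rnorm(3)
  fw <- kneeage:::agenet_forward(m, x, train = TRUE)
  lg <- kneeage:::mse_loss_grad(y, fw$yhat)
  gr <- kneeage:::agenet_backward(m, fw$cache, lg$grad)
  loss_par <- function(par) {
    mm <- m; mm$par <- par
    f <- kneeage:::agenet_forward(mm, x, train = TRUE)
    kneeage:::mse_loss_grad(y, f$yhat)$loss
  }
  for (k in c("b1.u1.w", "b2.u2.gamma", "head.w", "head.b")) {
    p <- m$par[[k]]
    for (i in sample(length(p), min(3, length(p)))) {
      p1 <- m$par; p1[[k]][i] <- p1[[k]][i] + 1e-5
      p2 <- m$par; p2[[k]][i] <- p2[[k]][i] - 1e-5
      num <- (loss_par(p1) - loss_par(p2)) / 2e-5
      expect_equal(gr[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("segmentation loss and network gradients are exact", {
  set.seed(7)
  ss <- segnet_spec(input_px = 8, n_blocks = 2, base_channels = 2,
                    block_dropout = 0)
  sm <- build_segnet(ss, seed = 4)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  g0 <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 2, 1))
  fw <- kneeage:::segnet_forward(sm, x, train = TRUE)
  lg <- kneeage:::seg_loss_grad(fw$logits, g0)
  gr <- kneeage:::segnet_backward(sm, fw$cache, lg$grad)
  loss_par <- function(par) {
    mm <- sm; mm$par <- par
    f <- kneeage:::segnet_forward(mm, x, train = TRUE)
    kneeage:::seg_loss_grad(f$logits, g0)$loss
  }
  for (k in c("b1.u1.w", "d2.t.w", "d1.u2.beta", "out.w")) {
    p <- sm$par[[k]]
    for (i in sample(length(p), min(3, length(p)))) {
      p1 <- sm$par; p1[[k]][i] <- p1[[k]][i] + 1e-5
      p2 <- sm$par; p2[[k]][i] <- p2[[k]][i] - 1e-5
      num <- (loss_par(p1) - loss_par(p2)) / 2e-5
      expect_equal(gr[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("Adam takes bounded steps and reduces a quadratic", {
  par <- list(a = c(5, -3))
  st <- kneeage:::adam_init(par)
  for (t in 1:200) {
    g <- list(a = 2 * par$a)
    up <- kneeage:::adam_step(par, g, st, lr = 0.1)
    # step magnitude is bounded by roughly the learning rate
    expect_lt(max(abs(up$par$a - par$a)), 0.11)
    par <- up$par; st <- up$state
  }
  expect_lt(sum(par$a^2), 0.1)
})

test_that("area resampling preserves means and physical content", {
  set.seed(8)
  img <- matrix(runif(60 * 45), 60, 45)
  dn <- resample_area(img, 20, 15)
  expect_equal(mean(dn), mean(img), tolerance = 1e-12)
  # integer-factor downsampling equals block averaging
  blk <- matrix(0, 20, 15)
  for (i in 1:20) for (j in 1:15) {
    blk[i, j] <- mean(img[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  }
  expect_equal(dn, blk, tolerance = 1e-12)
  # upsampling then averaging back is lossless for integer factors
  up <- resample_area(img, 120, 90)
  expect_equal(resample_area(up, 60, 45), img, tolerance = 1e-12)
})
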