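test_that("batch normalization matches its closed form", {
  expect_equal(batch_normalize(c(5, 5, 5), eps = 1e-5), c(0, 0, 0))
  # hand evaluation: mean 2, biased var 2/3
  expect_equal(batch_normalize(c(1, 2, 3), eps = 1e-12),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  set.seed(1)
  x <- matrix(rnorm(5 * 40, 3, 2), 5, 40)
  y <- batch_normalize(x, eps = 1e-7)
  expect_lt(max(abs(rowMeans(y))), 1e-6)
  v <- apply(y, 1, function(r) mean((r - mean(r))^2))
  expect_true(all(v >= 1 - 1e-3 & v <= 1))
  expect_error(batch_normalize(numeric(0)), "empty")
  expect_error(batch_normalize(1:3, eps = 0), "eps")
})

test_that("convolution matches a direct sliding-window oracle", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  y <- ovineid:::.conv2d_fwd(x, w, 1L, 1L)
  expect_equal(dim(y), c(6L, 6L, 3L, 2L))
  oracle <- function(oh, ow, oc, n) {
    acc <- 0
    for (c in 1:2) for (kw in 1:3) for (kh in 1:3) {
      h <- oh + kh - 2; wd <- ow + kw - 2
      if (h >= 1 && h <= 6 && wd >= 1 && wd <= 6)
        acc <- acc + x[h, wd, c, n] * w[kh, kw, c, oc]
    }
    acc
  }
  for (pt in list(c(1, 1, 1, 1), c(3, 4, 2, 2), c(6, 6, 3, 1))) {
    expect_equal(y[pt[1], pt[2], pt[3], pt[4]],
                 oracle(pt[1], pt[2], pt[3], pt[4]))
  }
  # strided output size
  y2 <- ovineid:::.conv2d_fwd(x, w, 2L, 1L)
  expect_equal(dim(y2)[1:2], c(3L, 3L))
})

test_that("layer backward passes agree with finite differences", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  dy <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  bw <- ovineid:::.conv2d_bwd(x, w, dy, 1L, 1L)
  fx <- function(v) sum(ovineid:::.conv2d_fwd(array(v, dim(x)), w, 1L, 1L) * dy)
  fw <- function(v) sum(ovineid:::.conv2d_fwd(x, array(v, dim(w)), 1L, 1L) * dy)
  for (i in c(1, 60, 149)) {
    expect_equal(num_grad(fx, as.vector(x), i), as.vector(bw$dx)[i],
                 tolerance = 1e-5)
  }
  for (i in c(2, 17, 33)) {
    expect_equal(num_grad(fw, as.vector(w), i), as.vector(bw$dw)[i],
                 tolerance = 1e-5)
  }

  # batch-norm layer (4d) gradient
  ly <- ovineid:::ly_bn(2)
  ly$params$gamma <- c(0.8, 1.3)
  g <- function(v) sum(ovineid:::ly_fwd(ly, array(v, dim(x)), TRUE) * dy)
  invisible(ovineid:::ly_fwd(ly, x, TRUE))
  dxbn <- ovineid:::ly_bwd(ly, dy)
  for (i in c(5, 120)) {
    expect_equal(num_grad(g, as.vector(x), i), as.vector(dxbn)[i],
                 tolerance = 1e-4)
  }

  # maxpool gradient routes to the argmax
  mp <- ovineid:::ly_maxpool(3, 2, 1)
  yp <- ovineid:::ly_fwd(mp, x, TRUE)
  dyp <- array(rnorm(length(yp)), dim(yp))
  dxp <- ovineid:::ly_bwd(mp, dyp)
  h <- function(v) sum(ovineid:::ly_fwd(mp, array(v, dim(x)), TRUE) * dyp)
  for (i in c(30, 88)) {
    expect_equal(num_grad(h, as.vector(x), i), as.vector(dxp)[i],
                 tolerance = 1e-5)
  }
})

test_that("SGD with momentum follows the classical update", {
  ly <- ovineid:::ly_linear(2, 1, bias = FALSE)
  ly$params$w <- matrix(c(1, 2), 1, 2)
  ly$grads$w <- matrix(c(0.5, -0.5), 1, 2)
  ovineid:::sgd_step(ly, lr = 0.1, momentum = 0.9, weight_decay = 0)
  expect_equal(ly$params$w, matrix(c(0.95, 2.05), 1, 2))
  # second step accumulates velocity
  ly$grads$w <- matrix(c(0.5, -0.5), 1, 2)
  ovineid:::sgd_step(ly, lr = 0.1, momentum = 0.9, weight_decay = 0)
  expect_equal(ly$params$w, matrix(c(0.95 - 0.1 * (0.45 + 0.5),
                                     2.05 + 0.1 * (0.45 + 0.5)), 1, 2))
})

test_that("parameter state round-trips through get/set", {
  b1 <- ovineid:::md_bottleneck(4, 8, 2, se_reduction = 4)
  b2 <- ovineid:::md_bottleneck(4, 8, 2, se_reduction = 4)
  st <- ovineid:::get_state(b1, "blk")
  ovineid:::set_state(b2, st, "blk")
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  expect_equal(ovineid:::bk_fwd(b1, x, FALSE), ovineid:::bk_fwd(b2, x, FALSE))
})
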