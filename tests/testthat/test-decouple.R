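test_that("ECA kernel size follows the adaptive odd rule", {
  expect_equal(eca_kernel_size(256), 5L)
  expect_equal(eca_kernel_size(2048), 7L)
  expect_equal(eca_kernel_size(64), 3L)
  expect_equal(eca_kernel_size(2), 3L)     # floor never drops below 3
  expect_error(eca_kernel_size(1), "C")
})

test_that("channel gate obeys the two-branch convex blend", {
  set.seed(7)
  C <- 16
  f <- array(rnorm(4 * 4 * C * 3), c(4, 4, C, 3))
  p <- ecbam_params(C, seed = 1)
  # zero kernels: pre-sigmoid zero -> gate 0.5
  p$children$chan$params$wa[] <- 0
  p$children$chan$params$wm[] <- 0
  expect_equal(ecam_gate(f, p), matrix(0.5, C, 3))
  # alpha = 1 isolates the average-pool branch
  p2 <- ecbam_params(C, seed = 2)
  p2$children$chan$params$alpha <- 1
  g1 <- ecam_gate(f, p2)
  p2$children$chan$params$wm <- p2$children$chan$params$wm + 5
  expect_equal(ecam_gate(f, p2), g1)
  # equal branches make the gate independent of alpha
  p3 <- ecbam_params(C, seed = 3)
  p3$children$chan$params$wm <- p3$children$chan$params$wa
  fc <- array(rep(abs(rnorm(C * 3)), each = 16), c(4, 4, C, 3)) # GAP == GMP
  p3$children$chan$params$alpha <- 0.2
  ga <- ecam_gate(fc, p3)
  p3$children$chan$params$alpha <- 0.9
  expect_equal(ecam_gate(fc, p3), ga)
})

test_that("spatial gate preserves dims and convolution equivariance", {
  set.seed(8)
  f <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  p <- ecbam_params(4, seed = 4)
  g <- sam_gate(f, p)
  expect_equal(dim(g), c(16L, 16L, 1L, 2L))
  expect_true(all(g > 0 & g < 1))
  # zero conv kernel -> uniform 0.5 map
  p0 <- ecbam_params(4, seed = 5)
  p0$children$sconv$params$w[] <- 0
  expect_equal(sam_gate(f, p0), array(0.5, c(16, 16, 1, 2)))
  # spatially constant input -> spatially constant gate away from the
  # zero-padded border (the 7x7 kernel sees the pad within 3 of the edge)
  fcst <- array(rep(rnorm(4 * 2), each = 256), c(16, 16, 4, 2))
  gc <- sam_gate(fcst, p)[4:13, 4:13, , , drop = FALSE]
  expect_lt(max(apply(gc, c(3, 4), function(mm) diff(range(mm)))), 1e-12)
  # translation equivariance in the interior: shift input by (1,1) with
  # wraparound, compare gates where both receptive fields avoid the pad and
  # the wrapped row/column
  fs <- f[c(16, 1:15), c(16, 1:15), , , drop = FALSE]
  gs <- sam_gate(fs, p)
  expect_equal(gs[5:13, 5:13, 1, ], g[4:12, 4:12, 1, ], tolerance = 1e-12)
})

test_that("the tandem attention block attenuates and has exact fixed points", {
  set.seed(9)
  f <- array(rnorm(4 * 4 * 16 * 3), c(4, 4, 16, 3))
  # gates forced to one: the `none` variant is the identity
  pid <- ecbam_params(16, variant = "none")
  expect_identical(ecbam(f, pid), f)
  # all-zero parameters: 0.5 channel gate x 0.5 spatial gate
  p0 <- ecbam_params(16, seed = 6)
  p0$children$chan$params$wa[] <- 0
  p0$children$chan$params$wm[] <- 0
  p0$children$sconv$params$w[] <- 0
  expect_equal(ecbam(f, p0), 0.25 * f)
  # attenuation in norm for random parameters
  for (s in 1:5) {
    p <- ecbam_params(16, seed = s)
    out <- ecbam(f, p)
    expect_true(all(abs(out) <= abs(f) + 1e-12))
    expect_lte(sqrt(sum(out^2)), sqrt(sum(f^2)))
  }
  # CBAM ablation variant also gates in (0,1)
  pc <- ecbam_params(16, variant = "cbam", seed = 7)
  outc <- ecbam(f, pc)
  expect_true(all(abs(outc) <= abs(f) + 1e-12))
})

test_that("decoupling preserves the exact reconstruction identity", {
  set.seed(10)
  dp <- decoupler_params(16, d_a = 6, hidden = 12, seed = 3)
  f <- array(rnorm(2 * 2 * 16 * 5), c(2, 2, 16, 5))
  x <- matrix(rnorm(16 * 5), 16, 5)
  bun <- decouple(f, x, dp)
  expect_equal(bun$x_id + bun$r, bun$x, tolerance = 1e-14)
  expect_equal(dim(bun$x_age), c(6L, 5L))
  # zero residual map -> x_id == x
  dp0 <- decoupler_params(16, d_a = 6, hidden = 12, seed = 4)
  dp0$children$r2$params$w[] <- 0
  dp0$children$r2$params$b[] <- 0
  b0 <- decouple(f, x, dp0)
  expect_equal(b0$x_id, x)
  expect_equal(b0$r, matrix(0, 16, 5))
  # x_age depends only on F; x_id inherits differences in x
  x2 <- x + 1
  b2 <- decouple(f, x2, dp)
  expect_equal(b2$x_age, bun$x_age)
  expect_false(isTRUE(all.equal(b2$x_id, bun$x_id)))
  # linear-subtraction ablation keeps the identity too
  dpl <- decoupler_params(16, d_a = 6, subtraction = "linear", seed = 5)
  bl <- decouple(f, x, dpl)
  expect_equal(bl$x_id + bl$r, bl$x)
  expect_error(decouple(f, matrix(0, 8, 5), dp), "dim")
})

test_that("kernel projections are linear in the projection vector", {
  set.seed(11)
  cp <- corr_params(6, 4, kernel = "identity", seed = 2)
  X <- matrix(rnorm(6 * 9), 6, 9); Y <- matrix(rnorm(4 * 9), 4, 9)
  cp$children$pu$params$w <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6)
  uv <- kernel_projections(X, Y, cp)
  expect_equal(uv$u, X[1, ])
  cp$children$pu$params$w <- 3 * cp$children$pu$params$w
  expect_equal(kernel_projections(X, Y, cp)$u, 3 * X[1, ])
  expect_identical(kernel_projections(X, Y, cp),
                   kernel_projections(X, Y, cp))
  expect_error(kernel_projections(X[, 1, drop = FALSE],
                                  Y[, 1, drop = FALSE], cp), "n >= 2")
})

test_that("batch correlation is a stabilized Pearson coefficient", {
  u <- c(1, 2, 3, 5)
  expect_equal(as.numeric(batch_correlation(u, u)), 1, tolerance = 1e-6)
  expect_equal(as.numeric(batch_correlation(u, -u)), -1, tolerance = 1e-6)
  z <- batch_correlation(rep(1, 5), rnorm(5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  set.seed(12)
  r <- batch_correlation(rnorm(10000), rnorm(10000))
  expect_lt(abs(as.numeric(r)), 0.05)
  expect_error(batch_correlation(1:3, 1:4), "length")
  # loss mapping
  expect_equal(correlation_loss(0), 0)
  expect_equal(correlation_loss(1), 1)
  expect_equal(correlation_loss(-1), 1)
  expect_equal(correlation_loss(0.3), 0.09)
})

test_that("correlation gradients point in the adversarial directions", {
  set.seed(13)
  n <- 64
  z <- rnorm(n)
  X <- rbind(z + rnorm(n, 0, 0.5), matrix(rnorm(3 * n), 3, n))
  Y <- rbind(z + rnorm(n, 0, 0.5), matrix(rnorm(2 * n), 2, n))
  cp <- corr_params(4, 3, hidden = 8, out = 4, seed = 3)
  rho2 <- function() {
    fw <- ovineid:::corr_forward(cp, X, Y, train = FALSE)
    as.numeric(fw$rho)^2
  }
  before <- rho2()
  # one small ascent step on the module must not decrease rho^2
  ovineid:::zero_grads(cp)
  fw <- ovineid:::corr_forward(cp, X, Y, train = TRUE)
  ovineid:::corr_backward(cp, fw)
  ovineid:::sgd_step(cp, lr = 1e-4, momentum = 0, maximize = TRUE)
  expect_gte(rho2(), before - 1e-10)
  # one small descent step on the codes must not increase rho^2
  ovineid:::zero_grads(cp)
  fw <- ovineid:::corr_forward(cp, X, Y, train = TRUE)
  gb <- ovineid:::corr_backward(cp, fw)
  after <- {
    X2 <- X - 1e-4 * gb$dx_id
    Y2 <- Y - 1e-4 * gb$dx_age
    fw2 <- ovineid:::corr_forward(cp, X2, Y2, train = FALSE)
    as.numeric(fw2$rho)^2
  }
  expect_lte(after, rho2() + 1e-10)
})

test_that("maximized linear projections recover the top canonical correlation", {
  set.seed(14)
  n <- 5000; d <- 8
  z <- rnorm(n)
  X <- matrix(rnorm(d * n), d, n); Y <- matrix(rnorm(d * n), d, n)
  X[2, ] <- 0.6 * X[2, ] + 0.8 * z
  Y[5, ] <- 0.6 * Y[5, ] + 0.8 * z
  oracle <- stats::cancor(t(X), t(Y))$cor[1]
  cp <- corr_params(d, d, kernel = "identity", prior_strength = 0, seed = 4)
  rho <- maximize_correlation(X, Y, cp, steps = 300, lr = 0.05)
  # the ascent maximizes rho^2, so the sign of rho is arbitrary; the
  # canonical correlation is its magnitude
  expect_lt(abs(abs(rho) - oracle), 0.02)
})
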