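# Age/identity decoupling: ECBAM attention on the age branch, nonlinear
# residual subtraction, and the kernel canonical-correlation module that is
# trained adversarially to decorrelate the identity and age codes.
#
# ECBAM = efficient channel attention (two unshared 1-D convolutions over the
# channel axis on the average- and max-pooled descriptors, blended by a
# trainable scalar alpha) followed by a spatial attention map; a CBAM variant
# (shared two-layer MLP channel gate) is kept for ablation.

#' ECA kernel size for a channel count
#'
#' Adaptive 1-D kernel size: `t = floor((log2(C) + b) / gamma)`, rounded up
#' to the next odd number, never below 3.
#'
#' @param C channel count (>= 2).
#' @param gamma,b mapping coefficients.
#' @return an odd integer kernel size.
#' @export
#' @examples
#' eca_kernel_size(256) # 5
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (C < 2) stop("C must be >= 2")
  t <- floor((log2(C) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(3, k))
}

#' ECBAM parameter set
#'
#' Creates the trainable parameters of the attention block: two unshared 1-D
#' channel-convolution kernels (average-pool and max-pool branches), the
#' blending scalar `alpha` (initialized at 0.5), and the spatial-attention
#' convolution. The `cbam` variant replaces the 1-D convolutions by a shared
#' bottleneck MLP.
#'
#' @param C channel count of the feature map the block will gate.
#' @param k 1-D kernel size (odd); default from [eca_kernel_size()].
#' @param spatial_kernel spatial attention kernel size (odd, default 7).
#' @param variant `"ecbam"`, `"cbam"` or `"none"` (identity gate, ablation).
#' @param reduction bottleneck reduction for the `cbam` variant.
#' @param seed initialization seed.
#' @return an `nn_module` of type `ecbam`.
#' @export
ecbam_params <- function(C, k = eca_kernel_size(C), spatial_kernel = 7,
                         variant = c("ecbam", "cbam", "none"), reduction = 8,
                         seed = 1L) {
  variant <- match.arg(variant)
  if (k %% 2 == 0 || spatial_kernel %% 2 == 0)
    stop("kernel sizes must be odd")
  with_seed(derive_seed(seed, "ecbam"), {
    ch <- list()
    if (variant == "ecbam") {
      ch$chan <- new_layer("ecam", list(
        wa = rnorm(k, 0, 1 / sqrt(k)),
        wm = rnorm(k, 0, 1 / sqrt(k)),
        alpha = 0.5))
    } else if (variant == "cbam") {
      ch$fc1 <- ly_linear(C, max(1L, C %/% reduction))
      ch$relu <- ly_relu()
      ch$fc2 <- ly_linear(max(1L, C %/% reduction), C)
    }
    if (variant != "none") {
      ch$sconv <- ly_conv(spatial_kernel, spatial_kernel, 2L, 1L,
                          pad = (spatial_kernel - 1L) %/% 2L)
    }
    new_module("ecbam", ch, list(C = C, k = k, variant = variant))
  })
}

# 1-D convolution over the channel axis with zero padding; z is C x N
conv1d_channels <- function(z, w) {
  C <- nrow(z); k <- length(w); half <- (k - 1L) %/% 2L
  out <- matrix(0, C, ncol(z))
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    out[ok, ] <- out[ok, ] + w[j] * z[src[ok], , drop = FALSE]
  }
  out
}

conv1d_channels_bwd <- function(z, w, dout) {
  C <- nrow(z); k <- length(w); half <- (k - 1L) %/% 2L
  dz <- matrix(0, C, ncol(z)); dw <- numeric(k)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    dz[src[ok], ] <- dz[src[ok], , drop = FALSE] + w[j] * dout[ok, , drop = FALSE]
    dw[j] <- sum(dout[ok, , drop = FALSE] * z[src[ok], , drop = FALSE])
  }
  list(dz = dz, dw = dw)
}

#' Channel gate of the attention block
#'
#' For the ECBAM variant: `gate = sigmoid(alpha * conv_avg(GAP(F)) +
#' (1 - alpha) * conv_max(GMP(F)))`, both 1-D convolutions unshared.
#'
#' @param f feature map `h x w x C x N`.
#' @param p an [ecbam_params()].
#' @return `C x N` matrix of gates in (0, 1).
#' @export
ecam_gate <- function(f, p) {
  ecam_gate_fwd(p, f, cache = FALSE)$gate
}

ecam_gate_fwd <- function(p, f, cache = TRUE) {
  ch <- p$children
  if (p$variant == "none") {
    g <- matrix(1, dim(f)[3], dim(f)[4])
    if (cache) p$cg <- list(variant = "none")
    return(list(gate = g))
  }
  za <- gap2d(f)
  mp <- gmp2d(f)
  if (p$variant == "ecbam") {
    pr <- ch$chan$params
    a <- conv1d_channels(za, pr$wa)
    m <- conv1d_channels(mp$y, pr$wm)
    s <- pr$alpha * a + (1 - pr$alpha) * m
  } else {
    h1 <- ly_fwd(ch$relu, ly_fwd(ch$fc1, za, TRUE), TRUE)
    sa <- ly_fwd(ch$fc2, h1, TRUE)
    # shared MLP on the max branch (CBAM): reuse weights functionally
    hm <- relu(ch$fc1$params$w %*% mp$y + ch$fc1$params$b)
    sm <- ch$fc2$params$w %*% hm + ch$fc2$params$b
    s <- sa + sm
    if (cache) p$cbam_cache <- list(hm = hm, mp = mp$y)
  }
  g <- sigmoid(s)
  if (cache) p$cg <- list(za = za, mpy = mp$y, arg = mp$arg, g = g,
                          a = if (p$variant == "ecbam") a,
                          m = if (p$variant == "ecbam") m, variant = p$variant)
  list(gate = g)
}

# backward of the channel gate: dgate (C x N) -> dF contribution
ecam_gate_bwd <- function(p, dgate, fdim) {
  cg <- p$cg
  if (cg$variant == "none") return(array(0, fdim))
  ds <- dgate * cg$g * (1 - cg$g)
  ch <- p$children
  if (cg$variant == "ecbam") {
    pr <- ch$chan$params
    ba <- conv1d_channels_bwd(cg$za, pr$wa, pr$alpha * ds)
    bm <- conv1d_channels_bwd(cg$mpy, pr$wm, (1 - pr$alpha) * ds)
    ch$chan$grads$wa <- ch$chan$grads$wa + ba$dw
    ch$chan$grads$wm <- ch$chan$grads$wm + bm$dw
    ch$chan$grads$alpha <- ch$chan$grads$alpha + sum(ds * (cg$a - cg$m))
    dza <- ba$dz; dmp <- bm$dz
  } else {
    dsa <- ds
    dza <- ly_bwd(ch$fc1, ly_bwd(ch$relu, ly_bwd(ch$fc2, dsa)))
    cb <- p$cbam_cache
    dhm <- crossprod(ch$fc2$params$w, ds) * (cb$hm > 0)
    ch$fc2$grads$w <- ch$fc2$grads$w + ds %*% t(cb$hm)
    ch$fc2$grads$b <- ch$fc2$grads$b + rowSums(ds)
    ch$fc1$grads$w <- ch$fc1$grads$w + dhm %*% t(cb$mp)
    ch$fc1$grads$b <- ch$fc1$grads$b + rowSums(dhm)
    dmp <- crossprod(ch$fc1$params$w, dhm)
  }
  hw <- fdim[1] * fdim[2]
  dF <- bcast_cn(dza / hw, fdim)
  # max-pool branch: route gradient to per-(C,N) argmax positions
  dmp_v <- as.vector(dmp)
  m <- matrix(0, hw, fdim[3] * fdim[4])
  m[cbind(cg$arg, seq_along(dmp_v))] <- dmp_v
  dF + array(m, fdim)
}

#' Spatial gate of the attention block
#'
#' Concatenates the channel-mean and channel-max maps and passes them through
#' a `k x k` convolution and a sigmoid; spatial dims are preserved.
#'
#' @param f feature map `h x w x C x N`.
#' @param p an [ecbam_params()].
#' @return `h x w x 1 x N` array of gates in (0, 1).
#' @export
sam_gate <- function(f, p) {
  sam_gate_fwd(p, f, cache = FALSE)$gate
}

sam_gate_fwd <- function(p, f, cache = TRUE) {
  d <- dim(f)
  if (p$variant == "none") return(list(gate = array(1, c(d[1], d[2], 1, d[4]))))
  hw <- d[1] * d[2]
  stk <- array(0, c(d[1], d[2], 2, d[4]))
  argm <- matrix(0L, hw, d[4])
  for (n in seq_len(d[4])) {
    m <- matrix(f[, , , n], nrow = hw)      # hw x C
    stk[, , 1, n] <- rowMeans(m)
    am <- max.col(m, ties.method = "first")
    argm[, n] <- am
    stk[, , 2, n] <- m[cbind(seq_len(hw), am)]
  }
  s <- ly_fwd(p$children$sconv, stk, TRUE)
  g <- sigmoid(s)
  if (cache) p$cs <- list(g = g, argm = argm, d = d)
  list(gate = g)
}

sam_gate_bwd <- function(p, dgate) {
  cs <- p$cs; d <- cs$d
  ds <- dgate * cs$g * (1 - cs$g)
  dstk <- ly_bwd(p$children$sconv, ds)
  hw <- d[1] * d[2]
  dF <- array(0, d)
  for (n in seq_len(d[4])) {
    dm <- matrix(0, hw, d[3])
    dm <- dm + matrix(dstk[, , 1, n], hw, d[3]) / d[3]        # mean branch
    dmax <- as.vector(dstk[, , 2, n])
    dm[cbind(seq_len(hw), cs$argm[, n])] <-
      dm[cbind(seq_len(hw), cs$argm[, n])] + dmax
    dF[, , , n] <- array(dm, c(d[1], d[2], d[3]))
  }
  dF
}

#' Apply the full attention block
#'
#' Channel attention first, then spatial attention:
#' `F' = sam_gate(F * g_c) * (F * g_c)`. With all gates forced to 1 (variant
#' `"none"`) the input is returned unchanged; attenuation `|F'| <= |F|` holds
#' elementwise.
#'
#' @param f feature map `h x w x C x N`.
#' @param p an [ecbam_params()].
#' @return gated feature map, same shape.
#' @export
ecbam <- function(f, p) {
  ecbam_fwd(p, f, cache = FALSE)
}

ecbam_fwd <- function(p, f, cache = TRUE) {
  d <- dim(f)
  cg <- ecam_gate_fwd(p, f, cache = cache)
  fc <- f * bcast_cn(cg$gate, d)
  if (p$variant == "none") {
    if (cache) p$cf <- list(f = f, d = d, variant = "none")
    return(fc)
  }
  sg <- sam_gate_fwd(p, fc, cache = cache)
  # expand the 1-channel spatial gate over all C channels
  gs <- array(apply(sg$gate, 4, function(m) rep(as.vector(m), d[3])), d)
  out <- fc * gs
  if (cache) p$cf <- list(f = f, d = d, gc = cg$gate, gs = sg$gate,
                          fc = fc, gsfull = gs)
  out
}

ecbam_bwd <- function(p, dout) {
  cf <- p$cf; d <- cf$d
  if (identical(cf$variant, "none")) return(dout)
  # out = fc * gs
  dfc <- dout * cf$gsfull
  dgs_full <- dout * cf$fc
  # collapse channel axis of the spatial-gate gradient
  hw <- d[1] * d[2]
  dgs <- array(0, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[4])) {
    dgs[, , 1, n] <- array(rowSums(matrix(dgs_full[, , , n], hw, d[3])),
                           c(d[1], d[2]))
  }
  dfc <- dfc + sam_gate_bwd(p, dgs)
  # fc = f * bcast(gc)
  dF <- dfc * bcast_cn(cf$gc, d)
  dgc <- sum_hw(dfc * cf$f)
  dF + ecam_gate_bwd(p, dgc, d)
}

# ---- nonlinear decoupling head ----------------------------------------

#' Decoupling head parameters
#'
#' The age branch: attention (`ecbam_params`) on the final feature map,
#' global average pooling, and an MLP producing the age code `x_age`
#' (`d -> 256 -> d_a`); the residual map `R(x_age)` (`d_a -> 256 -> d`, or a
#' single linear map for the `linear` ablation) whose output is subtracted
#' from the embedding: `x_id = x - R(x_age)`.
#'
#' @param d embedding dim (backbone channel count).
#' @param d_a age code dim (default 128).
#' @param hidden hidden width of both MLPs.
#' @param attention attention variant passed to [ecbam_params()].
#' @param subtraction `"mlp"` (nonlinear residual map) or `"linear"`.
#' @param seed initialization seed.
#' @return an `nn_module` of type `decoupler`.
#' @export
decoupler_params <- function(d, d_a = 128L, hidden = 256L,
                             attention = c("ecbam", "cbam", "none"),
                             subtraction = c("mlp", "linear"), seed = 1L) {
  attention <- match.arg(attention)
  subtraction <- match.arg(subtraction)
  with_seed(derive_seed(seed, "decoupler"), {
    ch <- list(att = ecbam_params(d, variant = attention,
                                  seed = derive_seed(seed, "att")),
               a1 = ly_linear(d, hidden), arelu = ly_relu(),
               a2 = ly_linear(hidden, d_a))
    if (subtraction == "mlp") {
      ch$r1 <- ly_linear(d_a, hidden); ch$rrelu <- ly_relu()
      ch$r2 <- ly_linear(hidden, d)
    } else {
      ch$r1 <- ly_linear(d_a, d)
    }
    new_module("decoupler", ch,
               list(d = d, d_a = d_a, subtraction = subtraction))
  })
}

#' Decouple an embedding into age and identity codes
#'
#' `x_age = MLP_age(GAP(ecbam(F)))`, residual `R(x_age)`, `x_id = x - R(x_age)`; the
#' reconstruction `x_id + r = x` holds exactly by construction.
#'
#' @param f final feature map `h x w x d x N`.
#' @param x pooled embedding `d x N`.
#' @param params a [decoupler_params()].
#' @param train logical; cache for backward.
#' @return a `feature_bundle`: list with `F`, `x`, `x_age`, `r`, `x_id`.
#' @export
decouple <- function(f, x, params, train = FALSE) {
  ch <- params$children
  d <- dim(f)
  if (d[3] != params$d || nrow(x) != params$d) stop("dim mismatch")
  fe <- ecbam_fwd(ch$att, f, cache = train)
  z <- gap2d(fe)
  h <- ly_fwd(ch$arelu, ly_fwd(ch$a1, z, train), train)
  x_age <- ly_fwd(ch$a2, h, train)
  r <- if (params$subtraction == "mlp") {
    ly_fwd(ch$r2, ly_fwd(ch$rrelu, ly_fwd(ch$r1, x_age, train), train), train)
  } else {
    ly_fwd(ch$r1, x_age, train)
  }
  structure(list(F = f, x = x, x_age = x_age, r = r, x_id = x - r),
            class = "feature_bundle")
}

# backward: gradients on x_id and (optionally) directly on x_age;
# returns gradients on F and x
decouple_bwd <- function(params, dx_id, dx_age = NULL) {
  ch <- params$children
  dr <- -dx_id
  dxa <- if (params$subtraction == "mlp") {
    ly_bwd(ch$r1, ly_bwd(ch$rrelu, ly_bwd(ch$r2, dr)))
  } else {
    ly_bwd(ch$r1, dr)
  }
  if (!is.null(dx_age)) dxa <- dxa + dx_age
  dz <- ly_bwd(ch$a1, ly_bwd(ch$arelu, ly_bwd(ch$a2, dxa)))
  dfe_dim <- ch$att$cf$d %||% stop("decouple_bwd requires train=TRUE forward")
  dfe <- bcast_cn(dz / (dfe_dim[1] * dfe_dim[2]), dfe_dim)
  dF <- ecbam_bwd(ch$att, dfe)
  list(dF = dF, dx = dx_id)
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat(sprintf("<feature_bundle> n=%d d=%d d_a=%d  max|x_id + r - x| = %.2e\n",
              ncol(x$x), nrow(x$x), nrow(x$x_age),
              max(abs(x$x_id + x$r - x$x))))
  invisible(x)
}

# ---- correlation (BKCCA) module ---------------------------------------

#' Correlation-module parameters
#'
#' One-hidden-layer kernel maps `phi_u` (identity code) and `phi_v` (age
#' code) plus projection vectors `w_u`, `w_v`; the module projects both codes
#' to scalars and measures their batch Pearson correlation. A Gaussian prior
#' on all parameters is realized as an L2 penalty of strength
#' `prior_strength` during the adversarial ascent.
#'
#' @param d_id,d_age input dims of the two codes.
#' @param hidden hidden width of the kernel maps.
#' @param out output dim of the kernel maps (projection space).
#' @param prior_strength L2 (Gaussian prior) penalty, >= 0.
#' @param kernel `"mlp"` (nonlinear kernel maps, default) or `"identity"`
#'   (linear projections only; with this choice the maximized batch
#'   correlation is classical linear CCA's top canonical correlation).
#' @param n_pairs number of canonical pairs (default 1). With several
#'   pairs the projection rows are kept apart by an orthonormality penalty
#'   during the ascent, so the module can track — and the encoder suppress
#'   — a whole correlated subspace instead of a single direction.
#' @param seed initialization seed.
#' @return an `nn_module` of type `corr`.
#' @export
corr_params <- function(d_id, d_age, hidden = 64L, out = 32L,
                        prior_strength = 1e-4,
                        kernel = c("mlp", "identity"), n_pairs = 1L,
                        seed = 1L) {
  stopifnot(prior_strength >= 0, n_pairs >= 1)
  kernel <- match.arg(kernel)
  with_seed(derive_seed(seed, "corr"), {
    ch <- if (kernel == "mlp") {
      list(u1 = ly_linear(d_id, hidden), urelu = ly_relu(),
           u2 = ly_linear(hidden, out),
           v1 = ly_linear(d_age, hidden), vrelu = ly_relu(),
           v2 = ly_linear(hidden, out),
           pu = ly_linear(out, as.integer(n_pairs), bias = FALSE, gain = 1),
           pv = ly_linear(out, as.integer(n_pairs), bias = FALSE, gain = 1))
    } else {
      list(pu = ly_linear(d_id, as.integer(n_pairs), bias = FALSE, gain = 1),
           pv = ly_linear(d_age, as.integer(n_pairs), bias = FALSE, gain = 1))
    }
    new_module("corr", ch, list(prior_strength = prior_strength,
                                kernel = kernel,
                                n_pairs = as.integer(n_pairs)))
  })
}

#' Project the two codes to scalars
#'
#' `u_i = w_u' phi_u(x_id_i)`, `v_i = w_v' phi_v(x_age_i)`.
#'
#' @param x_id identity codes, `d_id x n` matrix (n >= 2).
#' @param x_age age codes, `d_age x n` matrix.
#' @param cp a [corr_params()].
#' @param train cache for backward.
#' @return list with `u` and `v`: numeric vectors of length n for a
#'   single-pair module, otherwise `n_pairs x n` matrices.
#' @export
kernel_projections <- function(x_id, x_age, cp, train = FALSE) {
  if (ncol(x_id) < 2) stop("need n >= 2")
  if (ncol(x_id) != ncol(x_age)) stop("batch size mismatch")
  ch <- cp$children
  if (identical(cp$kernel, "identity")) {
    u <- ly_fwd(ch$pu, x_id, train)
    v <- ly_fwd(ch$pv, x_age, train)
  } else {
    u <- ly_fwd(ch$pu, ly_fwd(ch$u2,
           ly_fwd(ch$urelu, ly_fwd(ch$u1, x_id, train), train), train), train)
    v <- ly_fwd(ch$pv, ly_fwd(ch$v2,
           ly_fwd(ch$vrelu, ly_fwd(ch$v1, x_age, train), train), train), train)
  }
  if (cp$n_pairs %||% 1L == 1L) list(u = as.numeric(u), v = as.numeric(v))
  else list(u = u, v = v)
}

#' Batch Pearson correlation with stabilized denominator
#'
#' Mean-centers both projections ("deviation of the neurons") and returns
#' their Pearson correlation; a zero-variance input yields 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param u,v numeric vectors of equal length n >= 2.
#' @param eps denominator stabilizer.
#' @return correlation in `[-1, 1]` (attribute `degenerate` flags the
#'   zero-variance case).
#' @export
batch_correlation <- function(u, v, eps = 1e-8) {
  if (length(u) != length(v)) stop("length mismatch")
  if (length(u) < 2) stop("need n >= 2")
  uc <- u - mean(u); vc <- v - mean(v)
  bu <- sum(uc^2); bv <- sum(vc^2)
  if (bu < eps^2 || bv < eps^2) {
    return(structure(0, degenerate = TRUE))
  }
  rho <- sum(uc * vc) / (sqrt(bu * bv) + eps)
  structure(max(-1, min(1, rho)), degenerate = FALSE)
}

# d rho / d u and d rho / d v (zero for degenerate batches)
rho_grads <- function(u, v, eps = 1e-8) {
  n <- length(u)
  uc <- u - mean(u); vc <- v - mean(v)
  bu <- sum(uc^2); bv <- sum(vc^2)
  if (bu < eps^2 || bv < eps^2)
    return(list(du = numeric(n), dv = numeric(n)))
  a <- sum(uc * vc)
  denom <- sqrt(bu * bv) + eps
  du <- vc / denom - a * bv * uc / (sqrt(bu * bv) * denom^2)
  dv <- uc / denom - a * bu * vc / (sqrt(bu * bv) * denom^2)
  list(du = du, dv = dv)
}

#' Squared-correlation loss
#'
#' The correlation term of the joint objective: `rho^2`, in `[0, 1]`.
#'
#' @param rho correlation in `[-1, 1]`.
#' @return `rho^2`.
#' @export
correlation_loss <- function(rho) {
  if (abs(rho) > 1 + 1e-12) stop("|rho| must be <= 1")
  as.numeric(rho)^2
}

# full correlation pass: returns the per-pair correlations and, via caches,
# supports backward into both the module parameters (ascent) and the codes
# (descent)
corr_forward <- function(cp, x_id, x_age, train = TRUE) {
  uv <- kernel_projections(x_id, x_age, cp, train = train)
  if (is.matrix(uv$u)) {
    rho <- vapply(seq_len(nrow(uv$u)), function(j)
      as.numeric(batch_correlation(uv$u[j, ], uv$v[j, ])), 1)
  } else {
    rho <- batch_correlation(uv$u, uv$v)
  }
  list(rho = rho, u = uv$u, v = uv$v)
}

# scalar summaries of a (possibly multi-pair) correlation pass
corr_loss_value <- function(rho) mean(as.numeric(rho)^2)
corr_rho_top <- function(rho) max(abs(as.numeric(rho)))

# backward of d(rho^2) through the module; returns gradients w.r.t. the codes
# and accumulates parameter gradients on cp
corr_backward <- function(cp, fw, scale = 1) {
  ch <- cp$children
  if (isTRUE(attr(fw$rho, "degenerate"))) {
    return(list(dx_id = NULL, dx_age = NULL))
  }
  if (is.matrix(fw$u)) {
    # mean over pairs of rho_j^2
    k <- nrow(fw$u)
    du <- matrix(0, k, ncol(fw$u)); dv <- du
    rho <- as.numeric(fw$rho)
    for (j in seq_len(k)) {
      g <- rho_grads(fw$u[j, ], fw$v[j, ])
      du[j, ] <- (2 * rho[j] / k) * scale * g$du
      dv[j, ] <- (2 * rho[j] / k) * scale * g$dv
    }
  } else {
    g <- rho_grads(fw$u, fw$v)
    drho2 <- 2 * as.numeric(fw$rho) * scale
    du <- matrix(drho2 * g$du, nrow = 1)
    dv <- matrix(drho2 * g$dv, nrow = 1)
  }
  if (identical(cp$kernel, "identity")) {
    dx_id <- ly_bwd(ch$pu, du)
    dx_age <- ly_bwd(ch$pv, dv)
  } else {
    dx_id <- ly_bwd(ch$u1, ly_bwd(ch$urelu,
               ly_bwd(ch$u2, ly_bwd(ch$pu, du))))
    dx_age <- ly_bwd(ch$v1, ly_bwd(ch$vrelu,
                ly_bwd(ch$v2, ly_bwd(ch$pv, dv))))
  }
  list(dx_id = dx_id, dx_age = dx_age)
}

#' Maximize the projected correlation for fixed codes
#'
#' Runs gradient-ascent steps on the correlation-module parameters to find
#' the most correlated projections of the two codes; this is the inner
#' maximization of the adversarial objective, and with identity kernel maps
#' it converges to the top canonical correlation.
#'
#' @param x_id,x_age code matrices (`d x n`).
#' @param cp a [corr_params()].
#' @param steps ascent steps.
#' @param lr ascent learning rate.
#' @return the final correlation(s) (numeric, one per pair).
#' @export
maximize_correlation <- function(x_id, x_age, cp, steps = 200, lr = 0.05) {
  rho <- 0
  for (s in seq_len(steps)) {
    zero_grads(cp)
    fw <- corr_forward(cp, x_id, x_age, train = TRUE)
    corr_backward(cp, fw, scale = 1)
    if (cp$n_pairs > 1L) corr_ortho_grads(cp)
    # the Gaussian prior on the module parameters acts as weight decay
    sgd_step(cp, lr = lr, momentum = 0.9,
             weight_decay = cp$prior_strength, maximize = TRUE)
    rho <- as.numeric(fw$rho)
  }
  rho
}

# ascent-side penalty keeping the projection rows near orthonormal so the
# pairs span distinct directions; gradient of -lambda * ||W W' - I||_F^2
# (applied as a *maximize*-direction gradient, hence the minus sign)
corr_ortho_grads <- function(cp, lambda = 0.1) {
  for (nm in c("pu", "pv")) {
    W <- cp$children[[nm]]$params$w
    G <- 4 * lambda * ((W %*% t(W)) - diag(nrow(W))) %*% W
    # grads are interpreted in maximize mode; subtracting the penalty
    # gradient means adding +G here would *increase* the penalty, so store
    # -G as the quantity to ascend
    cp$children[[nm]]$grads$w <- cp$children[[nm]]$grads$w - G
  }
  invisible(cp)
}
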