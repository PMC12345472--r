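# Minimal neural-network substrate: primitive layers as mutable environments
# with hand-written forward/backward passes. Tensor layouts:
#   * image batches:  H x W x C x N arrays (sample-contiguous);
#   * vector batches: d x N matrices (features in rows).
# Convolution and max pooling run through compiled im2col/GEMM kernels.

BN_EPS <- 1e-5

#' Batch normalization (the normalization step)
#'
#' Normalizes each feature over the batch: `(x - mu_B) / sqrt(sigma2_B + eps)`
#' with the biased (1/m) batch variance. This is the statistic-normalization
#' core used inside every BN layer of the networks.
#'
#' @param x numeric vector (one feature, batch values) or matrix
#'   (features x batch); normalization is per feature over the batch axis.
#' @param eps small positive stabilizer.
#' @return normalized values, same shape as `x`.
#' @export
#' @examples
#' batch_normalize(c(1, 2, 3)) # approx (-1.2247, 0, 1.2247)
batch_normalize <- function(x, eps = BN_EPS) {
  if (length(x) == 0) stop("empty batch")
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  if (is.matrix(x)) {
    m <- ncol(x)
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    (x - mu) / sqrt(v + eps)
  } else {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + eps)
  }
}

# ---- shape helpers -----------------------------------------------------

# per-channel mean of an (H,W,C,N) array -> length-C vector
channel_mean <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]
  s <- .colSums(x, hw, d[3] * d[4])             # C*N sums, no reshape copy
  .rowSums(s, d[3], d[4]) / (hw * d[4])
}

# Broadcast helpers return plain vectors meant to be combined with an
# (H,W,C,N) array via recycling; always put the array first in the
# expression so the dim attribute is kept.
# per-channel vector (length C) -> length hw*C, recycled over N
bc_c <- function(vec, hw) rep(vec, each = hw)
# per-(C,N) matrix -> full length hw*C*N
bc_cn <- function(g, hw) rep(as.vector(g), each = hw)

# kept for readability where a full array is genuinely needed
bcast_cn <- function(g, d) {
  array(rep(as.vector(g), each = d[1] * d[2]), dim = d)
}

# channel-and-batch sums: (H,W,C,N) -> (C,N)
sum_hw <- function(x) {
  d <- dim(x)
  matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), nrow = d[3])
}

# global average pool: (H,W,C,N) -> (C,N)
gap2d <- function(x) {
  d <- dim(x)
  sum_hw(x) / (d[1] * d[2])
}

# global max pool: (H,W,C,N) -> (C,N) plus argmax for backward
gmp2d <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]
  m <- matrix(x, nrow = hw)
  idx <- max.col(t(m), ties.method = "first")    # per column of m
  list(y = matrix(m[cbind(idx, seq_len(ncol(m)))], nrow = d[3]), arg = idx)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- primitive layers --------------------------------------------------

new_layer <- function(type, params = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  e$vel <- lapply(params, function(p) p * 0)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("ly_", type), "nn_layer")
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ly_conv <- function(kh, kw, in_c, out_c, stride = 1, pad = 0) {
  w <- array(rnorm(kh * kw * in_c * out_c, 0, sqrt(2 / (kh * kw * out_c))),
             dim = c(kh, kw, in_c, out_c))
  new_layer("conv", list(w = w), list(stride = stride, pad = pad))
}

ly_bn <- function(c, zero_init = FALSE, momentum = 0.1) {
  new_layer("bn",
            list(gamma = rep(if (zero_init) 0 else 1, c), beta = rep(0, c)),
            list(rmean = rep(0, c), rvar = rep(1, c), momentum = momentum))
}

ly_linear <- function(in_d, out_d, bias = TRUE, gain = 2) {
  params <- list(w = matrix(rnorm(out_d * in_d, 0, sqrt(gain / in_d)), out_d, in_d))
  if (bias) params$b <- rep(0, out_d)
  new_layer("linear", params)
}

ly_relu <- function() new_layer("relu")
ly_maxpool <- function(k = 3, stride = 2, pad = 1)
  new_layer("maxpool", extra = list(k = k, stride = stride, pad = pad))

# forward pass; caches what backward needs on the layer environment
ly_fwd <- function(ly, x, train = TRUE) {
  switch(ly$type,
    conv = {
      ly$x <- x
      .conv2d_fwd(x, ly$params$w, ly$stride, ly$pad)
    },
    bn = {
      is4d <- length(dim(x)) == 4
      if (train) {
        if (is4d) {
          d <- dim(x); hw <- d[1] * d[2]; m <- hw * d[4]
          st <- .bn_stats(x, hw, d[3], d[4])
          mu <- st$mu; v <- st$var
          invstd <- 1 / sqrt(v + BN_EPS)
          sc <- ly$params$gamma * invstd
          y <- .bn_apply(x, sc, ly$params$beta - mu * sc, hw, d[3], d[4])
          ly$x4 <- x; ly$mu <- mu
        } else {
          m <- ncol(x)
          mu <- rowMeans(x)
          xc <- x - mu
          v <- rowMeans(xc^2)
          invstd <- 1 / sqrt(v + BN_EPS)
          xhat <- xc * invstd
          y <- xhat * ly$params$gamma + ly$params$beta
        }
        ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
        ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * v * m / max(1, m - 1)
        if (!is4d) ly$xhat <- xhat
        ly$invstd <- invstd; ly$m <- m; ly$is4d <- is4d
        y
      } else {
        invstd <- 1 / sqrt(ly$rvar + BN_EPS)
        if (is4d) {
          hw <- dim(x)[1] * dim(x)[2]
          sc <- ly$params$gamma * invstd
          x * bc_c(sc, hw) + bc_c(ly$params$beta - ly$rmean * sc, hw)
        } else {
          (x - ly$rmean) * (ly$params$gamma * invstd) + ly$params$beta
        }
      }
    },
    linear = {
      ly$x <- x
      y <- ly$params$w %*% x
      if (!is.null(ly$params$b)) y <- y + ly$params$b
      y
    },
    relu = {
      ly$y <- .relu_fwd(x)
      ly$y
    },
    maxpool = {
      ly$xdim <- dim(x)
      r <- .maxpool_fwd(x, ly$k, ly$stride, ly$pad)
      ly$arg <- r$arg
      r$y
    },
    stop("unknown layer type: ", ly$type))
}

ly_bwd <- function(ly, dy) {
  switch(ly$type,
    conv = {
      r <- .conv2d_bwd(ly$x, ly$params$w, dy, ly$stride, ly$pad)
      ly$grads$w <- ly$grads$w + r$dw
      r$dx
    },
    bn = {
      if (ly$is4d) {
        d <- dim(dy)
        r <- .bn_bwd(dy, ly$x4, ly$mu, ly$invstd, ly$params$gamma,
                     d[1] * d[2], d[3], d[4])
        dgamma <- r$dgamma; dbeta <- r$dbeta; dx <- r$dx
      } else {
        dxhat <- dy * ly$params$gamma
        dgamma <- rowSums(dy * ly$xhat)
        dbeta <- rowSums(dy)
        dx <- (dxhat - rowMeans(dxhat) - ly$xhat * rowMeans(dxhat * ly$xhat)) *
              ly$invstd
      }
      ly$grads$gamma <- ly$grads$gamma + dgamma
      ly$grads$beta <- ly$grads$beta + dbeta
      dx
    },
    linear = {
      ly$grads$w <- ly$grads$w + dy %*% t(ly$x)
      if (!is.null(ly$params$b)) ly$grads$b <- ly$grads$b + rowSums(dy)
      t(ly$params$w) %*% dy
    },
    relu = .relu_bwd(dy, ly$y),
    maxpool = .maxpool_bwd(dy, ly$arg, ly$xdim),
    stop("unknown layer type: ", ly$type))
}

# ---- module plumbing ---------------------------------------------------

new_module <- function(type, children = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- children
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("md_", type), "nn_module")
  e
}

# all primitive layers under a module/layer/list, depth-first
collect_layers <- function(x) {
  if (inherits(x, "nn_layer")) return(list(x))
  if (inherits(x, "nn_module")) return(collect_layers(x$children))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

zero_grads <- function(x) {
  for (ly in collect_layers(x)) {
    ly$grads <- lapply(ly$grads, function(g) g * 0)
  }
  invisible(x)
}

n_params <- function(x) {
  sum(vapply(collect_layers(x),
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

# rescale accumulated gradients so their global L2 norm is at most max_norm
clip_grad_norm <- function(modules, max_norm) {
  lys <- collect_layers(modules)
  total <- 0
  for (ly in lys) for (g in ly$grads) total <- total + sum(g * g)
  total <- sqrt(total)
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    for (ly in lys) ly$grads <- lapply(ly$grads, function(g) g * sc)
  }
  total
}

# SGD with momentum and (coupled) weight decay, applied in place
sgd_step <- function(x, lr, momentum = 0.9, weight_decay = 0, maximize = FALSE) {
  sgn <- if (maximize) -1 else 1
  for (ly in collect_layers(x)) {
    for (nm in names(ly$params)) {
      g <- sgn * ly$grads[[nm]] + weight_decay * ly$params[[nm]]
      ly$vel[[nm]] <- momentum * ly$vel[[nm]] + g
      ly$params[[nm]] <- ly$params[[nm]] - lr * ly$vel[[nm]]
    }
  }
  invisible(x)
}

# flatten / restore parameter state (checkpointing, determinism tests)
get_state <- function(x, prefix = "net") {
  lys <- collect_layers(x)
  out <- list()
  for (i in seq_along(lys)) {
    for (nm in names(lys[[i]]$params)) {
      out[[sprintf("%s/%03d.%s.%s", prefix, i, lys[[i]]$type, nm)]] <-
        lys[[i]]$params[[nm]]
    }
    if (lys[[i]]$type == "bn") {
      out[[sprintf("%s/%03d.bn.rmean", prefix, i)]] <- lys[[i]]$rmean
      out[[sprintf("%s/%03d.bn.rvar", prefix, i)]] <- lys[[i]]$rvar
    }
  }
  out
}

set_state <- function(x, state, prefix = "net") {
  lys <- collect_layers(x)
  for (i in seq_along(lys)) {
    for (nm in names(lys[[i]]$params)) {
      key <- sprintf("%s/%03d.%s.%s", prefix, i, lys[[i]]$type, nm)
      if (!key %in% names(state)) stop("checkpoint missing key: ", key)
      p <- state[[key]]
      dim(p) <- dim(lys[[i]]$params[[nm]])
      lys[[i]]$params[[nm]] <- p
    }
    if (lys[[i]]$type == "bn") {
      lys[[i]]$rmean <- as.numeric(state[[sprintf("%s/%03d.bn.rmean", prefix, i)]])
      lys[[i]]$rvar <- as.numeric(state[[sprintf("%s/%03d.bn.rvar", prefix, i)]])
    }
  }
  invisible(x)
}
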