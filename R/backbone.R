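# Feature-extraction backbone: bottleneck residual stages with
# squeeze-and-excitation (SE) channel recalibration. Two presets are shipped:
# `fe_net50` (the full-scale network: stage widths 256/512/1024/2048, blocks
# 3/4/6/3, SE reduction 16, 224x224 input) and `fe_net_tiny` (32/64/128/256,
# blocks 1/1/2/1, 64x64 input) for desk-scale CPU training.

#' Backbone presets
#'
#' @param name `"fe_net50"` or `"fe_net_tiny"`, or pass a fully specified
#'   preset list to validate.
#' @return a `backbone_preset`: stage channel widths, blocks per stage, SE
#'   reduction and placement, stem geometry, input size and embedding dim.
#' @export
backbone_preset <- function(name = c("fe_net_tiny", "fe_net50")) {
  if (is.list(name)) return(validate_preset(structure(name, class = "backbone_preset")))
  name <- match.arg(name)
  p <- if (name == "fe_net50") {
    list(name = name,
         stage_channels = c(256L, 512L, 1024L, 2048L),
         blocks_per_stage = c(3L, 4L, 6L, 3L),
         stage_strides = c(1L, 2L, 2L, 2L),
         se_reduction = 16L,
         se_placement = "last_block_per_stage",
         stem = list(k = 7L, stride = 2L, out = 64L, pool = TRUE),
         input_size = c(224L, 224L),
         embed_dim = 2048L)
  } else {
    list(name = name,
         stage_channels = c(32L, 64L, 128L, 256L),
         blocks_per_stage = c(1L, 1L, 2L, 1L),
         stage_strides = c(2L, 2L, 2L, 2L),
         se_reduction = 8L,
         se_placement = "last_block_per_stage",
         stem = list(k = 3L, stride = 1L, out = 32L, pool = TRUE),
         input_size = c(64L, 64L),
         embed_dim = 256L)
  }
  validate_preset(structure(p, class = "backbone_preset"))
}

validate_preset <- function(p) {
  stopifnot(length(p$stage_channels) == 4, length(p$blocks_per_stage) == 4)
  if (any(p$stage_channels %% p$se_reduction != 0))
    stop("stage channels must be divisible by se_reduction")
  if (p$embed_dim != p$stage_channels[4])
    stop("embed_dim must equal the last stage channel count")
  if (!p$se_placement %in% c("last_block_per_stage", "every_block", "none"))
    stop("unknown se_placement")
  p
}

# ---- SE block ----------------------------------------------------------

md_se <- function(c, r) {
  new_module("se", list(fc1 = ly_linear(c, c %/% r), relu = ly_relu(),
                        fc2 = ly_linear(c %/% r, c)))
}

se_fwd <- function(se, x, train = TRUE) {
  d <- dim(x)
  z <- gap2d(x)                                   # C x N
  h <- ly_fwd(se$children$relu, ly_fwd(se$children$fc1, z, train), train)
  g <- sigmoid(ly_fwd(se$children$fc2, h, train)) # C x N gate
  se$x <- x; se$g <- g; se$d <- d
  x * bc_cn(g, d[1] * d[2])
}

se_bwd <- function(se, dy) {
  d <- se$d; g <- se$g
  dx <- dy * bc_cn(g, d[1] * d[2])
  dg <- sum_hw(dy * se$x)                         # C x N
  ds <- dg * g * (1 - g)                          # through sigmoid
  dz <- ly_bwd(se$children$fc1,
               ly_bwd(se$children$relu, ly_bwd(se$children$fc2, ds)))
  dx + bc_cn(dz / (d[1] * d[2]), d[1] * d[2])
}

#' Squeeze-and-excitation channel recalibration
#'
#' Computes the channel gate `g = sigmoid(W2 relu(W1 GAP(F)))` through a
#' bottleneck of width `C / r` and rescales each channel of the feature map.
#'
#' @param f feature map, `H x W x C x N` array.
#' @param se_params list with `w1` (`C/r x C`), `b1`, `w2` (`C x C/r`), `b2`.
#' @param r reduction ratio; `C` must be divisible by `r`.
#' @return list with `out` (gated map, same shape) and `gate` (`C x N`,
#'   values in (0,1)).
#' @export
se_recalibrate <- function(f, se_params, r) {
  d <- dim(f)
  if (length(d) != 4) stop("feature map must be H x W x C x N")
  C <- d[3]
  if (C %% r != 0) stop("C must be divisible by r")
  if (!all(dim(se_params$w1) == c(C %/% r, C)) ||
      !all(dim(se_params$w2) == c(C, C %/% r)))
    stop("se_params shapes inconsistent with C and r")
  z <- gap2d(f)
  h <- relu(se_params$w1 %*% z + (se_params$b1 %||% 0))
  g <- sigmoid(se_params$w2 %*% h + (se_params$b2 %||% 0))
  list(out = f * bcast_cn(g, d), gate = g)
}

# ---- bottleneck block --------------------------------------------------

md_bottleneck <- function(in_c, out_c, stride, se_reduction = NULL) {
  mid <- out_c %/% 4L
  ch <- list(conv1 = ly_conv(1, 1, in_c, mid),
             bn1 = ly_bn(mid), relu1 = ly_relu(),
             conv2 = ly_conv(3, 3, mid, mid, stride = stride, pad = 1),
             bn2 = ly_bn(mid), relu2 = ly_relu(),
             conv3 = ly_conv(1, 1, mid, out_c),
             bn3 = ly_bn(out_c, zero_init = TRUE),
             relu_out = ly_relu())
  if (!is.null(se_reduction)) ch$se <- md_se(out_c, se_reduction)
  if (in_c != out_c || stride != 1) {
    ch$dconv <- ly_conv(1, 1, in_c, out_c, stride = stride)
    ch$dbn <- ly_bn(out_c)
  }
  new_module("bottleneck", ch)
}

bk_fwd <- function(b, x, train = TRUE) {
  ch <- b$children
  y <- ly_fwd(ch$conv1, x, train)
  y <- ly_fwd(ch$relu1, ly_fwd(ch$bn1, y, train), train)
  y <- ly_fwd(ch$conv2, y, train)
  y <- ly_fwd(ch$relu2, ly_fwd(ch$bn2, y, train), train)
  y <- ly_fwd(ch$bn3, ly_fwd(ch$conv3, y, train), train)
  if (!is.null(ch$se)) y <- se_fwd(ch$se, y, train)
  idn <- if (!is.null(ch$dconv))
    ly_fwd(ch$dbn, ly_fwd(ch$dconv, x, train), train) else x
  ly_fwd(ch$relu_out, y + idn, train)
}

bk_bwd <- function(b, dy) {
  ch <- b$children
  ds <- ly_bwd(ch$relu_out, dy)
  dbr <- ds
  if (!is.null(ch$se)) dbr <- se_bwd(ch$se, dbr)
  dbr <- ly_bwd(ch$conv3, ly_bwd(ch$bn3, dbr))
  dbr <- ly_bwd(ch$bn2, ly_bwd(ch$relu2, dbr))
  dbr <- ly_bwd(ch$conv2, dbr)
  dbr <- ly_bwd(ch$bn1, ly_bwd(ch$relu1, dbr))
  dx <- ly_bwd(ch$conv1, dbr)
  didn <- if (!is.null(ch$dconv))
    ly_bwd(ch$dconv, ly_bwd(ch$dbn, ds)) else ds
  dx + didn
}

# ---- full backbone -----------------------------------------------------

#' Build a parameterized backbone
#'
#' Deterministic given `seed`: He fan-out initialization for convolutions,
#' zero-initialized final BN scale in each residual branch. SE blocks are
#' placed per the preset (default: after the last bottleneck of each stage).
#'
#' @param preset a [backbone_preset()] or preset name.
#' @param seed integer seed for initialization.
#' @return an `nn_module` of type `backbone`.
#' @export
build_backbone <- function(preset = backbone_preset("fe_net_tiny"), seed = 1L) {
  if (is.character(preset)) preset <- backbone_preset(preset)
  preset <- validate_preset(preset)
  with_seed(derive_seed(seed, "backbone"), {
    st <- preset$stem
    stem <- list(conv = ly_conv(st$k, st$k, 3L, st$out, stride = st$stride,
                                pad = (st$k - 1L) %/% 2L),
                 bn = ly_bn(st$out), relu = ly_relu())
    if (isTRUE(st$pool)) stem$pool <- ly_maxpool(3, 2, 1)
    stages <- vector("list", 4)
    in_c <- st$out
    for (s in 1:4) {
      blocks <- vector("list", preset$blocks_per_stage[s])
      for (bi in seq_along(blocks)) {
        use_se <- switch(preset$se_placement,
                         none = FALSE,
                         every_block = TRUE,
                         last_block_per_stage = bi == length(blocks))
        blocks[[bi]] <- md_bottleneck(
          in_c, preset$stage_channels[s],
          stride = if (bi == 1) preset$stage_strides[s] else 1L,
          se_reduction = if (use_se) preset$se_reduction else NULL)
        in_c <- preset$stage_channels[s]
      }
      stages[[s]] <- blocks
    }
    new_module("backbone", list(stem = stem, stages = stages),
               list(preset = preset))
  })
}

#' Run the backbone
#'
#' @param batch `H x W x 3 x N` image array matching the preset input size.
#' @param backbone a [build_backbone()] result.
#' @param train logical; `TRUE` uses batch statistics in BN and caches
#'   activations for the backward pass, `FALSE` is deterministic inference.
#' @return list with `F` (final feature map, `h x w x C x N`) and `x`
#'   (pooled embedding, `C x N`).
#' @export
forward_features <- function(batch, backbone, train = FALSE) {
  d <- dim(batch)
  ps <- backbone$preset
  if (length(d) != 4 || d[1] != ps$input_size[1] || d[2] != ps$input_size[2] ||
      d[3] != 3)
    stop(sprintf("input must be %d x %d x 3 x N", ps$input_size[1], ps$input_size[2]))
  ch <- backbone$children
  y <- ly_fwd(ch$stem$relu, ly_fwd(ch$stem$bn, ly_fwd(ch$stem$conv, batch, train), train), train)
  if (!is.null(ch$stem$pool)) y <- ly_fwd(ch$stem$pool, y, train)
  for (s in 1:4) for (b in ch$stages[[s]]) y <- bk_fwd(b, y, train)
  if (any(!is.finite(y))) stop("non-finite activations in backbone")
  list(F = y, x = gap2d(y))
}

# backward through the backbone given gradients on F and on the pooled x
backbone_bwd <- function(backbone, dF, dx = NULL) {
  if (!is.null(dx)) {
    d <- dim(dF)
    dF <- dF + bcast_cn(dx / (d[1] * d[2]), d)
  }
  ch <- backbone$children
  for (s in 4:1) {
    blocks <- ch$stages[[s]]
    for (bi in rev(seq_along(blocks))) dF <- bk_bwd(blocks[[bi]], dF)
  }
  if (!is.null(ch$stem$pool)) dF <- ly_bwd(ch$stem$pool, dF)
  dF <- ly_bwd(ch$stem$conv, ly_bwd(ch$stem$bn, ly_bwd(ch$stem$relu, dF)))
  dF
}
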