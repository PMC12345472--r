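# Synthetic longitudinal sheep-face cohorts.
#
# Real longitudinal sheep-face data are not publicly deposited, so every
# downstream stage is exercised on a controlled generator in which identity
# and age are independent factors by construction:
#   * identity = stable facial geometry (eye-nose triangle), coat colour,
#     coat texture and a discrete marking pattern, constant across ages;
#   * age = a saturating head-growth curve (rapid change over months 1-4,
#     stabilisation after month 8) plus a fur texture whose amplitude rises
#     after a fur-onset month (months 10-12 hardest);
#   * nuisance = lighting gain/bias, in-plane rotation and sensor noise.

# ---- identity ----------------------------------------------------------

#' Sample stable identity parameters for one synthetic sheep
#'
#' All fields are constant for an individual across its whole life, so over a
#' cohort they are independent of age by construction. The eye-nose triangle
#' (eye spacing, nose offset) carries the localized geometric identity
#' signal; coat hue, coat texture seed and a discrete marking pattern carry
#' appearance cues.
#'
#' @param seed integer; the identity is a deterministic function of it.
#' @return an object of class `identity_params` with fields `eye_spacing`
#'   (fraction of head width, in `[0.28, 0.52]`), `nose_offset` (2-vector,
#'   fraction of head size, each in `[-0.08, 0.08]`), `coat_seed` (integer),
#'   `marking_code` (integer in `0:3`) and `base_hue` (in `[0, 1]`).
#' @export
#' @examples
#' p <- make_identity(7)
#' identical(p, make_identity(7))
make_identity <- function(seed) {
  with_seed(derive_seed(seed, "identity"), {
    structure(list(
      eye_spacing  = runif(1, 0.28, 0.52),
      nose_offset  = runif(2, -0.08, 0.08),
      coat_seed    = sample.int(.Machine$integer.max - 1L, 1L),
      marking_code = sample(0:3, 1L),
      base_hue     = runif(1)
    ), class = "identity_params")
  })
}

#' @export
print.identity_params <- function(x, ...) {
  cat(sprintf(
    "<identity_params> eye_spacing=%.3f nose_offset=(%.3f, %.3f) hue=%.3f marking=%d\n",
    x$eye_spacing, x$nose_offset[1], x$nose_offset[2], x$base_hue, x$marking_code))
  invisible(x)
}

# ---- growth ------------------------------------------------------------

#' Saturating growth model for head size and late-age fur
#'
#' Head scale follows `s_max * (1 - exp(-age / tau))`; with the default
#' `tau = 2.5` months about 80% of growth has occurred by month 4, matching
#' the rapid early change and post-month-8 stabilisation of sheep faces.
#' Fur texture amplitude is `fur_gain * max(0, age - fur_onset)`, zero before
#' `fur_onset`.
#'
#' @param s_max asymptotic head scale (> 0).
#' @param tau growth time constant in months (> 0).
#' @param fur_onset month at which fur texture starts accumulating.
#' @param fur_gain fur amplitude per month past onset (>= 0).
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(s_max = 1, tau = 2.5, fur_onset = 8, fur_gain = 0.05) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (s_max <= 0) stop("s_max must be > 0")
  if (fur_gain < 0) stop("fur_gain must be >= 0")
  structure(list(s_max = s_max, tau = tau,
                 fur_onset = fur_onset, fur_gain = fur_gain),
            class = "growth_model")
}

#' Head scale at a given age
#'
#' @param age_months age in months (>= 0); vectorised.
#' @param g a [growth_model()].
#' @return `s_max * (1 - exp(-age_months / tau))`, monotone nondecreasing in
#'   age and approaching `s_max`.
#' @export
#' @examples
#' g <- growth_model(tau = 2.5)
#' growth_scale(2.5, g) # = s_max * (1 - exp(-1))
growth_scale <- function(age_months, g) {
  stopifnot(inherits(g, "growth_model"))
  if (any(age_months < 0)) stop("age_months must be >= 0")
  g$s_max * (1 - exp(-age_months / g$tau))
}

fur_amplitude <- function(age_months, g) {
  g$fur_gain * pmax(0, age_months - g$fur_onset)
}

# ---- nuisance ----------------------------------------------------------

#' Nuisance (imaging) parameters
#'
#' Photometric gain/bias, in-plane rotation and additive Gaussian noise,
#' applied after rendering to emulate lighting, pose and sensor variation.
#'
#' @param gain multiplicative luminance factor (> 0).
#' @param bias additive contrast offset.
#' @param rotation_deg in-plane rotation in degrees.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @return an object of class `nuisance_params`.
#' @export
nuisance_params <- function(gain = 1, bias = 0, rotation_deg = 0,
                            noise_sigma = 0, seed = 0L) {
  if (gain <= 0) stop("gain must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(gain = gain, bias = bias, rotation_deg = rotation_deg,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "nuisance_params")
}

# ---- rendering ---------------------------------------------------------

# sum of cosine gratings over normalised head coordinates; deterministic in
# (seed, n, freq range)
grating_field <- function(u, v, seed, n, fmin, fmax) {
  with_seed(seed, {
    f <- runif(n, fmin, fmax)
    th <- runif(n, 0, pi)
    ph <- runif(n, 0, 2 * pi)
    out <- 0
    for (i in seq_len(n)) {
      out <- out + cos(2 * pi * f[i] * (u * cos(th[i]) + v * sin(th[i])) + ph[i])
    }
    out / n
  })
}

hsv_to_rgb <- function(h, s, v) {
  # vectorised numeric HSV -> RGB, h,s,v in [0,1]; shapes broadcast to v
  if (length(h) == 1) h <- array(h, dim = dim(v) %||% length(v))
  if (length(s) == 1) s <- array(s, dim = dim(v) %||% length(v))
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  gg <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = gg, b = b)
}

#' Render one synthetic sheep face
#'
#' Draws a head ellipse whose size follows the growth curve, places the
#' eye-nose triangle from the identity geometry, colours the coat from the
#' identity hue/texture/marking, adds age-dependent fur texture, and finally
#' applies the nuisance transform (rotation, gain/bias, noise). Deterministic
#' given all arguments.
#'
#' @param identity an [make_identity()] result.
#' @param age_months integer age in `[1, 12]`.
#' @param nuisance a [nuisance_params()].
#' @param size `c(H, W)` in pixels (at least 32x32).
#' @param g a [growth_model()].
#' @return an object of class `labeled_face`: list with `pixels`
#'   (`H x W x 3` array in `[0, 1]`), `sheep_id`, `age_months`, `box`
#'   (`c(x, y, w, h)` pixels, tight around the head), `nuisance`, `origin`.
#' @export
render_face <- function(identity, age_months, nuisance = nuisance_params(),
                        size = c(64, 64), g = growth_model()) {
  stopifnot(inherits(identity, "identity_params"),
            inherits(nuisance, "nuisance_params"))
  if (age_months < 1 || age_months > 12) stop("age_months must be in [1, 12]")
  H <- size[1]; W <- size[2]
  if (H < 32 || W < 32) stop("size too small to place landmarks (min 32x32)")

  sc <- growth_scale(age_months, g) / g$s_max      # in (0, 1)
  rx <- 0.84 * (W / 2) * sc
  ry <- 0.92 * (H / 2) * sc   # head slightly taller than wide
  cx <- (W + 1) / 2; cy <- (H + 1) / 2

  xs <- matrix(rep(seq_len(W), each = H), nrow = H)   # column index
  ys <- matrix(rep(seq_len(H), times = W), nrow = H)  # row index
  u <- (xs - cx) / rx
  v <- (ys - cy) / ry
  inside <- (u^2 + v^2) <= 1

  # background with a mild vertical gradient
  bg <- 0.72 + 0.08 * (ys - 1) / (H - 1)
  r <- bg; gch <- bg; b <- bg

  # coat colour + stable texture (in head coordinates: age-invariant pattern)
  tex <- grating_field(u, v, derive_seed(identity$coat_seed, "coat"), 4, 0.5, 2.5)
  val <- 0.62 + 0.10 * tex
  sat <- 0.35

  # marking pattern
  mk <- identity$marking_code
  mark <- switch(as.character(mk),
    "0" = matrix(FALSE, H, W),
    "1" = abs(u) < 0.16,                                  # vertical blaze
    "2" = ((u + 0.45)^2 + (v - 0.1)^2) < 0.12,            # left cheek patch
    "3" = ((u - 0.45)^2 + (v - 0.1)^2) < 0.12)            # right cheek patch
  val[mark] <- pmin(1, val[mark] + 0.22)
  satm <- matrix(sat, H, W); satm[mark] <- 0.10

  # fur: mid-frequency texture, amplitude grows after fur_onset
  af <- fur_amplitude(age_months, g)
  if (af > 0) {
    fur <- grating_field(u, v, derive_seed(identity$coat_seed, "fur"), 6, 4, 9)
    val <- val + af * fur
  }

  col <- hsv_to_rgb(identity$base_hue, satm, pmin(pmax(val, 0), 1))
  r[inside] <- col$r[inside]; gch[inside] <- col$g[inside]; b[inside] <- col$b[inside]

  # eyes: dark ellipses on the upper face
  es <- identity$eye_spacing
  for (sgn in c(-1, 1)) {
    eye <- (((u - sgn * es) / 0.10)^2 + ((v + 0.28) / 0.13)^2) < 1
    r[eye] <- 0.07; gch[eye] <- 0.07; b[eye] <- 0.09
  }
  # nose: dark downward wedge displaced by the identity nose offset
  nx <- identity$nose_offset[1]; ny <- 0.42 + identity$nose_offset[2]
  nose <- (v >= ny) & (v <= ny + 0.24) &
          (abs(u - nx) <= 0.13 * (1 - (v - ny) / 0.24))
  r[nose] <- 0.16; gch[nose] <- 0.12; b[nose] <- 0.12

  img <- array(c(r, gch, b), dim = c(H, W, 3))

  # nuisance: rotate, then photometric, then noise
  theta <- nuisance$rotation_deg * pi / 180
  if (theta != 0) img <- rotate_bilinear(img, theta, fill = bg)
  img <- img * nuisance$gain + nuisance$bias
  if (nuisance$noise_sigma > 0) {
    img <- img + with_seed(derive_seed(nuisance$seed, "noise"),
                           array(rnorm(length(img), 0, nuisance$noise_sigma),
                                 dim = dim(img)))
  }
  img <- pmin(pmax(img, 0), 1)

  # tight box around the (possibly rotated) head ellipse
  hw <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
  hh <- sqrt((rx * sin(theta))^2 + (ry * cos(theta))^2)
  x0 <- max(1, floor(cx - hw)); y0 <- max(1, floor(cy - hh))
  x1 <- min(W, ceiling(cx + hw)); y1 <- min(H, ceiling(cy + hh))
  box <- c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)

  structure(list(pixels = img, sheep_id = NA_character_,
                 age_months = as.integer(age_months), box = box,
                 nuisance = nuisance, origin = "original"),
            class = "labeled_face")
}

# inverse-map bilinear rotation about the image centre
rotate_bilinear <- function(img, theta, fill = 0.75) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), nrow = H) - cx
  ys <- matrix(rep(seq_len(H), times = W), nrow = H) - cy
  # source coordinates (rotate by -theta)
  sx <- cos(theta) * xs + sin(theta) * ys + cx
  sy <- -sin(theta) * xs + cos(theta) * ys + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  fillm <- if (is.matrix(fill)) fill else matrix(fill, H, W)
  out <- img
  for (ch in 1:3) {
    plane <- img[, , ch]
    getpx <- function(yy, xx) {
      ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
      val <- fillm
      val[ok] <- plane[cbind(yy[ok], xx[ok])]
      val
    }
    v00 <- getpx(y0, x0); v01 <- getpx(y0, x0 + 1)
    v10 <- getpx(y0 + 1, x0); v11 <- getpx(y0 + 1, x0 + 1)
    out[, , ch] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                   fy * ((1 - fx) * v10 + fx * v11)
  }
  out
}

#' @export
print.labeled_face <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_face> %s age=%dmo %dx%d box=(%d,%d,%d,%d) [%s]\n",
              x$sheep_id, x$age_months, d[1], d[2],
              x$box[1], x$box[2], x$box[3], x$box[4], x$origin))
  invisible(x)
}

# ---- augmentation ------------------------------------------------------

#' Augmentation policy
#'
#' The training-set expansion policy: each original image yields itself plus
#' one photometric (luminance/contrast) jitter, one noise injection and one
#' random rotation -- a x4 expansion. The multiplier and all jitter ranges
#' are configurable.
#'
#' @param gain_range photometric gain drawn from `1 +/- gain_range`.
#' @param bias_range photometric bias drawn from `+/- bias_range`.
#' @param noise_sigma Gaussian noise s.d. for the noise variant.
#' @param rotation_deg rotation drawn from `+/- rotation_deg` degrees.
#' @param multiplier total images produced per input (default 4).
#' @return an object of class `augment_policy`.
#' @export
augment_policy <- function(gain_range = 0.2, bias_range = 0.1,
                           noise_sigma = 0.02, rotation_deg = 15,
                           multiplier = 4L) {
  stopifnot(gain_range >= 0, bias_range >= 0, noise_sigma >= 0,
            rotation_deg >= 0, multiplier >= 1)
  structure(list(gain_range = gain_range, bias_range = bias_range,
                 noise_sigma = noise_sigma, rotation_deg = rotation_deg,
                 multiplier = as.integer(multiplier)),
            class = "augment_policy")
}

#' Augment one labelled image
#'
#' Returns the original plus `multiplier - 1` variants cycling through
#' photometric jitter, noise injection and random rotation; identity and age
#' labels are preserved. Deterministic given `seed`.
#'
#' @param img a `labeled_face`.
#' @param policy an [augment_policy()].
#' @param seed integer seed.
#' @return list of `multiplier` `labeled_face` objects, the first being the
#'   input.
#' @export
augment_image <- function(img, policy = augment_policy(), seed = 0L) {
  stopifnot(inherits(img, "labeled_face"), inherits(policy, "augment_policy"))
  out <- vector("list", policy$multiplier)
  out[[1]] <- img
  if (policy$multiplier == 1L) return(out)
  kinds <- rep(c("photometric", "noise", "rotation"),
               length.out = policy$multiplier - 1L)
  draws <- with_seed(derive_seed(seed, "augment"), {
    lapply(seq_along(kinds), function(i) {
      c(gain = runif(1, 1 - policy$gain_range, 1 + policy$gain_range),
        bias = runif(1, -policy$bias_range, policy$bias_range),
        rot  = runif(1, -policy$rotation_deg, policy$rotation_deg),
        nz   = derive_seed(seed, paste0("noise", i)))
    })
  })
  for (i in seq_along(kinds)) {
    d <- draws[[i]]
    v <- img
    v$origin <- "augmented"
    if (kinds[i] == "photometric") {
      v$pixels <- pmin(pmax(img$pixels * d[["gain"]] + d[["bias"]], 0), 1)
    } else if (kinds[i] == "noise") {
      if (policy$noise_sigma > 0) {
        v$pixels <- pmin(pmax(img$pixels +
          with_seed(as.integer(d[["nz"]]),
                    array(rnorm(length(img$pixels), 0, policy$noise_sigma),
                          dim = dim(img$pixels))), 0), 1)
      }
    } else {
      th <- d[["rot"]] * pi / 180
      if (th != 0) {
        v$pixels <- rotate_bilinear(img$pixels, th,
                                    fill = mean(img$pixels[1, , ]))
        v$box <- rotate_box(img$box, th, dim(img$pixels)[1:2])
      }
    }
    out[[i + 1L]] <- v
  }
  out
}

# bbox of the rotated bbox corners, clipped to the image
rotate_box <- function(box, theta, hw) {
  H <- hw[1]; W <- hw[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- c(box[1], box[1] + box[3] - 1)
  ys <- c(box[2], box[2] + box[4] - 1)
  corners <- expand.grid(x = xs, y = ys)
  rx <- cos(theta) * (corners$x - cx) - sin(theta) * (corners$y - cy) + cx
  ry <- sin(theta) * (corners$x - cx) + cos(theta) * (corners$y - cy) + cy
  x0 <- max(1, floor(min(rx))); y0 <- max(1, floor(min(ry)))
  x1 <- min(W, ceiling(max(rx))); y1 <- min(H, ceiling(max(ry)))
  c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)
}

# ---- dataset generation ------------------------------------------------

#' Generate a synthetic longitudinal cohort on disk
#'
#' Renders `n_ids x length(ages) x reps_per_cell` original images, assigns
#' splits under the chosen protocol, optionally expands the training split by
#' the augmentation multiplier, writes PNGs plus CSV and JSONL manifests to
#' `out_dir`, and returns the manifest.
#'
#' Protocols: `age_based` puts ages 1-4 in train, 5-8 in validation and 9-12
#' in test (every individual appears in all splits at disjoint ages);
#' `id_based` partitions individuals 80%/9%/11% across splits so no
#' individual crosses splits.
#'
#' @param n_ids number of individuals.
#' @param ages integer ages in months (subset of 1:12).
#' @param reps_per_cell images per (individual, age) cell.
#' @param protocol `"age_based"` or `"id_based"`.
#' @param augment_train if `TRUE`, expand only the train split by the policy
#'   multiplier.
#' @param seed root seed; everything (identities, nuisances, augmentation)
#'   derives from it.
#' @param out_dir output directory (created if needed).
#' @param size image size `c(H, W)`.
#' @param g growth model.
#' @param policy augmentation policy.
#' @return a `dataset_manifest` (see [read_manifest()]).
#' @export
generate_dataset <- function(n_ids, ages = 1:12, reps_per_cell = 2,
                             protocol = c("age_based", "id_based"),
                             augment_train = FALSE, seed = 1L, out_dir,
                             size = c(64, 64), g = growth_model(),
                             policy = augment_policy()) {
  protocol <- match.arg(protocol)
  if (length(ages) == 0) stop("ages must be nonempty")
  if (any(ages < 1 | ages > 12)) stop("ages must be within 1..12")
  if (protocol == "id_based" && n_ids < 3)
    stop("id_based protocol needs at least 3 individuals")
  if (n_ids < 1) stop("n_ids must be >= 1")
  dir.create(file.path(out_dir, "img"), recursive = TRUE, showWarnings = FALSE)

  ids <- sprintf("sheep%03d", seq_len(n_ids))
  idents <- make_cohort_identities(n_ids, seed = seed)

  split_of <- make_split_assigner(protocol, ids, ages, seed)

  rows <- list(); k <- 0L
  for (i in seq_len(n_ids)) {
    for (a in ages) {
      for (rep in seq_len(reps_per_cell)) {
        k <- k + 1L
        nseed <- derive_seed(seed, sprintf("nui-%d-%d-%d", i, a, rep))
        nui <- with_seed(nseed, nuisance_params(
          gain = runif(1, 0.85, 1.15), bias = runif(1, -0.08, 0.08),
          rotation_deg = runif(1, -10, 10),
          noise_sigma = runif(1, 0, 0.02), seed = nseed))
        img <- render_face(idents[[i]], a, nui, size = size, g = g)
        img$sheep_id <- ids[i]
        sp <- split_of(ids[i], a)
        base <- sprintf("img/%s_a%02d_r%02d", ids[i], a, rep)
        variants <- if (augment_train && sp == "train") {
          augment_image(img, policy,
                        seed = derive_seed(seed, sprintf("aug-%d-%d-%d", i, a, rep)))
        } else list(img)
        for (j in seq_along(variants)) {
          v <- variants[[j]]
          path <- if (j == 1L) paste0(base, ".png")
                  else sprintf("%s_aug%d.png", base, j - 1L)
          png::writePNG(v$pixels, file.path(out_dir, path))
          rows[[length(rows) + 1L]] <- data.frame(
            path = path, sheep_id = ids[i], age_months = a,
            x = v$box[1], y = v$box[2], w = v$box[3], h = v$box[4],
            split = sp, origin = v$origin, stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  m <- new_manifest(records, protocol)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}

#' Sample a cohort of mutually distinct identities
#'
#' Identities for an enrolled cohort are drawn by stratified
#' (Latin-hypercube) sampling over the continuous identity fields — eye
#' spacing, the two nose-offset components and coat hue — with marking
#' patterns assigned round-robin. This emulates the enrollment setting in
#' which the individuals of a herd are a priori distinct, and guarantees
#' that any two cohort members differ appreciably in at least one stable
#' trait; each field remains constant over the individual's life, so
#' identity stays independent of age by construction.
#'
#' @param n number of individuals.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return list of `n` `identity_params`.
#' @export
make_cohort_identities <- function(n, seed = 1L) {
  with_seed(derive_seed(seed, "cohort-ids"), {
    strat <- function(lo, hi) {
      # one draw per stratum, strata order permuted
      ((sample.int(n) - runif(n)) / n) * (hi - lo) + lo
    }
    es <- strat(0.28, 0.52)
    nx <- strat(-0.08, 0.08)
    ny <- strat(-0.08, 0.08)
    hue <- strat(0, 1)
    lapply(seq_len(n), function(i) {
      structure(list(
        eye_spacing  = es[i],
        nose_offset  = c(nx[i], ny[i]),
        coat_seed    = sample.int(.Machine$integer.max - 1L, 1L),
        marking_code = (i - 1L) %% 4L,
        base_hue     = hue[i]
      ), class = "identity_params")
    })
  })
}

make_split_assigner <- function(protocol, ids, ages, seed) {
  if (protocol == "age_based") {
    function(id, age) {
      if (age <= 4) "train" else if (age <= 8) "val" else "test"
    }
  } else {
    n <- length(ids)
    n_tr <- max(1L, round(n * 44 / 55))
    n_va <- max(1L, round(n * 5 / 55))
    if (n_tr + n_va >= n) { n_tr <- n - 2L; n_va <- 1L }
    perm <- with_seed(derive_seed(seed, "idsplit"), sample(ids))
    assign <- stats::setNames(rep("test", n), perm)
    assign[perm[seq_len(n_tr)]] <- "train"
    assign[perm[n_tr + seq_len(n_va)]] <- "val"
    function(id, age) unname(assign[id])
  }
}
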