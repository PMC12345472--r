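# Model evaluation: identification metrics overall and per age group,
# verification EER on cosine scores, decoupling leakage diagnostics, and
# gradient-weighted class-activation (saliency) maps.

default_age_groups <- function() list(`1-3` = 1:3, `4-6` = 4:6,
                                      `7-9` = 7:9, `10-12` = 10:12)

#' Evaluate a trained model on one split
#'
#' Identification is nearest class vector on the unit-normalized identity
#' code. Computes precision/recall/F1/accuracy (pooled one-vs-rest),
#' mAP@0.5 (the predicted box is the input crop box for this
#' classification-only pipeline), both EER variants with FAR/FRR curves,
#' per-age-group metric rows, and leakage diagnostics.
#'
#' @param fit an `ovineid_fit` (or a model plus `classes`).
#' @param manifest a `dataset_manifest`.
#' @param dir data directory.
#' @param split split to evaluate.
#' @param age_groups named list of month vectors; default the four groups
#'   1-3, 4-6, 7-9, 10-12.
#' @param classes identity labels in training order (taken from `fit` if
#'   absent).
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(fit, manifest, dir, split = "test",
                     age_groups = default_age_groups(), classes = NULL) {
  model <- if (inherits(fit, "ovineid_fit")) fit$model else fit
  if (is.null(classes)) classes <- fit$classes
  ds <- load_split(manifest, dir, split)
  ev <- model_embed(model, ds$x)
  pred <- classes[predict_ids(model, ev$x_id)]
  truth <- as.character(ds$sheep_id)

  cc <- confusion_counts(pred, truth)
  overall <- classification_metrics(cc)

  # classification mAP: each prediction keeps its crop box, scored by the
  # top cosine similarity
  W <- unit_cols(model$cosface$children$wlayer$params$w)
  cosm <- crossprod(W, unit_cols(ev$x_id))
  score <- apply(cosm, 2, max)
  boxes <- as.data.frame(ds$box)
  names(boxes) <- c("x", "y", "w", "h")
  map50 <- map_at_50(cbind(data.frame(class = pred, score = score), boxes),
                     cbind(data.frame(class = truth), boxes))

  # verification pairs: all pairs of distinct images, cosine similarity on
  # the identity code
  xn <- unit_cols(ev$x_id)
  sims <- crossprod(xn)
  iu <- which(upper.tri(sims))
  same <- outer(truth, truth, "==")[iu]
  eer <- eer_metrics(sims[iu], same, counts = cc)

  per_group <- lapply(names(age_groups), function(g) {
    sel <- ds$age_months %in% age_groups[[g]]
    if (!any(sel)) {
      return(data.frame(group = g, n = 0L, top1 = NA, precision = NA,
                        recall = NA, f1 = NA, accuracy = NA, empty = TRUE))
    }
    mg <- classification_metrics(confusion_counts(pred[sel], truth[sel]))
    data.frame(group = g, n = sum(sel), top1 = mean(pred[sel] == truth[sel]),
               precision = mg$precision, recall = mg$recall, f1 = mg$f1,
               accuracy = mg$accuracy, empty = FALSE)
  })
  per_group <- do.call(rbind, per_group)

  leak <- decoupling_report(model, manifest, dir, split = split, data = ds,
                            embeddings = ev)

  structure(list(
    split = split, n = length(truth),
    top1_accuracy = mean(pred == truth),
    precision = overall$precision, recall = overall$recall,
    f1 = overall$f1, accuracy = overall$accuracy,
    map50 = as.numeric(map50), map50_per_class = attr(map50, "per_class"),
    eer_eq11 = eer$eer_eq11, eer_roc = eer$eer_roc, far_frr = eer$curve,
    per_age_group = per_group, leakage = leak,
    counts = cc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split=%s n=%d top1=%.3f P=%.3f R=%.3f F1=%.3f mAP@0.5=%.3f\n",
              x$split, x$n, x$top1_accuracy, x$precision, x$recall, x$f1, x$map50))
  cat(sprintf("  eer_eq11=%.4f eer_roc=%.4f | R2(age|x_age)=%.3f R2(age|x_id)=%.3f |rho|=%.3f\n",
              x$eer_eq11, x$eer_roc, x$leakage$r2_age_code,
              x$leakage$r2_id_code, x$leakage$abs_rho))
  print(x$per_age_group, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON file; the FAR/FRR curve goes to a two-column CSV
#'   next to it (`<path>_farfrr.csv`).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- report
  class(obj) <- NULL
  obj$counts <- list(pooled = as.list(report$counts$pooled),
                     per_class = report$counts$per_class)
  curve <- obj$far_frr
  obj$far_frr <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (nrow(curve)) {
    utils::write.csv(curve[, c("FAR", "FRR")],
                     paste0(sub("\\.json$", "", path), "_farfrr.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

# truncated-SVD least squares (pseudo-inverse restricted to the leading
# singular directions); handles singular / underdetermined designs and keeps
# the regression stable when d approaches n
pinv_coef <- function(A, y, rcond = 1e-8, max_rank = Inf) {
  sv <- svd(A)
  keep <- which(sv$d > rcond * sv$d[1])
  if (length(keep) > max_rank) keep <- keep[seq_len(max_rank)]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

# cross-fitted linear R^2 of y on the columns of X (d x n): fit least
# squares (pseudo-inverse) on one half, score on the held-out half, and
# pool; cross-fitting keeps the permutation null at ~0 even when d is
# comparable to n
r2_cv <- function(X, y, seed = 1L) {
  n <- length(y)
  idx <- with_seed(derive_seed(seed, "r2cv"), sample.int(n))
  half <- idx[seq_len(n %/% 2)]
  other <- setdiff(seq_len(n), half)
  sse <- 0; sst <- 0
  for (tr in list(half, other)) {
    te <- setdiff(seq_len(n), tr)
    A <- cbind(1, t(X[, tr, drop = FALSE]))
    fitc <- pinv_coef(A, y[tr], max_rank = min(64L, length(tr) %/% 4L))
    pred <- as.numeric(cbind(1, t(X[, te, drop = FALSE])) %*% fitc)
    sse <- sse + sum((y[te] - pred)^2)
    sst <- sst + sum((y[te] - mean(y[tr]))^2)
  }
  r2 <- 1 - sse / sst
  if (r2 < 0) structure(0, clipped = TRUE) else r2
}

#' Decoupling leakage diagnostics
#'
#' Quantifies residual age information: cross-fitted linear R^2 of age
#' regressed on the age code and on the identity code, plus the final
#' projected correlation |rho| from the adversarial module. For a properly
#' decoupled model the age code predicts age well and the identity code
#' does not.
#'
#' The default split is `"all"`: under the age-based protocol a single
#' split spans only four months (and the growth curve is flat over the
#' test window), so age is unidentifiable within one split for any code;
#' the leakage question is only meaningful across the full age range.
#'
#' @param fit an `ovineid_fit` or `ovineid_model`.
#' @param manifest,dir,split evaluation data.
#' @param data,embeddings optional pre-loaded split / embeddings.
#' @return list with `r2_age_code`, `r2_id_code`, `r2_embedding`,
#'   `abs_rho`.
#' @export
decoupling_report <- function(fit, manifest, dir, split = "all",
                              data = NULL, embeddings = NULL) {
  model <- if (inherits(fit, "ovineid_fit")) fit$model else fit
  if (is.null(data)) data <- load_split(manifest, dir, split)
  if (is.null(embeddings)) embeddings <- model_embed(model, data$x)
  age <- data$age_months
  r2_id <- r2_cv(embeddings$x_id, age)
  r2_x <- r2_cv(embeddings$x, age)
  r2_age <- if (is.null(embeddings$x_age)) NA_real_
            else r2_cv(embeddings$x_age, age)
  abs_rho <- NA_real_
  if (model$use_corr && !is.null(embeddings$x_age)) {
    fw <- corr_forward(model$corr, embeddings$x_id, embeddings$x_age,
                       train = FALSE)
    abs_rho <- corr_rho_top(fw$rho)
  }
  list(r2_age_code = as.numeric(r2_age), r2_id_code = as.numeric(r2_id),
       r2_embedding = as.numeric(r2_x), abs_rho = abs_rho)
}

# ---- saliency ----------------------------------------------------------

upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # align centers of source and target grids
  ys <- (seq_len(H) - 0.5) * h / H + 0.5
  xs <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
       m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

# gradient-weighted class activation map from a feature map and the gradient
# of the target logit w.r.t. it
gradcam_from <- function(Fmap, dF, out_size) {
  d <- dim(Fmap)
  wts <- apply(dF, 3, mean)                        # GAP of gradients
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + wts[c] * Fmap[, , c]
  cam[cam < 0] <- 0
  cam <- upsample_bilinear(cam, out_size[1], out_size[2])
  mx <- max(cam)
  if (mx <= 0) return(structure(matrix(0, out_size[1], out_size[2]),
                                zero_gradient = TRUE))
  cam / mx
}

#' Saliency map for one image and target identity
#'
#' Gradient-weighted channel combination of the final feature map (the
#' gradient of the target-class cosine logit), rectified, bilinearly
#' upsampled to the input resolution and max-normalized to `[0, 1]`.
#'
#' @param fit an `ovineid_fit` or `ovineid_model`.
#' @param image `H x W x 3` pixel array (or a `labeled_face`).
#' @param target_class integer class index (1-based) or class label.
#' @param classes label vector for label lookup.
#' @return `H x W` matrix in `[0, 1]`; attribute `zero_gradient` flags an
#'   all-zero map.
#' @export
saliency_map <- function(fit, image, target_class, classes = NULL) {
  model <- if (inherits(fit, "ovineid_fit")) fit$model else fit
  if (is.null(classes) && inherits(fit, "ovineid_fit")) classes <- fit$classes
  if (inherits(image, "labeled_face")) image <- image$pixels
  if (is.character(target_class)) {
    if (is.null(classes)) stop("classes needed to resolve a label")
    target_class <- match(target_class, classes)
  }
  if (is.na(target_class) || target_class < 1 || target_class > model$n_classes)
    stop("invalid target class")
  x <- array(image, dim = c(dim(image)[1], dim(image)[2], 3, 1))
  bun <- model_forward(model, x, train = TRUE)
  # d logit / d x_id for logit = s * cos(theta_target)
  xid <- bun$x_id[, 1]
  nx <- sqrt(sum(xid^2)) + 1e-12
  xhat <- xid / nx
  wt <- model$cosface$children$wlayer$params$w[, target_class]
  what <- wt / (sqrt(sum(wt^2)) + 1e-12)
  dxid <- model$cosface$s * (what - sum(what * xhat) * xhat) / nx
  dxid <- matrix(dxid, ncol = 1)
  if (model$use_decouple) {
    gr <- decouple_bwd(model$decoupler, dxid)
    dF <- gr$dF
    dx <- gr$dx
  } else {
    dF <- array(0, dim(bun$F))
    dx <- dxid
  }
  d <- dim(bun$F)
  dF <- dF + bcast_cn(matrix(dx / (d[1] * d[2]), d[3], 1), d)
  gradcam_from(bun$F[, , , 1, drop = TRUE], array(dF, d[1:3]),
               dim(image)[1:2])
}
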