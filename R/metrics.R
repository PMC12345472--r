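# Evaluation metric suite: one-vs-rest confusion tallies, the derived
# classification metrics, box IoU, mAP@0.5, and the two equal-error-rate
# variants (the pooled misclassification form and the ROC FAR=FRR form).

#' One-vs-rest confusion counts
#'
#' Tallies TP/FP/TN/FN per class (one-vs-rest) and micro-pooled totals over
#' all classes; the pooled totals sum to `n * n_classes`.
#'
#' @param predicted,truth equal-length vectors of class labels.
#' @return an object of class `confusion_counts`: list with `per_class`
#'   (data.frame) and `pooled` (named vector TP/FP/TN/FN).
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  predicted <- as.character(predicted); truth <- as.character(truth)
  classes <- sort(unique(c(predicted, truth)))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               stringsAsFactors = FALSE)
  }))
  pooled <- c(TP = sum(per$TP), FP = sum(per$FP), TN = sum(per$TN),
              FN = sum(per$FN))
  structure(list(per_class = per, pooled = pooled, n = length(truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %d samples, %d classes; pooled TP=%d FP=%d TN=%d FN=%d\n",
              x$n, nrow(x$per_class), x$pooled["TP"], x$pooled["FP"],
              x$pooled["TN"], x$pooled["FN"]))
  invisible(x)
}

safe_div <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2 P R / (P + R)`, `Accuracy = (TP+TN)/(TP+TN+FP+FN)`; a 0/0 ratio
#' is reported as 0 with attribute `undefined = TRUE`.
#'
#' @param c a [confusion_counts()] or a named vector with TP/FP/TN/FN.
#' @return named list with `precision`, `recall`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(c) {
  p <- if (inherits(c, "confusion_counts")) c$pooled else c
  precision <- safe_div(p[["TP"]], p[["TP"]] + p[["FP"]])
  recall <- safe_div(p[["TP"]], p[["TP"]] + p[["FN"]])
  f1 <- if (precision + recall == 0) structure(0, undefined = TRUE)
        else 2 * precision * recall / (precision + recall)
  accuracy <- safe_div(p[["TP"]] + p[["TN"]],
                       p[["TP"]] + p[["TN"]] + p[["FP"]] + p[["FN"]])
  list(precision = as.numeric(precision), recall = as.numeric(recall),
       f1 = as.numeric(f1), accuracy = as.numeric(accuracy))
}

#' Intersection over union of two boxes
#'
#' Boxes are `c(x, y, w, h)`; degenerate unions yield 0 with attribute
#' `undefined = TRUE`.
#'
#' @param boxA,boxB numeric boxes `c(x, y, w, h)` with `w, h >= 0`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(boxA, boxB) {
  if (any(c(boxA[3:4], boxB[3:4]) < 0)) stop("negative box size")
  ix <- max(0, min(boxA[1] + boxA[3], boxB[1] + boxB[3]) - max(boxA[1], boxB[1]))
  iy <- max(0, min(boxA[2] + boxA[4], boxB[2] + boxB[4]) - max(boxA[2], boxB[2]))
  inter <- ix * iy
  uni <- boxA[3] * boxA[4] + boxB[3] * boxB[4] - inter
  if (uni <= 0) return(structure(0, undefined = TRUE))
  as.numeric(inter / uni)
}

#' Mean average precision at IoU 0.5
#'
#' Per-class all-point-interpolated average precision: predictions are
#' ranked by score; one counts as TP iff its class matches and its box
#' overlaps a not-yet-matched ground truth of that class with IoU >= 0.5.
#' Classes without ground truth are excluded (attribute `skipped`).
#'
#' @param pred data.frame with columns `class`, `score`, `x`, `y`, `w`, `h`.
#' @param truth data.frame with columns `class`, `x`, `y`, `w`, `h`.
#' @param iou_threshold matching threshold (default 0.5).
#' @return mAP in `[0, 1]`; attribute `per_class` holds each class AP.
#' @export
map_at_50 <- function(pred, truth, iou_threshold = 0.5) {
  classes <- sort(unique(truth$class))
  skipped <- setdiff(unique(pred$class), classes)
  aps <- vapply(classes, function(cl) {
    gt <- truth[truth$class == cl, , drop = FALSE]
    pr <- pred[pred$class == cl, , drop = FALSE]
    if (nrow(pr) == 0) return(0)
    pr <- pr[order(-pr$score), , drop = FALSE]
    matched <- rep(FALSE, nrow(gt))
    tp <- numeric(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(gt))) {
        if (matched[j]) next
        ov <- iou(as.numeric(pr[i, c("x", "y", "w", "h")]),
                  as.numeric(gt[j, c("x", "y", "w", "h")]))
        if (ov > best) { best <- ov; bj <- j }
      }
      if (bj > 0 && best >= iou_threshold) { tp[i] <- 1; matched[bj] <- TRUE }
    }
    cum_tp <- cumsum(tp)
    rec <- cum_tp / nrow(gt)
    prec <- cum_tp / seq_along(tp)
    # all-point interpolation: integrate precision envelope over recall
    ap <- 0; prev_r <- 0
    for (i in seq_along(tp)) {
      if (tp[i] == 1) {
        ap <- ap + max(prec[i:length(prec)]) * (rec[i] - prev_r)
        prev_r <- rec[i]
      }
    }
    ap
  }, 1)
  structure(mean(aps), per_class = stats::setNames(aps, classes),
            skipped = skipped)
}

#' Equal-error-rate metrics for verification scores
#'
#' Two quantities are reported side by side: `eer_eq11`, the pooled
#' misclassification rate `(FP + FN) / (TP + TN + FP + FN)` computed from
#' classification counts; and `eer_roc`, the rate at the decision threshold
#' where the false-acceptance rate (FAR, fraction of different-identity
#' pairs accepted) equals the false-rejection rate (FRR, fraction of
#' same-identity pairs rejected), linearly interpolated between adjacent
#' thresholds on the score axis.
#'
#' @param scores numeric similarity scores for verification pairs.
#' @param same logical; `TRUE` for same-identity pairs.
#' @param counts optional [confusion_counts()] for `eer_eq11`.
#' @return list with `eer_eq11` (or `NA` without counts), `eer_roc`,
#'   and `curve` (data.frame threshold/FAR/FRR).
#' @export
eer_metrics <- function(scores, same, counts = NULL) {
  if (length(scores) == 0) stop("empty score set")
  if (length(scores) != length(same)) stop("length mismatch")
  eer_eq11 <- NA_real_
  if (!is.null(counts)) {
    p <- if (inherits(counts, "confusion_counts")) counts$pooled else counts
    eer_eq11 <- as.numeric((p[["FP"]] + p[["FN"]]) /
                           (p[["TP"]] + p[["TN"]] + p[["FP"]] + p[["FN"]]))
  }
  if (!any(same) || all(same)) {
    return(list(eer_eq11 = eer_eq11, eer_roc = NA_real_,
                curve = data.frame()))
  }
  thr0 <- sort(unique(scores))
  nd <- sum(!same); ns <- sum(same)
  cnt_d <- tabulate(match(scores[!same], thr0), nbins = length(thr0))
  cnt_s <- tabulate(match(scores[same], thr0), nbins = length(thr0))
  ge_d <- rev(cumsum(rev(cnt_d)))          # diff-pair scores >= threshold
  lt_s <- cumsum(cnt_s) - cnt_s            # same-pair scores < threshold
  thr <- c(thr0[1] - 1e-9, thr0, thr0[length(thr0)] + 1e-9)
  far <- c(1, ge_d / nd, 0)
  frr <- c(0, lt_s / ns, 1)
  d <- far - frr   # decreasing in t from +1 to -1
  k <- which(d <= 0)[1]
  eer_roc <- if (is.na(k)) {
    far[length(far)]
  } else if (k == 1 || d[k] == 0) {
    (far[k] + frr[k]) / 2
  } else {
    # linear interpolation between thresholds k-1 and k where FAR crosses FRR
    w <- d[k - 1] / (d[k - 1] - d[k])
    f1 <- far[k - 1] + w * (far[k] - far[k - 1])
    f2 <- frr[k - 1] + w * (frr[k] - frr[k - 1])
    (f1 + f2) / 2
  }
  list(eer_eq11 = eer_eq11, eer_roc = as.numeric(eer_roc),
       curve = data.frame(threshold = thr, FAR = far, FRR = frr))
}
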