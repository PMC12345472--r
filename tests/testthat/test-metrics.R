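test_that("confusion counts tally one-vs-rest correctly", {
  cc <- confusion_counts(c("A", "B", "B"), c("A", "A", "B"))
  a <- cc$per_class[cc$per_class$class == "A", ]
  expect_equal(unlist(a[, c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 0, TN = 1, FN = 1))
  b <- cc$per_class[cc$per_class$class == "B", ]
  expect_equal(unlist(b[, c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 1, TN = 1, FN = 0))
  expect_equal(sum(cc$pooled), 3 * 2)   # n x classes conserved
  # permutation invariance
  perm <- c(3, 1, 2)
  cc2 <- confusion_counts(c("A", "B", "B")[perm], c("A", "A", "B")[perm])
  expect_equal(cc2$pooled, cc$pooled)
  # perfect classifier
  cp <- confusion_counts(c("A", "B"), c("A", "B"))
  expect_equal(unname(cp$pooled[c("FP", "FN")]), c(0, 0))
  expect_error(confusion_counts("A", c("A", "B")), "length")
})

test_that("classification metrics match their printed formulas", {
  m <- classification_metrics(c(TP = 9, FP = 1, TN = 0, FN = 3))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75), tolerance = 1e-6)
  expect_equal(round(m$f1, 4), 0.8182)
  m2 <- classification_metrics(c(TP = 9, TN = 87, FP = 1, FN = 3))
  expect_equal(m2$accuracy, 0.96)
  perfect <- classification_metrics(c(TP = 10, TN = 90, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1,
                                  accuracy = 1))
  # 0/0 denominators flagged as zero, not NaN
  z <- classification_metrics(c(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("IoU follows the overlap/union geometry", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7, tolerance = 1e-9)
  # symmetry
  expect_equal(iou(c(0, 0, 3, 1), c(1, 0, 3, 2)),
               iou(c(1, 0, 3, 2), c(0, 0, 3, 1)))
  deg <- iou(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "undefined"))
  expect_error(iou(c(0, 0, -1, 2), c(0, 0, 1, 1)), "negative")
})

test_that("mAP@0.5 integrates ranked precision-recall correctly", {
  box <- function(x) data.frame(x = x, y = 0, w = 2, h = 2)
  # all correct with perfect boxes
  truth <- cbind(data.frame(class = c("a", "b")), box(c(0, 10)))
  pred <- cbind(data.frame(class = c("a", "b"), score = c(0.9, 0.8)),
                box(c(0, 10)))
  expect_equal(as.numeric(map_at_50(pred, truth)), 1)
  # one class, 2 gts, ranked (TP, FP, TP) -> AP = 1*0.5 + (2/3)*0.5
  truth2 <- cbind(data.frame(class = c("a", "a")), box(c(0, 10)))
  pred2 <- cbind(data.frame(class = "a", score = c(0.9, 0.8, 0.7)),
                 box(c(0, 50, 10)))
  expect_equal(round(as.numeric(map_at_50(pred2, truth2)), 4), 0.8333)
  # shifting every box below the IoU threshold zeroes the score
  pred3 <- pred
  pred3$x <- pred3$x + 1.5   # IoU = 1/7 < 0.5
  expect_equal(as.numeric(map_at_50(pred3, truth)), 0)
})

test_that("both EER variants behave as defined", {
  cc <- list(pooled = c(TP = 8, TN = 88, FP = 2, FN = 2))
  e <- eer_metrics(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                   counts = cc$pooled)
  expect_equal(e$eer_eq11, 0.04)
  expect_equal(e$eer_roc, 0)                     # perfectly separated
  # identical scores for all pairs: chance-level equal error
  e2 <- eer_metrics(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(e2$eer_roc, 0.5)
  # FAR/FRR curves are proper rates
  set.seed(16)
  sc <- c(rnorm(50, 1), rnorm(50, 0))
  e3 <- eer_metrics(sc, rep(c(TRUE, FALSE), each = 50))
  expect_true(all(e3$curve$FAR >= 0 & e3$curve$FAR <= 1))
  expect_true(all(e3$curve$FRR >= 0 & e3$curve$FRR <= 1))
  expect_true(e3$eer_roc > 0 && e3$eer_roc < 0.5)
  expect_error(eer_metrics(numeric(0), logical(0)), "empty")
})
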