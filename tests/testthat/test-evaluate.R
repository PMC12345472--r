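# a minimally trained fit on the shared small cohort, cached per session
cached_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      cache <<- train(co$manifest, co$dir,
                      training_config(tiny_run = TRUE, batch_size = 8L,
                                      epochs = 2L, seed = 4))
    }
    cache
  }
})

test_that("evaluation reports are complete and internally consistent", {
  co <- small_cohort()
  fit <- cached_fit()
  rep <- evaluate(fit, co$manifest, co$dir, split = "test")
  expect_s3_class(rep, "eval_report")
  rates <- c(rep$precision, rep$recall, rep$f1, rep$accuracy, rep$map50,
             rep$eer_eq11, rep$eer_roc, rep$top1_accuracy)
  expect_true(all(rates >= 0 & rates <= 1))
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(rep$f1, 2 * rep$precision * rep$recall /
                         (rep$precision + rep$recall), tolerance = 1e-9)
  # default grouping: the four age windows; the test split (ages 9-12)
  # populates the 7-9 (via age 9) and 10-12 groups only
  expect_equal(rep$per_age_group$group, c("1-3", "4-6", "7-9", "10-12"))
  expect_true(all(rep$per_age_group$empty[1:2]))
  expect_false(any(rep$per_age_group$empty[3:4]))
  # group top-1 accuracies, weighted by counts, aggregate to the overall
  pg <- rep$per_age_group[!rep$per_age_group$empty, ]
  expect_equal(sum(pg$top1 * pg$n) / sum(pg$n), rep$top1_accuracy,
               tolerance = 1e-9)
  # JSON serialization round-trips the headline numbers
  p <- file.path(tempdir(), "report.json")
  write_eval_report(rep, p)
  r2 <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(r2$map50, rep$map50, tolerance = 1e-12)
  expect_equal(r2$top1_accuracy, rep$top1_accuracy, tolerance = 1e-12)
  expect_true(file.exists(file.path(tempdir(), "report_farfrr.csv")))
})

test_that("per-age-group accuracy aggregates over a multi-group split", {
  co <- small_cohort()
  fit <- cached_fit()
  # evaluate the train split, which spans ages 1-4 (two groups populated is
  # not possible there either, so use custom groups inside 9-12)
  rep <- evaluate(fit, co$manifest, co$dir, split = "test",
                  age_groups = list(`9-10` = 9:10, `11-12` = 11:12))
  pg <- rep$per_age_group
  expect_equal(nrow(pg), 2L)
  expect_false(any(pg$empty))
  expect_equal(sum(pg$top1 * pg$n) / sum(pg$n), rep$top1_accuracy,
               tolerance = 1e-9)
})

test_that("leakage diagnostics separate pass-through from decoupled codes", {
  co <- small_cohort()
  ds <- load_split(co$manifest, co$dir, "train")
  # pass-through control: a backbone-only model has x_id == x, so both
  # regressions see the same features
  m0 <- build_model("fe_net_tiny", n_classes = 4, use_decouple = FALSE,
                    use_corr = FALSE, seed = 2)
  lr0 <- decoupling_report(m0, co$manifest, co$dir, split = "train",
                           data = ds)
  expect_equal(lr0$r2_id_code, lr0$r2_embedding, tolerance = 1e-9)
  expect_true(is.na(lr0$r2_age_code))
  # permutation null: shuffled ages carry no linear signal
  set.seed(17)
  emb <- ovineid:::model_embed(m0, ds$x)
  shuffled <- sample(ds$age_months)
  r2n <- ovineid:::r2_cv(emb$x_id, shuffled)
  expect_lt(as.numeric(r2n), 0.15)
  # R2 values are clipped into [0, 1]
  expect_gte(as.numeric(r2n), 0)
})

test_that("saliency maps satisfy their contract", {
  co <- small_cohort()
  fit <- cached_fit()
  img <- render_face(make_identity(1), 10)
  sm <- saliency_map(fit, img, fit$classes[1])
  expect_equal(dim(sm), c(64L, 64L))
  expect_true(all(sm >= 0 & sm <= 1))
  expect_equal(max(sm), 1)
  # scale invariance: doubling the CosFace scale leaves the normalized map
  # unchanged
  fit$model$cosface$s <- fit$model$cosface$s * 2
  sm2 <- saliency_map(fit, img, fit$classes[1])
  fit$model$cosface$s <- fit$model$cosface$s / 2
  expect_equal(sm, sm2, tolerance = 1e-9)
  expect_error(saliency_map(fit, img, "nonexistent-sheep"), "class")
})

test_that("the activation-map combination matches an analytic case", {
  # if the target gradient is 1/hw on channel 1 and 0 elsewhere, the map is
  # proportional to the rectified channel-1 activation
  set.seed(18)
  Fm <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  dF <- array(0, c(4, 4, 3)); dF[, , 1] <- 1 / 16
  cam <- ovineid:::gradcam_from(Fm, dF, c(4, 4))
  ref <- pmax(Fm[, , 1] / 16, 0)
  expect_equal(cam, ref / max(ref), tolerance = 1e-9)
  # zero gradient flags a uniform zero map
  cam0 <- ovineid:::gradcam_from(Fm, array(0, c(4, 4, 3)), c(4, 4))
  expect_true(attr(cam0, "zero_gradient"))
  expect_equal(max(cam0), 0)
  # upsampling keeps values and returns the requested size
  up <- ovineid:::upsample_bilinear(matrix(c(0, 1, 1, 0), 2, 2), 8, 8)
  expect_equal(dim(up), c(8L, 8L))
  expect_true(all(up >= 0 & up <= 1))
})
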