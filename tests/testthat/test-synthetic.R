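test_that("identity parameters are deterministic, bounded and distinct", {
  expect_identical(make_identity(7), make_identity(7))
  ids <- lapply(1:100, make_identity)
  expect_true(all(vapply(ids, function(p)
    p$eye_spacing >= 0.28 && p$eye_spacing <= 0.52, TRUE)))
  expect_true(all(vapply(ids, function(p)
    all(abs(p$nose_offset) <= 0.08), TRUE)))
  expect_true(all(vapply(ids, function(p)
    p$base_hue >= 0 && p$base_hue <= 1, TRUE)))
  key <- vapply(ids, function(p)
    paste(p$eye_spacing, p$nose_offset[1], p$base_hue), "")
  expect_length(unique(key), 100L)
})

test_that("growth curve follows the saturating-exponential form", {
  g <- growth_model(s_max = 2, tau = 2.5)
  expect_equal(growth_scale(0, g), 0)
  expect_equal(growth_scale(2.5, g), 2 * (1 - exp(-1)))
  expect_lt(abs(growth_scale(120, growth_model(tau = 2)) - 1), 1e-6)
  ages <- seq(0, 12, by = 0.25)
  expect_true(all(diff(growth_scale(ages, g)) >= 0))
  expect_error(growth_model(tau = 0), "tau")
  expect_error(growth_model(tau = -1), "tau")
  # fur term zero before onset, linear after
  g2 <- growth_model(fur_onset = 8, fur_gain = 0.1)
  expect_equal(ovineid:::fur_amplitude(c(1, 7, 8), g2), c(0, 0, 0))
  expect_equal(ovineid:::fur_amplitude(10, g2), 0.2)
})

test_that("rendering is deterministic and respects the nuisance identity", {
  id <- make_identity(3)
  r1 <- render_face(id, 9, nuisance_params(rotation_deg = 5,
                                           noise_sigma = 0.01, seed = 2))
  r2 <- render_face(id, 9, nuisance_params(rotation_deg = 5,
                                           noise_sigma = 0.01, seed = 2))
  expect_identical(r1, r2)
  plain <- render_face(id, 9)
  noident <- render_face(id, 9, nuisance_params(gain = 1, bias = 0,
                                                rotation_deg = 0,
                                                noise_sigma = 0))
  expect_identical(plain$pixels, noident$pixels)
  expect_true(all(plain$pixels >= 0 & plain$pixels <= 1))
  expect_error(render_face(id, 0), "age")
  expect_error(render_face(id, 13), "age")
  expect_error(render_face(id, 6, size = c(16, 16)), "small")
})

test_that("age changes pixels only inside the growing head region", {
  id <- make_identity(11)
  a <- render_face(id, 3)
  b <- render_face(id, 9)
  diffmask <- apply(abs(a$pixels - b$pixels) > 1e-12, c(1, 2), any)
  # the larger (age 9) head box must contain every differing pixel
  bx <- b$box
  outside <- diffmask
  outside[bx[2]:(bx[2] + bx[4] - 1), bx[1]:(bx[1] + bx[3] - 1)] <- FALSE
  expect_false(any(outside))
  expect_true(any(diffmask))
  # box tightly encloses the head: corners of the box region touch content
  expect_true(bx[3] > a$box[3] && bx[4] > a$box[4])
})

test_that("augmentation produces exactly the policy multiplier", {
  img <- placeholder_face(5)
  out <- augment_image(img, augment_policy(), seed = 9)
  expect_length(out, 4L)
  expect_identical(out[[1]], img)
  expect_true(all(vapply(out[-1], function(v) v$origin == "augmented", TRUE)))
  expect_true(all(vapply(out, function(v) v$sheep_id == img$sheep_id, TRUE)))
  expect_true(all(vapply(out, function(v) v$age_months == img$age_months, TRUE)))
  # identity policy: zero ranges reproduce the original four times
  idp <- augment_policy(gain_range = 0, bias_range = 0, noise_sigma = 0,
                        rotation_deg = 0)
  copies <- augment_image(img, idp, seed = 9)
  for (v in copies) expect_equal(v$pixels, img$pixels)
  # determinism
  expect_identical(augment_image(img, augment_policy(), seed = 4),
                   augment_image(img, augment_policy(), seed = 4))
  # configurable multiplier
  expect_length(augment_image(img, augment_policy(multiplier = 6), 1), 6L)
})

test_that("generated cohorts have the right counts and split structure", {
  co <- small_cohort()
  man <- co$manifest
  expect_equal(nrow(man$records), 4 * 12 * 2)
  ct <- manifest_counts(man)
  expect_equal(unname(ct), c(32L, 32L, 32L))
  r <- man$records
  expect_true(all(r$age_months[r$split == "train"] <= 4))
  expect_true(all(r$age_months[r$split == "val"] %in% 5:8))
  expect_true(all(r$age_months[r$split == "test"] >= 9))
  expect_true(all(file.exists(file.path(co$dir, r$path))))
})

test_that("augmentation expands only the train split by exactly 4", {
  dir <- file.path(tempdir(), "ovineid-aug-cohort")
  man <- generate_dataset(n_ids = 3, ages = 1:12, reps_per_cell = 1,
                          protocol = "age_based", augment_train = TRUE,
                          seed = 5, out_dir = dir)
  ct <- manifest_counts(man)
  expect_equal(unname(ct["train"]), 3L * 4L * 1L * 4L)
  expect_equal(unname(ct["val"]), 12L)
  expect_equal(unname(ct["test"]), 12L)
  expect_true(all(man$records$origin[man$records$split != "train"] == "original"))
})

test_that("id-based protocol keeps individuals in a single split", {
  dir <- file.path(tempdir(), "ovineid-id-cohort")
  man <- generate_dataset(n_ids = 8, ages = c(2, 6, 10), reps_per_cell = 1,
                          protocol = "id_based", seed = 2, out_dir = dir)
  sets <- lapply(split(man$records$sheep_id, man$records$split), unique)
  expect_length(intersect(sets$train, sets$val), 0L)
  expect_length(intersect(sets$train, sets$test), 0L)
  expect_length(intersect(sets$val, sets$test), 0L)
  expect_error(generate_dataset(2, protocol = "id_based", seed = 1,
                                out_dir = tempfile()), "at least 3")
})

test_that("identity fields are independent of age across a cohort", {
  # balanced (id x age) grid of >= 1000 cells; identity fields are constant
  # within an individual, so their sample correlation with age must vanish
  ids <- lapply(1:90, function(i) make_identity(i))
  grid <- expand.grid(id = 1:90, age = 1:12)
  for (field in c("eye_spacing", "base_hue")) {
    v <- vapply(grid$id, function(i) ids[[i]][[field]], 1)
    expect_lt(abs(cor(v, grid$age)), 0.05)
  }
})
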