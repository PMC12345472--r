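# Shared fixture builders. Everything is generated in code at test time;
# expensive artifacts are cached per session.

# tiny labelled image without going through the renderer (for augmentation /
# metric plumbing tests)
placeholder_face <- function(seed = 1L, hw = 16L) {
  px <- ovineid:::with_seed(seed, array(runif(hw * hw * 3), c(hw, hw, 3)))
  structure(list(pixels = px, sheep_id = sprintf("s%03d", seed %% 997L),
                 age_months = 1L + (seed %% 12L),
                 box = c(x = 2, y = 2, w = hw - 3, h = hw - 3),
                 nuisance = nuisance_params(), origin = "original"),
            class = "labeled_face")
}

# small generated cohort on disk, cached for the whole test session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ovineid-small-cohort")
      man <- generate_dataset(n_ids = 4, ages = 1:12, reps_per_cell = 2,
                              protocol = "age_based", seed = 42,
                              out_dir = dir)
      cache <<- list(dir = dir, manifest = man)
    }
    cache
  }
})

num_grad <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}
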