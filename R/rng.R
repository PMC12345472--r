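# Seed plumbing: every stochastic operation draws from a seed derived
# deterministically from a root seed and a character tag, so a whole pipeline
# is reproducible from one integer and independent stages do not share
# streams.

#' Derive a child seed from a root seed and a tag
#'
#' Deterministic 31-bit hash (FNV-style) of the root seed and a label.
#' Used to give each pipeline stage (rendering, augmentation, initialization,
#' batching, ...) an independent, reproducible random stream.
#'
#' @param root integer root seed.
#' @param tag character label for the consuming stage.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "render") != derive_seed(1, "augment")
derive_seed <- function(root, tag) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(tag))
  h <- 2166136261
  bytes <- c(utf8ToInt(tag), 255L,
             as.integer(abs(root)) %% 256L,
             (as.integer(abs(root)) %/% 256L) %% 256L,
             (as.integer(abs(root)) %/% 65536L) %% 256L,
             (as.integer(abs(root)) %/% 16777216L) %% 256L)
  for (b in bytes) {
    h <- (h * 16777619) %% 2147483629
    h <- xor_int(h, b)
  }
  as.integer(h %% 2147483629)
}

# bitwXor on doubles that fit in 31 bits
xor_int <- function(a, b) {
  bitwXor(as.integer(a %% 2147483648), as.integer(b))
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
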