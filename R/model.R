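# Full model: backbone -> (embedding x, feature map F) -> decoupling head
# -> identity/age codes -> CosFace + age-regression + correlation heads.
# Ablation switches select the attention variant, the subtraction form, and
# whether the decoupling head / correlation module exist at all.

#' Assemble the full identification model
#'
#' @param preset backbone preset name or object (see [backbone_preset()]).
#' @param n_classes number of identities for the CosFace head.
#' @param d_a age-code dimension.
#' @param attention `"ecbam"`, `"cbam"` or `"none"` (attention on the age
#'   branch).
#' @param subtraction `"mlp"` or `"linear"` residual map.
#' @param use_decouple if `FALSE`, the model is the backbone-only baseline:
#'   `x_id = x`, no age branch, no correlation module.
#' @param use_corr include the adversarial correlation module.
#' @param n_pairs canonical pairs in the correlation module.
#' @param corr_kernel kernel maps of the correlation module (`"mlp"` or
#'   `"identity"`).
#' @param corr_prior Gaussian-prior (L2) strength on the correlation
#'   module.
#' @param s,b CosFace scale and margin.
#' @param seed initialization seed.
#' @return an object of class `ovineid_model`.
#' @export
build_model <- function(preset = "fe_net_tiny", n_classes, d_a = 128L,
                        attention = "ecbam", subtraction = "mlp",
                        use_decouple = TRUE, use_corr = TRUE, n_pairs = 1L,
                        corr_kernel = "mlp", corr_prior = 1e-4,
                        s = 30, b = 0.35, seed = 1L) {
  if (is.character(preset)) preset <- backbone_preset(preset)
  d <- preset$embed_dim
  m <- list(
    backbone = build_backbone(preset, seed = derive_seed(seed, "bb")),
    cosface = cosface_config(n_classes, d, s = s, b = b,
                             seed = derive_seed(seed, "cf")),
    preset = preset, n_classes = as.integer(n_classes), d_a = as.integer(d_a),
    use_decouple = isTRUE(use_decouple), use_corr = isTRUE(use_corr) && isTRUE(use_decouple),
    attention = attention, subtraction = subtraction, seed = as.integer(seed))
  if (m$use_decouple) {
    m$decoupler <- decoupler_params(d, d_a = d_a, attention = attention,
                                    subtraction = subtraction,
                                    seed = derive_seed(seed, "dec"))
    m$agereg <- age_regressor(d_a, seed = derive_seed(seed, "ar"))
  }
  if (m$use_corr) {
    m$corr <- corr_params(d, d_a, n_pairs = n_pairs, kernel = corr_kernel,
                          prior_strength = corr_prior,
                          seed = derive_seed(seed, "corr"))
  }
  structure(m, class = "ovineid_model")
}

#' @export
print.ovineid_model <- function(x, ...) {
  cat(sprintf(
    "<ovineid_model> preset=%s classes=%d decouple=%s(%s,%s) corr=%s params=%d\n",
    x$preset$name, x$n_classes,
    x$use_decouple, x$attention, x$subtraction, x$use_corr,
    n_params(model_components(x))))
  invisible(x)
}

# components updated by the descent step (everything except the correlation
# module, which is trained by ascent)
model_components <- function(m) {
  out <- list(m$backbone, m$cosface)
  if (m$use_decouple) out <- c(out, list(m$decoupler, m$agereg))
  out
}

#' Forward pass producing the feature bundle
#'
#' @param m an [build_model()] result.
#' @param x image batch (`H x W x 3 x N`).
#' @param train training mode (batch statistics + caches).
#' @return a `feature_bundle`; for the backbone-only ablation `x_id = x` and
#'   `x_age`/`r` are absent.
#' @export
model_forward <- function(m, x, train = FALSE) {
  ft <- forward_features(x, m$backbone, train = train)
  if (m$use_decouple) {
    decouple(ft$F, ft$x, m$decoupler, train = train)
  } else {
    structure(list(F = ft$F, x = ft$x, x_age = NULL, r = NULL, x_id = ft$x),
              class = "feature_bundle")
  }
}

# eval-mode embeddings over an arbitrary number of images, chunked to bound
# memory
model_embed <- function(m, x, chunk = 64L) {
  n <- dim(x)[4]
  ids <- NULL; ages <- NULL; embs <- NULL; f_last <- NULL
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1L)
    bun <- model_forward(m, x[, , , i0:i1, drop = FALSE], train = FALSE)
    ids <- cbind(ids, bun$x_id)
    embs <- cbind(embs, bun$x)
    if (!is.null(bun$x_age)) ages <- cbind(ages, bun$x_age)
  }
  list(x_id = ids, x_age = ages, x = embs)
}

# nearest-class prediction on unit-normalized identity codes
predict_ids <- function(m, x_id) {
  W <- unit_cols(m$cosface$children$wlayer$params$w)
  cosm <- crossprod(W, unit_cols(x_id))
  max.col(t(cosm), ties.method = "first")
}

# ---- checkpointing -----------------------------------------------------

model_state <- function(m) {
  st <- get_state(m$backbone, "backbone")
  st <- c(st, get_state(m$cosface, "cosface"))
  if (m$use_decouple) {
    st <- c(st, get_state(m$decoupler, "decoupler"), get_state(m$agereg, "agereg"))
  }
  if (m$use_corr) st <- c(st, get_state(m$corr, "corr"))
  st
}

#' Save a model checkpoint
#'
#' Single archive with all parameter tensors keyed by module path, the
#' preset, the architecture options and a content hash.
#'
#' @param m an `ovineid_model` or an `ovineid_fit`.
#' @param path output file.
#' @param classes identity labels in training order (taken from a fit
#'   automatically).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(m, path, classes = NULL) {
  if (inherits(m, "ovineid_fit")) {
    if (is.null(classes)) classes <- m$classes
    m <- m$model
  }
  arch <- list(preset = m$preset, n_classes = m$n_classes, d_a = m$d_a,
               attention = m$attention, subtraction = m$subtraction,
               use_decouple = m$use_decouple, use_corr = m$use_corr,
               n_pairs = if (m$use_corr) m$corr$n_pairs else 1L,
               corr_kernel = if (m$use_corr) m$corr$kernel else "mlp",
               corr_prior = if (m$use_corr) m$corr$prior_strength else 1e-4,
               s = m$cosface$s, b = m$cosface$b, seed = m$seed)
  st <- model_state(m)
  obj <- list(arch = arch, state = st, classes = classes,
              hash = sum(vapply(st, function(p) sum(as.numeric(p)), 0)))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @return the restored `ovineid_model`; attribute `classes` carries the
#'   identity labels if they were saved.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  a <- obj$arch
  m <- build_model(preset = a$preset, n_classes = a$n_classes, d_a = a$d_a,
                   attention = a$attention, subtraction = a$subtraction,
                   use_decouple = a$use_decouple, use_corr = a$use_corr,
                   n_pairs = a$n_pairs %||% 1L,
                   corr_kernel = a$corr_kernel %||% "mlp",
                   corr_prior = a$corr_prior %||% 1e-4,
                   s = a$s, b = a$b, seed = a$seed)
  set_state(m$backbone, obj$state, "backbone")
  set_state(m$cosface, obj$state, "cosface")
  if (m$use_decouple) {
    set_state(m$decoupler, obj$state, "decoupler")
    set_state(m$agereg, obj$state, "agereg")
  }
  if (m$use_corr) set_state(m$corr, obj$state, "corr")
  attr(m, "classes") <- obj$classes
  m
}
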