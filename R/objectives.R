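# Training objectives: CosFace identity loss on the identity code, half-MSE
# linear age regression on the age code, and their weighted combination with
# the squared-correlation penalty.

#' CosFace configuration
#'
#' Scaled cosine-margin softmax over unit class vectors in identity-code
#' space. The margin `b` is subtracted from the true-class cosine only.
#'
#' @param n_classes number of identities N.
#' @param d identity-code dimension.
#' @param s scale factor (> 0), default 30.
#' @param b cosine margin (>= 0), default 0.35.
#' @param seed initialization seed for the class vectors.
#' @return an object of class `cosface_config` (an `nn_module` whose single
#'   layer holds the `d x N` class-weight matrix).
#' @export
cosface_config <- function(n_classes, d, s = 30, b = 0.35, seed = 1L) {
  stopifnot(s > 0, b >= 0, n_classes >= 1)
  w <- with_seed(derive_seed(seed, "cosface"),
                 matrix(rnorm(d * n_classes), d, n_classes))
  m <- new_module("cosface",
                  list(wlayer = new_layer("linear",
                                          list(w = w))),
                  list(s = s, b = b, n_classes = as.integer(n_classes), d = d))
  class(m) <- c("cosface_config", class(m))
  m
}

unit_cols <- function(m, eps = 1e-12) {
  nrm <- sqrt(colSums(m^2)) + eps
  sweep(m, 2, nrm, "/")
}

#' CosFace identity loss
#'
#' Per sample `i` with true class `y`:
#' `-log( exp(s (cos t_y - b)) / (exp(s (cos t_y - b)) +
#' sum_{j != y} exp(s cos t_j)) )`, averaged over the batch, where
#' `cos t_j` is the cosine between the unit-normalized identity code and
#' the unit-normalized class vector `j`. With a single class the competitor
#' sum is empty and the loss is 0.
#'
#' @param x_id identity codes, `d x n` matrix.
#' @param cfg a [cosface_config()].
#' @param labels integer class labels in `1..N` (or a factor).
#' @return mean loss (>= 0).
#' @export
cosface_loss <- function(x_id, cfg, labels) {
  cosface_pass(x_id, cfg, labels, backward = FALSE)$loss
}

cosface_pass <- function(x_id, cfg, labels, backward = TRUE) {
  if (is.factor(labels)) labels <- as.integer(labels)
  n <- ncol(x_id)
  if (n < 1) stop("batch nonempty required")
  if (any(labels < 1 | labels > cfg$n_classes)) stop("label out of range")
  eps <- 1e-12
  xn_norm <- sqrt(colSums(x_id^2)) + eps
  xn <- sweep(x_id, 2, xn_norm, "/")
  W <- cfg$children$wlayer$params$w
  wn_norm <- sqrt(colSums(W^2)) + eps
  wn <- sweep(W, 2, wn_norm, "/")
  cosm <- crossprod(wn, xn)                       # N_cls x n
  logits <- cfg$s * cosm
  idx <- cbind(labels, seq_len(n))
  logits[idx] <- cfg$s * (cosm[idx] - cfg$b)
  mx <- apply(logits, 2, max)
  lse <- mx + log(colSums(exp(sweep(logits, 2, mx))))
  loss <- mean(lse - logits[idx])
  out <- list(loss = loss)
  if (backward) {
    p <- exp(sweep(logits, 2, lse))               # softmax, N_cls x n
    dlog <- p
    dlog[idx] <- dlog[idx] - 1
    dlog <- dlog / n
    dcos <- cfg$s * dlog
    dxn <- wn %*% dcos
    dwn <- xn %*% t(dcos)
    # through unit normalization of x: dx = (dxn - xn * <xn, dxn>) / |x|
    dx <- sweep(dxn - sweep(xn, 2, colSums(xn * dxn), "*"), 2, xn_norm, "/")
    dW <- sweep(dwn - sweep(wn, 2, colSums(wn * dwn), "*"), 2, wn_norm, "/")
    cfg$children$wlayer$grads$w <- cfg$children$wlayer$grads$w + dW
    out$dx <- dx
    # correct predictions for convenience
    out$pred <- max.col(t(cosm), ties.method = "first")
  }
  out
}

#' Linear age regressor
#'
#' A single linear map from the age code to predicted age in months.
#'
#' @param d_a age-code dimension.
#' @param seed initialization seed.
#' @return an `nn_module` of type `age_reg`.
#' @export
age_regressor <- function(d_a, seed = 1L) {
  with_seed(derive_seed(seed, "agereg"),
            new_module("age_reg", list(lin = ly_linear(d_a, 1L, gain = 1))))
}

#' Age regression loss (half mean squared error)
#'
#' `(1 / (2 m)) * sum_i (F_age(x_age_i) - z_i)^2` over a batch of m samples;
#' zero iff every prediction is exact.
#'
#' @param x_age age codes, `d_a x m` matrix.
#' @param reg an [age_regressor()].
#' @param ages numeric age labels in months.
#' @return the loss (>= 0).
#' @export
age_loss <- function(x_age, reg, ages) {
  age_pass(x_age, reg, ages, backward = FALSE)$loss
}

age_pass <- function(x_age, reg, ages, backward = TRUE) {
  m <- ncol(x_age)
  if (m < 1) stop("empty batch")
  pred <- as.numeric(ly_fwd(reg$children$lin, x_age, train = backward))
  err <- pred - ages
  out <- list(loss = sum(err^2) / (2 * m), pred = pred)
  if (backward) {
    dpred <- matrix(err / m, nrow = 1)
    out$dx <- ly_bwd(reg$children$lin, dpred)
  }
  out
}

#' Root mean squared age error (reporting metric)
#' @param pred predicted ages.
#' @param ages true ages.
#' @return `sqrt(mean((pred - ages)^2))`.
#' @export
age_rmse <- function(pred, ages) sqrt(mean((pred - ages)^2))

#' Weighted joint loss
#'
#' `L = L_id + alpha * L_grow + beta * L_id_grow`; defaults `alpha = 0.01`,
#' `beta = 1` (the best-performing weights of the grid search).
#'
#' @param l_id identity loss.
#' @param l_grow age regression loss.
#' @param l_corr squared-correlation loss.
#' @param alpha weight of the age term.
#' @param beta weight of the correlation term.
#' @return the combined loss.
#' @export
joint_loss <- function(l_id, l_grow, l_corr, alpha = 0.01, beta = 1) {
  stopifnot(is.finite(l_id), is.finite(l_grow), is.finite(l_corr))
  l_id + alpha * l_grow + beta * l_corr
}
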