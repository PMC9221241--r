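# Loss functions for binary lesion segmentation.
#
# y is the \{0,1\} ground-truth mask, y_hat the predicted probability map in
# (0,1); both may be vectors, matrices or arrays of equal shape and are
# treated as flat pixel sets. BCE is mean-reduced over pixels so magnitudes
# stay comparable across resolutions; Dice is a set overlap over the whole
# input. Probabilities are clamped to [eps, 1 - eps] (eps = 1e-7) before any
# logarithm.

.loss_eps <- 1e-7

#' @noRd
clamp_probs <- function(p, eps = .loss_eps) pmin(pmax(p, eps), 1 - eps)

#' @noRd
check_loss_inputs <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("y and y_hat must have the same length", call. = FALSE)
  }
  if (any(y != 0 & y != 1)) {
    stop("y must be a binary \\{0,1\\} mask", call. = FALSE)
  }
  invisible(NULL)
}

#' Segmentation losses
#'
#' `bce_loss()` is the mean binary cross-entropy; `dice_loss()` is
#' `1 - (2 * sum(y * y_hat) + delta) / (sum(y^2) + sum(y_hat^2) + delta)`,
#' with `delta` a small smoothing constant that guards the empty-mask case
#' and lets lesion-free slices still propagate gradient; `hybrid_loss()` is
#' their L2 combination `sqrt(bce^2 + dice^2)`, the training objective of the
#' network; `focal_loss()` is the standard focal form used as a comparison
#' baseline, reducing to `alpha`-weighted BCE at `gamma = 0`.
#'
#' @param y Ground-truth binary mask (any shape).
#' @param y_hat Predicted probabilities in (0,1), same shape as `y`.
#' @param delta Dice smoothing constant; values in `[1e-15, 1e-13]` are
#'   equivalent to within numerical noise on any non-empty mask.
#' @param gamma Focal-loss focusing exponent (>= 0).
#' @param alpha Focal-loss foreground weight in (0,1).
#' @return A single non-negative number.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.9, 0.1))     # -mean(log(0.9), log(0.9))
#' dice_loss(c(1, 0, 0, 0), rep(0.5, 4))
#' hybrid_loss(c(1, 0, 0, 0), rep(0.5, 4))
bce_loss <- function(y, y_hat) {
  check_loss_inputs(y, y_hat)
  p <- clamp_probs(y_hat)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname bce_loss
#' @export
dice_loss <- function(y, y_hat, delta = 1e-15) {
  check_loss_inputs(y, y_hat)
  stopifnot(delta > 0)
  S <- sum(y * y_hat)
  D <- sum(y * y) + sum(y_hat * y_hat)
  1 - (2 * S + delta) / (D + delta)
}

#' @rdname bce_loss
#' @export
hybrid_loss <- function(y, y_hat, delta = 1e-15) {
  b <- bce_loss(y, y_hat)
  d <- dice_loss(y, y_hat, delta)
  sqrt(b * b + d * d)
}

#' @rdname bce_loss
#' @export
focal_loss <- function(y, y_hat, gamma = 2, alpha = 0.25) {
  check_loss_inputs(y, y_hat)
  stopifnot(gamma >= 0, alpha > 0, alpha < 1)
  p <- clamp_probs(y_hat)
  -mean(alpha * (1 - p)^gamma * y * log(p) +
          (1 - alpha) * p^gamma * (1 - y) * log(1 - p))
}

# ---- analytic gradients (d loss / d y_hat) ---------------------------------

#' @noRd
bce_grad <- function(y, y_hat) {
  p <- clamp_probs(y_hat)
  g <- (p - y) / (p * (1 - p)) / length(y)
  g[y_hat <= .loss_eps | y_hat >= 1 - .loss_eps] <- 0  # clamped region is flat
  array(g, dim(y_hat) %||% length(y_hat))
}

#' @noRd
dice_grad <- function(y, y_hat, delta = 1e-15) {
  S <- sum(y * y_hat)
  D <- sum(y * y) + sum(y_hat * y_hat)
  g <- -(2 * y * (D + delta) - (2 * S + delta) * 2 * y_hat) / (D + delta)^2
  array(g, dim(y_hat) %||% length(y_hat))
}

#' @noRd
hybrid_grad <- function(y, y_hat, delta = 1e-15) {
  b <- bce_loss(y, y_hat)
  d <- dice_loss(y, y_hat, delta)
  h <- sqrt(b * b + d * d)
  if (h == 0) return(array(0, dim(y_hat) %||% length(y_hat)))
  (b * bce_grad(y, y_hat) + d * dice_grad(y, y_hat, delta)) / h
}

#' @noRd
focal_grad <- function(y, y_hat, gamma = 2, alpha = 0.25) {
  p <- clamp_probs(y_hat)
  # d/dp of the per-pixel focal terms; the gamma * (.)^(gamma-1) factors
  # vanish identically at gamma = 0
  gpos <- alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  gneg <- (1 - alpha) *
    (-gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
  if (gamma == 0) {
    gpos <- -alpha / p
    gneg <- (1 - alpha) / (1 - p)
  }
  gi <- (y * gpos + (1 - y) * gneg) / length(y)
  gi[y_hat <= .loss_eps | y_hat >= 1 - .loss_eps] <- 0
  array(gi, dim(y_hat) %||% length(y_hat))
}

#' Resolve a loss name to value and gradient functions.
#' @noRd
loss_fns <- function(loss = c("hybrid", "bce", "dice", "focal"),
                     delta = 1e-15, gamma = 2, alpha = 0.25) {
  loss <- match.arg(loss)
  switch(loss,
    bce = list(value = bce_loss, grad = bce_grad),
    dice = list(value = function(y, p) dice_loss(y, p, delta),
                grad = function(y, p) dice_grad(y, p, delta)),
    hybrid = list(value = function(y, p) hybrid_loss(y, p, delta),
                  grad = function(y, p) hybrid_grad(y, p, delta)),
    focal = list(value = function(y, p) focal_loss(y, p, gamma, alpha),
                 grad = function(y, p) focal_grad(y, p, gamma, alpha)))
}
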