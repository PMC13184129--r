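# Focal Tversky loss for severely imbalanced binary segmentation.
#
# Per image i: TI_i = (sum p*g + eps) / (sum p*g + alpha*sum p*(1-g)
#                      + beta*sum (1-p)*g + eps),  L_i = (1 - TI_i)^gamma,
# reduced by the batch mean. alpha weights false positives, beta false
# negatives; gamma > 1 focuses the loss on poorly segmented slices.

#' Loss configuration
#'
#' @param alpha false-positive weight in `[0, 1]`.
#' @param beta false-negative weight in `[0, 1]`. By default `alpha + beta`
#'   must equal 1 (disable with `enforce_sum = FALSE`).
#' @param gamma focal exponent (> 0).
#' @param epsilon smoothing constant added to numerator and denominator;
#'   keeps the index defined on empty-ground-truth slices.
#' @param reduction only `"mean"` is supported.
#' @param enforce_sum require `alpha + beta == 1`.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, gamma = 2.0, epsilon = 1e-6,
                        reduction = "mean", enforce_sum = TRUE) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  if (enforce_sum && abs(alpha + beta - 1) > 1e-12)
    stop("alpha + beta must equal 1 (set enforce_sum = FALSE to relax)")
  reduction <- match.arg(reduction, "mean")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, reduction = reduction),
            class = "loss_config")
}

# split a (H,W,1,N) or (H,W,N) array into per-image sums of the three terms
tversky_terms <- function(p, g) {
  dp <- dim(p)
  n <- if (length(dp) >= 3L) dp[length(dp)] else 1L
  m <- length(p) / n
  pm <- matrix(p, m, n)
  gm <- matrix(g, m, n)
  list(tp = colSums(pm * gm),
       fp = colSums(pm * (1 - gm)),
       fn = colSums((1 - pm) * gm))
}

check_pg <- function(p, g) {
  if (!identical(dim(as.array(p)), dim(as.array(g))) &&
      length(p) != length(g))
    stop("probability map and mask have different geometry")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(g != 0 & g != 1)) stop("mask values must be 0 or 1")
}

#' Tversky index
#'
#' Asymmetric overlap between a probability map and a binary mask; with
#' `alpha = beta = 0.5` and a binarized `p` it equals the Dice coefficient.
#'
#' @param p probability map (values in `[0, 1]`).
#' @param g binary ground-truth mask of the same geometry.
#' @param alpha,beta false-positive / false-negative weights.
#' @param epsilon smoothing constant.
#' @return scalar (single image) or per-image vector (batched input with
#'   images along the last dimension).
#' @export
tversky_index <- function(p, g, alpha = 0.7, beta = 0.3, epsilon = 1e-6) {
  p <- if (is_ad(p)) p$value else p
  check_pg(p, g)
  tt <- tversky_terms(p, g)
  (tt$tp + epsilon) / (tt$tp + alpha * tt$fp + beta * tt$fn + epsilon)
}

#' Focal Tversky loss
#'
#' Mean over the batch of `(1 - TI_i)^gamma`. Accepts plain arrays (returns
#' a number) or an `ad_tensor` probability map (returns a differentiable
#' scalar node with an analytic gradient).
#'
#' @param p probabilities: array (H, W, 1, N) / (H, W, N) / (H, W), or an
#'   `ad_tensor` of such shape.
#' @param g binary masks of matching geometry.
#' @param config a [loss_config()].
#' @return numeric scalar, or a scalar `ad_tensor` when `p` is one.
#' @export
focal_tversky_loss <- function(p, g, config = loss_config()) {
  pv <- if (is_ad(p)) p$value else p
  if (length(pv) == 0L) stop("empty batch")
  check_pg(pv, g)
  a <- config$alpha; b <- config$beta
  gam <- config$gamma; eps <- config$epsilon
  tt <- tversky_terms(pv, g)
  n <- length(tt$tp)
  S <- tt$tp
  D <- tt$tp + a * tt$fp + b * tt$fn
  ti <- (S + eps) / (D + eps)
  li <- pmax(1 - ti, 0)^gam
  value <- mean(li)
  if (!is_ad(p)) return(value)
  dims <- dim(pv)
  m <- length(pv) / n
  ad_tensor(value, list(p), function(gout) {
    gm <- matrix(g, m, n)
    # d ti / d p = (g*(D+eps) - (S+eps)*(g + a*(1-g) - b*g)) / (D+eps)^2
    num1 <- sweep(gm, 2L, D + eps, "*")
    dDdp <- gm * (1 - a - b) + a   # g + a(1-g) - b g = (1-a-b) g + a
    num2 <- sweep(dDdp, 2L, S + eps, "*")
    dti <- sweep(num1 - num2, 2L, (D + eps)^2, "/")
    dli <- sweep(dti, 2L, -gam * pmax(1 - ti, 0)^(gam - 1), "*")
    gp <- dli * (as.numeric(gout) / n)
    dim(gp) <- dims
    list(gp)
  })
}
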