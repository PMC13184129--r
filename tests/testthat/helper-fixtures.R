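# Shared fixtures: tiny phantom cohorts and random binary masks.

tiny_phantom_config <- function(seed = 1L, ...) {
  args <- list(n_patients = 2L, slices_per_nerve = 4L,
               image_height = 64L, image_width = 64L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_config, args)
}

random_mask <- function(h = 16L, w = 16L, p = 0.15) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# independent pixel-set-operation oracle for the segmentation metrics
set_metrics_oracle <- function(pred, gt) {
  A <- which(pred == 1L)
  B <- which(gt == 1L)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  list(dsc = if (uni > 0) 2 * inter / (length(A) + length(B)) else NA_real_,
       iou = if (uni > 0) inter / uni else NA_real_,
       precision = if (length(A) > 0) inter / length(A) else NA_real_,
       recall = if (length(B) > 0) inter / length(B) else NA_real_)
}

# brute-force two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the observed absolute-difference ranks
wilcoxon_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
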