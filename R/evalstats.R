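# Per-slice segmentation metrics, the three-tier failure taxonomy,
# aggregation, and paired Wilcoxon signed-rank model comparison with
# Bonferroni correction.

#' Pixel-wise confusion counts
#'
#' @param pred,gt binary matrices of identical geometry.
#' @return list with `tp`, `fp`, `fn`, `tn` (integer pixel counts).
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth geometry differ")
  p <- pred == 1L; g <- gt == 1L
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  tn <- length(pred) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-slice metrics from confusion counts
#'
#' Dice (`2*TP / (2*TP + FP + FN)`), IoU (`TP / (TP + FP + FN)`), precision
#' (`TP / (TP + FP)`), recall (`TP / (TP + FN)`). A metric whose
#' denominator is zero is returned as `NA` (undefined), never silently 0
#' or 1.
#'
#' @param counts list from [confusion()].
#' @return list with `dsc`, `iou`, `precision`, `recall`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  u <- tp + fp + fn
  list(dsc = if (u > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       iou = if (u > 0) tp / u else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Three-tier failure taxonomy
#'
#' Cumulative per-slice failure percentages: complete failure (DSC = 0),
#' tracking failure (DSC < 0.2), boundary delineation failure (DSC < 0.3).
#' Nested thresholds, so complete <= tracking <= boundary by construction.
#'
#' @param dsc_values numeric vector of per-slice DSC values in `[0, 1]`.
#' @return list with `complete`, `tracking`, `boundary` (percentages) and
#'   `n`.
#' @export
classify_failure <- function(dsc_values) {
  dsc_values <- dsc_values[!is.na(dsc_values)]
  if (length(dsc_values) == 0L) stop("no DSC values to classify")
  if (any(dsc_values < 0 | dsc_values > 1)) stop("DSC values must lie in [0, 1]")
  n <- length(dsc_values)
  list(complete = 100 * sum(dsc_values == 0) / n,
       tracking = 100 * sum(dsc_values < 0.2) / n,
       boundary = 100 * sum(dsc_values < 0.3) / n,
       n = n)
}

#' Aggregate per-slice metrics
#'
#' Mean, sample SD (n-1 denominator) and median per metric; undefined
#' (`NA`) entries are excluded with their count reported.
#'
#' @param df data frame with columns `dsc`, `iou`, `precision`, `recall`
#'   (or any subset).
#' @return data frame with one row per metric: `metric`, `mean`, `sd`,
#'   `median`, `n`, `n_undefined`.
#' @export
aggregate_metrics <- function(df) {
  cols <- intersect(c("dsc", "iou", "precision", "recall"), names(df))
  if (nrow(df) == 0L) stop("no slices to aggregate")
  out <- lapply(cols, function(cn) {
    v <- df[[cn]]
    nu <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("metric '", cn, "' undefined on every slice")
      return(data.frame(metric = cn, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, n = 0L, n_undefined = nu))
    }
    data.frame(metric = cn, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               median = stats::median(v), n = length(v), n_undefined = nu)
  })
  do.call(rbind, out)
}

# Exact distribution of the positive-rank sum W+ under the null that each
# of the n signs is +/- with probability 1/2, with mid-ranks (possibly
# half-integer; handled by doubling). Returns P(W+ <= w) and P(W+ >= w).
signed_rank_tails <- function(ranks2, w2) {
  total <- sum(ranks2)
  # generating-function DP over achievable doubled rank sums
  probs <- numeric(total + 1L)  # index = sum + 1
  probs[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  sums <- 0:total
  c(lower = sum(probs[sums <= w2 + 1e-9]),
    upper = sum(probs[sums >= w2 - 1e-9]))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences: zero differences dropped,
#' mid-ranks for ties, exact sign-enumeration distribution for `n <= 25`,
#' normal approximation with tie correction and 0.5 continuity correction
#' otherwise. The two-sided p-value is `min(1, 2 * min(lower, upper))` of
#' the exact tails.
#'
#' @param a,b paired numeric vectors, or `b = NULL` with `a` already the
#'   differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (W+), `p_value`, `n` (non-zero
#'   differences), `method`, `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_max = 25L) {
  d <- if (is.null(b)) a else a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))                 # mid-ranks
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    tails <- signed_rank_tails(as.integer(round(2 * r)), 2 * w)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method, all_zero = FALSE)
}

#' Compare two models on one metric
#'
#' Wilcoxon signed-rank on paired per-slice metric values with Bonferroni
#' adjustment for a family of `family_size` comparisons.
#'
#' @param a,b paired metric vectors (model A vs model B on identical
#'   slices).
#' @param family_size Bonferroni family size `m`; adjusted p =
#'   `min(1, m * p)`.
#' @return list: `p_raw`, `p_adjusted`, `family_size`, `direction`
#'   (+1 if A tends higher, -1 lower, 0 tied), `statistic`, `n`,
#'   `all_zero`.
#' @export
compare_models <- function(a, b, family_size = 6L) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  wt <- wilcoxon_signed_rank(a, b)
  list(p_raw = wt$p_value,
       p_adjusted = min(1, family_size * wt$p_value),
       family_size = as.integer(family_size),
       direction = sign(stats::median(a - b)),
       statistic = wt$statistic, n = wt$n, all_zero = wt$all_zero)
}

#' Compare two per-slice metric tables across all four metrics
#'
#' @param df_a,df_b data frames from [evaluate_predictions()] (or with
#'   columns `dsc`, `iou`, `precision`, `recall`), row-aligned by slice.
#' @param family_size Bonferroni family size per metric.
#' @return data frame with one row per metric.
#' @export
compare_metric_tables <- function(df_a, df_b, family_size = 6L) {
  cols <- intersect(c("dsc", "iou", "precision", "recall"),
                    intersect(names(df_a), names(df_b)))
  out <- lapply(cols, function(cn) {
    keep <- !is.na(df_a[[cn]]) & !is.na(df_b[[cn]])
    r <- compare_models(df_a[[cn]][keep], df_b[[cn]][keep], family_size)
    data.frame(metric = cn, p_raw = r$p_raw, p_adjusted = r$p_adjusted,
               family_size = r$family_size, direction = r$direction,
               statistic = r$statistic, n = r$n)
  })
  do.call(rbind, out)
}

#' Evaluate predicted masks against ground truth
#'
#' Per-slice confusion-derived metrics over paired mask lists. Slices with
#' empty ground truth are excluded from metric rows (DSC undefined when
#' TP+FP+FN can only count prediction pixels) and reported via
#' `n_empty_gt`; a per-slice `empty_prediction` flag records absence of any
#' predicted mask.
#'
#' @param preds,gts lists of binary matrices (paired).
#' @param meta optional data frame of per-slice provenance (recycled
#'   columns `patient_id`, `side`, `slice_index`).
#' @return list with `per_slice` (data frame), `summary`
#'   (from [aggregate_metrics()]), `failures` (from [classify_failure()]),
#'   and `n_empty_gt`.
#' @export
evaluate_predictions <- function(preds, gts, meta = NULL) {
  if (length(preds) != length(gts)) stop("prediction/ground-truth count mismatch")
  rows <- list()
  n_empty <- 0L
  for (i in seq_along(preds)) {
    if (sum(gts[[i]]) == 0L) { n_empty <- n_empty + 1L; next }
    cc <- confusion(preds[[i]], gts[[i]])
    m <- seg_metrics(cc)
    row <- data.frame(slice = i, dsc = m$dsc, iou = m$iou,
                      precision = m$precision, recall = m$recall,
                      empty_prediction = (cc$tp + cc$fp) == 0L)
    if (!is.null(meta)) row <- cbind(meta[i, , drop = FALSE], row)
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("no slices with non-empty ground truth")
  per_slice <- do.call(rbind, rows)
  rownames(per_slice) <- NULL
  list(per_slice = per_slice,
       summary = aggregate_metrics(per_slice),
       failures = classify_failure(per_slice$dsc),
       n_empty_gt = n_empty)
}
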