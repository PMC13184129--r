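# Standardized preprocessing: orientation canonicalization (left-side
# slices horizontally flipped to right-side orientation), min-max scaling
# to an 8-bit range, Lanczos aspect-preserving resize to fit the target
# boundary, and centered zero-padding to target_size x target_size.
#
# Conventions fixed for bit-reproducibility: round-half-up for intensity
# quantization and dimension rounding; odd padding remainders put the extra
# pixel on the bottom/right; masks are resampled nearest-neighbour and
# re-binarized at 0.5 (never Lanczos, whose ringing would leave the {0,1}
# domain); row-major, origin top-left, "horizontal flip" reverses columns.

round_half_up <- function(x) floor(x + 0.5)

#' Preprocessing configuration
#'
#' @param target_size output side length in pixels (>= 8).
#' @param resample_filter `"lanczos"` (images) -- masks always use
#'   nearest-neighbour.
#' @param pad_value intensity used for padding.
#' @param flip_left flip left-side slices to right-side orientation.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 256L, resample_filter = "lanczos",
                              pad_value = 0L, flip_left = TRUE) {
  if (target_size < 8L) stop("target_size must be >= 8")
  resample_filter <- match.arg(resample_filter, "lanczos")
  structure(list(target_size = as.integer(target_size),
                 resample_filter = resample_filter,
                 pad_value = pad_value, flip_left = flip_left),
            class = "preprocess_config")
}

#' Min-max scaling to the 8-bit range
#'
#' Maps the image minimum to 0 and maximum to 255 with round-half-up
#' quantization. A constant image maps to all zeros with a warning.
#'
#' @param image numeric matrix.
#' @return integer matrix with values in 0..255.
#' @export
minmax_to_8bit <- function(image) {
  if (length(image) == 0L) stop("empty image")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: min-max normalization maps it to all zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  out <- round_half_up((image - rng[1]) / (rng[2] - rng[1]) * 255)
  matrix(as.integer(out), nrow(image), ncol(image))
}

#' Canonicalize slice orientation
#'
#' Left-side slices (and their masks) are mirrored about the vertical axis
#' so every series is in right-side orientation; right-side input is
#' returned unchanged.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same geometry (or `NULL`).
#' @param side `"left"` or `"right"`.
#' @return list with `image` and `mask`.
#' @export
canonicalize_side <- function(image, mask = NULL, side) {
  side <- match.arg(side, c("left", "right"))
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask geometry differ")
  if (side == "left") {
    image <- flip_h(image)
    if (!is.null(mask)) mask <- flip_h(mask)
  }
  list(image = image, mask = mask)
}

# Lanczos-3 resampling weight matrix mapping n_in samples to n_out.
# On downscale the kernel is widened by the inverse scale (standard
# area-correct behaviour); rows are renormalized after edge clipping.
lanczos_matrix <- function(n_out, n_in, a = 3) {
  s <- n_out / n_in
  fscale <- max(1, 1 / s)
  A <- matrix(0, n_out, n_in)
  sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / s - 0.5          # 0-based source coordinate
    lo <- max(0L, as.integer(floor(src - a * fscale)))
    hi <- min(n_in - 1L, as.integer(ceiling(src + a * fscale)))
    j <- lo:hi
    t <- (j - src) / fscale
    w <- sinc(t) * sinc(t / a)
    w[abs(t) >= a] <- 0
    if (sum(w) == 0) w[which.min(abs(t))] <- 1
    A[i, j + 1L] <- w / sum(w)
  }
  A
}

nearest_matrix <- function(n_out, n_in) {
  s <- n_out / n_in
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / s - 0.5
    j <- min(max(as.integer(round_half_up(src)), 0L), n_in - 1L)
    A[i, j + 1L] <- 1
  }
  A
}

#' Aspect-preserving resize to fit a square boundary
#'
#' The scale is `target_size / max(H, W)`; output dimensions are
#' round-half-up of the scaled input dimensions, so the larger dimension is
#' exactly `target_size`. Images use separable Lanczos-3; masks use
#' nearest-neighbour and are re-binarized.
#'
#' @param image numeric or integer matrix.
#' @param target_size boundary side length.
#' @param kind `"image"` (Lanczos, result clamped/quantized to the input's
#'   integer range when integer input) or `"mask"` (nearest-neighbour).
#' @return matrix of the fitted size.
#' @export
fit_resize <- function(image, target_size = 256L, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (target_size < 8L) stop("target_size must be >= 8")
  H <- nrow(image); W <- ncol(image)
  if (H == 0L || W == 0L) stop("empty image")
  s <- target_size / max(H, W)
  Ho <- as.integer(round_half_up(H * s))
  Wo <- as.integer(round_half_up(W * s))
  if (Ho == H && Wo == W) return(image)
  was_int <- is.integer(image)
  if (kind == "mask") {
    A <- nearest_matrix(Ho, H); B <- nearest_matrix(Wo, W)
    out <- A %*% image %*% t(B)
    return(matrix(as.integer(out >= 0.5), Ho, Wo))
  }
  A <- lanczos_matrix(Ho, H); B <- lanczos_matrix(Wo, W)
  out <- A %*% image %*% t(B)
  if (was_int) {
    out <- pmin(pmax(round_half_up(out), 0), 255)
    out <- matrix(as.integer(out), Ho, Wo)
  }
  out
}

#' Center an image in a square canvas with padding
#'
#' Top/left margin is `floor((target - dim) / 2)`; an odd remainder puts
#' the extra pixel on the bottom/right.
#'
#' @param image matrix with both dimensions `<= target_size`.
#' @param target_size canvas side length.
#' @param pad_value fill value.
#' @return `target_size x target_size` matrix.
#' @export
center_pad <- function(image, target_size = 256L, pad_value = 0L) {
  H <- nrow(image); W <- ncol(image)
  if (H > target_size || W > target_size)
    stop("input (", H, "x", W, ") larger than target ", target_size)
  out <- matrix(if (is.integer(image)) as.integer(pad_value) else pad_value,
                target_size, target_size)
  top <- (target_size - H) %/% 2L
  left <- (target_size - W) %/% 2L
  out[top + seq_len(H), left + seq_len(W)] <- image
  out
}

#' Preprocess one slice + mask pair
#'
#' Composition: canonicalize side, min-max to 8-bit, Lanczos fit-resize,
#' centered zero-padding. The mask undergoes only the geometric operations
#' (flip, nearest-neighbour resize, pad) and stays in {0, 1}.
#'
#' @param image raw numeric matrix.
#' @param mask binary matrix or `NULL`.
#' @param side `"left"` or `"right"`.
#' @param config a [preprocess_config()].
#' @return list with `image` (integer, 0..255, target square) and `mask`.
#' @export
preprocess_slice <- function(image, mask = NULL, side = "right",
                             config = preprocess_config()) {
  if (config$flip_left) {
    cs <- canonicalize_side(image, mask, side)
    image <- cs$image; mask <- cs$mask
  }
  image <- minmax_to_8bit(image)
  image <- fit_resize(image, config$target_size, kind = "image")
  image <- center_pad(image, config$target_size, config$pad_value)
  if (!is.null(mask)) {
    mask <- fit_resize(mask, config$target_size, kind = "mask")
    mask <- center_pad(mask, config$target_size, 0L)
  }
  list(image = image, mask = mask)
}

#' Preprocess a whole series
#'
#' @param series a `nerve_series`.
#' @param config a [preprocess_config()].
#' @return a `nerve_series` of model-ready 8-bit slices and binary masks in
#'   right-side orientation.
#' @export
preprocess_series <- function(series, config = preprocess_config()) {
  if (length(series$slices) != length(series$masks))
    stop("slice/mask count mismatch")
  out_s <- vector("list", length(series$slices))
  out_m <- vector("list", length(series$masks))
  for (i in seq_along(series$slices)) {
    r <- preprocess_slice(series$slices[[i]], series$masks[[i]],
                          series$side, config)
    out_s[[i]] <- r$image
    out_m[[i]] <- r$mask
  }
  new_nerve_series(series$patient_id, series$side, out_s, out_m)
}

#' Preprocess every series of a cohort
#' @param cohort an `ian_cohort`.
#' @param config a [preprocess_config()].
#' @return an `ian_cohort` of preprocessed series.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  structure(lapply(cohort, function(p) {
    list(patient_id = p$patient_id,
         right = preprocess_series(p$right, config),
         left = preprocess_series(p$left, config))
  }), class = "ian_cohort")
}
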