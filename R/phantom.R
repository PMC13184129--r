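# Synthetic MRN-like phantom: slice series of a thin bright tubular nerve
# on a textured darker background, with ground-truth masks. The generator
# reproduces the statistical regime the segmentation method assumes --
# severe foreground/background class imbalance (nerve cross-section a few
# pixels wide), bright-nerve contrast, smooth slice-to-slice nerve paths,
# optional low-intensity artifact voids -- without modelling MR physics.

#' Phantom generator configuration
#'
#' @param n_patients number of synthetic patients; each contributes a left
#'   and a right nerve series.
#' @param slices_per_nerve slices per series (clinical series run ~118
#'   slices per nerve; the default is desk-scale).
#' @param image_height,image_width slice dimensions in pixels.
#' @param nerve_radius_range min/max nerve ellipse radius in pixels.
#' @param nerve_contrast ratio of nerve intensity to the local background
#'   (> 1). The default keeps the nerve strictly brighter than any
#'   background texture, so at zero noise the brightest pixel of a clean
#'   slice always lies inside the mask.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise on the `[0, 1]` magnitude image.
#' @param artifact_prob per-slice probability of a low-intensity artifact
#'   (void patch and/or streak) that may overlap the nerve.
#' @param path_smoothness maximum displacement (pixels, Euclidean) of the
#'   nerve center between consecutive slices.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the full configuration.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 4L,
                           slices_per_nerve = 32L,
                           image_height = 256L,
                           image_width = 256L,
                           nerve_radius_range = c(1.0, 3.0),
                           nerve_contrast = 2.5,
                           noise_sigma = 0.05,
                           artifact_prob = 0.1,
                           path_smoothness = 2.0,
                           seed = 1L) {
  if (n_patients < 1L || slices_per_nerve < 1L) stop("counts must be >= 1")
  if (image_height < 8L || image_width < 8L) stop("image dimensions too small")
  if (nerve_contrast <= 1) stop("nerve_contrast must exceed 1")
  if (artifact_prob < 0 || artifact_prob > 1) stop("artifact_prob must lie in [0, 1]")
  if (any(nerve_radius_range <= 0) || diff(nerve_radius_range) < 0)
    stop("nerve_radius_range must be positive and ordered")
  rmax <- nerve_radius_range[2]
  if (2 * rmax + 4 > min(image_height, image_width))
    stop("nerve radius cannot fit inside the image")
  if (pi * rmax^2 / (image_height * image_width) > 0.01)
    stop("maximum nerve cross-section would exceed 1% of the image; ",
         "enlarge the image or shrink the radius range")
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_nerve = as.integer(slices_per_nerve),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 nerve_radius_range = as.numeric(nerve_radius_range),
                 nerve_contrast = nerve_contrast,
                 noise_sigma = noise_sigma,
                 artifact_prob = artifact_prob,
                 path_smoothness = path_smoothness,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# smooth low-frequency background texture: coarse uniform grid, bilinearly
# upsampled. Base 0.35, amplitude 0.08 -> texture in [0.27, 0.43].
phantom_background <- function(H, W) {
  coarse <- matrix(stats::runif(64, -1, 1), 8, 8)
  tex <- bilinear_matrix(H, 8) %*% coarse %*% t(bilinear_matrix(W, 8))
  0.35 + 0.08 * tex
}

render_ellipse <- function(H, W, cy, cx, ry, rx) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

# one series rendered in canonical (right-side) orientation
render_series_canonical <- function(cfg) {
  H <- cfg$image_height; W <- cfg$image_width
  ns <- cfg$slices_per_nerve
  rr <- cfg$nerve_radius_range
  # nerve path starts laterally (right-ish columns), wanders smoothly
  cy <- stats::runif(1, 0.35 * H, 0.70 * H)
  cx <- stats::runif(1, 0.55 * W, 0.80 * W)
  margin <- rr[2] + 2
  slices <- vector("list", ns)
  masks <- vector("list", ns)
  for (s in seq_len(ns)) {
    if (s > 1L) {
      ang <- stats::runif(1, 0, 2 * pi)
      step <- stats::runif(1, 0, cfg$path_smoothness)
      cy <- min(max(cy + step * sin(ang), margin), H - margin)
      cx <- min(max(cx + step * cos(ang), margin), W - margin)
    }
    ry <- stats::runif(1, rr[1], rr[2])
    rx <- stats::runif(1, rr[1], rr[2])
    bg <- phantom_background(H, W)
    # darker cortical ring around the nerve path
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    dist <- sqrt((xx - cx)^2 + (yy - cy)^2)
    ring_r <- 3 * rr[2] + 3
    ring <- dist >= ring_r & dist <= ring_r + 2.5
    img <- bg
    img[ring] <- img[ring] * 0.6
    mask <- render_ellipse(H, W, cy, cx, ry, rx)
    # hard class-imbalance guarantee: discrete rendering never exceeds 1%
    while (sum(mask) > 0.01 * H * W) {
      ry <- ry * 0.9; rx <- rx * 0.9
      mask <- render_ellipse(H, W, cy, cx, ry, rx)
    }
    img[mask] <- pmin(bg[mask] * cfg$nerve_contrast, 0.98)
    # optional artifacts: signal-void patch and/or low-intensity streak
    if (stats::runif(1) < cfg$artifact_prob) {
      py <- stats::runif(1, 1, H); px <- stats::runif(1, 1, W)
      pr <- stats::runif(2, 3, max(4, min(H, W) / 8))
      void <- render_ellipse(H, W, py, px, pr[1], pr[2])
      img[void] <- img[void] * 0.1
      if (stats::runif(1) < 0.5) {
        row <- sample.int(H, 1)
        band <- max(1L, row - 1L):min(H, row + 1L)
        img[band, ] <- img[band, ] * 0.3
      }
    }
    if (cfg$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, cfg$noise_sigma), H, W)
    }
    img <- pmin(pmax(img, 0), 1)
    slices[[s]] <- img
    masks[[s]] <- matrix(as.integer(mask), H, W)
  }
  list(slices = slices, masks = masks)
}

new_nerve_series <- function(patient_id, side, slices, masks) {
  stopifnot(length(slices) == length(masks))
  structure(list(patient_id = patient_id, side = side,
                 slices = slices, masks = masks),
            class = "nerve_series")
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Generate a synthetic cohort
#'
#' Produces `n_patients` patients, each with a left and a right nerve
#' series. Left-side series are stored mirrored (nerve on the opposite
#' image side), so the preprocessing orientation flip is exercised.
#' Deterministic given the configuration seed.
#'
#' @param config a [phantom_config()].
#' @return an `ian_cohort`: list of patients, each holding `patient_id`,
#'   `left` and `right` `nerve_series`.
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, {
    cohort <- lapply(seq_len(config$n_patients), function(p) {
      pid <- sprintf("P%03d", p)
      right <- render_series_canonical(config)
      leftc <- render_series_canonical(config)
      left <- list(slices = lapply(leftc$slices, flip_h),
                   masks = lapply(leftc$masks, flip_h))
      list(patient_id = pid,
           right = new_nerve_series(pid, "right", right$slices, right$masks),
           left = new_nerve_series(pid, "left", left$slices, left$masks))
    })
    structure(cohort, class = "ian_cohort")
  })
}

#' All series of a cohort as a flat list
#' @param cohort an `ian_cohort`.
#' @return list of `nerve_series`.
#' @export
cohort_series <- function(cohort) {
  out <- list()
  for (p in cohort) {
    out[[length(out) + 1L]] <- p$right
    out[[length(out) + 1L]] <- p$left
  }
  out
}

#' Foreground-fraction summary over a cohort
#'
#' @param cohort an `ian_cohort` or list of `nerve_series`.
#' @return list with `mean`, `max` per-slice foreground fraction and
#'   `n_slices`.
#' @export
foreground_stats <- function(cohort) {
  series <- if (inherits(cohort, "ian_cohort")) cohort_series(cohort) else cohort
  fr <- unlist(lapply(series, function(s) {
    vapply(s$masks, function(m) sum(m) / length(m), numeric(1))
  }))
  if (length(fr) == 0L) stop("empty cohort")
  list(mean = mean(fr), max = max(fr), n_slices = length(fr))
}

#' Mask centroid (row, column), 1-based
#' @param mask binary matrix.
#' @return numeric length-2 vector, `NA` for an empty mask.
#' @export
mask_centroid <- function(mask) {
  w <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(w) == 0L) return(c(NA_real_, NA_real_))
  c(mean(w[, 1]), mean(w[, 2]))
}

#' @export
print.nerve_series <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("nerve_series %s/%s: %d slices of %dx%d\n",
              x$patient_id, x$side, length(x$slices), d[1], d[2]))
  invisible(x)
}

#' Write a cohort as per-series PNG directories
#'
#' Each series becomes `<patient>_<side>/slice_###.png` plus
#' `mask_###.png`, with a cohort-level `manifest.csv` (patient_id, side,
#' slice_index, image, mask).
#'
#' @param cohort an `ian_cohort`.
#' @param dir output directory.
#' @return the manifest as a data frame, invisibly.
#' @export
write_cohort_png <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort_series(cohort)) {
    sd <- file.path(dir, paste0(s$patient_id, "_", s$side))
    dir.create(sd, showWarnings = FALSE)
    for (i in seq_along(s$slices)) {
      ip <- file.path(sd, sprintf("slice_%03d.png", i))
      mp <- file.path(sd, sprintf("mask_%03d.png", i))
      png::writePNG(s$slices[[i]] + 0.0, ip)
      png::writePNG(s$masks[[i]] + 0.0, mp)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = s$patient_id, side = s$side, slice_index = i,
        image = ip, mask = mp, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort_png()]
#' @param dir directory containing `manifest.csv`.
#' @return an `ian_cohort`.
#' @export
read_cohort_png <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  pats <- unique(mf$patient_id)
  cohort <- lapply(pats, function(pid) {
    one_side <- function(side) {
      rows <- mf[mf$patient_id == pid & mf$side == side, ]
      rows <- rows[order(rows$slice_index), ]
      slices <- lapply(rows$image, function(p) png_gray(png::readPNG(p)))
      masks <- lapply(rows$mask, function(p) {
        m <- png_gray(png::readPNG(p))
        matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
      })
      new_nerve_series(pid, side, slices, masks)
    }
    list(patient_id = pid, right = one_side("right"), left = one_side("left"))
  })
  structure(cohort, class = "ian_cohort")
}

# collapse an RGB(A) PNG array to grayscale
png_gray <- function(a) {
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a
}
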