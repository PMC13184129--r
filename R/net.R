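# U-shaped split-attention encoder-decoder with an MSPA bottleneck.
#
# Topology: conv stem -> S encoder stages (split-attention residual block +
# 2x2 index-retaining max-pool) -> multi split-pool aggregation (MSPA)
# bottleneck -> S decoder stages (max-unpool guided by the encoder's pooling
# indices, skip concatenation, conv + BN + ReLU) -> 1x1 conv head -> sigmoid.

#' Network configuration
#'
#' @param in_channels number of input channels (grayscale slices: 1).
#' @param stage_channels channel width of each encoder stage; its length is
#'   the number of stages `S`. Input height/width must be divisible by `2^S`.
#' @param radix number of parallel convolutional splits recombined by
#'   softmax attention inside each residual block.
#' @param msa_kernels odd kernel sizes of the parallel bottleneck
#'   convolutions (multi split aggregation).
#' @param mpa_pool_sizes adaptive-average-pool output resolutions of the
#'   multi pool aggregation branch.
#' @param out_channels output channels (binary segmentation: 1).
#' @param preset `"default"` (32-64-128-256) or `"small"` (8-16-32-64), a
#'   desk-scale width suitable for quick experiments and smoke training.
#' @return a `net_config` list.
#' @export
net_config <- function(in_channels = 1L,
                       stage_channels = NULL,
                       radix = 2L,
                       msa_kernels = c(1L, 3L, 5L, 7L),
                       mpa_pool_sizes = c(1L, 2L, 3L),
                       out_channels = 1L,
                       preset = c("default", "small")) {
  preset <- match.arg(preset)
  if (is.null(stage_channels)) {
    stage_channels <- if (preset == "small") c(8L, 16L, 32L, 64L)
                      else c(32L, 64L, 128L, 256L)
  }
  stage_channels <- as.integer(stage_channels)
  if (radix < 1L) stop("radix must be >= 1")
  if (any(msa_kernels %% 2L == 0L)) stop("msa_kernels must be odd")
  cS <- stage_channels[length(stage_channels)]
  if (cS %% 4L != 0L)
    stop("bottleneck channels (", cS, ") must be divisible by 4 for MSPA")
  structure(list(in_channels = as.integer(in_channels),
                 stage_channels = stage_channels,
                 num_stages = length(stage_channels),
                 radix = as.integer(radix),
                 msa_kernels = as.integer(msa_kernels),
                 mpa_pool_sizes = as.integer(mpa_pool_sizes),
                 out_channels = as.integer(out_channels)),
            class = "net_config")
}

# He-style initializer for a (kh, kw, cin, cout) conv weight
init_conv_w <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

new_module_env <- function() new.env(parent = emptyenv())

add_conv <- function(model, name, k, cin, cout) {
  model$params[[paste0(name, ".w")]] <- ad_param(init_conv_w(k, k, cin, cout))
  model$params[[paste0(name, ".b")]] <- ad_param(numeric(cout))
}

add_bn <- function(model, name, c) {
  model$params[[paste0(name, ".g")]] <- ad_param(rep(1, c))
  model$params[[paste0(name, ".beta")]] <- ad_param(numeric(c))
  model$state[[name]] <- bn_state(c)
}

add_dense <- function(model, name, cin, cout) {
  model$params[[paste0(name, ".w")]] <-
    ad_param(matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout))
  model$params[[paste0(name, ".b")]] <- ad_param(numeric(cout))
}

#' Build a segmentation network
#'
#' Allocates and initializes all parameters of the architecture described in
#' [net_config()]. Initialization is drawn from the current RNG stream; wrap
#' in [withr::with_seed()] (or pass `seed`) for reproducibility.
#'
#' @param config a [net_config()].
#' @param seed optional integer; when given, parameter initialization is run
#'   under this seed without disturbing the caller's RNG state.
#' @return an object of class `ianseg_model`.
#' @export
build_model <- function(config = net_config(), seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, build_model(config, seed = NULL)))
  }
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- list()
  model$state <- list()
  ch <- config$stage_channels
  S <- config$num_stages
  R <- config$radix

  # stem
  add_conv(model, "stem", 3L, config$in_channels, ch[1]); add_bn(model, "stem.bn", ch[1])

  # encoder split-attention blocks
  prev <- ch[1]
  for (i in seq_len(S)) {
    pre <- sprintf("enc%d", i)
    for (r in seq_len(R)) {
      add_conv(model, sprintf("%s.split%d", pre, r), 3L, prev, ch[i])
      add_bn(model, sprintf("%s.split%d.bn", pre, r), ch[i])
    }
    hidden <- max(ch[i] %/% 4L, 4L)
    add_dense(model, paste0(pre, ".fc1"), ch[i], hidden)
    add_dense(model, paste0(pre, ".fc2"), hidden, R * ch[i])
    if (prev != ch[i]) {
      add_conv(model, paste0(pre, ".proj"), 1L, prev, ch[i])
      add_bn(model, paste0(pre, ".proj.bn"), ch[i])
    }
    prev <- ch[i]
  }

  # MSPA bottleneck
  C <- ch[S]; C4 <- C %/% 4L
  for (k in config$msa_kernels) {
    add_conv(model, sprintf("msa.k%d", k), k, C, C4)
    add_bn(model, sprintf("msa.k%d.bn", k), C4)
  }
  for (p in config$mpa_pool_sizes) {
    add_conv(model, sprintf("mpa.p%d", p), 1L, C, C4)
    add_bn(model, sprintf("mpa.p%d.bn", p), C4)
  }
  n_mpa <- length(config$mpa_pool_sizes)
  fuse_in <- C + C + n_mpa * C4
  add_conv(model, "mspa.fuse", 1L, fuse_in, C); add_bn(model, "mspa.fuse.bn", C)

  # decoder
  for (i in seq_len(S)) {
    cout <- if (i == 1L) ch[1] else ch[i - 1L]
    add_conv(model, sprintf("dec%d", i), 3L, 2L * ch[i], cout)
    add_bn(model, sprintf("dec%d.bn", i), cout)
  }
  add_conv(model, "head", 1L, ch[1], config$out_channels)
  # prior-probability initialization of the head bias: with ~1% foreground,
  # starting the sigmoid near the class prior avoids the large initial
  # false-positive gradient that slows convergence on imbalanced masks
  model$params[["head.b"]]$value <- rep(stats::qlogis(0.01), config$out_channels)

  class(model) <- c("ianseg_model", class(model))
  model
}

p_ <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("no parameter '", name, "'")
  p
}

conv_bn_relu <- function(model, name, x, training) {
  h <- ad_conv2d(x, p_(model, paste0(name, ".w")), p_(model, paste0(name, ".b")))
  h <- ad_batchnorm(h, p_(model, paste0(name, ".bn.g")),
                    p_(model, paste0(name, ".bn.beta")),
                    model$state[[paste0(name, ".bn")]], training)
  ad_relu(h)
}

#' Split-attention residual block
#'
#' Computes `radix` parallel conv-BN-ReLU splits, pools their sum globally,
#' maps it through a two-layer bottleneck to per-radix logits, applies a
#' softmax across the radix dimension, combines the splits with the
#' resulting attention weights, and adds the identity path (1x1-projected
#' when the channel count changes).
#'
#' @param model an `ianseg_model`.
#' @param stage encoder stage index (names the block's parameters).
#' @param x input `ad_tensor` of shape (H, W, C_in, N).
#' @param training logical; batch-norm mode.
#' @return an `ad_tensor` of shape (H, W, C_stage, N).
#' @keywords internal
split_attention_block <- function(model, stage, x, training) {
  cfg <- model$config
  R <- cfg$radix
  ch <- cfg$stage_channels[stage]
  pre <- sprintf("enc%d", stage)
  splits <- lapply(seq_len(R), function(r) {
    conv_bn_relu(model, sprintf("%s.split%d", pre, r), x, training)
  })
  s <- splits[[1]]
  if (R > 1L) for (r in 2:R) s <- ad_add(s, splits[[r]])
  gap <- ad_global_avgpool(s)                        # (N, C)
  h <- ad_relu(ad_dense(gap, p_(model, paste0(pre, ".fc1.w")),
                        p_(model, paste0(pre, ".fc1.b"))))
  logits <- ad_dense(h, p_(model, paste0(pre, ".fc2.w")),
                     p_(model, paste0(pre, ".fc2.b")))   # (N, R*C), radix-fastest
  N <- nrow(logits$value)
  lg <- ad_tensor(array(t(logits$value), c(R, ch, N)), list(logits),
                  function(g) list(t(matrix(g, R * ch, N))))
  a <- ad_softmax_dim1(lg)
  if (isTRUE(model$record_attention)) {
    model$last_attention[[sprintf("stage%d", stage)]] <- a$value
  }
  v <- ad_attn_combine(splits, a)
  cin <- dim(x$value)[3]
  idn <- if (cin == ch) x else {
    hh <- ad_conv2d(x, p_(model, paste0(pre, ".proj.w")),
                    p_(model, paste0(pre, ".proj.b")))
    ad_batchnorm(hh, p_(model, paste0(pre, ".proj.bn.g")),
                 p_(model, paste0(pre, ".proj.bn.beta")),
                 model$state[[paste0(pre, ".proj.bn")]], training)
  }
  ad_relu(ad_add(v, idn))
}

#' Encoder pass
#'
#' @param model an `ianseg_model`.
#' @param x `ad_tensor` or array of shape (H, W, in_channels, N); H and W
#'   must be divisible by `2^S`.
#' @param training logical.
#' @return list with `bottleneck` (tensor), `skips` (pre-pool stage outputs)
#'   and `pools` (pooling records carrying the argmax indices).
#' @export
encode <- function(model, x, training = FALSE) {
  if (!is_ad(x)) x <- ad_const(x)
  cfg <- model$config
  S <- cfg$num_stages
  d <- dim(x$value)
  if (d[1] %% 2L^S != 0L || d[2] %% 2L^S != 0L) {
    bad <- which(d[1] %% 2L^seq_len(S) != 0L | d[2] %% 2L^seq_len(S) != 0L)[1]
    stop("input ", d[1], "x", d[2], " not divisible by 2^", S,
         "; pooling fails at encoder stage ", bad)
  }
  h <- conv_bn_relu(model, "stem", x, training)
  skips <- vector("list", S)
  pools <- vector("list", S)
  for (i in seq_len(S)) {
    h <- split_attention_block(model, i, h, training)
    skips[[i]] <- h
    pl <- ad_maxpool2(h)
    pools[[i]] <- pl
    h <- pl$out
  }
  list(bottleneck = h, skips = skips, pools = pools)
}

#' MSPA bottleneck
#'
#' Multi split aggregation (parallel 1/3/5/7 convolutions, each to C/4
#' channels, concatenated) fused with multi pool aggregation (adaptive
#' average pooling to 1x1/2x2/3x3, 1x1-convolved, bilinearly upsampled,
#' concatenated) and the input itself, projected back to C channels by a
#' 1x1 conv + BN + ReLU.
#'
#' @param model an `ianseg_model`.
#' @param x bottleneck `ad_tensor` (H, W, C, N), C divisible by 4.
#' @param training logical.
#' @return `ad_tensor` with the same shape as `x`.
#' @export
mspa <- function(model, x, training = FALSE) {
  if (!is_ad(x)) x <- ad_const(x)
  cfg <- model$config
  d <- dim(x$value)
  msa <- ad_concat_c(lapply(cfg$msa_kernels, function(k) {
    conv_bn_relu(model, sprintf("msa.k%d", k), x, training)
  }))
  mpa <- ad_concat_c(lapply(cfg$mpa_pool_sizes, function(p) {
    h <- ad_adaptive_avgpool(x, p)
    h <- conv_bn_relu(model, sprintf("mpa.p%d", p), h, training)
    ad_upsample_bilinear(h, d[1], d[2])
  }))
  conv_bn_relu(model, "mspa.fuse", ad_concat_c(list(x, msa, mpa)), training)
}

#' Decoder pass
#'
#' Deepest stage first: max-unpool with the encoder's recorded indices
#' (non-argmax positions exactly zero), concatenate the corresponding skip,
#' and apply conv + batch norm + ReLU; a final 1x1 conv produces logits at
#' the input resolution.
#'
#' @param model an `ianseg_model`.
#' @param state the list returned by [encode()], with `bottleneck` replaced
#'   by the MSPA output if desired.
#' @param x bottleneck-resolution `ad_tensor` to start from (defaults to
#'   `state$bottleneck`).
#' @param training logical.
#' @return logits `ad_tensor` (H, W, out_channels, N).
#' @export
decode <- function(model, state, x = NULL, training = FALSE) {
  S <- model$config$num_stages
  h <- if (is.null(x)) state$bottleneck else x
  for (i in rev(seq_len(S))) {
    h <- ad_maxunpool2(h, state$pools[[i]])
    h <- ad_concat_c(list(h, state$skips[[i]]))
    h <- conv_bn_relu(model, sprintf("dec%d", i), h, training)
  }
  ad_conv2d(h, p_(model, "head.w"), p_(model, "head.b"))
}

#' Full forward pass
#'
#' @param model an `ianseg_model`.
#' @param x array (H, W, in_channels, N) of preprocessed slices scaled to
#'   `[0, 1]`, or (H, W) / (H, W, N) shorthands.
#' @param training logical; batch-norm uses batch statistics when `TRUE`.
#' @return `ad_tensor` of per-pixel foreground probabilities in (0, 1).
#' @export
forward <- function(model, x, training = FALSE) {
  x <- as_input_array(x, model$config$in_channels)
  st <- encode(model, ad_const(x), training)
  b <- mspa(model, st$bottleneck, training)
  logits <- decode(model, st, b, training)
  ad_sigmoid(logits)
}

# coerce (H,W), (H,W,N) or (H,W,C,N) input to (H,W,C,N)
as_input_array <- function(x, in_channels = 1L) {
  if (is_ad(x)) x <- x$value
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    x <- array(as.numeric(x), c(dim(as.matrix(x)), 1L, 1L))
  } else if (length(d) == 3L) {
    x <- array(x, c(d[1], d[2], 1L, d[3]))
    x <- aperm(x, c(1L, 2L, 3L, 4L))
  } else if (length(d) != 4L) {
    stop("input must have 2-4 dimensions")
  }
  if (dim(x)[3] != in_channels)
    stop("input has ", dim(x)[3], " channels; model expects ", in_channels)
  x
}

#' @export
print.ianseg_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("Split-attention U-shaped segmentation network (MSPA bottleneck)\n")
  cat(sprintf("  stages: %d  channels: %s  radix: %d\n", cfg$num_stages,
              paste(cfg$stage_channels, collapse = "-"), cfg$radix))
  cat(sprintf("  MSA kernels: %s  MPA pools: %s\n",
              paste(cfg$msa_kernels, collapse = ","),
              paste(cfg$mpa_pool_sizes, collapse = ",")))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  invisible(x)
}

#' Enable or disable attention-weight recording
#'
#' When enabled, each forward pass stores the per-stage softmax attention
#' arrays (radix x channels x batch) in `model$last_attention`.
#' @param model an `ianseg_model`.
#' @param on logical.
#' @return the model, invisibly.
#' @export
record_attention <- function(model, on = TRUE) {
  model$record_attention <- on
  model$last_attention <- list()
  invisible(model)
}

#' Serialize model weights to a single file
#' @param model an `ianseg_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value),
               state = lapply(model$state, function(s)
                 list(running_mean = s$running_mean, running_var = s$running_var))),
          path)
  invisible(path)
}

#' Load model weights saved by [save_checkpoint()]
#' @param path file path.
#' @return an `ianseg_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = 1L)
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  for (nm in names(ck$state)) {
    model$state[[nm]]$running_mean <- ck$state[[nm]]$running_mean
    model$state[[nm]]$running_var <- ck$state[[nm]]$running_var
  }
  model
}
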