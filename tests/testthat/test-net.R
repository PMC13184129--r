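small_cfg <- function() net_config(stage_channels = c(4L, 4L, 4L, 8L))

test_that("output shape equals input shape at 64, 128 and 256", {
  model <- build_model(small_cfg(), seed = 1L)
  for (sz in c(64L, 128L, 256L)) {
    x <- array(runif(sz * sz), c(sz, sz, 1L, 1L))
    p <- forward(model, x)
    expect_identical(dim(p$value), c(sz, sz, 1L, 1L))
    expect_true(all(p$value > 0 & p$value < 1))
  }
})

test_that("indivisible input dimensions raise a stage-naming shape error", {
  model <- build_model(small_cfg(), seed = 1L)
  x <- array(runif(250 * 250), c(250L, 250L, 1L, 1L))
  expect_error(forward(model, x), "stage")
  # 4-stage encoder: 16x16 bottleneck from 256, 4x4 from 64
  st <- encode(model, array(runif(64 * 64), c(64L, 64L, 1L, 1L)))
  expect_identical(dim(st$bottleneck$value)[1:2], c(4L, 4L))
})

test_that("unpooling restores argmax positions exactly and zeros elsewhere", {
  set.seed(21)
  x <- ianseg:::ad_const(array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2)))
  pl <- ianseg:::ad_maxpool2(x)
  up <- ianseg:::ad_maxunpool2(pl$out, pl)
  v <- x$value; u <- up$value
  # brute-force window check
  for (n in 1:2) for (c in 1:3) for (i in seq(1, 7, 2)) for (j in seq(1, 7, 2)) {
    win <- v[i:(i + 1), j:(j + 1), c, n]
    uwin <- u[i:(i + 1), j:(j + 1), c, n]
    am <- which.max(win)
    expect_identical(uwin[am], win[am])
    expect_true(all(uwin[-am] == 0))
  }
})

test_that("adaptive average pooling equals brute-force window means", {
  set.seed(22)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  for (k in 1:3) {
    got <- ianseg:::resample_sep(x, ianseg:::adaptive_avg_matrix(16, k),
                                 ianseg:::adaptive_avg_matrix(16, k))
    for (c in 1:2) for (i in 1:k) for (j in 1:k) {
      rows <- (floor((i - 1) * 16 / k) + 1):ceiling(i * 16 / k)
      cols <- (floor((j - 1) * 16 / k) + 1):ceiling(j * 16 / k)
      expect_equal(got[i, j, c, 1], mean(x[rows, cols, c, 1]), tolerance = 1e-12)
    }
  }
  # constant map pools to the same constant
  const <- array(3.5, c(4, 4, 1, 1))
  expect_equal(as.vector(ianseg:::resample_sep(const,
                 ianseg:::adaptive_avg_matrix(4, 2),
                 ianseg:::adaptive_avg_matrix(4, 2))), rep(3.5, 4))
})

test_that("split-attention weights sum to one across the radix", {
  model <- build_model(net_config(stage_channels = c(4L, 4L, 4L, 8L), radix = 3L),
                       seed = 2L)
  record_attention(model)
  invisible(forward(model, array(runif(32 * 32 * 3), c(32, 32, 1, 3))))
  expect_length(model$last_attention, 4L)
  for (a in model$last_attention) {
    sums <- apply(a, c(2, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("radix 1 reduces attention to a constant weight of one", {
  model <- build_model(net_config(stage_channels = c(4L, 4L, 4L, 8L), radix = 1L),
                       seed = 3L)
  record_attention(model)
  invisible(forward(model, array(runif(16 * 16), c(16, 16, 1, 1))))
  for (a in model$last_attention) expect_true(all(a == 1))
})

test_that("MSPA preserves bottleneck geometry and rejects bad channel counts", {
  model <- build_model(small_cfg(), seed = 4L)
  st <- encode(model, array(runif(32 * 32 * 2), c(32, 32, 1, 2)), training = TRUE)
  out <- mspa(model, st$bottleneck, training = TRUE)
  expect_identical(dim(out$value), dim(st$bottleneck$value))
  expect_error(net_config(stage_channels = c(4L, 4L, 4L, 6L)), "divisible by 4")
  expect_error(net_config(msa_kernels = c(1L, 2L)), "odd")
  expect_error(net_config(radix = 0L), "radix")
})

test_that("forward is finite on zero input and deterministic in eval mode", {
  model <- build_model(small_cfg(), seed = 5L)
  z <- forward(model, array(0, c(16, 16, 1, 1)))
  expect_true(all(is.finite(z$value)))
  x <- array(runif(16 * 16), c(16, 16))
  batch <- array(c(x, x), c(16, 16, 1, 2))
  p <- forward(model, batch)$value
  expect_identical(p[, , 1, 1], p[, , 1, 2])
})

test_that("every parameter receives a gradient from a scalar loss", {
  model <- build_model(small_cfg(), seed = 6L)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  g <- array(rbinom(16 * 16 * 2, 1, 0.1), c(16, 16, 1, 2))
  p <- forward(model, x, training = TRUE)
  loss <- focal_tversky_loss(p, g)
  ianseg:::ad_zero_grad(model$params)
  ianseg:::ad_backward(loss)
  for (nm in names(model$params)) {
    gr <- model$params[[nm]]$grad
    expect_false(is.null(gr), info = nm)
    expect_identical(length(gr), length(model$params[[nm]]$value))
    expect_true(all(is.finite(gr)), info = nm)
  }
})

test_that("network gradients match finite differences on sampled parameters", {
  set.seed(23)
  model <- build_model(net_config(stage_channels = c(2L, 2L, 4L, 4L)), seed = 7L)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  g <- array(rbinom(256, 1, 0.08), c(16, 16, 1, 1))
  fn <- function() {
    focal_tversky_loss(forward(model, x, training = TRUE), g)$value
  }
  loss <- focal_tversky_loss(forward(model, x, training = TRUE), g)
  ianseg:::ad_zero_grad(model$params)
  ianseg:::ad_backward(loss)
  eps <- 1e-5
  for (nm in sample(names(model$params), 12)) {
    pr <- model$params[[nm]]
    i <- sample(length(pr$value), 1)
    an <- pr$grad[i]
    v0 <- pr$value[i]
    pr$value[i] <- v0 + eps; fp <- fn()
    pr$value[i] <- v0 - eps; fm <- fn()
    pr$value[i] <- v0
    gn <- (fp - fm) / (2 * eps)
    expect_lt(abs(gn - an), 1e-4 * max(1, abs(gn) + abs(an)))
  }
})

test_that("checkpoints round-trip weights and predictions", {
  model <- build_model(small_cfg(), seed = 8L)
  x <- array(runif(16 * 16), c(16, 16))
  p1 <- predict_mask(model, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(predict_mask(back, x), p1)
})
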