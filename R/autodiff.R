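#' @useDynLib ianseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Each tensor is an environment holding `value` (an array), `grad`
# (accumulated during backward), `parents` (upstream tensors) and `vjp`,
# a function mapping the output cotangent to a list of parent cotangents.
# Nodes are stamped with a monotone id at creation, so reverse creation
# order is a valid reverse-topological order for backprop.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_tensor <- function(value, parents = list(), vjp = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$grad <- NULL
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  class(e) <- "ad_tensor"
  e
}

#' Create a trainable parameter tensor
#' @param value numeric array of initial values
#' @return an `ad_tensor` leaf marked as a parameter
#' @keywords internal
ad_param <- function(value) {
  e <- ad_tensor(value)
  e$is_param <- TRUE
  e
}

ad_const <- function(value) ad_tensor(value)

is_ad <- function(x) inherits(x, "ad_tensor")

ad_value <- function(x) if (is_ad(x)) x$value else x

# Reverse pass from a scalar (or any) node. Accumulates `grad` on every
# reachable tensor; parameters keep theirs until ad_zero_grad().
ad_backward <- function(root, seed_grad = NULL) {
  if (is.null(seed_grad)) {
    seed_grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value)
                       else dim(root$value))
  }
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  root$grad <- seed_grad
  for (nd in nodes) {
    if (is.null(nd$vjp) || is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (is.null(nd$is_param)) nd$grad <- NULL  # free intermediates
  }
  invisible(root)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops -------------------------------------------------------

ad_add <- function(a, b) {
  out <- ad_tensor(a$value + b$value, list(a, b),
                   function(g) list(g, g))
  out
}

ad_relu <- function(x) {
  v <- x$value
  m <- v > 0
  ad_tensor(v * m, list(x), function(g) list(g * m))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_tensor(s, list(x), function(g) list(g * s * (1 - s)))
}

# ---- conv / dense ----------------------------------------------------------

ad_conv2d <- function(x, w, b) {
  y <- conv2d_fwd_cpp(x$value, w$value, b$value)
  ad_tensor(y, list(x, w, b), function(g) {
    r <- conv2d_bwd_cpp(x$value, w$value, g)
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

# x: (n, in) matrix; w: (in, out); b: length out
ad_dense <- function(x, w, b) {
  y <- x$value %*% w$value
  y <- sweep(y, 2L, b$value, "+")
  ad_tensor(y, list(x, w, b), function(g) {
    list(g %*% t(w$value), crossprod(x$value, g), colSums(g))
  })
}

# ---- pooling ---------------------------------------------------------------

# 2x2 stride-2 max-pool retaining within-grid argmax positions (linear
# indices into the pre-pool array). Ties resolved to the first (top-left
# scan order) position.
ad_maxpool2 <- function(x) {
  v <- x$value
  d <- dim(v)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("max-pool requires even spatial dims, got ", H, "x", W)
  i1 <- seq.int(1L, H, 2L); j1 <- seq.int(1L, W, 2L)
  q <- cbind(as.vector(v[i1,     j1,     , , drop = FALSE]),
             as.vector(v[i1 + 1L, j1,    , , drop = FALSE]),
             as.vector(v[i1,     j1 + 1L, , , drop = FALSE]),
             as.vector(v[i1 + 1L, j1 + 1L, , , drop = FALSE]))
  k <- max.col(q, ties.method = "first")
  out <- q[cbind(seq_len(nrow(q)), k)]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  dim(out) <- c(Ho, Wo, C, N)
  # map (output position, k) -> linear index in the input array
  oh <- rep_len(seq_len(Ho), length(k))
  ow <- rep_len(rep(seq_len(Wo), each = Ho), length(k))
  cn <- (seq_along(k) - 1L) %/% (Ho * Wo)   # combined channel+image block
  ih <- 2L * oh - 1L + as.integer(k == 2L | k == 4L)
  iw <- 2L * ow - 1L + as.integer(k >= 3L)
  idx <- ih + H * (iw - 1L) + H * W * cn
  node <- ad_tensor(out, list(x), function(g) {
    gx <- numeric(length(v))
    gx[idx] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
  list(out = node, idx = idx, in_dim = d)
}

# Max-unpooling: values placed at the recorded argmax positions, zeros
# elsewhere. `pool` is the list returned by ad_maxpool2.
ad_maxunpool2 <- function(x, pool) {
  d <- pool$in_dim
  idx <- pool$idx
  v <- numeric(prod(d))
  v[idx] <- as.vector(x$value)
  dim(v) <- d
  ad_tensor(v, list(x), function(g) {
    gi <- g[idx]
    dim(gi) <- dim(x$value)
    list(gi)
  })
}

# ---- separable linear spatial maps (resize / adaptive pool / upsample) -----

# y[., ., c, n] = A %*% x[., ., c, n] %*% t(B); linear, so the vjp applies
# the transposes. A: (Hout x Hin), B: (Wout x Win).
resample_sep <- function(v, A, B) {
  d <- dim(v)
  H <- d[1]; W <- d[2]; rest <- prod(d[-(1:2)])
  Ho <- nrow(A); Wo <- nrow(B)
  y1 <- A %*% matrix(v, H, W * rest)                 # (Ho, W*rest)
  dim(y1) <- c(Ho, W, rest)
  y1 <- aperm(y1, c(2L, 1L, 3L))                     # (W, Ho, rest)
  y2 <- B %*% matrix(y1, W, Ho * rest)               # (Wo, Ho*rest)
  dim(y2) <- c(Wo, Ho, rest)
  y2 <- aperm(y2, c(2L, 1L, 3L))
  dim(y2) <- c(Ho, Wo, d[-(1:2)])
  y2
}

ad_spatial_linear <- function(x, A, B) {
  ad_tensor(resample_sep(x$value, A, B), list(x), function(g) {
    list(resample_sep(g, t(A), t(B)))
  })
}

# Averaging matrix for adaptive average pooling 1D: rows partition [1..n]
# into k windows [floor(i*n/k)+1, ceil((i+1)*n/k)], each row averaging its
# window.
adaptive_avg_matrix <- function(n, k) {
  A <- matrix(0, k, n)
  for (i in seq_len(k)) {
    a <- floor((i - 1) * n / k) + 1L
    b <- ceiling(i * n / k)
    A[i, a:b] <- 1 / (b - a + 1L)
  }
  A
}

# Bilinear interpolation matrix (align_corners = FALSE convention):
# source coordinate of output i is (i + 0.5) * n_in/n_out - 0.5, clamped.
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * s - 0.5
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src)
    fr <- src - lo
    lo <- as.integer(lo) + 1L
    hi <- min(lo + 1L, n_in)
    A[i, lo] <- A[i, lo] + (1 - fr)
    A[i, hi] <- A[i, hi] + fr
  }
  A
}

ad_adaptive_avgpool <- function(x, k) {
  d <- dim(x$value)
  ad_spatial_linear(x, adaptive_avg_matrix(d[1], k), adaptive_avg_matrix(d[2], k))
}

ad_upsample_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$value)
  ad_spatial_linear(x, bilinear_matrix(h_out, d[1]), bilinear_matrix(w_out, d[2]))
}

# ---- structure ops ---------------------------------------------------------

# concatenate along the channel axis (dim 3)
ad_concat_c <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d0 <- dim(vals[[1]])
  cc <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d0[1], d0[2], sum(cc), d0[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ends <- cumsum(cc)
  starts <- c(1, head(ends, -1) + 1)
  ad_tensor(out, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      g[, , starts[i]:ends[i], , drop = FALSE]
    })
  })
}

# global average pool (H,W,C,N) -> (N, C) matrix
ad_global_avgpool <- function(x) {
  d <- dim(x$value)
  m <- d[1] * d[2]
  v <- apply(x$value, c(4L, 3L), sum) / m      # (N, C)
  if (is.null(dim(v))) dim(v) <- c(d[4], d[3])
  ad_tensor(v, list(x), function(g) {
    gx <- array(rep(as.vector(t(g)), each = m) / m, d)
    list(gx)
  })
}

# softmax over dim 1 of an (R, C, N) array
ad_softmax_dim1 <- function(x) {
  v <- x$value
  d <- dim(v)
  m <- apply(v, c(2L, 3L), max)
  e <- exp(v - array(rep(m, each = d[1]), d))
  s <- apply(e, c(2L, 3L), sum)
  sm <- e / array(rep(s, each = d[1]), d)
  ad_tensor(sm, list(x), function(g) {
    dot <- apply(g * sm, c(2L, 3L), sum)
    list(sm * (g - array(rep(dot, each = d[1]), d)))
  })
}

# attention-weighted sum of radix splits: out = sum_r a[r,c,n] * U_r
# splits: list of R tensors (H,W,C,N); a: (R,C,N)
ad_attn_combine <- function(splits, a) {
  R <- length(splits)
  d <- dim(splits[[1]]$value)
  av <- a$value
  out <- array(0, d)
  for (r in seq_len(R)) {
    w <- array(rep(av[r, , ], each = d[1] * d[2]), d)
    out <- out + w * splits[[r]]$value
  }
  ad_tensor(out, c(splits, list(a)), function(g) {
    gs <- vector("list", R + 1L)
    ga <- array(0, dim(av))
    for (r in seq_len(R)) {
      w <- array(rep(av[r, , ], each = d[1] * d[2]), d)
      gs[[r]] <- g * w
      ga[r, , ] <- apply(g * splits[[r]]$value, c(3L, 4L), sum)
    }
    gs[[R + 1L]] <- ga
    gs
  })
}

# ---- batch normalization ---------------------------------------------------

# Per-channel batch norm over (H, W, N). `state` is an environment with
# running_mean / running_var, updated in training mode.
ad_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  per_c <- function(a) aperm(a, c(1L, 2L, 4L, 3L))  # channel last
  xc <- matrix(per_c(v), ncol = C)                  # (m, C)
  if (training) {
    mu <- colMeans(xc)
    varc <- colMeans(sweep(xc, 2L, mu)^2)           # biased, as in BN
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * varc
  } else {
    mu <- state$running_mean
    varc <- state$running_var
  }
  inv_sd <- 1 / sqrt(varc + eps)
  xhat <- sweep(sweep(xc, 2L, mu), 2L, inv_sd, "*")
  yc <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  back_perm <- function(mat) {
    a <- array(mat, c(d[1], d[2], d[4], d[3]))
    aperm(a, c(1L, 2L, 4L, 3L))
  }
  y <- back_perm(yc)
  ad_tensor(y, list(x, gamma, beta), function(g) {
    gc <- matrix(per_c(g), ncol = C)
    dgamma <- colSums(gc * xhat)
    dbeta <- colSums(gc)
    dxhat <- sweep(gc, 2L, gamma$value, "*")
    if (training) {
      # standard BN backward through batch statistics
      t1 <- sweep(dxhat, 2L, colSums(dxhat) / m)
      t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / m, "*")
      dx <- sweep(t1 - t2, 2L, inv_sd, "*")
    } else {
      dx <- sweep(dxhat, 2L, inv_sd, "*")
    }
    list(back_perm(dx), dgamma, dbeta)
  })
}

bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(channels)
  e$running_var <- rep(1, channels)
  e
}
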