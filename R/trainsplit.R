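# Patient-level Monte Carlo cross-validation and the training loop:
# AdamW, cosine annealing, focal Tversky objective, early stopping with
# best-weight restoration. Splitting at the patient level keeps the left
# and right nerves of one patient in the same partition (no leakage).

#' Training configuration
#'
#' @param lr0 initial learning rate of AdamW.
#' @param weight_decay decoupled weight decay.
#' @param epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param patience early-stopping patience in epochs (<= epochs).
#' @param n_repeats Monte Carlo cross-validation repeats.
#' @param threshold probability cutoff for mask binarization.
#' @param seed integer base seed.
#' @param monitor validation quantity watched by early stopping
#'   (`"val_dsc"`, maximized).
#' @return a `train_config` list.
#' @export
train_config <- function(lr0 = 1e-3, weight_decay = 1e-4, epochs = 50L,
                         batch_size = 32L, patience = 25L, n_repeats = 10L,
                         threshold = 0.5, seed = 1L, monitor = "val_dsc") {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (patience > epochs) stop("patience must not exceed epochs")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  monitor <- match.arg(monitor, "val_dsc")
  structure(list(lr0 = lr0, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), n_repeats = as.integer(n_repeats),
                 threshold = threshold, seed = as.integer(seed),
                 monitor = monitor),
            class = "train_config")
}

#' Patient-level train/val/test split
#'
#' Deterministic shuffle under `seed`; `n_val = round(f_val * N)`,
#' `n_test = round(f_test * N)`, remainder to train (keeps train largest).
#'
#' @param patient_ids character vector of patient identifiers.
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed integer.
#' @return a `split_plan`: list with `seed` and `assignment` (named
#'   character vector patient -> partition).
#' @export
make_split <- function(patient_ids, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  N <- length(patient_ids)
  if (N < 3L) stop("need at least 3 patients")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_val <- as.integer(round_half_up(fractions[2] * N))
  n_test <- as.integer(round_half_up(fractions[3] * N))
  n_train <- N - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("a partition would be empty with ", N, " patients")
  shuffled <- withr::with_seed(seed, sample(patient_ids))
  assignment <- stats::setNames(
    rep(c("train", "val", "test"), c(n_train, n_val, n_test)), shuffled)
  assignment <- assignment[patient_ids]  # stable order
  structure(list(seed = as.integer(seed), assignment = assignment,
                 sizes = c(train = n_train, val = n_val, test = n_test)),
            class = "split_plan")
}

#' Monte Carlo repeated splits
#'
#' `n_repeats` independent patient-level splits with seeds
#' `base_seed + repeat_index` (0-based). Unlike k-fold, test sets of
#' different repeats may overlap or jointly miss patients.
#'
#' @param patient_ids character vector.
#' @param n_repeats number of repeats (>= 1).
#' @param base_seed integer.
#' @param fractions train/val/test fractions.
#' @return list of `split_plan`s, each carrying `repeat_index`.
#' @export
monte_carlo_splits <- function(patient_ids, n_repeats = 10L, base_seed = 1L,
                               fractions = c(0.7, 0.15, 0.15)) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  lapply(seq_len(n_repeats) - 1L, function(k) {
    pl <- make_split(patient_ids, fractions, seed = base_seed + k)
    pl$repeat_index <- k
    pl
  })
}

#' Cosine annealing learning-rate schedule
#'
#' `lr(e) = lr0 * (1 + cos(pi * e / total_epochs)) / 2` with minimum 0.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= total_epochs`.
#' @param lr0 initial learning rate.
#' @param total_epochs schedule length.
#' @return learning rate.
#' @export
cosine_lr <- function(epoch, lr0 = 1e-3, total_epochs = 50L) {
  lr0 * (1 + cos(pi * epoch / total_epochs)) / 2
}

# gather the slices/masks of the cohort patients in one partition as a
# (H, W, 1, n) array pair; slices rescaled from 8-bit to [0, 1].
partition_arrays <- function(cohort, plan, part) {
  pats <- names(plan$assignment)[plan$assignment == part]
  xs <- list(); gs <- list()
  for (p in cohort) {
    if (!(p$patient_id %in% pats)) next
    for (s in list(p$right, p$left)) {
      for (i in seq_along(s$slices)) {
        xs[[length(xs) + 1L]] <- s$slices[[i]]
        gs[[length(gs) + 1L]] <- s$masks[[i]]
      }
    }
  }
  if (length(xs) == 0L) stop("partition '", part, "' holds no slices")
  d <- dim(xs[[1]])
  x <- array(unlist(xs), c(d[1], d[2], 1L, length(xs)))
  g <- array(unlist(gs), c(d[1], d[2], 1L, length(gs)))
  if (max(x) > 1) x <- x / 255
  list(x = x, g = g)
}

# AdamW step over all parameters; opt is an environment carrying moments
adamw_step <- function(params, opt, lr, weight_decay, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
  }
  invisible(NULL)
}

new_adamw <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L; e$m <- list(); e$v <- list()
  e
}

# mean DSC of binarized predictions over an array batch (forward in eval
# mode, chunked to bound memory)
batch_mean_dsc <- function(model, x, g, threshold = 0.5, chunk = 16L) {
  n <- dim(x)[4]
  dsc <- numeric(0)
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    p <- forward(model, x[, , , a:b, drop = FALSE], training = FALSE)$value
    for (j in seq_len(b - a + 1L)) {
      pm <- (p[, , 1L, j] >= threshold) * 1L
      gm <- g[, , 1L, j]
      if (sum(gm) == 0L) next
      cc <- confusion(matrix(pm, dim(x)[1]), matrix(gm, dim(x)[1]))
      dsc <- c(dsc, seg_metrics(cc)$dsc)
    }
  }
  if (length(dsc) == 0L) return(NA_real_)
  mean(dsc)
}

#' Train the network on one split
#'
#' AdamW (decoupled weight decay) under a cosine annealing schedule, focal
#' Tversky objective, per-epoch validation mean DSC, early stopping with
#' patience and best-weight restoration.
#'
#' @param cohort preprocessed `ian_cohort`.
#' @param plan a `split_plan` from [make_split()].
#' @param net_cfg a [net_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch weights), `log` (data frame:
#'   epoch, train_loss, val_dsc, lr), `best_epoch`, `plan`.
#' @export
train_model <- function(cohort, plan, net_cfg = net_config(preset = "small"),
                        loss_cfg = loss_config(), train_cfg = train_config(),
                        verbose = FALSE) {
  tr <- partition_arrays(cohort, plan, "train")
  va <- partition_arrays(cohort, plan, "val")
  model <- build_model(net_cfg, seed = train_cfg$seed)
  opt <- new_adamw()
  n <- dim(tr$x)[4]
  log_rows <- list()
  best <- -Inf; best_epoch <- NA_integer_; best_values <- NULL; best_state <- NULL
  since_best <- 0L
  withr::with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      lr <- cosine_lr(epoch, train_cfg$lr0, train_cfg$epochs)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (a in seq(1L, n, by = train_cfg$batch_size)) {
        b <- min(a + train_cfg$batch_size - 1L, n)
        idx <- ord[a:b]
        xb <- tr$x[, , , idx, drop = FALSE]
        gb <- tr$g[, , , idx, drop = FALSE]
        p <- forward(model, xb, training = TRUE)
        loss <- focal_tversky_loss(p, gb, loss_cfg)
        if (!is.finite(loss$value))
          stop("training diverged: non-finite loss at epoch ", epoch)
        ad_zero_grad(model$params)
        ad_backward(loss)
        adamw_step(model$params, opt, lr, train_cfg$weight_decay)
        losses <- c(losses, loss$value)
      }
      val_dsc <- batch_mean_dsc(model, va$x, va$g, train_cfg$threshold)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_dsc = val_dsc, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.4f  lr %.2e",
                        epoch, mean(losses), val_dsc, lr))
      if (!is.na(val_dsc) && val_dsc > best) {
        best <- val_dsc; best_epoch <- epoch; since_best <- 0L
        best_values <- lapply(model$params, function(p) p$value)
        best_state <- lapply(model$state, function(s)
          list(running_mean = s$running_mean, running_var = s$running_var))
      } else {
        since_best <- since_best + 1L
        if (since_best >= train_cfg$patience) break
      }
    }
  })
  if (!is.null(best_values)) {
    for (nm in names(best_values)) model$params[[nm]]$value <- best_values[[nm]]
    for (nm in names(best_state)) {
      model$state[[nm]]$running_mean <- best_state[[nm]]$running_mean
      model$state[[nm]]$running_var <- best_state[[nm]]$running_var
    }
  }
  list(model = model, log = do.call(rbind, log_rows),
       best_epoch = best_epoch, best_val_dsc = best, plan = plan)
}

#' Predict a binary mask for one slice
#'
#' @param model a trained `ianseg_model`.
#' @param slice preprocessed slice: integer 8-bit or `[0, 1]` numeric
#'   matrix with dimensions divisible by `2^S`.
#' @param threshold probability cutoff.
#' @return binary integer matrix.
#' @export
predict_mask <- function(model, slice, threshold = 0.5) {
  x <- as.matrix(slice)
  if (max(x) > 1) x <- x / 255
  p <- forward(model, array(x, c(dim(x), 1L, 1L)), training = FALSE)$value
  matrix(as.integer(p[, , 1L, 1L] >= threshold), nrow(x), ncol(x))
}

#' @export
predict.ianseg_model <- function(object, newdata, threshold = 0.5, ...) {
  predict_mask(object, newdata, threshold)
}

#' Evaluate a trained model on one split partition
#'
#' @param model a trained `ianseg_model`.
#' @param cohort preprocessed cohort.
#' @param plan `split_plan`.
#' @param part partition name (default `"test"`).
#' @param threshold binarization cutoff.
#' @return output of [evaluate_predictions()].
#' @export
evaluate_split <- function(model, cohort, plan, part = "test", threshold = 0.5) {
  da <- partition_arrays(cohort, plan, part)
  n <- dim(da$x)[4]
  preds <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    preds[[i]] <- predict_mask(model, da$x[, , 1L, i], threshold)
    gts[[i]] <- matrix(as.integer(da$g[, , 1L, i]), dim(da$g)[1])
  }
  evaluate_predictions(preds, gts)
}
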