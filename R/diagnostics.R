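# Capacity sanity diagnostic: a small network must be able to memorize a
# handful of phantom slices. Used by the test suite and the acceptance
# script.

#' Overfit smoke experiment
#'
#' Trains a small-width network to memorize `n_slices` phantom slices
#' (64x64) with AdamW and the focal Tversky objective, and reports the
#' final training DSC. A healthy architecture reaches DSC >= 0.95 well
#' within the default step budget.
#'
#' @param seed integer seed for phantom generation and initialization.
#' @param steps number of optimization steps.
#' @param n_slices number of slices to memorize.
#' @param lr learning rate; the default is deliberately higher than the
#'   full training schedule's initial rate because the memorization budget
#'   is only a couple of hundred steps.
#' @return list with `dsc` (mean training DSC after the last step),
#'   `losses` (per-step loss trace), `model`.
#' @export
overfit_smoke <- function(seed = 7L, steps = 200L, n_slices = 4L, lr = 1e-2) {
  cfg <- phantom_config(n_patients = 1L, slices_per_nerve = n_slices,
                        image_height = 64L, image_width = 64L,
                        noise_sigma = 0.02, artifact_prob = 0,
                        seed = seed)
  cohort <- generate_cohort(cfg)
  series <- preprocess_series(cohort[[1]]$right,
                              preprocess_config(target_size = 64L))
  x <- array(unlist(series$slices), c(64L, 64L, 1L, n_slices)) / 255
  g <- array(unlist(series$masks), c(64L, 64L, 1L, n_slices))
  model <- build_model(net_config(preset = "small"), seed = seed)
  opt <- new_adamw()
  lcfg <- loss_config()
  losses <- numeric(steps)
  for (st in seq_len(steps)) {
    p <- forward(model, x, training = TRUE)
    loss <- focal_tversky_loss(p, g, lcfg)
    losses[st] <- loss$value
    ad_zero_grad(model$params)
    ad_backward(loss)
    adamw_step(model$params, opt, lr, weight_decay = 1e-4)
  }
  dsc <- batch_mean_dsc(model, x, g)
  list(dsc = dsc, losses = losses, model = model)
}
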