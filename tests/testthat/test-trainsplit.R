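pids <- function(n) sprintf("P%03d", seq_len(n))

test_that("patient-level split sizes follow the rounding rule", {
  pl <- make_split(pids(20), seed = 1L)
  expect_identical(unname(pl$sizes), c(14L, 3L, 3L))
  # 29-patient regime: round(0.15 * 29) = 4, train keeps the remainder
  pl29 <- make_split(pids(29), seed = 2L)
  expect_identical(unname(pl29$sizes), c(21L, 4L, 4L))
  expect_setequal(names(pl$assignment), pids(20))
  expect_identical(make_split(pids(20), seed = 9L),
                   make_split(pids(20), seed = 9L))
  expect_error(make_split(pids(2)), "at least 3")
  expect_error(make_split(pids(10), fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("Monte Carlo splits are valid partitions with derived seeds", {
  plans <- monte_carlo_splits(pids(20), n_repeats = 10L, base_seed = 100L)
  expect_length(plans, 10L)
  for (k in seq_along(plans)) {
    pl <- plans[[k]]
    expect_identical(pl$seed, 100L + k - 1L)
    expect_setequal(names(pl$assignment), pids(20))
    expect_identical(as.integer(table(factor(pl$assignment,
                                             c("train", "val", "test")))),
                     c(14L, 3L, 3L))
  }
  # repeats differ (random splitting, not k-fold)
  expect_false(identical(plans[[1]]$assignment, plans[[2]]$assignment))
  # test sets may jointly miss patients; no error, just a property of MC
  test_union <- unique(unlist(lapply(plans, function(p)
    names(p$assignment)[p$assignment == "test"])))
  expect_lte(length(test_union), 20L)
  single <- monte_carlo_splits(pids(10), n_repeats = 1L, base_seed = 5L)
  expect_identical(single[[1]]$assignment, make_split(pids(10), seed = 5L)$assignment)
})

test_that("both sides of a patient always land in one partition", {
  cohort <- generate_cohort(tiny_phantom_config(n_patients = 4L))
  plans <- monte_carlo_splits(vapply(cohort, `[[`, "", "patient_id"),
                              n_repeats = 3L, base_seed = 1L,
                              fractions = c(0.5, 0.25, 0.25))
  for (pl in plans) {
    for (part in c("train", "val", "test")) {
      da <- ianseg:::partition_arrays(cohort, pl, part)
      n_pat <- sum(pl$assignment == part)
      # 2 sides x slices_per_nerve slices per patient
      expect_identical(dim(da$x)[4], n_pat * 2L * 4L)
    }
  }
})

test_that("cosine annealing matches its closed form", {
  expect_equal(cosine_lr(0, 1e-3, 50), 1e-3)
  expect_equal(cosine_lr(50, 1e-3, 50), 0)
  expect_equal(cosine_lr(25, 1e-3, 50), 5e-4)
  e <- 0:50
  expect_equal(cosine_lr(e, 1e-3, 50), 1e-3 * (1 + cos(pi * e / 50)) / 2)
})

test_that("training runs, logs the cosine schedule, and early-stops correctly", {
  cohort <- generate_cohort(tiny_phantom_config(n_patients = 4L,
                                                slices_per_nerve = 2L))
  pre <- preprocess_cohort(cohort, preprocess_config(target_size = 32L))
  plan <- make_split(vapply(pre, `[[`, "", "patient_id"),
                     fractions = c(0.5, 0.25, 0.25), seed = 1L)
  tc <- train_config(epochs = 3L, batch_size = 4L, patience = 3L, seed = 2L)
  fit <- train_model(pre, plan, net_config(stage_channels = c(2L, 2L, 4L, 4L)),
                     loss_config(), tc)
  expect_identical(nrow(fit$log), 3L)
  expect_equal(fit$log$lr, cosine_lr(0:2, tc$lr0, 3L), tolerance = 1e-12)
  expect_true(all(is.finite(fit$log$train_loss)))
  # best-epoch val DSC is the max of the log
  expect_equal(fit$best_val_dsc, max(fit$log$val_dsc))
  expect_identical(fit$best_epoch, fit$log$epoch[which.max(fit$log$val_dsc)])
  # prediction contract
  x <- pre[[1]]$right$slices[[1]]
  m1 <- predict_mask(fit$model, x)
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_identical(m1, predict_mask(fit$model, x))
})

test_that("epoch-0 loss is reproducible across identical invocations", {
  cohort <- generate_cohort(tiny_phantom_config(n_patients = 3L,
                                                slices_per_nerve = 2L))
  pre <- preprocess_cohort(cohort, preprocess_config(target_size = 32L))
  plan <- make_split(vapply(pre, `[[`, "", "patient_id"),
                     fractions = c(0.34, 0.33, 0.33), seed = 3L)
  run <- function() {
    fit <- train_model(pre, plan, net_config(stage_channels = c(2L, 2L, 2L, 4L)),
                       loss_config(), train_config(epochs = 1L, batch_size = 4L,
                                                   patience = 1L, seed = 4L))
    fit$log$train_loss[1]
  }
  expect_identical(run(), run())
})

test_that("early stopping patience arithmetic", {
  # with a frozen monitored metric, training stops after 1 + patience epochs
  cohort <- generate_cohort(tiny_phantom_config(n_patients = 3L,
                                                slices_per_nerve = 2L))
  pre <- preprocess_cohort(cohort, preprocess_config(target_size = 32L))
  plan <- make_split(vapply(pre, `[[`, "", "patient_id"),
                     fractions = c(0.34, 0.33, 0.33), seed = 3L)
  # a threshold no probability reaches in few epochs keeps val DSC at 0
  tc <- train_config(epochs = 10L, batch_size = 8L, patience = 2L, seed = 5L,
                     lr0 = 1e-6)
  fit <- train_model(pre, plan, net_config(stage_channels = c(2L, 2L, 2L, 4L)),
                     loss_config(), tc)
  if (all(diff(fit$log$val_dsc) <= 0)) {
    expect_lte(nrow(fit$log), 1L + tc$patience)
  }
  expect_error(train_config(patience = 30L, epochs = 20L), "patience")
})
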