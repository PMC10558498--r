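grp_spec <- grouping_spec("grp", "grp")

test_that("zero epochs returns the initialised scorer and an empty history", {
  rec <- toy_records(40, seed = 2)
  fit <- train_scorer(rec, assign_groups(rec, grp_spec),
                      train_config("bce", epochs = 0, seed = 5))
  expect_equal(nrow(fit$history), 0L)
  expect_equal(fit$best_epoch, 0L)
  init <- linear_scorer(4, init_sd = 0.01, seed = 5)
  expect_equal(fit$scorer$params, init$params)
})

test_that("bce training separates a linearly separable cohort", {
  rec <- toy_records(300, d = 4, seed = 6)
  fit <- train_scorer(rec, assign_groups(rec, grp_spec),
                      train_config("bce", learning_rate = 0.05, epochs = 20,
                                   batch_size = 32, seed = 6))
  s <- predict_scores(fit, rec)
  expect_gt(overall_auc(s), 0.95)
  # the learned direction should align with the informative feature
  expect_gt(abs(fit$scorer$params$w[1]), max(abs(fit$scorer$params$w[-1])))
})

test_that("trained bce AUC approaches the Gaussian closed form pnorm(d/sqrt(2))", {
  d <- 1.5
  rec <- toy_records(2000, d = d, seed = 8)
  fit <- train_scorer(rec, NULL,
                      train_config("bce", learning_rate = 0.05, epochs = 15,
                                   batch_size = 64, seed = 8))
  test <- toy_records(2000, d = d, seed = 88)
  expect_equal(overall_auc(predict_scores(fit, test)), pnorm(d / sqrt(2)),
               tolerance = 0.03)
})

test_that("minority oversampling equalises class counts deterministically", {
  rec <- toy_records(100, prevalence = 0.1, seed = 10)
  n_min <- sum(rec$label)
  expect_true(n_min > 0 && n_min < 50)
  idx <- oversample_minority(rec, seed = 4)
  y <- rec$label[idx]
  expect_equal(sum(y == 1), sum(y == 0))           # 50% prevalence exactly
  expect_length(idx, 2 * (100 - n_min))            # e.g. 10/90 -> 90/90
  expect_equal(sort(unique(idx[seq_len(100)])), 1:100)  # originals all kept
  expect_identical(idx, oversample_minority(rec, seed = 4))
  expect_false(identical(idx, oversample_minority(rec, seed = 5)))

  balanced <- toy_records(40, prevalence = 0.5, seed = 30)
  balanced$label <- rep(c(0L, 1L), 20)
  expect_identical(oversample_minority(balanced, 1), 1:40)
  single <- balanced; single$label <- rep(1L, 40)
  expect_error(oversample_minority(single), class = "fairdx_spec_error")
})

test_that("prediction is order-preserving, finite and batch-free", {
  rec <- toy_records(30, seed = 12)
  fit <- train_scorer(rec, NULL, train_config("bce", epochs = 2, seed = 12))
  empty <- predict_scores(fit, rec[0, ])
  expect_length(empty$scores, 0)

  dup <- rec[c(1, 1, 5), ]
  sd_ <- predict_scores(fit, dup)
  expect_equal(sd_$scores[1], sd_$scores[2])

  full <- predict_scores(fit, rec)$scores
  onebyone <- vapply(seq_len(nrow(rec)), function(i)
    predict_scores(fit, rec[i, ])$scores, numeric(1))
  expect_equal(full, onebyone)
  expect_true(all(is.finite(full)))
})

test_that("identical config, data and seed reproduce the history exactly", {
  rec <- toy_records(120, seed = 14)
  a <- assign_groups(rec, grp_spec)
  for (mode in c("bce", "proposed", "oversample")) {
    cfg <- train_config(mode, epochs = 3, batch_size = 16,
                        learning_rate = 0.01, seed = 99)
    f1 <- train_scorer(rec, a, cfg)
    f2 <- train_scorer(rec, a, cfg)
    expect_identical(f1$history, f2$history)
    expect_identical(f1$scorer$params, f2$scorer$params)
  }
})

test_that("degenerate training inputs raise errors", {
  rec <- toy_records(40, seed = 16)
  rec$label <- rep(1L, 40)
  expect_error(train_scorer(rec, NULL, train_config("bce")),
               class = "fairdx_spec_error")
  rec2 <- toy_records(40, seed = 16)
  rec2$grp <- "A"
  expect_error(train_scorer(rec2, assign_groups(rec2, grp_spec),
                            train_config("proposed")),
               class = "fairdx_spec_error")
})

test_that("ineligible batches are skipped and counted in the history", {
  # 2 positives among 80 samples with batch 16: most batches lack a positive
  rec <- toy_records(80, prevalence = 0.5, seed = 18)
  rec$label <- c(rep(1L, 2), rep(0L, 78))
  a <- assign_groups(rec, grp_spec)
  cfg <- train_config("proposed", epochs = 2, batch_size = 16,
                      learning_rate = 0.01, seed = 18, dev_fraction = 0.1)
  fit <- train_scorer(rec, a, cfg)
  # toy_records gives one image per patient: dev carve-out is 8 of 80,
  # leaving 72 training samples = 5 batches of 16 per epoch
  n_batches <- ceiling(72 / 16)
  for (ep in fit$history$epoch) {
    n_sel <- sum(fit$selection_log$epoch == ep)
    expect_equal(n_sel + fit$history$n_skipped[fit$history$epoch == ep],
                 n_batches)
  }
  expect_gt(sum(fit$history$n_skipped), 0)
})

test_that("the selection log records the worst group per applied step", {
  rec <- toy_records(150, seed = 20)
  a <- assign_groups(rec, grp_spec)
  fit <- train_scorer(rec, a, train_config("proposed", epochs = 2,
                                           batch_size = 24, seed = 20,
                                           learning_rate = 0.01))
  expect_true(all(fit$selection_log$category %in% c("A", "B")))
  expect_true(all(fit$selection_log$batch_pf >= 0 &
                  fit$selection_log$batch_pf <= 1))
})

test_that("model selection returns the epoch with the best dev AUC", {
  rec <- toy_records(200, d = 2, seed = 22)
  fit <- train_scorer(rec, NULL, train_config("bce", epochs = 6,
                                              learning_rate = 0.02,
                                              batch_size = 32, seed = 22))
  expect_equal(fit$best_epoch, which.max(fit$history$dev_auc))
})
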