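ns <- asNamespace("sirnadesign")

test_that("metrics match hand cases", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$prc, 1)
  m2 <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(m2$auc, 0)
  m3 <- compute_metrics(c(0.6, 0.4, 0.6, 0.4), c(1, 0, 0, 1))
  expect_equal(m3$auc, 0.5)
  # single-class labels: threshold metrics undefined, PCC still computed
  m4 <- compute_metrics(c(0.2, 0.6, 0.9), c(1, 1, 1),
                        efficacies = c(0.1, 0.5, 0.8))
  expect_true(is.na(m4$auc) && is.na(m4$f1) && is.na(m4$prc))
  expect_gt(m4$pcc, 0.99)
})

test_that("AUC equals the exhaustive concordant-pair oracle for n <= 12", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 3), 1))  # coarse rounding forces ties
    expect_equal(compute_metrics(scores, labels)$auc,
                 auc_oracle(scores, labels))
  }
})

test_that("AUC agrees with an independent package implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  expect_equal(compute_metrics(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("complement symmetry: AUC(y) + AUC(1-y) = 1 for tie-free scores", {
  set.seed(3)
  for (i in 1:20) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(compute_metrics(scores, labels)$auc +
                   compute_metrics(scores, 1 - labels)$auc, 1)
  }
})

test_that("training is deterministic given the seed", {
  ds <- fixture("ds_small", toy_dataset(60, seed = 21))
  cfg <- tiny_config()
  f1 <- sirna_fit(ds, cfg, epochs = 2, seed = 11, batch_size = 32,
                  engine = naive_fold_engine())
  f2 <- sirna_fit(ds, cfg, epochs = 2, seed = 11, batch_size = 32,
                  engine = naive_fold_engine())
  expect_equal(ns$flatten_params(f1$params), ns$flatten_params(f2$params),
               ignore_attr = TRUE)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("smoothed training loss decreases on plantable signal", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))
  fit <- fixture("fit_train",
                 sirna_fit(ds, tiny_config(), epochs = 5, seed = 2,
                           batch_size = 50, engine = naive_fold_engine()))
  h <- fit$history$train_loss
  expect_lt(mean(utils::tail(h, 2)), mean(utils::head(h, 2)))
  expect_gt(fit$metrics$auc, 0.6)
})

test_that("shuffled labels are not learnable (negative control)", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))
  shuf <- ds
  set.seed(4)
  perm <- sample(nrow(ds))
  shuf$norm_efficacy <- ds$norm_efficacy[perm]
  shuf$label <- ds$label[perm]
  fit <- sirna_fit(shuf, tiny_config(), epochs = 3, seed = 2, batch_size = 50,
                   engine = naive_fold_engine())
  expect_gt(fit$metrics$auc, 0.25)
  expect_lt(fit$metrics$auc, 0.75)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  ds <- fixture("ds_small", toy_dataset(60, seed = 21))
  bad <- ds
  bad$norm_efficacy[1] <- NaN
  expect_error(sirna_fit(bad, tiny_config(), epochs = 1, seed = 1,
                         batch_size = 60, val_idx = 2:6,
                         engine = naive_fold_engine()),
               "diverged")
  expect_error(sirna_fit(ds[ds$label == 1, ][1:5, ], tiny_config()),
               "each label")
})

test_that("cross-validation scores each record exactly once", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))[1:100, ]
  cv <- cross_validate(ds, k = 4, seed = 9, config = tiny_config(),
                       engine = naive_fold_engine(), epochs = 2,
                       batch_size = 50)
  expect_equal(nrow(cv$fold_metrics), 4L)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_length(cv$mean, 4)
  expect_true(all(is.finite(cv$stderr[c("auc")])))
})

test_that("leave-one-out is a valid degenerate split", {
  ds <- fixture("ds_small", toy_dataset(60, seed = 21))[1:10, ]
  # k = n: every fold is a single record; metrics per fold are degenerate but
  # the driver must run and aggregate
  cv <- suppressWarnings(cross_validate(ds, k = 10, seed = 1,
                                        config = tiny_config(),
                                        engine = naive_fold_engine(),
                                        epochs = 1, batch_size = 9))
  expect_equal(nrow(cv$fold_metrics), 10L)
})

test_that("inter-dataset evaluation blocks unremoved overlap", {
  ds <- fixture("ds_small", toy_dataset(60, seed = 21))
  expect_error(inter_dataset(ds, ds, tiny_config()),
               "no training records remain")
})

test_that("inter-dataset transfer beats chance on shared generator", {
  tx <- gen_transcripts(10, 300, seed = 41)
  tr <- gen_efficacy_dataset(220, tx, seed = 42)
  te <- gen_efficacy_dataset(80, tx, seed = 43)
  res <- inter_dataset(tr, te, tiny_config(), epochs = 8, batch_size = 64,
                       engine = naive_fold_engine())
  expect_gt(res$metrics$auc, 0.6)
  expect_equal(res$metrics$n, 80L)
})

test_that("the ablation grid enumerates exactly the 15 non-empty subsets", {
  g <- ablation_grid()
  expect_equal(nrow(g), 15L)
  expect_equal(anyDuplicated(g$name), 0L)
  expect_true(all(rowSums(g[, 1:4]) > 0))
  expect_error(ablation_run(data.frame(), grid = rbind(g, g[1, ])),
               "duplicate")
})

test_that("the ablation driver trains every subset under one split", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))
  res <- fixture("ablation_res",
                 ablation_run(ds, seed = 5, config = tiny_config(),
                              engine = naive_fold_engine(), epochs = 2,
                              batch_size = 50))
  expect_equal(nrow(res), 15L)
  expect_true(all(is.finite(res$auc)))
  expect_true(all(res$epochs_to_converge >= 1 & res$epochs_to_converge <= res$epochs_run))
  # the thermodynamic channel carries the planted asymmetry signal: the
  # all-features row must beat the rows lacking it substantially less often
  # than chance would allow; check it at least beats the empty-signal row set
  expect_gte(res$auc[res$name == "si+m+emb+td"],
             max(res$auc[!res$use_thermo]) - 0.15)
})

test_that("residuals and fitted values are consistent", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))
  fit <- fixture("fit_train",
                 sirna_fit(ds, tiny_config(), epochs = 5, seed = 2,
                           batch_size = 50, engine = naive_fold_engine()))
  expect_equal(residuals(fit), ds$norm_efficacy - fitted(fit))
  expect_output(print(fit), "validation: AUC")
  expect_output(print(summary(fit)), "Parameters per component")
  sim <- simulate(fit, nsim = 3, seed = 42)
  expect_equal(dim(sim), c(nrow(ds), 3L))
  expect_true(all(sim >= 0 & sim <= 1))
  expect_identical(sim, simulate(fit, nsim = 3, seed = 42))
})
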