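# Evaluation metrics and the cross-validation / ablation drivers.

auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

average_precision <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos) || all(pos)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  hit <- pos[ord]
  prec_at <- cumsum(hit) / seq_along(hit)
  sum(prec_at[hit]) / sum(hit)
}

#' Classification and regression metrics for efficacy scores
#'
#' AUC by the rank statistic (ties share concordance 1/2), PRC as the
#' interpolated area under the precision-recall curve (average precision),
#' F1 at `class_threshold` on the scores, and the Pearson correlation between
#' scores and continuous efficacies. With a single-class label vector the
#' threshold metrics are reported `NA` while PCC is still computed.
#'
#' @param scores Predicted scores in \[0, 1\].
#' @param labels Binary labels (0/1).
#' @param efficacies Continuous normalized efficacies (for PCC); defaults to
#'   `labels`.
#' @param class_threshold Score threshold for the F1 point metric.
#' @return List with `auc`, `prc`, `f1`, `pcc`, `n`, `threshold_used`.
#' @export
compute_metrics <- function(scores, labels, efficacies = NULL,
                            class_threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  eff <- efficacies %||% labels
  pred <- as.integer(scores >= class_threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) NA_real_
        else if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  sds <- stats::sd(scores); sde <- stats::sd(eff)
  pcc <- if (length(scores) < 2L || !is.finite(sds) || !is.finite(sde) ||
             sds < 1e-12 || sde < 1e-12) NA_real_
         else stats::cor(scores, eff)
  list(auc = auc_rank(scores, labels),
       prc = average_precision(scores, labels),
       f1 = f1, pcc = pcc, n = length(scores),
       threshold_used = class_threshold)
}

#' Stratified k-fold cross-validation
#'
#' Each record is scored exactly once by a model that never saw it; the
#' held-out fold also serves as the early-stopping validation split. The
#' summary reports the mean and standard error across folds.
#'
#' @param dataset A `sirna_dataset`.
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and every fit.
#' @param config A [sirna_config()].
#' @param engine,embedding_source,cache_dir Feature-encoding options (see
#'   [sirna_fit()]).
#' @param ... Passed to the training loop (`epochs`, `lr`, `batch_size`,
#'   `patience`, `verbose`).
#' @return List with `fold_metrics` (data frame, one row per fold), `mean`,
#'   `stderr`, `scores` (out-of-fold score per record), `folds`.
#' @export
cross_validate <- function(dataset, k = 5L, seed = 1L, config = sirna_config(),
                           engine = fold_engine(), embedding_source = "fallback",
                           cache_dir = NULL, ...) {
  folds <- make_folds(dataset$label, k, seed)
  enc <- encode_dataset(dataset, config, engine, embedding_source, cache_dir)
  scores <- numeric(enc$n)
  rows <- list()
  for (f in sort(unique(folds))) {
    val_idx <- which(folds == f)
    old <- local_seed(seed + f)
    res <- fit_encoded(enc, config, which(folds != f), val_idx, ...)
    restore_seed(old)
    s <- score_encoded(res$params, config, enc, res$scaling, val_idx)
    scores[val_idx] <- s
    m <- compute_metrics(s, enc$label[val_idx], enc$y[val_idx])
    rows[[f]] <- data.frame(fold = f, auc = m$auc, prc = m$prc, f1 = m$f1,
                            pcc = m$pcc, n = m$n)
  }
  fm <- do.call(rbind, rows)
  cols <- c("auc", "prc", "f1", "pcc")
  list(fold_metrics = fm,
       mean = colMeans(fm[cols], na.rm = TRUE),
       stderr = vapply(fm[cols], function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
                       numeric(1)),
       scores = scores, folds = folds)
}

#' Train on one dataset, evaluate on another
#'
#' Redundancy between the sets is removed first: training records with more
#' than `identity_cutoff` percent Needleman-Wunsch identity to any test
#' record are dropped (logged on the result). Any surviving exact overlap is
#' an error.
#'
#' @param train_ds,test_ds `sirna_dataset`s.
#' @param config A [sirna_config()].
#' @param identity_cutoff Percent identity for [deduplicate()].
#' @param seed Seed for the single fit.
#' @param ... Passed to [sirna_fit()].
#' @return List with `metrics` on the test set, `fit`, `removals`.
#' @export
inter_dataset <- function(train_ds, test_ds, config = sirna_config(),
                          identity_cutoff = 80, seed = 1L, ...) {
  ded <- deduplicate(train_ds, test_ds, identity_cutoff)
  removals <- attr(ded, "removals")
  if (nrow(ded) == 0L)
    stop("inter_dataset: no training records remain after deduplication")
  if (any(ded$antisense_seq %in% test_ds$antisense_seq))
    stop("inter_dataset: train/test overlap survived deduplication")
  fit <- sirna_fit(ded, config, seed = seed, ...)
  scores <- predict(fit, test_ds)
  list(metrics = compute_metrics(scores, test_ds$label, test_ds$norm_efficacy),
       fit = fit, removals = removals, scores = scores)
}

#' All non-empty feature-group combinations
#'
#' The four feature groups (siRNA sequence encoder, mRNA sequence encoder,
#' pretrained embeddings, thermodynamic parameters) yield exactly 15
#' non-empty subsets.
#'
#' @return Data frame with logical columns `use_sirna`, `use_mrna`,
#'   `use_pretrained`, `use_thermo` and a `name` column.
#' @export
ablation_grid <- function() {
  g <- expand.grid(use_sirna = c(FALSE, TRUE), use_mrna = c(FALSE, TRUE),
                   use_pretrained = c(FALSE, TRUE), use_thermo = c(FALSE, TRUE))
  g <- g[rowSums(g) > 0L, , drop = FALSE]
  tags <- c("si", "m", "emb", "td")
  g$name <- apply(g[, 1:4], 1L, function(r) paste(tags[as.logical(r)], collapse = "+"))
  if (anyDuplicated(g$name)) stop("duplicate feature subsets in ablation grid")
  rownames(g) <- NULL
  g
}

#' Feature-set ablation driver
#'
#' Trains one model per feature-group subset under identical seed and
#' train/validation split, and records validation metrics plus convergence
#' speed (first epoch reaching 95% of the final validation AUC).
#'
#' @param dataset A `sirna_dataset`.
#' @param grid Subset table from [ablation_grid()].
#' @param seed Shared seed for the split and every fit.
#' @param config Base [sirna_config()]; its feature switches are overridden
#'   row by row.
#' @param val_frac Validation fraction (stratified, shared across rows).
#' @param engine,embedding_source,cache_dir Feature-encoding options.
#' @param ... Passed to the training loop (`epochs`, `lr`, ...).
#' @return Data frame: one row per subset with `auc`, `prc`, `f1`, `pcc`,
#'   `epochs_to_converge`, `epochs_run`.
#' @export
ablation_run <- function(dataset, grid = ablation_grid(), seed = 1L,
                         config = sirna_config(), val_frac = 0.15,
                         engine = fold_engine(), embedding_source = "fallback",
                         cache_dir = NULL, ...) {
  if (anyDuplicated(grid$name)) stop("duplicate feature subsets in grid")
  enc <- encode_dataset(dataset, config, engine, embedding_source, cache_dir)
  old <- local_seed(seed)
  val_idx <- unlist(lapply(split(seq_len(enc$n), dataset$label), function(ix)
    ix[sample.int(length(ix), max(1L, round(val_frac * length(ix))))]))
  restore_seed(old)
  train_idx <- setdiff(seq_len(enc$n), val_idx)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg[c("use_sirna", "use_mrna", "use_pretrained", "use_thermo")] <-
      as.list(unlist(grid[i, 1:4]))
    validate_config(cfg)
    old <- local_seed(seed)
    res <- fit_encoded(enc, cfg, train_idx, val_idx, ...)
    restore_seed(old)
    s <- score_encoded(res$params, cfg, enc, res$scaling, val_idx)
    m <- compute_metrics(s, enc$label[val_idx], enc$y[val_idx])
    h <- res$history
    final_auc <- h$val_auc[nrow(h)]
    conv <- which(h$val_auc >= 0.95 * final_auc)[1]
    rows[[i]] <- data.frame(name = grid$name[i], grid[i, 1:4],
                            auc = m$auc, prc = m$prc, f1 = m$f1, pcc = m$pcc,
                            epochs_to_converge = conv, epochs_run = nrow(h))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
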