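# Training: Adam on mean-squared error between the sigmoid score and
# normalized efficacy (binary metrics are computed post hoc at a score
# threshold), early stopping on validation loss.

adam_init <- function(p) {
  if (is.matrix(p)) return(list(m = p * 0, v = p * 0))
  lapply(p, adam_init)
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.matrix(p)) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    return(list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st))
  }
  newp <- p; newst <- st
  for (i in seq_along(p)) {
    r <- adam_step(p[[i]], g[[i]], st[[i]], lr, t, beta1, beta2, eps)
    newp[[i]] <- r$p; newst[[i]] <- r$st
  }
  list(p = newp, st = newst)
}

grads_finite <- function(g) {
  if (is.matrix(g)) return(all(is.finite(g)))
  all(vapply(g, grads_finite, logical(1)))
}

grad_sqnorm <- function(g) {
  if (is.matrix(g)) return(sum(g * g))
  sum(vapply(g, grad_sqnorm, numeric(1)))
}

grad_scale <- function(g, k) {
  if (is.matrix(g)) return(g * k)
  lapply(g, grad_scale, k = k)
}

# Forward-only scoring of encoded records.
score_encoded <- function(params, cfg, enc, scaling, idx, batch_size = 256L) {
  out <- numeric(length(idx))
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    b <- slice_batch(enc, cfg, take, scaling)
    fwd <- model_forward(wrap_params(params), cfg, b, length(take))
    out[pos:(pos + length(take) - 1L)] <- as.vector(fwd$score$v)
    pos <- pos + length(take)
  }
  out
}

fit_encoded <- function(enc, cfg, train_idx, val_idx, epochs = 15L, lr = 1e-3,
                        batch_size = 64L, patience = 10L, clip_norm = 5,
                        verbose = FALSE) {
  scaling <- list()
  if (cfg$use_thermo) scaling$thermo <- scale_fit(enc$thermo[train_idx, , drop = FALSE])
  if (cfg$use_pretrained) scaling$pre <- scale_fit(enc$pre[train_idx, , drop = FALSE])
  params <- init_params(cfg)
  st <- adam_init(params)
  step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- list()
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- train_idx[sample.int(length(train_idx))]
    losses <- c()
    pos <- 1L
    while (pos <= length(ord)) {
      take <- ord[pos:min(pos + batch_size - 1L, length(ord))]
      pos <- pos + length(take)
      b <- slice_batch(enc, cfg, take, scaling)
      pn <- wrap_params(params)
      fwd <- model_forward(pn, cfg, b, length(take), train = TRUE)
      loss <- if (cfg$loss == "bce") ad_bce(fwd$score, b$y)
              else ad_mean_sq_err(fwd$score, b$y)
      if (!is.finite(loss$v[1]))
        stop("training diverged: non-finite loss at epoch ", ep,
             " (lr = ", lr, "); lower the learning rate")
      ad_backward(loss)
      g <- param_grads(pn)
      if (!grads_finite(g))
        stop("training diverged: non-finite gradients at epoch ", ep)
      gn <- sqrt(grad_sqnorm(g))
      if (is.finite(clip_norm) && gn > clip_norm) g <- grad_scale(g, clip_norm / gn)
      step <- step + 1L
      r <- adam_step(params, g, st, lr, step)
      params <- r$p; st <- r$st
      losses <- c(losses, loss$v[1])
    }
    vs <- score_encoded(params, cfg, enc, scaling, val_idx)
    vy <- enc$y[val_idx]
    val_loss <- mean((vs - vy)^2)
    vm <- compute_metrics(vs, enc$label[val_idx], vy)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_loss = val_loss, val_auc = vm$auc,
                             val_pcc = vm$pcc)
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f  auc %s", ep,
                      mean(losses), val_loss, format(vm$auc, digits = 3)))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best$params, scaling = scaling, history = do.call(rbind, hist),
       best_epoch = best$epoch)
}

#' Fit the siRNA efficacy model
#'
#' Trains the dual-encoder fusion network on a harmonized dataset by Adam on
#' mean squared error between the sigmoid score and normalized efficacy
#' (binary-cross-entropy available via the configuration), with early
#' stopping on validation loss. Deterministic given `seed` (and a
#' single-threaded BLAS).
#'
#' @param dataset A `sirna_dataset` (see [harmonize_dataset()] or
#'   [gen_efficacy_dataset()]) with columns `antisense_seq`, `window_seq`,
#'   `norm_efficacy`, `label`.
#' @param config A [sirna_config()].
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed covering initialization and shuffling.
#' @param val_frac Fraction held out (stratified) for early stopping when
#'   `val_idx` is not given.
#' @param val_idx Optional explicit validation row indices.
#' @param patience Early-stopping patience in epochs.
#' @param engine Folding engine for thermodynamic features.
#' @param embedding_source `"fallback"` or `"pretrained"` for the pooled
#'   embedding channel.
#' @param cache_dir Pretrained embedding cache directory.
#' @param encoded Pre-computed [encode_dataset()] output (skips encoding).
#' @param verbose Print per-epoch progress.
#' @return An object of class `sirna_fit` with components `params`, `config`,
#'   `scaling`, `history`, `metrics` (validation), `fitted` (scores on all
#'   rows), and the training call.
#' @seealso [predict.sirna_fit()], [cross_validate()], [saliency()]
#' @export
sirna_fit <- function(dataset, config = sirna_config(), epochs = 15L,
                      lr = 1e-3, batch_size = 64L, seed = 1L,
                      val_frac = 0.1, val_idx = NULL, patience = 10L,
                      engine = fold_engine(), embedding_source = "fallback",
                      cache_dir = NULL, encoded = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(dataset))
  if (sum(dataset$label == 1) < 2L || sum(dataset$label == 0) < 2L)
    stop("need at least 2 records of each label to train")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  enc <- encoded %||% encode_dataset(dataset, config, engine,
                                     embedding_source, cache_dir)
  n <- enc$n
  if (is.null(val_idx)) {
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), dataset$label), function(ix)
      ix[sample.int(length(ix), max(1L, round(val_frac * length(ix))))]))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  res <- fit_encoded(enc, config, train_idx, val_idx, epochs, lr, batch_size,
                     patience, verbose = verbose)
  fitted_all <- score_encoded(res$params, config, enc, res$scaling, seq_len(n))
  vm <- compute_metrics(fitted_all[val_idx], enc$label[val_idx], enc$y[val_idx])
  structure(list(params = res$params, config = config, scaling = res$scaling,
                 history = res$history, best_epoch = res$best_epoch,
                 metrics = vm, fitted = fitted_all, y = enc$y,
                 label = enc$label, val_idx = val_idx,
                 embedding_source = embedding_source, cache_dir = cache_dir,
                 seed = seed, call = match.call()),
            class = "sirna_fit")
}

#' Predict efficacy scores for new siRNA records
#'
#' @param object A `sirna_fit`.
#' @param newdata A `sirna_dataset`-like data frame with `antisense_seq` and
#'   `window_seq` columns (efficacy columns are not required).
#' @param engine Folding engine for thermodynamic features.
#' @param encoded Optional pre-computed [encode_dataset()] output.
#' @param batch_size Scoring batch size.
#' @param ... Unused.
#' @return Numeric vector of predicted normalized efficacies in \[0, 1\].
#' @export
predict.sirna_fit <- function(object, newdata = NULL, engine = fold_engine(),
                              encoded = NULL, batch_size = 256L, ...) {
  if (is.null(encoded)) {
    stopifnot(!is.null(newdata))
    if (is.null(newdata$norm_efficacy)) newdata$norm_efficacy <- 0
    if (is.null(newdata$label)) newdata$label <- 0L
    encoded <- encode_dataset(newdata, object$config, engine,
                              object$embedding_source, object$cache_dir)
  }
  score_encoded(object$params, object$config, encoded, object$scaling,
                seq_len(encoded$n), batch_size)
}

#' @export
fitted.sirna_fit <- function(object, ...) object$fitted

#' @export
residuals.sirna_fit <- function(object, ...) object$y - object$fitted

#' @export
coef.sirna_fit <- function(object, ...) flatten_params(object$params)

#' Simulate efficacy responses from a fitted model
#'
#' Draws are the fitted scores plus Gaussian noise at the residual standard
#' deviation, clipped to \[0, 1\] — the same observation model the synthetic
#' generator uses.
#'
#' @param object A `sirna_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.sirna_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  mu <- fitted(object)
  sigma <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, pmin(pmax(
    mu + stats::rnorm(length(mu), 0, sigma), 0), 1)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.sirna_fit <- function(x, ...) {
  cfg <- x$config
  groups <- c("siRNA-encoder", "mRNA-encoder", "pretrained", "thermo")[
    unlist(cfg[c("use_sirna", "use_mrna", "use_pretrained", "use_thermo")])]
  cat("siRNA efficacy model (dual-encoder fusion)\n")
  cat("  feature groups:", paste(groups, collapse = " + "), "\n")
  cat("  hidden", cfg$lstm_hidden, "/ transformer d_model", 2L * cfg$lstm_hidden,
      "x", cfg$transformer_layers, "layers /", sum(lengths(coef(x))),
      "parameters\n")
  cat("  trained", nrow(x$history), "epochs (best", x$best_epoch, ") seed",
      x$seed, "\n")
  m <- x$metrics
  cat(sprintf("  validation: AUC %.3f  PRC %.3f  F1 %.3f  PCC %.3f  (n = %d)\n",
              m$auc, m$prc, m$f1, m$pcc, m$n))
  invisible(x)
}

#' @export
summary.sirna_fit <- function(object, ...) {
  structure(list(fit = object, card = model_card(object)),
            class = "summary.sirna_fit")
}

#' @export
print.summary.sirna_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters per component:\n")
  print(x$card, row.names = FALSE)
  invisible(x)
}

#' Per-component parameter counts
#' @param fit A `sirna_fit` or parameter list.
#' @return Data frame with columns `component`, `n_params`.
#' @export
model_card <- function(fit) {
  p <- if (inherits(fit, "sirna_fit")) fit$params else fit
  data.frame(component = names(p),
             n_params = vapply(p, function(x) sum(lengths(flatten_params(list(x = x)))),
                               numeric(1)))
}

#' Training-history / diagnostic plots
#'
#' `type = "history"` draws training and validation loss with validation AUC;
#' `type = "saliency"` draws the dataset-mean saliency heatmap (requires
#' `dataset`).
#'
#' @param x A `sirna_fit`.
#' @param type Plot type.
#' @param dataset Dataset for the saliency map.
#' @param ... Passed to the underlying plot functions.
#' @export
plot.sirna_fit <- function(x, type = c("history", "saliency"),
                           dataset = NULL, ...) {
  type <- match.arg(type)
  if (type == "history") {
    h <- x$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                      pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "MSE loss",
                      main = "training history", ...)
    graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                     col = 1:2, bty = "n")
  } else {
    stopifnot(!is.null(dataset))
    plot_saliency(saliency_map(x, dataset), ...)
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' Single-file checkpoint carrying weights, configuration, feature scaling
#' and a schema version; a reloaded model reproduces scores bitwise.
#'
#' @param fit A `sirna_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_model()` returns the `sirna_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "sirna_fit"))
  obj <- unclass(fit)
  obj$schema_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported checkpoint schema in ", path)
  obj$schema_version <- NULL
  structure(obj, class = "sirna_fit")
}
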