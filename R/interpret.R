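# Gradient-based interpretation: saliency maps over guide positions and
# class-conditional base-preference maps.

#' Gradient saliency map over siRNA positions
#'
#' Absolute gradient of the predicted efficacy score with respect to the
#' one-hot siRNA input channel, per position and base, with every other
#' input held fixed. `saliency()` maps a single record; `saliency_map()`
#' averages element-wise over a dataset.
#'
#' @param fit A `sirna_fit` whose configuration has the siRNA one-hot
#'   channel enabled (`use_sirna`).
#' @param record One-row data frame (or list) with `antisense_seq` and
#'   `window_seq`.
#' @param engine Folding engine for thermodynamic features.
#' @return 19 x 4 non-negative matrix (rows = guide positions 1-19, columns
#'   A, C, G, U).
#' @export
saliency <- function(fit, record, engine = fold_engine()) {
  saliency_map(fit, as.data.frame(record, stringsAsFactors = FALSE), engine)
}

#' @rdname saliency
#' @param dataset A `sirna_dataset`.
#' @param batch_size Records per backward pass.
#' @export
saliency_map <- function(fit, dataset, engine = fold_engine(),
                         batch_size = 128L) {
  cfg <- fit$config
  if (!cfg$use_sirna)
    stop("capability error: model was built without the one-hot siRNA channel")
  if (is.null(dataset$norm_efficacy)) dataset$norm_efficacy <- 0
  if (is.null(dataset$label)) dataset$label <- 0L
  enc <- encode_dataset(dataset, cfg, engine, fit$embedding_source, fit$cache_dir)
  L <- cfg$sirna_len
  acc <- matrix(0, L, 4L)
  n <- enc$n
  pos <- 1L
  while (pos <= n) {
    take <- pos:min(pos + batch_size - 1L, n)
    b <- slice_batch(enc, cfg, take, fit$scaling)
    fwd <- model_forward(wrap_params(fit$params), cfg, b, length(take))
    # summing scores gives each record's own gradient (no cross-terms)
    ad_backward(ad_sum_all(fwd$score))
    g <- abs(fwd$inputs$sirna$g)
    for (i in seq_along(take))
      acc <- acc + g[((i - 1L) * L + 1L):(i * L), 1:4, drop = FALSE]
    pos <- pos + length(take)
  }
  out <- acc / n
  dimnames(out) <- list(position = seq_len(L), base = RNA_BASES)
  out
}

#' Per-position base enrichment in positives versus negatives
#'
#' `freq(base, position | positive) - freq(base, position | negative)`;
#' each position's four enrichments sum to zero.
#'
#' @param dataset A `sirna_dataset` with both classes present.
#' @return 19 x 4 matrix (positions x bases).
#' @export
base_preference <- function(dataset) {
  lab <- dataset$label
  if (length(unique(lab)) < 2L)
    stop("base_preference: both classes must be present")
  L <- nchar(dataset$antisense_seq[1])
  freq <- function(seqs) {
    ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L, byrow = TRUE)
    t(vapply(seq_len(L), function(t)
      vapply(RNA_BASES, function(b) mean(ch[, t] == b), numeric(1)),
      numeric(4)))
  }
  out <- freq(dataset$antisense_seq[lab == 1]) -
    freq(dataset$antisense_seq[lab == 0])
  dimnames(out) <- list(position = seq_len(L), base = RNA_BASES)
  out
}

#' Write a position-by-base map to TSV (and optionally an image)
#'
#' The numeric TSV twin is always written; set `image = TRUE` for a PNG
#' heatmap beside it.
#'
#' @param map Matrix from [saliency_map()] or [base_preference()].
#' @param path Output TSV path.
#' @param image Also write `<path>.png`.
#' @return `path`, invisibly.
#' @export
render_maps <- function(map, path, image = FALSE) {
  if (is.null(map) || length(map) == 0L) stop("render_maps: empty map")
  df <- data.frame(position = seq_len(nrow(map)), map, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (image) {
    grDevices::png(paste0(path, ".png"), width = 640, height = 360)
    plot_saliency(map)
    grDevices::dev.off()
  }
  invisible(path)
}

#' @rdname render_maps
#' @param main Plot title.
#' @export
plot_saliency <- function(map, main = "saliency") {
  graphics::image(x = seq_len(nrow(map)), y = seq_len(ncol(map)), z = map,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "guide position (5' -> 3')", ylab = "", axes = FALSE,
                  main = main)
  graphics::axis(1, at = seq_len(nrow(map)))
  graphics::axis(2, at = seq_len(ncol(map)), labels = colnames(map), las = 1)
  invisible(map)
}

#' Read a map written by [render_maps()] back into a matrix
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(position = df$position, base = colnames(m))
  m
}
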