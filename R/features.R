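# Dataset -> model input tensors.
#
# All records are encoded once up front; batches are row-slices. The
# pretrained channel enters fusion as the position-mean of each record's
# L x D embedding matrix (siRNA and mRNA concatenated), computed from a
# position-by-base lookup so the fallback source never materializes one
# matrix per record.

onehot_block <- function(seqs, L, D = 5L) {
  stopifnot(D == 5L)
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  idx <- match(ch, RNA_ALPHABET)
  if (anyNA(idx)) stop("onehot_block: character outside {A,C,G,U,X}")
  n <- length(seqs)
  m <- matrix(0, n * L, D)
  # row (i-1)*L + t for record i, position t; ch unrolls column-major
  rows <- rep(seq_len(n) - 1L, times = L) * L + rep(seq_len(L), each = n)
  m[cbind(rows, as.vector(idx))] <- 1
  m
}

# Position-mean of the deterministic fallback embedding for many sequences.
pooled_fallback <- function(seqs, L, D) {
  lookup <- matrix(0, 5L * L, D)  # rows keyed (position, base incl X=zero)
  for (t in seq_len(L))
    for (b in seq_len(4L))
      lookup[(t - 1L) * 5L + b, ] <- fallback_row(b, t, D)
  ch <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), RNA_ALPHABET),
               ncol = L, byrow = TRUE)
  out <- matrix(0, length(seqs), D)
  for (t in seq_len(L))
    out <- out + lookup[(t - 1L) * 5L + ch[, t], , drop = FALSE]
  out / L
}

pooled_embedding <- function(seqs, ids, L, source, D, cache_dir = NULL) {
  if (source == "fallback") return(pooled_fallback(seqs, L, D))
  t(vapply(seq_along(seqs), function(i) {
    emb <- embed_sequence(seqs[i], source = source, D = D, seq_id = ids[i],
                          cache_dir = cache_dir)
    colMeans(emb$values)
  }, numeric(D)))
}

#' Encode a dataset into model input matrices
#'
#' @param dataset A `sirna_dataset` (columns `antisense_seq`, `window_seq`,
#'   `norm_efficacy`, `label`).
#' @param cfg A [sirna_config()].
#' @param engine Folding engine for the thermodynamic features.
#' @param embedding_source Source for the pretrained channel (`"fallback"` or
#'   `"pretrained"`).
#' @param cache_dir Cache directory for pretrained matrices.
#' @return List of plain matrices: `sirna_oh` (n*19 x seq_dim), `mrna_oh`
#'   (n*57 x seq_dim), `pre` (n x 2*pretrained_dim), `thermo` (n x 26),
#'   plus `y`, `label`, `n`.
#' @export
encode_dataset <- function(dataset, cfg = sirna_config(),
                           engine = fold_engine(),
                           embedding_source = "fallback",
                           cache_dir = NULL) {
  n <- nrow(dataset)
  out <- list(n = n, y = dataset$norm_efficacy, label = dataset$label)
  if (cfg$use_sirna)
    out$sirna_oh <- onehot_block(dataset$antisense_seq, cfg$sirna_len, cfg$seq_dim)
  if (cfg$use_mrna)
    out$mrna_oh <- onehot_block(dataset$window_seq, cfg$mrna_len, cfg$seq_dim)
  if (cfg$use_pretrained) {
    ids <- if (!is.null(dataset$transcript_id))
      paste0(dataset$transcript_id, "_", seq_len(n)) else as.character(seq_len(n))
    out$pre <- cbind(
      pooled_embedding(dataset$antisense_seq, paste0("si_", ids), cfg$sirna_len,
                       embedding_source, cfg$pretrained_dim, cache_dir),
      pooled_embedding(dataset$window_seq, paste0("m_", ids), cfg$mrna_len,
                       embedding_source, cfg$pretrained_dim, cache_dir))
  }
  if (cfg$use_thermo)
    out$thermo <- thermo_matrix(dataset, engine = engine)
  out
}

# Row indices into a (n*L x D) block for record set `samples`.
block_rows <- function(samples, L) {
  rep((samples - 1L) * L, each = L) + seq_len(L)
}

# Slice encoded inputs for a batch of record indices, applying stored
# feature scaling.
slice_batch <- function(enc, cfg, samples, scaling = NULL) {
  b <- list()
  if (cfg$use_sirna)
    b$sirna_oh <- enc$sirna_oh[block_rows(samples, cfg$sirna_len), , drop = FALSE]
  if (cfg$use_mrna)
    b$mrna_oh <- enc$mrna_oh[block_rows(samples, cfg$mrna_len), , drop = FALSE]
  if (cfg$use_pretrained) {
    b$pre <- enc$pre[samples, , drop = FALSE]
    if (!is.null(scaling)) b$pre <- scale_apply(b$pre, scaling$pre)
  }
  if (cfg$use_thermo) {
    b$thermo <- enc$thermo[samples, , drop = FALSE]
    if (!is.null(scaling)) b$thermo <- scale_apply(b$thermo, scaling$thermo)
  }
  b$y <- enc$y[samples]
  b
}

scale_fit <- function(m) {
  mu <- colMeans(m)
  sd_ <- apply(m, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  list(center = mu, scale = sd_)
}

scale_apply <- function(m, s) {
  sweep(sweep(m, 2L, s$center, "-"), 2L, s$scale, "/")
}
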