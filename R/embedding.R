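# Per-position sequence embeddings.
#
# Three sources behind one shape contract (rows == sequence length):
#  * pretrained  - adapter over an external RNA language model (L x 640),
#                  served from a cache of pre-computed matrices;
#  * fallback    - deterministic pseudo-random rows keyed by (base, position),
#                  same shape contract, no weights needed;
#  * onehot      - L x 5 indicator over {A, C, G, U, X}, the channel the
#                  saliency gradients are taken with respect to.
# X padding positions are zero rows in every source.

EMBED_DIM_PRETRAINED <- 640L

new_embedding <- function(values, seq_id, source) {
  structure(list(values = values, seq_id = seq_id, source = source,
                 D = ncol(values)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("embedding_matrix [", nrow(x$values), " x ", x$D, "] source=", x$source,
      " seq_id=", x$seq_id, "\n", sep = "")
  invisible(x)
}

#' Embed an RNA sequence as a per-position feature matrix
#'
#' @param seq Sequence over A/C/G/U/X.
#' @param source One of `"pretrained"`, `"fallback"`, `"onehot"`.
#' @param D Embedding width for the fallback source (pretrained is fixed at
#'   640, onehot at 5).
#' @param seq_id Identifier stored on the result.
#' @param cache_dir Directory of pre-computed pretrained matrices (files named
#'   `<seq_id>.tsv`, see [save_embedding()]). When the requested id is not
#'   cached the pretrained source downgrades to the deterministic fallback at
#'   width 640 with a prominent warning (or errors if `strict = TRUE`).
#' @param strict Error instead of downgrading when pretrained weights are
#'   unavailable.
#' @return An `embedding_matrix` (list with `values`, `seq_id`, `source`, `D`).
#' @export
embed_sequence <- function(seq, source = c("fallback", "pretrained", "onehot"),
                           D = EMBED_DIM_PRETRAINED, seq_id = "seq",
                           cache_dir = NULL, strict = FALSE) {
  source <- match.arg(source)
  if (!is_valid_rna(seq, allow_x = TRUE))
    stop("embed_sequence: invalid character in sequence")
  switch(source,
    onehot = embed_onehot(seq, seq_id),
    fallback = embed_fallback(seq, D = D, seq_id = seq_id),
    pretrained = embed_pretrained(seq, seq_id = seq_id, cache_dir = cache_dir,
                                  strict = strict))
}

#' @rdname embed_sequence
#' @export
embed_onehot <- function(seq, seq_id = "seq") {
  ch <- seq_chars(seq)
  idx <- match(ch, RNA_ALPHABET)
  if (anyNA(idx)) stop("embed_onehot: character outside {A,C,G,U,X}")
  m <- matrix(0, length(ch), 5L, dimnames = list(NULL, RNA_ALPHABET))
  m[cbind(seq_along(ch), idx)] <- 1
  new_embedding(m, seq_id, "onehot")
}

#' Decode a one-hot matrix back to its sequence
#' @param x An `embedding_matrix` with source `"onehot"`.
#' @return The sequence string.
#' @export
onehot_decode <- function(x) {
  stopifnot(inherits(x, "embedding_matrix"), x$source == "onehot")
  paste(RNA_ALPHABET[max.col(x$values)], collapse = "")
}

# Deterministic pseudo-random row for (base, position): a fixed integer hash
# seeds R's RNG locally, so rows are identical across processes and platforms.
fallback_row <- function(base_idx, pos, D) {
  old <- local_seed((base_idx * 7919L + pos * 104729L) %% 2147483587L)
  on.exit(restore_seed(old))
  stats::rnorm(D) / sqrt(D)
}

#' @rdname embed_sequence
#' @export
embed_fallback <- function(seq, D = EMBED_DIM_PRETRAINED, seq_id = "seq") {
  ch <- seq_chars(seq)
  m <- matrix(0, length(ch), D)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(ch)) {
    if (ch[i] == "X") next  # padding stays a zero row
    key <- paste0(ch[i], i)
    if (is.null(cache[[key]]))
      cache[[key]] <- fallback_row(match(ch[i], RNA_BASES), i, D)
    m[i, ] <- cache[[key]]
  }
  new_embedding(m, seq_id, "fallback")
}

#' @rdname embed_sequence
#' @export
embed_pretrained <- function(seq, seq_id = "seq", cache_dir = NULL,
                             strict = FALSE) {
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(seq_id, ".tsv"))
    if (file.exists(f)) {
      emb <- load_embedding(f)
      if (nrow(emb$values) != nchar(seq))
        stop("cached embedding for ", seq_id, " has ", nrow(emb$values),
             " rows; sequence has ", nchar(seq))
      # X positions are outside the language model's vocabulary: zero them.
      emb$values[seq_chars(seq) == "X", ] <- 0
      emb$source <- "pretrained"
      return(emb)
    }
  }
  if (strict)
    stop("pretrained embeddings unavailable for ", seq_id,
         " (no cache entry); rerun with the adapter cache populated")
  warning("pretrained embedding unavailable for ", seq_id,
          "; DOWNGRADING to deterministic fallback (reduced fidelity)",
          call. = FALSE)
  emb <- embed_fallback(seq, D = EMBED_DIM_PRETRAINED, seq_id = seq_id)
  emb
}

#' Persist / load an embedding matrix
#'
#' Plain-text array container: `#`-prefixed header lines carry `seq_id`,
#' `source` and dimensions, followed by one tab-separated row per sequence
#' position. Round trip is lossless to full double precision.
#'
#' @param x An `embedding_matrix`.
#' @param path File path (`.tsv`).
#' @return `save_embedding()` returns `path` invisibly; `load_embedding()`
#'   returns the `embedding_matrix`.
#' @export
save_embedding <- function(x, path) {
  stopifnot(inherits(x, "embedding_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seq_id=%s", x$seq_id),
               sprintf("# source=%s", x$source),
               sprintf("# dim=%d %d", nrow(x$values), ncol(x$values))), con)
  utils::write.table(format(x$values, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L || !all(startsWith(hdr, "#")))
    stop("corrupt embedding file (bad header): ", path)
  seq_id <- sub("^# seq_id=", "", hdr[1])
  source <- sub("^# source=", "", hdr[2])
  dims <- as.integer(strsplit(sub("^# dim=", "", hdr[3]), " ")[[1]])
  vals <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                                      colClasses = "numeric"))
  dimnames(vals) <- NULL
  if (!identical(dim(vals), dims))
    stop("corrupt embedding file (dim mismatch): ", path)
  new_embedding(vals, seq_id, source)
}
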