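# Shared fixtures and independent oracles for the test suite. Fixtures are
# generated in code; expensive objects are cached per session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

random_rna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small but complete model configuration for fast training tests
tiny_config <- function(...) {
  sirna_config(hidden_dim = 8L, conv_out_channels = 4L, attention_heads = 4L,
               transformer_ff = 16L, mlp_hidden_sizes = 8L,
               pretrained_dim = 16L, ...)
}

toy_dataset <- function(n = 120, seed = 7, ...) {
  tx <- gen_transcripts(10, 300, seed = seed)
  gen_efficacy_dataset(n, tx, seed = seed + 1, ...)
}

# ---- independent oracles ---------------------------------------------------

# Exhaustive global-alignment oracle: enumerates every alignment of a and b,
# returns the optimal score and, among co-optimal alignments, the identity of
# the one preferred by the move order diagonal > up > left read from the
# sequence ends backwards (matching the documented traceback).
nw_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {   # optimal score aligning a[1..i] with b[1..j]
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    r <- if (i == 0 && j == 0) 0
    else {
      cand <- -Inf
      if (i > 0 && j > 0)
        cand <- max(cand, best(i - 1, j - 1) +
                      (if (ac[i] == bc[j]) match else mismatch))
      if (i > 0) cand <- max(cand, best(i - 1, j) + gap)
      if (j > 0) cand <- max(cand, best(i, j - 1) + gap)
      cand
    }
    memo[[key]] <- r
    r
  }
  score <- best(length(ac), length(bc))
  i <- length(ac); j <- length(bc)
  matches <- 0L; alen <- 0L
  while (i > 0 || j > 0) {
    here <- best(i, j)
    if (i > 0 && j > 0 &&
        here == best(i - 1, j - 1) + (if (ac[i] == bc[j]) match else mismatch)) {
      matches <- matches + (ac[i] == bc[j]); alen <- alen + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && here == best(i - 1, j) + gap) {
      alen <- alen + 1L; i <- i - 1
    } else {
      alen <- alen + 1L; j <- j - 1
    }
  }
  list(score = score, identity = 100 * matches / alen)
}

# Brute-force AUC: concordant-pair count over all positive/negative pairs,
# ties counted 1/2.
auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Independent duplex free-energy summation: explicit position loop with its
# own end-penalty logic (separate code path from duplex_dg).
duplex_dg_oracle <- function(seq, tab) {
  ch <- strsplit(seq, "")[[1]]
  total <- tab$init_dg
  for (i in seq_len(length(ch) - 1))
    total <- total + tab$stack_dg[[paste0(ch[i], ch[i + 1])]]
  for (end_base in c(ch[1], ch[length(ch)]))
    if (end_base == "A" || end_base == "U")
      total <- total + tab$terminal_au_penalty
  total
}

# numeric gradient of f wrt matrix m by central differences
num_grad <- function(f, m, eps = 1e-5) {
  g <- m * 0
  for (i in seq_along(m)) {
    mp <- m; mp[i] <- mp[i] + eps
    mm <- m; mm[i] <- mm[i] - eps
    g[i] <- (f(mp) - f(mm)) / (2 * eps)
  }
  g
}
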