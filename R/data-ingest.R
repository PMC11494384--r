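#' Read a delimited siRNA efficacy table
#'
#' Reads a CSV/TSV efficacy table and maps its columns onto the package's raw
#' record schema. Sequences are upper-cased with T converted to U; rows whose
#' sequence contains characters outside A/C/G/U are excluded and logged on the
#' returned object.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping record fields to column names. Required
#'   entries: `antisense` (siRNA antisense sequence 5'->3'), `inhibition`
#'   (measured inhibition, original units). Optional: `transcript_id`,
#'   `source_dataset`.
#' @param sep Field separator; `NULL` guesses from the file extension
#'   (`.csv` -> comma, otherwise tab).
#' @return A `data.frame` with columns `antisense_seq`, `raw_inhibition`,
#'   `transcript_id`, `source_dataset`; excluded rows are recorded in
#'   `attr(, "excluded")` with a reason per row.
#' @export
read_efficacy_table <- function(path,
                                schema = list(antisense = "antisense",
                                              inhibition = "inhibition",
                                              transcript_id = "transcript_id",
                                              source_dataset = "source_dataset"),
                                sep = NULL) {
  if (!file.exists(path)) stop("efficacy table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L) stop("empty efficacy table: ", path)
  for (fld in c("antisense", "inhibition")) {
    col <- schema[[fld]]
    if (is.null(col) || !col %in% names(df))
      stop("schema error: required column '", fld, "' (", col %||% "<unset>",
           ") missing from ", path)
  }
  get_col <- function(fld, default) {
    col <- schema[[fld]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  out <- data.frame(
    antisense_seq  = rna_clean(as.character(df[[schema$antisense]])),
    raw_inhibition = as.numeric(df[[schema$inhibition]]),
    transcript_id  = as.character(get_col("transcript_id", NA_character_)),
    source_dataset = as.character(get_col("source_dataset", "default")),
    stringsAsFactors = FALSE
  )
  bad_alpha <- !is_valid_rna(out$antisense_seq)
  bad_val <- !is.finite(out$raw_inhibition)
  bad <- bad_alpha | bad_val
  excluded <- NULL
  if (any(bad)) {
    excluded <- data.frame(
      row = which(bad),
      antisense_seq = out$antisense_seq[bad],
      reason = ifelse(bad_alpha[bad], "non-ACGU character", "non-numeric inhibition"),
      stringsAsFactors = FALSE
    )
    message("read_efficacy_table: excluded ", sum(bad), " row(s): ",
            paste(unique(excluded$reason), collapse = ", "))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "excluded") <- excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonize siRNA sequences to 19 nucleotides
#'
#' 19-nt sequences are returned unchanged; 21-nt sequences (19-mer plus a
#' 2-nt 3' overhang) keep positions 1-19 and drop the overhang at positions
#' 20-21. Other lengths are rejected.
#'
#' @param seq Character vector of RNA sequences, length 19 or 21 each.
#' @return Character vector of 19-nt sequences.
#' @export
harmonize_sirna <- function(seq) {
  n <- nchar(seq)
  bad <- !(n %in% c(19L, 21L))
  if (any(bad))
    stop("unsupported siRNA length(s): ", paste(unique(n[bad]), collapse = ", "),
         " (expected 19 or 21)")
  ifelse(n == 21L, substr(seq, 1L, 19L), seq)
}

#' Normalize inhibition per source dataset and assign binary labels
#'
#' Each dataset group's raw inhibition is scaled by that group's maximum so
#' normalized efficacy lies in \[0, 1\], then labelled positive when the
#' normalized value is at or above `threshold_frac` of the maximum
#' (default 0.70; ties count as positive).
#'
#' @param records Data frame with columns `raw_inhibition` and
#'   `source_dataset` (as from [read_efficacy_table()]).
#' @param threshold_frac Positive-label threshold as a fraction of the dataset
#'   maximum.
#' @return The input with added columns `norm_efficacy` (clipped to \[0, 1\])
#'   and `label` (1 positive / 0 negative).
#' @export
normalize_and_label <- function(records, threshold_frac = 0.70) {
  stopifnot(is.data.frame(records), "raw_inhibition" %in% names(records))
  if (!"source_dataset" %in% names(records)) records$source_dataset <- "default"
  grp_max <- tapply(records$raw_inhibition, records$source_dataset, max)
  if (any(grp_max <= 0))
    stop("normalization error: dataset group(s) with non-positive maximum inhibition: ",
         paste(names(grp_max)[grp_max <= 0], collapse = ", "))
  records$norm_efficacy <- pmin(pmax(
    records$raw_inhibition / as.numeric(grp_max[records$source_dataset]), 0), 1)
  records$label <- as.integer(records$norm_efficacy >= threshold_frac)
  records
}

#' Locate the complementary site of a guide strand on a transcript
#'
#' Finds exact occurrences of the reverse complement of the antisense (guide)
#' sequence on the mRNA sense strand. The first occurrence is returned; when
#' several exist a warning lists them all.
#'
#' @param antisense_seq 19-nt guide sequence, 5'->3'.
#' @param transcript_seq Transcript sequence (A/C/G/U).
#' @return List with `site_start`, `site_end` (0-based half-open on the
#'   transcript), and `n_matches`.
#' @export
locate_site <- function(antisense_seq, transcript_seq) {
  stopifnot(is_valid_rna(antisense_seq), is_valid_rna(transcript_seq))
  target <- rna_revcomp(antisense_seq)
  hits <- gregexpr(target, transcript_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("site not found: no complementary site for guide ", antisense_seq)
  if (length(hits) > 1L)
    warning("multiple complementary sites (", length(hits), ") at 0-based starts ",
            paste(hits - 1L, collapse = ", "), "; using the first")
  start0 <- hits[1] - 1L
  list(site_start = start0, site_end = start0 + nchar(antisense_seq),
       n_matches = length(hits))
}

#' Extract the flanked mRNA context window around a target site
#'
#' Takes the 19-nt complementary site as the centre and extends `flank5`
#' upstream and `flank3` downstream. Extensions running past a transcript end
#' are padded with the `X` symbol so the window length is always
#' `flank5 + (site_end - site_start) + flank3` (57 at defaults).
#'
#' @param transcript_seq Transcript sequence.
#' @param site_start,site_end 0-based half-open site coordinates.
#' @param flank5,flank3 Flank lengths in nucleotides.
#' @return List with `window_seq`, `pad5`, `pad3`, `site_start`, `site_end`.
#' @export
extract_context <- function(transcript_seq, site_start, site_end,
                            flank5 = 19L, flank3 = 19L) {
  L <- nchar(transcript_seq)
  stopifnot(site_start >= 0L, site_end <= L, site_end > site_start)
  pad5 <- max(0L, flank5 - site_start)
  pad3 <- max(0L, site_end + flank3 - L)
  lo <- max(0L, site_start - flank5)   # 0-based
  hi <- min(L, site_end + flank3)
  core <- substr(transcript_seq, lo + 1L, hi)
  window <- paste0(strrep("X", pad5), core, strrep("X", pad3))
  stopifnot(nchar(window) == flank5 + (site_end - site_start) + flank3)
  list(window_seq = window, pad5 = pad5, pad3 = pad3,
       site_start = site_start, site_end = site_end)
}

# -- Needleman-Wunsch global alignment ---------------------------------------

# Full DP matrix, match/mismatch/gap scoring, vectorized per column via a
# prefix-max scan (the up-gap recurrence is a running maximum).
nw_matrix <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1L, m + 1L)
  M[, 1L] <- gap * (0:n)
  M[1L, ] <- gap * (0:m)
  for (j in seq_len(m)) {
    sub <- ifelse(a == b[j], match, mismatch)
    cand <- pmax(M[1:n, j] + sub,          # diagonal
                 M[2:(n + 1L), j] + gap)   # left (gap in a)
    # up moves: M[i+1, j+1] = max(cand[i], M[i, j+1] + gap) as a prefix scan
    u <- c(M[1L, j + 1L], cand - gap * (1:n))
    M[, j + 1L] <- cummax(u) + gap * (0:n)
  }
  M
}

#' Percent identity from Needleman-Wunsch global alignment
#'
#' Global alignment by dynamic programming with the fixed scoring scheme
#' match = 1, mismatch = 0, gap = -1 and deterministic traceback preferring
#' diagonal over up (gap in `seqB`) over left (gap in `seqA`). Identity is
#' 100 x matches / alignment length, gaps included in the denominator.
#'
#' @param seqA,seqB Non-empty sequences.
#' @param match,mismatch,gap Scoring parameters.
#' @return Percent identity in \[0, 100\] with the aligned strings in
#'   `attr(, "alignment")`.
#' @export
nw_identity <- function(seqA, seqB, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("nw_identity: empty sequence")
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  M <- nw_matrix(a, b, match, mismatch, gap)
  i <- length(a); j <- length(b)
  alnA <- character(0); alnB <- character(0)
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == M[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      alnA <- c(a[i], alnA); alnB <- c(b[j], alnB); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == M[i, j + 1L] + gap) {
      alnA <- c(a[i], alnA); alnB <- c("-", alnB); i <- i - 1L
    } else {
      alnA <- c("-", alnA); alnB <- c(b[j], alnB); j <- j - 1L
    }
  }
  ident <- 100 * sum(alnA == alnB & alnA != "-") / length(alnA)
  structure(ident, alignment = c(paste(alnA, collapse = ""),
                                 paste(alnB, collapse = "")))
}

#' Remove training sequences redundant with a test set
#'
#' Drops every training sequence whose Needleman-Wunsch percent identity with
#' any test sequence is strictly greater than `identity_cutoff` (default 80;
#' a pair at exactly the cutoff is retained).
#'
#' @param train_records,test_records Data frames with an `antisense_seq`
#'   column, or character vectors of sequences.
#' @param identity_cutoff Percent identity above which a training record is
#'   removed.
#' @return The filtered training records; removed pairs are recorded in
#'   `attr(, "removals")` (columns `train_seq`, `test_seq`, `identity`).
#' @export
deduplicate <- function(train_records, test_records, identity_cutoff = 80) {
  get_seqs <- function(x) if (is.data.frame(x)) x$antisense_seq else as.character(x)
  tr <- get_seqs(train_records); te <- unique(get_seqs(test_records))
  removals <- list()
  drop <- logical(length(tr))
  for (i in seq_along(tr)) {
    for (s in te) {
      id <- as.numeric(nw_identity(tr[i], s))
      if (id > identity_cutoff) {
        drop[i] <- TRUE
        removals[[length(removals) + 1L]] <-
          data.frame(train_seq = tr[i], test_seq = s, identity = id,
                     stringsAsFactors = FALSE)
        break
      }
    }
  }
  out <- if (is.data.frame(train_records)) {
    r <- train_records[!drop, , drop = FALSE]; rownames(r) <- NULL; r
  } else tr[!drop]
  attr(out, "removals") <- if (length(removals)) do.call(rbind, removals) else NULL
  out
}

#' Stratified k-fold assignment
#'
#' Shuffles records within each label stratum under `seed`, then deals each
#' record to the currently smallest fold, so fold sizes differ by at most one
#' and both labels appear in every fold whenever counts allow.
#'
#' @param labels Vector of binary labels (or any grouping used for
#'   stratification).
#' @param k Number of folds.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @export
make_folds <- function(labels, k = 5L, seed) {
  n <- length(labels)
  if (n < k) stop("fewer records (", n, ") than folds (", k, ")")
  if (missing(seed)) stop("make_folds: seed is required")
  fold <- integer(n)
  sizes <- integer(k)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (lv in sort(unique(labels))) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      f <- which.min(sizes)
      fold[i] <- f
      sizes[f] <- sizes[f] + 1L
    }
  }
  fold
}

# Seed handling that leaves the caller's RNG state untouched.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Build a harmonized siRNA dataset from an efficacy table and transcripts
#'
#' Convenience pipeline: harmonize guide sequences to 19 nt, locate each
#' guide's complementary site on its transcript, extract the 57-nt context
#' window, normalize inhibition per source dataset, and label. Records whose
#' guide has no complementary site on the named transcript are dropped with a
#' message.
#'
#' @param records Raw records from [read_efficacy_table()].
#' @param transcripts Named character vector of transcript sequences (see
#'   [read_transcripts()]).
#' @param threshold_frac Labelling threshold, fraction of dataset maximum.
#' @param flank5,flank3 Context flank lengths.
#' @return A `sirna_dataset` data frame with columns `antisense_seq`,
#'   `window_seq`, `norm_efficacy`, `label`, `source_dataset`,
#'   `transcript_id`, `site_start`, `site_end`.
#' @export
harmonize_dataset <- function(records, transcripts, threshold_frac = 0.70,
                              flank5 = 19L, flank3 = 19L) {
  records$antisense_seq <- harmonize_sirna(records$antisense_seq)
  n <- nrow(records)
  window_seq <- character(n); s0 <- integer(n); s1 <- integer(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    tid <- records$transcript_id[i]
    if (is.na(tid) || !tid %in% names(transcripts)) next
    site <- tryCatch(
      suppressWarnings(locate_site(records$antisense_seq[i], transcripts[[tid]])),
      error = function(e) NULL)
    if (is.null(site)) next
    ctx <- extract_context(transcripts[[tid]], site$site_start, site$site_end,
                           flank5, flank3)
    window_seq[i] <- ctx$window_seq; s0[i] <- site$site_start; s1[i] <- site$site_end
    keep[i] <- TRUE
  }
  if (!all(keep))
    message("harmonize_dataset: dropped ", sum(!keep),
            " record(s) without a complementary site")
  out <- records[keep, , drop = FALSE]
  out$window_seq <- window_seq[keep]
  out$site_start <- s0[keep]
  out$site_end <- s1[keep]
  out <- normalize_and_label(out, threshold_frac)
  rownames(out) <- NULL
  class(out) <- c("sirna_dataset", "data.frame")
  out
}

#' @export
print.sirna_dataset <- function(x, ...) {
  cat("siRNA dataset: ", nrow(x), " records, ",
      sum(x$label == 1), " positive / ", sum(x$label == 0), " negative",
      if (!is.null(x$source_dataset))
        paste0(" (datasets: ", paste(unique(x$source_dataset), collapse = ", "), ")"),
      "\n", sep = "")
  NextMethod()
}
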