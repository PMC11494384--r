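#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")
RNA_ALPHABET <- c(RNA_BASES, "X")

#' Clean a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases and converts T to U. Does not validate; see
#' [is_valid_rna()].
#'
#' @param seq Character vector of sequences.
#' @return Character vector of the same length.
#' @export
rna_clean <- function(seq) {
  chartr("tT", "uU", toupper(seq))
}

#' @rdname rna_clean
#' @param allow_x Whether the padding symbol `X` is permitted.
#' @export
is_valid_rna <- function(seq, allow_x = FALSE) {
  pat <- if (allow_x) "^[ACGUX]+$" else "^[ACGU]+$"
  grepl(pat, seq)
}

#' Reverse complement of an RNA sequence
#'
#' `X` padding characters complement to `X`.
#'
#' @param seq Character vector of RNA sequences (A, C, G, U, X).
#' @return Character vector of reverse complements.
#' @export
rna_revcomp <- function(seq) {
  comp <- chartr("ACGUX", "UGCAX", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Read transcripts from a FASTA file
#'
#' Multi-record, wrapped-line FASTA via Biostrings; sequences are returned as
#' an upper-case RNA character vector named by record id (first word of the
#' header).
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet; T is mapped to U).
#' @return Named character vector of RNA sequences.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- rna_clean(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write transcripts to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
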