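# Thermodynamic features from the RNA nearest-neighbor model.
#
# Duplex stability is additive over dinucleotide stacks (Turner rules, Xia
# 1998 delta-G at 37 C) plus an initiation term and a penalty per AU-closed
# helix end. The guide strand is assumed fully Watson-Crick paired to its
# target site.

#' Load the RNA nearest-neighbor parameter table
#'
#' Reads the vendored Xia et al. (1998) Watson-Crick stack free energies
#' (delta-G at 37 C, kcal/mol), the duplex initiation term, and the terminal
#' AU penalty. The table is validated: all 16 stacks present, stack values
#' negative, reverse-complement symmetric.
#'
#' @param path Path to a parameter TSV (columns `entry`, `value`); defaults to
#'   the vendored table.
#' @return List with `stack_dg` (named vector of 16 stacks), `init_dg`,
#'   `terminal_au_penalty`, and `version`.
#' @export
nn_table <- function(path = system.file("extdata", "nn_rna_dg37.tsv",
                                        package = "sirnadesign")) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(raw$value, raw$entry)
  stacks <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  missing <- setdiff(stacks, names(vals))
  if (length(missing)) stop("NN table missing stacks: ", paste(missing, collapse = ", "))
  stack_dg <- vals[stacks]
  if (any(stack_dg >= 0)) stop("NN table: stack free energies must be negative")
  rc <- rna_revcomp(stacks)
  if (any(abs(stack_dg - stack_dg[rc]) > 1e-9))
    stop("NN table: reverse-complement symmetry violated")
  ver <- grep("version=", readLines(path, n = 10L), value = TRUE)
  list(stack_dg = stack_dg,
       init_dg = unname(vals["init"]),
       terminal_au_penalty = unname(vals["terminal_au"]),
       version = sub(".*version=(\\S+).*", "\\1", ver[1] %||% "unversioned"))
}

stack_dinucs <- function(seq) {
  n <- nchar(seq)
  substring(seq, 1:(n - 1L), 2:n)
}

#' Duplex formation free energy of a fully paired guide strand
#'
#' Nearest-neighbor sum: initiation + the consecutive stack free energies +
#' the terminal AU penalty for each helix end closed by an A-U or U-A pair.
#' Lower (more negative) is more stable.
#'
#' @param antisense_seq Guide sequence (length >= 2, A/C/G/U), assumed fully
#'   Watson-Crick paired to its complement.
#' @param table Parameter table from [nn_table()].
#' @return Free energy in kcal/mol.
#' @export
duplex_dg <- function(antisense_seq, table = nn_table()) {
  if (!is_valid_rna(antisense_seq)) stop("duplex_dg: non-ACGU character in sequence")
  if (nchar(antisense_seq) < 2L) stop("duplex_dg: sequence length must be >= 2")
  dinucs <- stack_dinucs(antisense_seq)
  ends <- c(substr(antisense_seq, 1L, 1L),
            substr(antisense_seq, nchar(antisense_seq), nchar(antisense_seq)))
  table$init_dg + sum(table$stack_dg[dinucs]) +
    table$terminal_au_penalty * sum(ends %in% c("A", "U"))
}

#' Mean terminal stack stability at one end of the guide strand
#'
#' The mean nearest-neighbor stack free energy over the `n_stacks` stacks
#' nearest the requested end. The 5'/3' differential (see
#' [thermo_vector()]'s `asymmetry_ddg`) is the classic strand-selection
#' asymmetry signal.
#'
#' @param antisense_seq Guide sequence, length >= `n_stacks + 1`.
#' @param table Parameter table from [nn_table()].
#' @param end `"5prime"` or `"3prime"`.
#' @param n_stacks Number of terminal stacks to average (default 2).
#' @return Mean stack free energy in kcal/mol.
#' @export
end_stability <- function(antisense_seq, table = nn_table(),
                          end = c("5prime", "3prime"), n_stacks = 2L) {
  end <- match.arg(end)
  n <- nchar(antisense_seq)
  stopifnot(n >= n_stacks + 1L)
  dinucs <- stack_dinucs(antisense_seq)
  idx <- if (end == "5prime") seq_len(n_stacks) else seq(length(dinucs) - n_stacks + 1L, length(dinucs))
  mean(table$stack_dg[dinucs[idx]])
}

#' Mono- and dinucleotide composition of a sequence
#'
#' Counts divided by sequence length (mononucleotides) and length - 1
#' (dinucleotides). `X` padding positions are excluded from both numerators
#' and denominators; dinucleotides containing `X` are skipped.
#'
#' @param seq Sequence over A/C/G/U/X.
#' @return Named vector: `gc_fraction`, `frac_A` ... `frac_U`,
#'   `frac_AA` ... `frac_UU` (21 values).
#' @export
composition <- function(seq) {
  if (!is_valid_rna(seq, allow_x = TRUE)) stop("composition: invalid character")
  ch <- seq_chars(seq)
  keep <- ch != "X"
  mono_n <- sum(keep)
  mono <- vapply(RNA_BASES, function(b) sum(ch == b), numeric(1)) / max(mono_n, 1L)
  dn <- stack_dinucs(seq)
  dn <- dn[!grepl("X", dn, fixed = TRUE)]
  dins <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  di <- vapply(dins, function(d) sum(dn == d), numeric(1)) / max(length(dn), 1L)
  c(gc_fraction = unname(mono["G"] + mono["C"]),
    stats::setNames(mono, paste0("frac_", RNA_BASES)),
    stats::setNames(di, paste0("frac_", dins)))
}

#' Minimum free energy of single-strand self-structure
#'
#' Dispatches to a pluggable folding engine (see [rnafold_engine()] and
#' [naive_fold_engine()]).
#'
#' @param seq Sequence (length >= 4).
#' @param engine Folding engine from [fold_engine()].
#' @return MFE in kcal/mol (<= 0).
#' @export
intramolecular_dg <- function(seq, engine = fold_engine()) {
  stopifnot(nchar(seq) >= 4L)
  engine$fold(seq)$mfe
}

#' Full thermodynamic and composition feature vector
#'
#' Ordered, named vector of 26 features: `duplex_dg`, `sirna_dg`
#' (intramolecular MFE of the guide), `end5_dg`, `end3_dg`,
#' `asymmetry_ddg = end5_dg - end3_dg`, `gc_fraction`, 4 mononucleotide
#' fractions, and 16 dinucleotide fractions.
#'
#' @param antisense_seq 19-nt guide sequence.
#' @param context Optional mRNA context (unused by the energy terms, which
#'   assume full complementarity at the site; kept for interface symmetry).
#' @param table Parameter table from [nn_table()].
#' @param engine Folding engine for the intramolecular term.
#' @return Named numeric vector of length 26.
#' @export
thermo_vector <- function(antisense_seq, context = NULL, table = nn_table(),
                          engine = fold_engine()) {
  e5 <- end_stability(antisense_seq, table, "5prime")
  e3 <- end_stability(antisense_seq, table, "3prime")
  out <- c(duplex_dg = duplex_dg(antisense_seq, table),
           sirna_dg = intramolecular_dg(antisense_seq, engine),
           end5_dg = e5, end3_dg = e3, asymmetry_ddg = e5 - e3,
           composition(antisense_seq))
  stopifnot(length(out) == length(thermo_feature_names()))
  out
}

#' @rdname thermo_vector
#' @export
thermo_feature_names <- function() {
  dins <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  c("duplex_dg", "sirna_dg", "end5_dg", "end3_dg", "asymmetry_ddg",
    "gc_fraction", paste0("frac_", RNA_BASES), paste0("frac_", dins))
}

#' Thermodynamic feature matrix for a dataset
#'
#' @param dataset A `sirna_dataset` or data frame with `antisense_seq`.
#' @inheritParams thermo_vector
#' @return Numeric matrix, one row per record, columns named as in
#'   [thermo_feature_names()].
#' @export
thermo_matrix <- function(dataset, table = nn_table(), engine = fold_engine()) {
  seqs <- if (is.data.frame(dataset)) dataset$antisense_seq else as.character(dataset)
  out <- t(vapply(seqs, function(s) {
    e5 <- end_stability(s, table, "5prime")
    e3 <- end_stability(s, table, "3prime")
    c(duplex_dg = duplex_dg(s, table), sirna_dg = 0,
      end5_dg = e5, end3_dg = e3, asymmetry_ddg = e5 - e3, composition(s))
  }, numeric(length(thermo_feature_names())), USE.NAMES = FALSE))
  colnames(out) <- thermo_feature_names()
  out[, "sirna_dg"] <- engine$fold_many(seqs)  # batched: one engine call
  out
}
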