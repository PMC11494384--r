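# Synthetic fixtures with a planted, recoverable efficacy rule.
#
# The generator emulates a single-laboratory efficacy screen: random
# transcripts, random 19-nt target sites, and a ground-truth efficacy that
# depends only on features the model can access -- the 5'/3' terminal
# stability differential of the guide (strand-selection asymmetry), an A/G
# bonus at guide position 1 and a U bonus at position 19 (the classic
# position preferences of functional siRNAs), and a mild penalty for GC
# content away from 0.5 -- passed through a logistic link with additive
# Gaussian noise.

#' The planted efficacy rule
#'
#' @param weight_asymmetry Logit weight per kcal/mol of the 5'-3' terminal
#'   stack differential (`asymmetry_ddg`).
#' @param bonus_pos1_AG Logit bonus when guide position 1 is A or G.
#' @param bonus_pos19_U Logit bonus when guide position 19 is U.
#' @param weight_gc Logit weight per unit of |GC fraction - 0.5|.
#' @param noise_sigma Gaussian noise s.d. added after the logistic link.
#' @param intercept Logit intercept.
#' @return A `planted_rule` list.
#' @export
planted_rule <- function(weight_asymmetry = 2.0, bonus_pos1_AG = 0.5,
                         bonus_pos19_U = 0.5, weight_gc = -1.0,
                         noise_sigma = 0.1, intercept = 0) {
  stopifnot(noise_sigma >= 0)
  structure(list(weight_asymmetry = weight_asymmetry,
                 bonus_pos1_AG = bonus_pos1_AG,
                 bonus_pos19_U = bonus_pos19_U,
                 weight_gc = weight_gc,
                 noise_sigma = noise_sigma,
                 intercept = intercept),
            class = "planted_rule")
}

#' Generate random transcripts
#'
#' Positions are i.i.d. with the requested GC content; deterministic given
#' the seed.
#'
#' @param n Number of transcripts.
#' @param length Transcript length (>= 57).
#' @param gc_target Expected GC fraction.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Named character vector of RNA sequences (write with
#'   [write_transcripts()]).
#' @export
gen_transcripts <- function(n, length = 500L, gc_target = 0.5, seed = 1L,
                            prefix = "synth_tx") {
  stopifnot(length >= 57L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, U = (1 - gc_target) / 2)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(RNA_BASES, length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  stats::setNames(seqs, sprintf("%s_%03d", prefix, seq_len(n)))
}

# Noiseless planted score on the logit scale.
planted_logit <- function(antisense_seq, rule, table = nn_table()) {
  e5 <- end_stability(antisense_seq, table, "5prime")
  e3 <- end_stability(antisense_seq, table, "3prime")
  gc <- unname(composition(antisense_seq)["gc_fraction"])
  p1 <- substr(antisense_seq, 1L, 1L) %in% c("A", "G")
  p19 <- substr(antisense_seq, 19L, 19L) == "U"
  rule$intercept +
    rule$weight_asymmetry * (e5 - e3) +
    rule$bonus_pos1_AG * p1 +
    rule$bonus_pos19_U * p19 +
    rule$weight_gc * abs(gc - 0.5)
}

#' Generate a synthetic efficacy dataset with planted signal
#'
#' Sites are drawn uniformly over the transcripts; each guide's true efficacy
#' is `plogis(planted logit)` plus Gaussian noise, clipped to \[0, 1\];
#' raw inhibition is 100 x the noisy score. Records are harmonized, context
#' windows extracted, and labels assigned at `threshold_frac` of the dataset
#' maximum, exactly as for real data. The noiseless truth is kept in the
#' `true_score` column, and the rule is serialized in `attr(, "rule")`.
#'
#' @param n_records Number of siRNA records.
#' @param transcripts Named transcript vector from [gen_transcripts()].
#' @param rule A [planted_rule()].
#' @param seed Integer seed.
#' @param threshold_frac Labelling threshold.
#' @param table Nearest-neighbor table.
#' @param source_dataset Dataset tag.
#' @return A `sirna_dataset` with additional `true_score` column.
#' @export
gen_efficacy_dataset <- function(n_records, transcripts, rule = planted_rule(),
                                 seed = 1L, threshold_frac = 0.70,
                                 table = nn_table(),
                                 source_dataset = "synthetic") {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  tid <- sample(names(transcripts), n_records, replace = TRUE)
  lens <- nchar(transcripts)[tid]
  start0 <- vapply(lens, function(L) sample.int(L - 18L, 1L) - 1L, integer(1))
  window <- substring(transcripts[tid], start0 + 1L, start0 + 19L)
  anti <- rna_revcomp(window)
  truth <- stats::plogis(vapply(anti, planted_logit, numeric(1), rule = rule,
                                table = table, USE.NAMES = FALSE))
  noisy <- pmin(pmax(truth + stats::rnorm(n_records, 0, rule$noise_sigma), 0), 1)
  df <- data.frame(antisense_seq = anti,
                   raw_inhibition = 100 * noisy,
                   transcript_id = tid,
                   source_dataset = source_dataset,
                   site_start = start0, site_end = start0 + 19L,
                   true_score = truth,
                   stringsAsFactors = FALSE)
  df$window_seq <- vapply(seq_len(n_records), function(i)
    extract_context(transcripts[[tid[i]]], start0[i], start0[i] + 19L)$window_seq,
    character(1))
  df <- normalize_and_label(df, threshold_frac)
  rownames(df) <- NULL
  attr(df, "rule") <- rule
  class(df) <- c("sirna_dataset", "data.frame")
  df
}

#' Write an efficacy table (and its truth file) to disk
#'
#' The table is written in the delimited format [read_efficacy_table()]
#' consumes; the noiseless truth scores go to `<path>.truth.tsv` alongside.
#'
#' @param dataset Output of [gen_efficacy_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_efficacy_table <- function(dataset, path) {
  utils::write.table(
    dataset[, c("antisense_seq", "raw_inhibition", "transcript_id",
                "source_dataset")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$true_score))
    utils::write.table(dataset[, c("antisense_seq", "true_score")],
                       paste0(path, ".truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Structured/unstructured off-target fixture pair
#'
#' Two transcripts embedding the same guide-complementary site at the same
#' offset: in one the site forms the 5' arm of a perfect hairpin stem
#' (buried in structure), in the other it sits in an unstructured A-rich
#' context. Exercises the site-accessibility term of [pita_like_ddg()].
#'
#' @param seed Integer seed for the guide draw.
#' @return List with `guide`, `stem`, `unpaired` (named sequences) and
#'   `site_start` (0-based, identical in both transcripts).
#' @export
gen_offtarget_fixture <- function(seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  chk <- naive_fold_engine()
  # GC-rich guide (stable stem) redrawn until the site itself carries no
  # self-complementary >= 4-mer, so the unpaired context is truly unstructured
  repeat {
    guide <- paste(sample(RNA_BASES, 19L, replace = TRUE,
                          prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
    site <- rna_revcomp(guide)
    if (chk$fold(site)$mfe == 0) break
  }
  pad <- strrep("A", 20L)
  stem <- paste0(pad, site, "GAAA", rna_revcomp(site), pad)
  # pure-A tail: adenines cannot pair with the site or each other
  unpaired <- paste0(pad, site, strrep("A", nchar(stem) - 20L - 19L))
  list(guide = guide,
       stem = c(stem_fixture = stem),
       unpaired = c(unpaired_fixture = unpaired),
       site_start = 20L)
}
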