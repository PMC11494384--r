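# End-to-end siRNA design: scan a target transcript with a 19-nt sliding
# window, screen candidates against functionality rules, immune-stimulatory
# motifs and toxic seeds, score efficacy with a fitted model, attach
# PITA-style site-accessibility off-target labels, and rank.

IMMUNE_MOTIFS <- c("UGUGU", "GUCCUUCA", "CUGAAUU")

#' Enumerate all 19-nt candidate sites on a transcript
#'
#' Sliding window of 19 nucleotides, step 1: a transcript of length L yields
#' exactly L - 18 candidates. The guide (antisense) strand of each candidate
#' is the reverse complement of its window.
#'
#' @param mrna_seq Target transcript (A/C/G/U, length >= 19).
#' @return Data frame with `site_start`, `site_end` (0-based half-open),
#'   `window_seq` (sense) and `antisense_seq`.
#' @export
enumerate_candidates <- function(mrna_seq) {
  mrna_seq <- rna_clean(mrna_seq)
  L <- nchar(mrna_seq)
  if (L < 19L) stop("transcript shorter than 19 nt")
  starts <- 0:(L - 19L)
  windows <- substring(mrna_seq, starts + 1L, starts + 19L)
  data.frame(site_start = starts, site_end = starts + 19L,
             window_seq = windows, antisense_seq = rna_revcomp(windows),
             stringsAsFactors = FALSE)
}

#' Default functionality-filter rule set
#'
#' Documented, editable defaults for sequence properties detrimental to RNAi
#' activity: GC fraction outside \[0.30, 0.65\] (`gc_range`), any
#' single-base run of 5 or more (`base_run`), and any literal mirror
#' palindrome of 7 nt or longer (`palindrome`).
#'
#' @return Named list of rule parameter lists.
#' @export
default_filter_rules <- function() {
  list(gc_range = list(min = 0.30, max = 0.65),
       base_run = list(max_run = 4L),
       palindrome = list(min_len = 7L))
}

has_mirror_palindrome <- function(seq, min_len) {
  ch <- seq_chars(seq)
  n <- length(ch)
  for (len in seq(min_len, n)) {
    for (i in seq_len(n - len + 1L)) {
      w <- ch[i:(i + len - 1L)]
      if (all(w == rev(w))) return(TRUE)
    }
  }
  FALSE
}

longest_base_run <- function(seq) {
  r <- rle(seq_chars(seq))
  max(r$lengths)
}

#' Evaluate functionality-filter rules on a candidate guide
#'
#' Each enabled rule is evaluated independently; the trail records every
#' rule's verdict so downstream reports can name the failed rule.
#'
#' @param antisense_seq 19-nt guide sequence.
#' @param rules Rule set as from [default_filter_rules()]; unknown rule ids
#'   are a configuration error; an empty list passes everything.
#' @return Data frame `rule`, `pass` with overall verdict in
#'   `attr(, "pass")`.
#' @export
functionality_filter <- function(antisense_seq, rules = default_filter_rules()) {
  known <- c("gc_range", "base_run", "palindrome")
  if (length(setdiff(names(rules), known)))
    stop("config error: unknown filter rule id(s): ",
         paste(setdiff(names(rules), known), collapse = ", "))
  rows <- list()
  for (id in names(rules)) {
    p <- rules[[id]]
    ok <- switch(id,
      gc_range = {
        gc <- unname(composition(antisense_seq)["gc_fraction"])
        gc >= p$min && gc <= p$max
      },
      base_run = longest_base_run(antisense_seq) <= p$max_run,
      palindrome = !has_mirror_palindrome(antisense_seq, p$min_len))
    rows[[id]] <- data.frame(rule = id, pass = ok, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(rule = character(0), pass = logical(0))
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  out
}

#' Scan a candidate for immune-stimulatory motifs
#'
#' Both the guide (antisense) and the passenger (sense) strand are scanned
#' for the configured motifs (defaults: UGUGU, GUCCUUCA, CUGAAUU); all
#' overlapping occurrences are reported.
#'
#' @param antisense_seq Guide sequence.
#' @param motifs Character vector of motifs.
#' @return Data frame `motif`, `strand`, `offset` (0-based within the
#'   strand); zero rows when clean.
#' @export
immune_motif_scan <- function(antisense_seq, motifs = IMMUNE_MOTIFS) {
  strands <- c(antisense = antisense_seq, sense = rna_revcomp(antisense_seq))
  rows <- list()
  for (sn in names(strands)) {
    s <- strands[[sn]]
    for (m in motifs) {
      # overlapping occurrences via lookahead
      hits <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
      if (hits[1] != -1L)
        rows[[length(rows) + 1L]] <-
          data.frame(motif = m, strand = sn, offset = as.integer(hits) - 1L,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(motif = character(0), strand = character(0),
                  offset = integer(0))
}

#' Toxic-seed screening
#'
#' Flags a candidate when its seed (guide positions 2-8) exactly matches a
#' blacklist entry. The blacklist ships empty by default; supply one 7-mer
#' per line (comments with `#`).
#'
#' @param antisense_seq Guide sequence.
#' @param blacklist Character vector of 7-mer seeds (see
#'   [load_seed_blacklist()]).
#' @return Logical flag with the seed as `attr(, "seed")`.
#' @export
toxic_seed_filter <- function(antisense_seq, blacklist = character(0)) {
  seed <- substr(antisense_seq, 2L, 8L)
  structure(seed %in% blacklist, seed = seed)
}

#' @rdname toxic_seed_filter
#' @param path Blacklist file, one seed per line.
#' @export
load_seed_blacklist <- function(path) {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  seeds <- rna_clean(lines[keep])
  bad <- which(!grepl("^[ACGU]{7}$", seeds))
  if (length(bad))
    stop("malformed blacklist line ", which(keep)[bad[1]], ": '",
         lines[keep][bad[1]], "' (expected a 7-mer over ACGU)")
  seeds
}

# Map a guide position p (1..19) to the 1-based transcript coordinate of its
# paired base, given the transcript position j of the base paired with guide
# position 8 (the 3' end of the seed match).
guide_to_target <- function(p, j) j + (8L - p)

#' PITA-style site-accessibility off-target score
#'
#' For every exact Watson-Crick match of the guide seed (positions 2-8) on
#' the transcript, the pairing is extended to the maximal contiguous
#' complementary run containing the seed, and the score is
#' `ddG = dG_duplex - dG_open` where `dG_duplex` is the nearest-neighbor
#' duplex energy over the paired region and
#' `dG_open = MFE(window) - MFE(window with the site forced single-stranded)`
#' over a window of the site +/- `window_flank` nt. A site buried in
#' structure has a strongly negative `dG_open`, making `ddG` less favorable.
#'
#' @param antisense_seq Guide sequence (19 nt).
#' @param transcript_seq Off-target transcript to scan.
#' @param engine Folding engine (the naive fallback yields `dG_open = 0`).
#' @param table Nearest-neighbor table.
#' @param window_flank Accessibility window half-width in nt.
#' @return Data frame of seed-match sites (`site_start` 0-based of the paired
#'   region, `paired_len`, `dg_duplex`, `dg_open`, `ddg`), sorted most
#'   favorable (lowest `ddg`) first; zero rows when the seed never matches.
#' @export
pita_like_ddg <- function(antisense_seq, transcript_seq,
                          engine = fold_engine(), table = nn_table(),
                          window_flank = 70L) {
  seed <- substr(antisense_seq, 2L, 8L)
  target_seed <- rna_revcomp(seed)
  L <- nchar(transcript_seq)
  tch <- seq_chars(transcript_seq)
  gch <- seq_chars(antisense_seq)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  hits <- gregexpr(paste0("(?=", target_seed, ")"), transcript_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(site_start = integer(0), paired_len = integer(0),
                      dg_duplex = numeric(0), dg_open = numeric(0),
                      ddg = numeric(0)))
  rows <- list()
  for (h in as.integer(hits)) {
    # transcript position paired with guide position 8 is the first base of
    # the seed match (guide read 5'->3' pairs antiparallel to the target)
    j <- h
    paired <- function(p) {
      tpos <- guide_to_target(p, j)
      tpos >= 1L && tpos <= L && tch[tpos] == comp[[gch[p]]]
    }
    lo <- 2L
    while (lo > 1L && paired(lo - 1L)) lo <- lo - 1L
    hi <- 8L
    while (hi < 19L && paired(hi + 1L)) hi <- hi + 1L
    guide_part <- substr(antisense_seq, lo, hi)
    dgd <- duplex_dg(guide_part, table)
    t_lo <- guide_to_target(hi, j); t_hi <- guide_to_target(lo, j)
    w_lo <- max(1L, t_lo - window_flank); w_hi <- min(L, t_hi + window_flank)
    win <- substr(transcript_seq, w_lo, w_hi)
    site_in_win <- (t_lo - w_lo + 1L):(t_hi - w_lo + 1L)
    mfe_free <- engine$fold(win)$mfe
    mfe_blocked <- engine$fold(win, force_unpaired = site_in_win)$mfe
    dgo <- mfe_free - mfe_blocked   # <= 0; the opening cost with its sign
    rows[[length(rows) + 1L]] <-
      data.frame(site_start = t_lo - 1L, paired_len = hi - lo + 1L,
                 dg_duplex = dgd, dg_open = dgo, ddg = dgd - dgo)
  }
  out <- do.call(rbind, rows)
  out[order(out$ddg, out$site_start), , drop = FALSE]
}

#' Join externally computed off-target scores onto candidates
#'
#' Parses a tabular output file of an external miRNA-target tool (columns
#' including a guide/siRNA sequence and a numeric score) and joins scores to
#' candidates by exact sequence match. Duplicate rows: last wins, with a
#' warning. No re-implementation of the external model is attempted.
#'
#' @param candidates Data frame with `antisense_seq`.
#' @param tool_output Path to the external tool's tab-separated output.
#' @param seq_col,score_col Column names in the file.
#' @return `candidates` with an added `external_score` column (NA and a
#'   message for candidates absent from the file).
#' @export
external_offtarget_adapter <- function(candidates, tool_output,
                                       seq_col = "sequence",
                                       score_col = "score") {
  df <- tryCatch(
    utils::read.table(tool_output, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("unparseable off-target file ", tool_output,
                             ": ", conditionMessage(e)))
  if (!all(c(seq_col, score_col) %in% names(df)))
    stop("off-target file lacks required columns: ", seq_col, ", ", score_col)
  if (anyDuplicated(df[[seq_col]])) {
    warning("duplicate sequences in off-target file; last occurrence wins")
    df <- df[!duplicated(df[[seq_col]], fromLast = TRUE), , drop = FALSE]
  }
  sc <- df[[score_col]][match(rna_clean(candidates$antisense_seq),
                              rna_clean(df[[seq_col]]))]
  if (anyNA(sc))
    message(sum(is.na(sc)), " candidate(s) missing from external score file")
  candidates$external_score <- sc
  candidates
}

#' Design ranked siRNA candidates against a target mRNA
#'
#' The complete pipeline: enumerate 19-nt windows, evaluate functionality
#' rules, predict efficacy with a fitted model, scan for immune-stimulatory
#' motifs and toxic seeds (toxicity labels), score PITA-style off-target
#' accessibility against an interested mRNA set (off-target labels), and
#' rank by predicted efficacy (descending; ties by site position). Labels
#' mark candidates but never alter predicted efficacy; removal of
#' rule-failing candidates is configurable.
#'
#' @param fit A `sirna_fit`.
#' @param mrna_seq Target transcript sequence (or single-record FASTA path).
#' @param offtarget_set Named character vector of transcripts to screen for
#'   miRNA-like off-targets (or FASTA path); `NULL` skips off-target scoring.
#' @param blacklist Toxic-seed 7-mers.
#' @param rules Functionality rules ([default_filter_rules()]); `list()`
#'   disables filtering.
#' @param drop_failing Remove candidates failing a functionality rule
#'   (default) instead of keeping them labelled.
#' @param pita_threshold Off-target label threshold: a candidate whose best
#'   (lowest) ddG against the set is at or below this many kcal/mol is
#'   flagged.
#' @param engine Folding engine.
#' @param transcript_id Id used in reports.
#' @return A `candidate_report` data frame, ranked, with filter trail,
#'   toxicity and off-target columns; summary counts in
#'   `attr(, "summary")`.
#' @export
design_sirna <- function(fit, mrna_seq, offtarget_set = NULL,
                         blacklist = character(0),
                         rules = default_filter_rules(),
                         drop_failing = TRUE, pita_threshold = -10,
                         engine = fold_engine(), transcript_id = "target") {
  if (length(mrna_seq) == 1L && file.exists(mrna_seq)) {
    tr <- read_transcripts(mrna_seq)
    transcript_id <- names(tr)[1]
    mrna_seq <- tr[[1]]
  }
  if (is.character(offtarget_set) && length(offtarget_set) == 1L &&
      file.exists(offtarget_set))
    offtarget_set <- read_transcripts(offtarget_set)
  cand <- enumerate_candidates(mrna_seq)
  n0 <- nrow(cand)
  trails <- lapply(cand$antisense_seq, functionality_filter, rules = rules)
  cand$filter_pass <- vapply(trails, attr, logical(1), "pass")
  cand$failed_rules <- vapply(trails, function(tr)
    paste(tr$rule[!tr$pass], collapse = ","), character(1))
  if (drop_failing) cand <- cand[cand$filter_pass, , drop = FALSE]
  n_filtered <- n0 - nrow(cand)
  if (nrow(cand) == 0L) {
    out <- cbind(cand, predicted_efficacy = numeric(0),
                 toxicity_label = logical(0), offtarget_label = logical(0),
                 rank = integer(0))
    attr(out, "summary") <- list(candidates = n0, failed_filter = n_filtered,
                                 reported = 0L)
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }
  # context windows + prediction
  ds <- cand
  ds$window_seq <- vapply(seq_len(nrow(cand)), function(i)
    extract_context(mrna_seq, cand$site_start[i], cand$site_end[i])$window_seq,
    character(1))
  ds$norm_efficacy <- 0; ds$label <- 0L
  cand$predicted_efficacy <- predict(fit, ds, engine = engine)
  # toxicity: immune motifs on either strand, toxic seed
  motif_hits <- lapply(cand$antisense_seq, immune_motif_scan)
  cand$immune_motifs <- vapply(motif_hits, function(h)
    paste(unique(h$motif), collapse = ","), character(1))
  seed_flag <- vapply(cand$antisense_seq, function(s)
    as.logical(toxic_seed_filter(s, blacklist)), logical(1))
  cand$toxic_seed <- seed_flag
  cand$toxicity_label <- nzchar(cand$immune_motifs) | seed_flag
  # off-target: best PITA-style ddG over the interested set
  if (!is.null(offtarget_set) && length(offtarget_set)) {
    best <- vapply(cand$antisense_seq, function(g) {
      ddgs <- vapply(offtarget_set, function(tr) {
        r <- pita_like_ddg(g, tr, engine = engine)
        if (nrow(r)) r$ddg[1] else NA_real_
      }, numeric(1))
      if (all(is.na(ddgs))) NA_real_ else min(ddgs, na.rm = TRUE)
    }, numeric(1))
    cand$pita_ddg <- unname(best)
    cand$offtarget_label <- !is.na(best) & best <= pita_threshold
  } else {
    cand$pita_ddg <- NA_real_
    cand$offtarget_label <- FALSE
  }
  ord <- order(-cand$predicted_efficacy, cand$site_start)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "summary") <- list(candidates = n0, failed_filter = n_filtered,
                                toxic = sum(cand$toxicity_label),
                                offtarget = sum(cand$offtarget_label),
                                reported = nrow(cand))
  attr(cand, "transcript_id") <- transcript_id
  class(cand) <- c("candidate_report", "data.frame")
  cand
}

#' @export
print.candidate_report <- function(x, n = 10L, ...) {
  s <- attr(x, "summary")
  cat("siRNA candidate report for '", attr(x, "transcript_id") %||% "target",
      "': ", s$reported, " ranked (", s$candidates, " scanned, ",
      s$failed_filter, " failed filters, ", s$toxic %||% 0L, " toxicity-labelled, ",
      s$offtarget %||% 0L, " off-target-labelled)\n", sep = "")
  print.data.frame(utils::head(x[, c("rank", "site_start", "antisense_seq",
                                     "predicted_efficacy", "toxicity_label",
                                     "offtarget_label")], n), row.names = FALSE)
  invisible(x)
}

#' Write a candidate report as TSV and BED6
#'
#' @param report A `candidate_report`.
#' @param tsv_path Output TSV (all columns).
#' @param bed_path Optional BED6 of target sites (score = 1000 x predicted
#'   efficacy, rounded).
#' @return `tsv_path`, invisibly.
#' @export
write_candidate_report <- function(report, tsv_path, bed_path = NULL) {
  utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = attr(report, "transcript_id") %||% "target",
                      start = report$site_start, end = report$site_end,
                      name = report$antisense_seq,
                      score = round(1000 * report$predicted_efficacy),
                      strand = "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
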