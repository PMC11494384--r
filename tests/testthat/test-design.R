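ns <- asNamespace("sirnadesign")

test_that("candidate enumeration is exhaustive with step 1", {
  expect_equal(nrow(enumerate_candidates(random_rna(1, 19, seed = 1))), 1L)
  tx <- random_rna(1, 100, seed = 2)
  cand <- enumerate_candidates(tx)
  expect_equal(nrow(cand), 82L)
  for (i in c(1, 40, 82)) {
    expect_equal(cand$window_seq[i], substr(tx, i, i + 18))
    expect_equal(cand$antisense_seq[i], rna_revcomp(cand$window_seq[i]))
    expect_equal(cand$site_end[i] - cand$site_start[i], 19L)
  }
  expect_error(enumerate_candidates("ACGU"), "shorter")
  # property: count is always L - 18
  set.seed(3)
  for (L in sample(19:400, 10))
    expect_equal(nrow(enumerate_candidates(random_rna(1, L))), L - 18L)
})

test_that("functionality rules evaluate independently with stable ids", {
  tr <- functionality_filter("GCGCGCGCGCGCGCGCGCG")
  expect_false(tr$pass[tr$rule == "gc_range"])
  expect_false(attr(tr, "pass"))
  tr2 <- functionality_filter("ACGUACGUACGUACGUACG")
  expect_true(attr(tr2, "pass"))
  expect_false(attr(functionality_filter(strrep("A", 19)), "pass"))  # run rule
  # literal mirror palindrome of >= 7
  pal <- paste0("ACGUGCA", random_rna(1, 12, seed = 4))
  expect_false(functionality_filter(pal)$pass[3])
  expect_true(attr(functionality_filter("GGGGGGGGGGGGGGGGGGG", list()), "pass"))
  expect_error(functionality_filter("ACGUACGUACGUACGUACG",
                                    list(nonsense = list())), "unknown filter rule")
})

test_that("immune motifs are found on either strand with all offsets", {
  hit <- immune_motif_scan(paste0("UGUGU", random_rna(1, 14, seed = 5)))
  expect_true(any(hit$motif == "UGUGU" & hit$strand == "antisense" &
                    hit$offset == 0))
  # motif on the passenger strand only
  g <- rna_revcomp(paste0("GUCCUUCA", random_rna(1, 11, seed = 6)))
  hit2 <- immune_motif_scan(g)
  expect_true(any(hit2$motif == "GUCCUUCA" & hit2$strand == "sense"))
  expect_equal(nrow(immune_motif_scan(strrep("A", 19))), 0L)
  # overlapping occurrences are all reported (brute-force cross-check)
  s <- "UGUGUGUGU"
  hits <- immune_motif_scan(s)
  brute <- which(vapply(1:5, function(i) substr(s, i, i + 4) == "UGUGU",
                        logical(1))) - 1L
  expect_setequal(hits$offset[hits$motif == "UGUGU" & hits$strand == "antisense"],
                  brute)
})

test_that("toxic seeds are matched exactly at guide positions 2-8", {
  g <- random_rna(1, 19, seed = 7)
  seed7 <- substr(g, 2, 8)
  expect_true(as.logical(toxic_seed_filter(g, seed7)))
  expect_false(as.logical(toxic_seed_filter(g, character(0))))
  near <- paste0(substr(seed7, 1, 6), setdiff(c("A", "C", "G", "U"),
                                              substr(seed7, 7, 7))[1])
  expect_false(as.logical(toxic_seed_filter(g, near)))
  f <- withr::local_tempfile()
  writeLines(c("# comment", seed7, "ACGU"), f)
  expect_error(load_seed_blacklist(f), "malformed blacklist line 3")
  writeLines(c(seed7, "uaacgua"), f)
  expect_equal(load_seed_blacklist(f), c(seed7, "UAACGUA"))
})

test_that("site-accessibility scoring reduces to duplex energy without structure", {
  g <- gen_offtarget_fixture(seed = 8)$guide   # site free of self-structure
  tx <- paste0(strrep("A", 30), rna_revcomp(g), strrep("A", 30))
  res <- pita_like_ddg(g, tx, engine = naive_fold_engine())
  expect_equal(nrow(res), 1L)
  expect_equal(res$dg_open, 0)          # degenerate engine: no opening cost
  expect_equal(res$ddg, res$dg_duplex)
  expect_equal(res$paired_len, 19L)
  expect_equal(res$dg_duplex, duplex_dg(g))
  # no seed match: empty result, not an error
  expect_equal(nrow(pita_like_ddg(strrep("A", 19), strrep("G", 100),
                                  engine = naive_fold_engine())), 0L)
})

test_that("a site buried in a hairpin stem scores strictly less favorably", {
  fx <- gen_offtarget_fixture(seed = 3)
  eng <- rnafold_engine()
  stem <- pita_like_ddg(fx$guide, fx$stem[[1]], engine = eng)
  open <- pita_like_ddg(fx$guide, fx$unpaired[[1]], engine = eng)
  expect_equal(stem$site_start[1], open$site_start[1])
  expect_lt(stem$dg_open[1], 0)
  expect_equal(open$dg_open[1], 0, tolerance = 0.5)
  expect_gt(stem$ddg[1], open$ddg[1])
})

test_that("external off-target scores join by sequence with last-wins policy", {
  cand <- data.frame(antisense_seq = random_rna(3, 19, seed = 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tscore",
               paste(cand$antisense_seq[1], -0.2, sep = "\t"),
               paste(cand$antisense_seq[2], -0.1, sep = "\t"),
               paste(cand$antisense_seq[1], -0.5, sep = "\t")), f)
  expect_warning(out <- suppressMessages(external_offtarget_adapter(cand, f)),
                 "last occurrence wins")
  expect_equal(out$external_score, c(-0.5, -0.1, NA))
  writeLines("no header here", f)
  expect_error(suppressWarnings(external_offtarget_adapter(cand, f)), "columns")
})

test_that("the design pipeline ranks all candidates under a constant model", {
  # zero-weight model scores every candidate 0.5: with filters disabled the
  # report must contain all L-18 candidates, tie-broken by position
  cfg <- tiny_config()
  set.seed(10)
  p <- init_params(cfg)
  zero <- function(x) if (is.matrix(x)) x * 0 else lapply(x, zero)
  fit <- structure(list(params = zero(p), config = cfg,
                        scaling = list(thermo = list(center = rep(0, 26),
                                                     scale = rep(1, 26)),
                                       pre = list(center = rep(0, 32),
                                                  scale = rep(1, 32))),
                        embedding_source = "fallback", cache_dir = NULL),
                   class = "sirna_fit")
  tx <- random_rna(1, 80, seed = 11)
  rep_ <- design_sirna(fit, tx, rules = list(), drop_failing = FALSE,
                       engine = naive_fold_engine())
  expect_equal(nrow(rep_), 80L - 18L)
  expect_equal(rep_$predicted_efficacy, rep(0.5, 62))
  expect_equal(rep_$site_start, 0:61)          # ties resolved by position
  expect_equal(rep_$rank, 1:62)
  s <- attr(rep_, "summary")
  expect_equal(s$candidates, 62L)
  expect_equal(s$failed_filter, 0L)
})

test_that("toxicity and off-target labels never alter predicted efficacy", {
  ds <- fixture("ds_train", toy_dataset(200, seed = 31))
  fit <- fixture("fit_train",
                 sirna_fit(ds, tiny_config(), epochs = 5, seed = 2,
                           batch_size = 50, engine = naive_fold_engine()))
  tx <- random_rna(1, 70, seed = 12)
  base <- design_sirna(fit, tx, rules = list(), drop_failing = FALSE,
                       engine = naive_fold_engine())
  seeds <- substr(base$antisense_seq, 2, 8)
  flagged <- design_sirna(fit, tx, rules = list(), drop_failing = FALSE,
                          blacklist = seeds, engine = naive_fold_engine())
  expect_true(all(flagged$toxicity_label))
  expect_equal(flagged$predicted_efficacy[order(flagged$site_start)],
               base$predicted_efficacy[order(base$site_start)])
  # report writers
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_candidate_report(base, tsv, bed)
  bed_df <- utils::read.table(bed, sep = "\t")
  expect_equal(nrow(bed_df), nrow(base))
  expect_true(all(bed_df$V3 - bed_df$V2 == 19))
})
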