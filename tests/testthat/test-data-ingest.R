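test_that("efficacy tables are read, cleaned and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("seq,target,inhib",
               "ACGTACGTACGTACGTACG,tx1,55",
               "acguacguacguacguacg,tx1,80",
               "ACGNACGUACGUACGUACG,tx2,10"), f)
  schema <- list(antisense = "seq", inhibition = "inhib", transcript_id = "target")
  recs <- suppressMessages(read_efficacy_table(f, schema))
  expect_equal(nrow(recs), 2L)  # N-containing row excluded
  expect_equal(recs$antisense_seq[1], "ACGUACGUACGUACGUACG")  # T -> U, upper
  excl <- attr(recs, "excluded")
  expect_equal(excl$reason, "non-ACGU character")
  expect_error(read_efficacy_table(f, list(antisense = "nope", inhibition = "inhib")),
               "schema error")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("seq,target,inhib", f2)
  expect_error(suppressWarnings(read_efficacy_table(f2, schema)), "empty")
})

test_that("row count is preserved for clean tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  seqs <- random_rna(5, 19, seed = 1)
  writeLines(c("antisense\tinhibition", paste(seqs, 10 * 1:5, sep = "\t")), f)
  expect_equal(nrow(read_efficacy_table(f)), 5L)
})

test_that("siRNA harmonization truncates the 3'-overhang and rejects odd lengths", {
  s19 <- random_rna(1, 19, seed = 2)
  expect_identical(harmonize_sirna(s19), s19)
  expect_identical(harmonize_sirna("AAAAAAAAAAAAAAAAAAAGG"),
                   strrep("A", 19))
  expect_error(harmonize_sirna(random_rna(1, 20)), "unsupported")
})

test_that("normalization scales by dataset maximum and labels at the threshold", {
  df <- data.frame(raw_inhibition = c(50, 80, 100), source_dataset = "d1")
  out <- normalize_and_label(df, 0.70)
  expect_equal(out$norm_efficacy, c(0.5, 0.8, 1.0))
  expect_equal(out$label, c(0L, 1L, 1L))
  # single record normalizes to its own maximum
  one <- normalize_and_label(data.frame(raw_inhibition = 42,
                                        source_dataset = "x"))
  expect_equal(one$norm_efficacy, 1)
  expect_equal(one$label, 1L)
  # threshold tie counts positive
  tie <- normalize_and_label(data.frame(raw_inhibition = c(70, 100),
                                        source_dataset = "x"))
  expect_equal(tie$label, c(1L, 1L))
  expect_error(normalize_and_label(data.frame(raw_inhibition = c(-5, 0),
                                              source_dataset = "x")),
               "non-positive")
})

test_that("normalization is invariant to uniform rescaling of raw values", {
  set.seed(3)
  raw <- runif(30, 10, 90)
  a <- normalize_and_label(data.frame(raw_inhibition = raw, source_dataset = "d"))
  b <- normalize_and_label(data.frame(raw_inhibition = 7.3 * raw, source_dataset = "d"))
  expect_equal(a$norm_efficacy, b$norm_efficacy)
  expect_identical(a$label, b$label)
})

test_that("complementary sites are located with 0-based half-open coordinates", {
  tx <- random_rna(1, 120, seed = 4)
  anti <- rna_revcomp(substr(tx, 11, 29))    # 0-based [10, 29)
  site <- locate_site(anti, tx)
  expect_equal(site$site_start, 10L)
  expect_equal(site$site_end, 29L)
  expect_error(locate_site(strrep("A", 19), paste0(strrep("G", 50))),
               "site not found")
  # two planted sites: first returned, both reported
  core <- random_rna(1, 19, seed = 5)
  tx2 <- paste0(strrep("G", 5), core, strrep("G", 16), core, strrep("G", 5))
  expect_warning(site2 <- locate_site(rna_revcomp(core), tx2),
                 "multiple complementary sites")
  expect_equal(site2$site_start, 5L)
  expect_equal(site2$n_matches, 2L)
})

test_that("context windows are 57 nt with X padding at transcript edges", {
  tx <- random_rna(1, 300, seed = 6)
  ctx <- extract_context(tx, 100, 119)
  expect_equal(nchar(ctx$window_seq), 57L)
  expect_equal(c(ctx$pad5, ctx$pad3), c(0L, 0L))
  expect_equal(ctx$window_seq, substr(tx, 82, 138))
  lo <- extract_context(tx, 0, 19)
  expect_equal(lo$pad5, 19L)
  expect_equal(substr(lo$window_seq, 1, 19), strrep("X", 19))
  hi <- extract_context(tx, 281, 300)
  expect_equal(hi$pad3, 19L)
})

test_that("stripping X from a window reproduces the transcript slice exactly", {
  set.seed(8)
  for (i in 1:1000) {
    L <- sample(57:200, 1)
    tx <- random_rna(1, L)
    s0 <- sample(0:(L - 19L), 1)
    ctx <- extract_context(tx, s0, s0 + 19L)
    stripped <- gsub("X", "", ctx$window_seq)
    lo <- max(0, s0 - 19)
    hi <- min(L, s0 + 19 + 19)
    expect_identical(stripped, substr(tx, lo + 1, hi))
  }
})

test_that("NW identity matches hand cases and is symmetric", {
  s <- random_rna(1, 19, seed = 9)
  expect_equal(as.numeric(nw_identity(s, s)), 100)
  expect_equal(as.numeric(nw_identity("AAAA", "UUUU")), 0)
  expect_equal(as.numeric(nw_identity("ACGU", "ACGG")), 75)
  set.seed(10)
  for (i in 1:20) {
    a <- random_rna(1, sample(3:12, 1)); b <- random_rna(1, sample(3:12, 1))
    expect_equal(as.numeric(nw_identity(a, b)), as.numeric(nw_identity(b, a)))
  }
  expect_error(nw_identity("", "ACGU"), "empty")
})

test_that("NW alignment agrees with the exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:40) {
    a <- random_rna(1, sample(1:8, 1))
    b <- random_rna(1, sample(1:8, 1))
    ora <- nw_oracle(a, b)
    got <- nw_identity(a, b)
    aln <- attr(got, "alignment")
    # our alignment achieves the optimal score
    ach <- sum(ifelse(strsplit(aln[1], "")[[1]] == "-" |
                        strsplit(aln[2], "")[[1]] == "-", -1,
                      ifelse(strsplit(aln[1], "")[[1]] ==
                               strsplit(aln[2], "")[[1]], 1, 0)))
    expect_equal(ach, ora$score)
    expect_equal(as.numeric(got), ora$identity)
  }
})

test_that("dedup removes only training sequences above the identity cutoff", {
  set.seed(12)
  train <- random_rna(12, 19)
  test <- random_rna(6, 19)
  kept <- deduplicate(train, test)
  expect_true(length(kept) >= 10)  # random 19-mers rarely reach 80%
  # exact copy is removed
  kept2 <- deduplicate(c(train, test[1]), test)
  expect_false(test[1] %in% kept2)
  expect_true(test[1] %in% attr(kept2, "removals")$train_seq)
  # identity of exactly the cutoff is retained (strictly-greater rule)
  a <- "AAAAAAAACC"; b <- "AAAAAAAAGG"   # 8/10 = 80%
  expect_equal(as.numeric(nw_identity(a, b)), 80)
  expect_identical(deduplicate(a, b, identity_cutoff = 80), a)
})

test_that("fold assignment is stratified, balanced and deterministic", {
  labels <- rep(c(0L, 1L), each = 5)
  f1 <- make_folds(labels, k = 5, seed = 99)
  f2 <- make_folds(labels, k = 5, seed = 99)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(f1) == 2))
  # balanced classes: every fold sees both labels
  labels2 <- rep(c(0L, 1L), 25)
  f3 <- make_folds(labels2, k = 5, seed = 1)
  tab <- table(f3, labels2)
  expect_true(all(tab > 0))
  expect_true(max(table(f3)) - min(table(f3)) <= 1)
  # union is everything, folds disjoint (one assignment per record)
  expect_equal(length(f3), length(labels2))
  expect_error(make_folds(c(0, 1), k = 5, seed = 1), "fewer records")
})
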