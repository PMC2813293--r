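test_that("aligner scores equal the brute-force Gotoh oracle on short instances", {
  set.seed(11)
  for (rep in 1:40) {
    La <- sample(5:30, 1)
    a <- random_seq(La)
    b <- switch(sample(3, 1),
                mutate_seq(a, sample(0:3, 1)),                      # subs only
                paste0(substr(a, 1, La %/% 2), random_seq(sample(1:6, 1)),
                       substr(a, La %/% 2 + 1, La)),                 # insertion
                random_seq(sample(5:30, 1)))                         # unrelated
    expect_equal(align_clone(a, b)$score, gotoh_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scoring arithmetic matches the scheme", {
  s <- random_seq(60)
  al <- align_clone(s, s)
  expect_equal(al$score, 60)
  expect_false(grepl("-", al$pattern))

  m1 <- mutate_seq(s, 1)
  expect_equal(align_clone(m1, s)$score, 58)  # L - 2 for one mismatch

  withins <- paste0(substr(s, 1, 30), "GCAAGG", substr(s, 31, 60))
  al2 <- align_clone(withins, s)
  expect_equal(al2$score, 60 - 11)            # one 6-long gap costs 5 + 6
  ind <- alignment_indels(al2)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$type, "insertion")
  expect_equal(ind$length, 6L)

  expect_error(align_clone("", s), "non-empty")
  expect_error(align_clone("ACGU", s), "ACGTN")
})

test_that("indels are canonicalized to their 3'-most position", {
  # insertion of "A" in a run of As can sit anywhere; 3' rule fixes it
  ref <- "CCGAAAATCC"
  clone <- "CCGAAAAATCC"  # one extra A in the A-run (ref pos 4-7)
  ind <- alignment_indels(align_clone(clone, ref))
  expect_equal(nrow(ind), 1)
  expect_equal(ind$length, 1L)
  expect_equal(ind$ref_pos, 7L)  # after the last A of the run
})

test_that("splice-isoform classification recovers generator truth without error", {
  m <- ref_model
  prof <- generate_individual(m, "iT", geno_rs4290270 = "TT", seed = 2)
  params <- generation_params(n_clones = 60, splice_fraction_b = 0.5,
                              edit_prob_a = c(0.3, 0.3, 0.3, 0.3),
                              edit_prob_b = c(0.8, 0.9, 0.9, 0.9),
                              error_rate = 0)
  lib <- generate_clone_library(m, prof, "amygdala", params, seed = 12)
  cls <- classify_clones(lib$clones, m)
  expect_identical(cls$isoform, lib$truth$isoform)
  expect_true(all(cls$margin >= 11))

  # single-clone wrapper agrees
  one <- classify_splice_isoform(lib$clones[[1]], m)
  expect_equal(one$isoform, lib$truth$isoform[1])

  # a clone truncated before the decision window is unclassified
  trunc <- substr(transcript_seq(m, "a"), 1, nchar(ref_model$utr5) + 400)
  expect_equal(classify_splice_isoform(trunc, m)$isoform, "unclassified")

  # reverse-complemented clones are recognized via the retry
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lib$clones[[1]])))
  cls_rc <- classify_clones(stats::setNames(rc, "rc"), m)
  expect_equal(cls_rc$isoform, lib$truth$isoform[1])
  expect_true(cls_rc$revcomp)
})

test_that("fast-path classification agrees with the full dynamic program", {
  m <- ref_model
  ta <- transcript_seq(m, "a")
  tb <- transcript_seq(m, "b")
  set.seed(21)
  for (rep in 1:6) {
    iso <- sample(c("a", "b"), 1)
    clone <- mutate_seq(if (iso == "a") ta else tb, sample(0:4, 1))
    fast <- classify_clones(stats::setNames(clone, "x"), m)
    sub <- align_clone(clone, ta)
    expect_equal(fast$score_a, sub$score)
    expect_equal(fast$score_b, align_clone(clone, tb)$score)
    expect_equal(fast$isoform, iso)
  }
})

test_that("variant calling returns exactly the applied variant set", {
  m <- ref_model
  pv <- pattern_variants(m, "a", 1:4)
  clone <- apply_variants(m, "a", pv)
  calls <- call_variants(clone, m, "a")
  expect_setequal(calls$c_pos, c(-42L, 711L, 1297L, 1322L))
  expect_true(all(calls$in_catalogue))
  expect_setequal(calls$editing_index, 1:4)

  expect_equal(nrow(call_variants(transcript_seq(m, "a"), m, "a")), 0)

  # partial b pattern, called in the b frame
  pvb <- pattern_variants(m, "b", c(2, 3, 4))
  cb <- call_variants(apply_variants(m, "b", pvb), m, "b")
  expect_setequal(cb$c_pos, c(804L, 830L, 1403L))
  expect_true(all(cb$in_catalogue))

  # one random error produces exactly one non-catalogue call
  set.seed(31)
  noisy <- mutate_seq(transcript_seq(m, "a"), 1)
  cn <- call_variants(noisy, m, "a")
  expect_equal(nrow(cn), 1)
  expect_false(cn$in_catalogue)

  # N bases never generate calls
  withN <- transcript_seq(m, "a")
  substr(withN, 100, 100) <- "N"
  expect_equal(nrow(call_variants(withN, m, "a")), 0)
})

test_that("QC filter tolerates Sanger-scale error loads", {
  expect_true(qc_filter(0))
  expect_true(qc_filter(5))
  expect_false(qc_filter(6))

  # at 1e-3 error over ~1.5 kb, expected mismatches ~1.5; >95% must pass
  m <- ref_model
  prof <- generate_individual(m, "iT", geno_rs4290270 = "TT", seed = 2)
  params <- generation_params(n_clones = 300, error_rate = 1e-3)
  lib <- generate_clone_library(m, prof, "ctx", params, seed = 13)
  ann <- annotate_clones(lib$clones, m)
  expect_gt(mean(ann$annotations$qc_pass), 0.95)
  # and the observed rs4290270 allele is reported
  expect_true(all(ann$annotations$allele_rs4290270 %in% c("A", "C", "G", "T")))
})
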