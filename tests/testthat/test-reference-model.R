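test_that("surrogate reference satisfies every catalogue constraint", {
  m <- ref_model
  expect_equal(nchar(m$cds_a) %% 3, 0)
  expect_equal(nchar(m$cds_b), nchar(m$cds_a) + 6)
  expect_equal(m$insertion$seq, "GCAAGG")
  expect_equal(m$insertion$after_c_pos, 439L)

  # every catalogue position carries its stated reference base
  for (i in seq_len(nrow(m$catalogue))) {
    row <- m$catalogue[i, ]
    iso <- if (row$scope == "b") "b" else "a"
    idx <- c_to_transcript(m, row$c_pos, iso)
    expect_equal(substr(transcript_seq(m, iso), idx, idx), row$ref)
  }

  # codon-level guarantees behind the printed consequences
  expect_equal(substr(m$cds_a, 385, 387), "CAA")        # Gln, C first base
  expect_equal(substr(m$cds_a, 1322, 1322), "G")        # G at codon-441 pos 2

  # removing the insertion from cds_b restores cds_a exactly
  restored <- paste0(substr(m$cds_b, 1, 439), substr(m$cds_b, 446, nchar(m$cds_b)))
  expect_identical(restored, m$cds_a)

  # the eight editing sites split 4/4 between the two scopes
  ed <- m$catalogue[m$catalogue$class == "editing", ]
  expect_equal(nrow(ed), 8)
  expect_equal(sum(ed$scope == "a"), 4)
  expect_equal(sum(ed$scope == "b"), 4)
  expect_true(all(!is.na(ed$editing_index)))
  expect_true(all(is.na(m$catalogue$editing_index[m$catalogue$class == "snp"])))
})

test_that("catalogue conflicts and empty catalogues are handled", {
  empty <- build_reference(catalogue = tph2_catalogue()[0, ])
  expect_s3_class(empty, "tph2_reference")
  expect_equal(nrow(empty$catalogue), 0)

  conflicted <- rbind(tph2_catalogue(),
                      data.frame(c_pos = 711L, ref = "C", alt = "G",
                                 scope = "a", class = "editing",
                                 editing_index = 2L, rs_id = NA))
  expect_error(build_reference(catalogue = conflicted), "conflict")
})

test_that("coding coordinate arithmetic is exact", {
  expect_equal(c_to_codon(1), list(codon = 1L, offset = 1L))
  expect_equal(c_to_codon(385)$codon, 129L)
  expect_equal(c_to_codon(385)$offset, 1L)
  expect_equal(c_to_codon(1322)$codon, 441L)
  expect_equal(c_to_codon(1322)$offset, 2L)
  expect_error(c_to_codon(0), "codon")
  expect_error(c_to_codon(-42), "codon")

  # identity 3*(codon-1) + offset = c_pos over the whole CDS
  pos <- seq_len(nchar(ref_model$cds_a))
  cc <- c_to_codon(pos)
  expect_true(all(3 * (cc$codon - 1) + cc$offset == pos))

  # frame conversion round trips outside the insertion
  p <- c(1L, 439L, 440L, 936L, 1125L)
  expect_equal(b_to_a_pos(a_to_b_pos(p)), p)
  expect_true(all(is.na(b_to_a_pos(440:445))))
  expect_equal(a_to_b_pos(440L), 446L)

  # transcript index mapping and its inverse, both frames
  m <- ref_model
  for (iso in c("a", "b")) {
    cp <- c(-42L, -1L, 1L, 439L, 900L)
    idx <- c_to_transcript(m, cp, iso)
    expect_equal(transcript_to_c(m, idx, iso), cp)
  }
  expect_error(c_to_transcript(m, 0L, "a"), "0")
})

test_that("apply_variants substitutes, round trips, and enforces scope", {
  m <- ref_model
  expect_identical(apply_variants(m, "a", NULL), transcript_seq(m, "a"))

  pv <- pattern_variants(m, "a", 1:4)
  edited <- apply_variants(m, "a", pv)
  refseq <- transcript_seq(m, "a")
  diffs <- which(strsplit(edited, "")[[1]] != strsplit(refseq, "")[[1]])
  expect_length(diffs, 4)
  expect_setequal(transcript_to_c(m, diffs, "a"), pv$c_pos)

  # reverse substitution restores the reference exactly
  back <- edited
  for (i in seq_len(nrow(pv))) {
    idx <- c_to_transcript(m, pv$c_pos[i], "a")
    substr(back, idx, idx) <- pv$ref[i]
  }
  expect_identical(back, refseq)

  expect_error(apply_variants(m, "b", pattern_variants(m, "a", 1)),
               "mutual-exclusivity")
  bad <- pattern_variants(m, "a", 2)
  bad$ref <- "T"
  expect_error(apply_variants(m, "a", bad), "inconsisten")
})

test_that("translation detects premature stops and the 2-residue insertion", {
  m <- ref_model
  a <- translate_cds(m$cds_a)
  b <- translate_cds(m$cds_b)
  expect_true(is.na(a$premature_stop_codon))
  expect_true(is.na(b$premature_stop_codon))
  expect_equal(nchar(b$protein), nchar(a$protein) + 2)

  # nonsense editing at TPH2b position 1 truncates at codon 129
  seqb <- apply_variants(m, "b", pattern_variants(m, "b", 1))
  cds_b_edited <- substr(seqb, nchar(m$utr5) + 1, nchar(seqb))
  tr <- translate_cds(cds_b_edited)
  expect_equal(tr$premature_stop_codon, 129L)
  expect_equal(nchar(tr$protein), 128)

  expect_equal(translate_cds("ATGTAA"),
               list(protein = "M", premature_stop_codon = NA_integer_))
  expect_error(translate_cds("ATGXAA"), "invalid")
  expect_error(translate_cds("ATGT"), "divisible")
})

test_that("donor-site scan finds the alternative GT downstream of GC", {
  expect_equal(scan_donor_sites(ref_model$intron3_context),
               list(primary_dinucleotide = "GC", alternative_gt_offset = 6L))
  expect_equal(scan_donor_sites("GTAAGTAA"),
               list(primary_dinucleotide = "GT",
                    alternative_gt_offset = NA_integer_))
  expect_equal(scan_donor_sites("GCAAAAAA"),
               list(primary_dinucleotide = "GC",
                    alternative_gt_offset = NA_integer_))
  expect_equal(scan_donor_sites("GCGTAAAA")$alternative_gt_offset, 2L)
  expect_error(scan_donor_sites("GCAAGG"), "8 nt")
})
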