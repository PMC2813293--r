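test_that("site classification separates edits, genomic alleles and discordance", {
  # c.1322 G>A on a G/G genome: RNA edit with G>A chemistry
  cls <- classify_site(1322, "G", "A", "a", c("G", "G"))
  expect_equal(cls$verdict, "rna_edit")
  expect_equal(cls$chemistry, "G>A")

  # observed T at heterozygous rs4290270: genomic allele, not an edit
  cls2 <- classify_site(1125, "A", "T", "a", c("A", "T"))
  expect_equal(cls2$verdict, "genomic_allele")
  expect_true(is.na(cls2$chemistry))

  # c.-42 T>C on T/T genome: the rare U>C chemistry
  cls3 <- classify_site(-42, "T", "C", "a", c("T", "T"))
  expect_equal(cls3$verdict, "rna_edit")
  expect_equal(cls3$chemistry, "U>C")

  # observed base matching neither genome allele nor hom-ref: discordant
  expect_equal(classify_site(711, "A", "G", "a", c("A", "C"))$verdict,
               "discordant")
  # missing genomic data is never guessed
  expect_equal(classify_site(711, "A", "G", "a", c(NA, NA))$verdict,
               "unclassifiable")
  # idempotence
  expect_identical(classify_site(1322, "G", "A", "a", c("G", "G")),
                   classify_site(1322, "G", "A", "a", c("G", "G")))
})

test_that("the catalogue exercises all four mammalian editing chemistries", {
  ed <- ref_model$catalogue[ref_model$catalogue$class == "editing", ]
  chem <- edit_chemistry(ed$ref, ed$alt)
  expect_true(all(chem %in% c("A>I", "C>U", "U>C", "G>A")))
  expect_setequal(unique(chem), c("A>I", "C>U", "U>C", "G>A"))
  expect_equal(edit_chemistry("A", "C"), "other")
})

test_that("pattern labels are deterministic and flag exclusivity violations", {
  expect_equal(assign_pattern("b", c(2, 3, 4))$label, "TPH2b 234")
  expect_equal(assign_pattern("a", integer(0))$label, "TPH2a unedited")
  expect_equal(assign_pattern("a", c(4, 1, 3, 2))$label, "TPH2a 1234")
  expect_false(assign_pattern("a", 1:4)$exclusivity_violation)
  expect_true(assign_pattern("b", 2, cross_scope_edit = TRUE)$exclusivity_violation)
  expect_error(assign_pattern("a", 5))
})

test_that("consequences derive from codon substitution, never stored strings", {
  m <- ref_model
  expect_equal(annotate_consequence(m, 385, "T", "b"),
               list(consequence = "nonsense", protein_change = "Q129X"))
  expect_equal(annotate_consequence(m, 711, "G", "a")$consequence, "synonymous")
  expect_equal(annotate_consequence(m, -42, "C", "a")$consequence, "utr")
  expect_equal(annotate_consequence(m, 830, "T", "b"),
               list(consequence = "missense", protein_change = "P277L"))
  expect_equal(annotate_consequence(m, 1297, "G", "a")$protein_change, "R433G")
  expect_equal(annotate_consequence(m, 1322, "A", "a")$protein_change, "R441H")
  expect_equal(annotate_consequence(m, 804, "G", "b")$consequence, "synonymous")
  # the b-frame c.1403 edit is a Gln-to-Arg missense
  expect_equal(annotate_consequence(m, 1403, "G", "b")$consequence, "missense")
  expect_match(annotate_consequence(m, 1403, "G", "b")$protein_change, "^Q\\d+R$")
})

test_that("discriminator recovers truth patterns exactly on error-free data", {
  m <- ref_model
  prof <- generate_individual(m, "iT", group = "control",
                              geno_rs4290270 = "TT", seed = 4)
  params <- generation_params(n_clones = 80, splice_fraction_b = 0.5,
                              edit_prob_a = c(0.4, 0.4, 0.4, 0.4),
                              edit_prob_b = c(0.7, 0.9, 0.9, 0.9),
                              error_rate = 0)
  lib <- generate_clone_library(m, prof, "amygdala", params, seed = 5)
  ann <- annotate_clones(lib$clones, m)
  disc <- discriminate_clones(ann, m, list(iT = prof), lib$manifest)

  merged <- merge(lib$truth, disc$patterns, by = "clone_id")
  expect_equal(nrow(merged), 80)
  expect_identical(merged$isoform.x, merged$isoform.y)
  expect_identical(norm_indices(merged$edited), norm_indices(merged$indices))
  expect_equal(sum(disc$patterns$exclusivity_violation), 0)
  expect_equal(nrow(disc$novel_candidates), 0)
  # every catalogue editing call on this T/T individual is an RNA edit, while
  # the clones' T allele at rs4290270 is recognized as a genomic allele
  ed_sites <- disc$sites[disc$sites$in_catalogue & !is.na(disc$sites$editing_index), ]
  expect_true(all(ed_sites$verdict == "rna_edit"))
  snp_sites <- disc$sites[disc$sites$in_catalogue & is.na(disc$sites$editing_index), ]
  expect_true(all(snp_sites$verdict == "genomic_allele"))
})

test_that("a cross-scope edit raises the exclusivity-violation flag", {
  m <- ref_model
  prof <- generate_individual(m, "iT", geno_rs4290270 = "TT", seed = 4)
  # hand-build a TPH2b clone carrying the a-pattern c.711A>G edit
  seq <- transcript_seq(m, "b")
  idx <- c_to_transcript(m, a_to_b_pos(711L), "b")
  substr(seq, idx, idx) <- "G"
  ann <- annotate_clones(stats::setNames(seq, "x1"), m)
  manifest <- data.frame(clone_id = "x1", individual = "iT",
                         group = "control", region = "amygdala")
  disc <- discriminate_clones(ann, m, list(iT = prof), manifest)
  expect_equal(disc$patterns$isoform, "b")
  expect_true(disc$patterns$exclusivity_violation)
  expect_equal(disc$patterns$label, "TPH2b unedited")
})
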