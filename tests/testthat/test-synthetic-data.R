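test_that("generators are byte-reproducible under a fixed seed", {
  m <- ref_model
  p1 <- generate_individual(m, "i1", geno_rs7305115 = "AG",
                            geno_rs4290270 = "AT", seed = 5)
  p2 <- generate_individual(m, "i1", geno_rs7305115 = "AG",
                            geno_rs4290270 = "AT", seed = 5)
  expect_identical(p1, p2)

  params <- generation_params(n_clones = 15, splice_fraction_b = 0.6,
                              edit_prob_b = c(0.5, 0.5, 0.5, 0.5))
  l1 <- generate_clone_library(m, p1, "amygdala", params, seed = 9)
  l2 <- generate_clone_library(m, p1, "amygdala", params, seed = 9)
  expect_identical(l1, l2)

  k1 <- generate_kinetic_dataset("mm", 100, 1, s_grid = c(10, 50, 200),
                                 noise_cv = 0.1, n_replicates = 3, seed = 2)
  k2 <- generate_kinetic_dataset("mm", 100, 1, s_grid = c(10, 50, 200),
                                 noise_cv = 0.1, n_replicates = 3, seed = 2)
  expect_identical(k1, k2)

  expect_identical(generate_genotype_cohort(0.3, 500, seed = 4),
                   generate_genotype_cohort(0.3, 500, seed = 4))
})

test_that("individual haplotypes carry SNP alleles but never edits", {
  m <- ref_model
  prof <- generate_individual(m, "het", geno_rs7305115 = "AG",
                              geno_rs4290270 = "AT", seed = 1)
  expect_setequal(genomic_genotype(prof, m, 1125L, "a"), c("A", "T"))
  expect_setequal(genomic_genotype(prof, m, 936L, "a"), c("A", "G"))
  # all eight editing-candidate positions are reference homozygous
  ed <- m$catalogue[m$catalogue$class == "editing", ]
  for (i in seq_len(nrow(ed))) {
    iso <- if (ed$scope[i] == "b") "b" else "a"
    gt <- genomic_genotype(prof, m, ed$c_pos[i], iso)
    expect_true(all(gt == ed$ref[i]))
  }
  # positions inside the TPH2b hexamer have no genomic counterpart
  expect_true(all(is.na(genomic_genotype(prof, m, 441L, "b"))))
})

test_that("genotype draws match their frequencies at 3-sigma", {
  freqs <- c(AA = 0.25, AT = 0.5, TT = 0.25)
  g <- draw_genotypes(freqs, 1e4, seed = 42)
  n <- 1e4
  for (gt in names(freqs)) {
    p <- freqs[[gt]]
    expect_lt(abs(mean(g == gt) - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_error(draw_genotypes(c(AA = 0.5, TT = 0.4), 10), "sum to 1")
  expect_identical(draw_genotypes(c(TT = 1), 5), rep("TT", 5))
})

test_that("allele gating suppresses TPH2b and editing on non-permissive alleles", {
  m <- ref_model
  profA <- generate_individual(m, "iA", geno_rs4290270 = "AA", seed = 3)
  params <- generation_params(n_clones = 300, splice_fraction_b = 0.9,
                              edit_prob_a = rep(0.9, 4),
                              edit_prob_b = rep(0.9, 4),
                              gating = TRUE, error_rate = 0)
  lib <- generate_clone_library(m, profA, "amygdala", params, seed = 8)
  expect_true(all(lib$truth$isoform == "a"))
  expect_true(all(lib$truth$edited == ""))
  # no clone carries the insertion
  expect_true(all(nchar(lib$clones) == nchar(transcript_seq(m, "a"))))

  # gating off: the same individual now expresses TPH2b and edits
  params_off <- generation_params(n_clones = 300, splice_fraction_b = 0.9,
                                  edit_prob_b = rep(0.9, 4),
                                  gating = FALSE, error_rate = 0)
  lib_off <- generate_clone_library(m, profA, "amygdala", params_off, seed = 8)
  expect_gt(sum(lib_off$truth$isoform == "b"), 0)
})

test_that("per-position editing probabilities are honoured at 3-sigma", {
  m <- ref_model
  prof <- generate_individual(m, "iT", geno_rs4290270 = "TT", seed = 2)
  probs <- c(0.78, 0.96, 0.96, 0.96)
  params <- generation_params(n_clones = 1000, splice_fraction_b = 1,
                              edit_prob_b = probs, error_rate = 0)
  lib <- generate_clone_library(m, prof, "amygdala", params, seed = 10)
  expect_true(all(lib$truth$isoform == "b"))
  sets <- strsplit(lib$truth$edited, ",")
  for (k in 1:4) {
    frac <- mean(vapply(sets, function(s) as.character(k) %in% s, logical(1)))
    expect_lt(abs(frac - probs[k]), 3 * sqrt(probs[k] * (1 - probs[k]) / 1000))
  }
})

test_that("kinetic data generator matches closed-form velocities", {
  # S = Km gives half-maximal velocity exactly
  d <- generate_kinetic_dataset("mm", km = 100, vmax = 1, s_grid = 100,
                                noise_cv = 0)
  expect_equal(d$v, 0.5)

  # substrate-inhibition with enormous Ki collapses to Michaelis-Menten
  g <- c(10, 30, 100, 300, 600)
  mm <- generate_kinetic_dataset("mm", 50, 1, s_grid = g, noise_cv = 0.05,
                                 seed = 7)
  si <- generate_kinetic_dataset("si", 50, 1, ki = 1e12, s_grid = g,
                                 noise_cv = 0.05, seed = 7)
  expect_equal(mm$v, si$v, tolerance = 1e-6)

  # Haldane optimum at sqrt(Km * Ki)
  s <- seq(1, 1000, by = 0.5)
  v <- si_velocity(s, km = 50, vmax = 1, ki = 200)
  expect_equal(s[which.max(v)], sqrt(50 * 200), tolerance = 0.01)
  expect_lt(v[s == 900], max(v))

  expect_error(generate_kinetic_dataset("si", 50, 1, s_grid = g), "Ki")
  expect_error(generate_kinetic_dataset("mm", -1, 1, s_grid = g), "positive")
})

test_that("genotype cohorts follow Hardy-Weinberg sampling", {
  all_bb <- generate_genotype_cohort(0, 100, seed = 1)
  expect_equal(unname(all_bb), c(0L, 0L, 100L))

  big <- generate_genotype_cohort(0.5, 1e5, seed = 2)
  expect_lt(abs(big[["AB"]] / 1e5 - 0.5), 3 * sqrt(0.25 / 1e5))

  custom <- generate_genotype_cohort(NA, 100, seed = 3, hwe = FALSE,
                                     genotype_probs = c(1, 0, 0))
  expect_equal(unname(custom), c(100L, 0L, 0L))
  expect_error(generate_genotype_cohort(1.5, 10), "\\[0, 1\\]")
})
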