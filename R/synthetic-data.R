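#' Parameters for synthetic clone-library generation
#'
#' Bundles the generation settings for [generate_clone_library()].  Defaults
#' describe an idealized library: clones split evenly between isoforms on
#' permissive alleles, no editing, Sanger-scale sequencing error of 1e-3
#' substitutions per base, and the allele gating rule enabled.
#'
#' The gating rule reflects the observation that TPH2b transcripts and RNA
#' editing occur only on one rs4290270 allele: transcripts originating from
#' the non-permissive allele are always isoform a and never edited.  Which
#' allele is permissive is configurable (`permissive_allele`, default `"T"`),
#' since the allele labelling convention differs between published summaries.
#'
#' @param n_clones Clones per library.
#' @param splice_fraction_b Probability that a transcript from a permissive
#'   allele is spliced as TPH2b.
#' @param edit_prob_a,edit_prob_b Length-4 vectors of per-position editing
#'   probabilities (editing indices 1-4) for TPH2a / TPH2b transcripts.
#' @param gating Logical; apply the allele gating rule.
#' @param permissive_allele rs4290270 allele (`"A"` or `"T"`) on which TPH2b
#'   splicing and editing are possible.
#' @param error_rate Per-base probability of a uniform random substitution
#'   sequencing error.
#' @return A list of class `tph2_genparams`.
#' @export
generation_params <- function(n_clones = 30L, splice_fraction_b = 0.5,
                              edit_prob_a = rep(0, 4), edit_prob_b = rep(0, 4),
                              gating = TRUE, permissive_allele = c("T", "A"),
                              error_rate = 1e-3) {
  permissive_allele <- match.arg(permissive_allele)
  probs <- c(splice_fraction_b, edit_prob_a, edit_prob_b, error_rate)
  if (any(probs < 0 | probs > 1) || length(edit_prob_a) != 4L ||
      length(edit_prob_b) != 4L) {
    stop("probabilities must lie in [0, 1]; edit probability vectors have length 4",
         call. = FALSE)
  }
  structure(list(n_clones = as.integer(n_clones),
                 splice_fraction_b = splice_fraction_b,
                 edit_prob_a = edit_prob_a, edit_prob_b = edit_prob_b,
                 gating = gating, permissive_allele = permissive_allele,
                 error_rate = error_rate),
            class = "tph2_genparams")
}

#' Draw diploid genotypes from genotype frequencies
#'
#' @param freqs Named numeric vector of genotype frequencies (e.g.
#'   `c(AA = 0.25, AT = 0.5, TT = 0.25)`); must sum to 1.
#' @param n Number of individuals to draw.
#' @param seed Optional integer seed.
#' @return Character vector of genotype labels.
#' @export
draw_genotypes <- function(freqs, n, seed = NULL) {
  if (abs(sum(freqs) - 1) > 1e-8 || any(freqs < 0)) {
    stop("genotype frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Generate a synthetic individual with per-allele genomic sequences
#'
#' Creates an individual profile: diploid genotypes at rs7305115 and
#' rs4290270 (either fixed or drawn from supplied frequencies) and the two
#' genomic haplotype sequences of the transcribed exons.  Haplotypes carry the
#' drawn SNP alleles at the catalogue SNP positions and reference bases at all
#' editing-candidate positions (edits are posttranscriptional and never appear
#' genomically).
#'
#' @param model A `tph2_reference`.
#' @param id Individual identifier.
#' @param group Cohort group label (e.g. `"control"`, `"drug_abuse"`,
#'   `"suicide"`, `"schizophrenia"`).
#' @param geno_rs7305115,geno_rs4290270 Two-letter genotype strings (e.g.
#'   `"AT"`), or `NULL` to draw from `freq_rs7305115` / `freq_rs4290270`.
#' @param freq_rs7305115,freq_rs4290270 Named genotype-frequency vectors used
#'   when the corresponding genotype is `NULL`.
#' @param seed Optional integer seed.
#' @return A list of class `tph2_individual` with fields `id`, `group`,
#'   `geno_rs7305115`, `geno_rs4290270` and `haplotypes` (two per-allele
#'   genomic exon sequences in the TPH2a transcript layout).
#' @export
generate_individual <- function(model, id, group = "control",
                                geno_rs7305115 = NULL, geno_rs4290270 = NULL,
                                freq_rs7305115 = c(AA = 1),
                                freq_rs4290270 = c(TT = 1),
                                seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  if (is.null(geno_rs7305115)) geno_rs7305115 <- draw_genotypes(freq_rs7305115, 1L)
  if (is.null(geno_rs4290270)) geno_rs4290270 <- draw_genotypes(freq_rs4290270, 1L)
  al1 <- strsplit(geno_rs7305115, "")[[1]]
  al2 <- strsplit(geno_rs4290270, "")[[1]]
  stopifnot(length(al1) == 2L, length(al2) == 2L)
  cat <- model$catalogue
  snp <- function(rs) cat[!is.na(cat$rs_id) & cat$rs_id == rs, , drop = FALSE]
  s936 <- snp("rs7305115"); s1125 <- snp("rs4290270")
  haplotypes <- lapply(1:2, function(h) {
    seq <- transcript_seq(model, "a")   # genomic exons, a-frame layout
    for (s in list(cbind(s936, allele = al1[h]), cbind(s1125, allele = al2[h]))) {
      if (nrow(s) == 0) next
      if (!s$allele %in% c(s$ref, s$alt)) {
        stop(sprintf("allele %s is neither ref nor alt of %s", s$allele, s$rs_id),
             call. = FALSE)
      }
      idx <- c_to_transcript(model, s$c_pos, "a")
      substr(seq, idx, idx) <- s$allele
    }
    seq
  })
  structure(list(id = id, group = group,
                 geno_rs7305115 = paste(sort(al1), collapse = ""),
                 geno_rs4290270 = paste(sort(al2), collapse = ""),
                 alleles_rs7305115 = al1, alleles_rs4290270 = al2,
                 haplotypes = haplotypes),
            class = "tph2_individual")
}

#' Genomic genotype of an individual at a coding position
#'
#' @param profile A `tph2_individual`.
#' @param model A `tph2_reference`.
#' @param c_pos Signed coding coordinate in the frame of `isoform`.
#' @param isoform Frame in which `c_pos` is expressed; b-frame positions are
#'   projected back to the genomic (a-frame) layout.  Positions inside the
#'   TPH2b-specific hexamer have no genomic counterpart and return `NA`.
#' @return Character vector of the two allelic bases, or `NA`s.
#' @export
genomic_genotype <- function(profile, model, c_pos, isoform = c("a", "b")) {
  isoform <- match.arg(isoform)
  pos_a <- if (isoform == "b" && c_pos > 0) b_to_a_pos(c_pos) else c_pos
  if (is.na(pos_a)) return(c(NA_character_, NA_character_))
  idx <- c_to_transcript(model, pos_a, "a")
  vapply(profile$haplotypes, substr, character(1), start = idx, stop = idx)
}

#' Generate a clone library with an exhaustive truth table
#'
#' Simulates sequencing of `params$n_clones` independent cDNA clones from one
#' individual and brain region.  Each clone is built by (i) drawing its allele
#' of origin uniformly from the diploid genotype, (ii) applying the allele
#' gating rule when enabled (non-permissive rs4290270 allele: isoform a, no
#' edits), (iii) drawing the splice isoform, (iv) drawing each in-scope
#' editing position independently with its per-position probability, and
#' (v) applying uniform random substitution sequencing errors.
#'
#' @param model A `tph2_reference`.
#' @param profile A `tph2_individual`.
#' @param region Brain-region label recorded in the manifest (e.g.
#'   `"amygdala"`).
#' @param params A `tph2_genparams`.
#' @param seed Optional integer seed; a fixed seed makes the library
#'   byte-reproducible.
#' @return A list with `clones` (named character vector of clone sequences),
#'   `manifest` (clone_id, individual, group, region) and `truth` (clone_id,
#'   allele_origin at rs4290270, isoform, comma-separated edited indices,
#'   n_seq_errors).
#' @export
generate_clone_library <- function(model, profile, region, params, seed = NULL) {
  stopifnot(inherits(params, "tph2_genparams"), inherits(profile, "tph2_individual"))
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  n <- params$n_clones
  bases <- c("A", "C", "G", "T")
  cat_a <- pattern_variants(model, "a")
  cat_b <- pattern_variants(model, "b")
  cat <- model$catalogue
  s936 <- cat[!is.na(cat$rs_id) & cat$rs_id == "rs7305115", , drop = FALSE]
  s1125 <- cat[!is.na(cat$rs_id) & cat$rs_id == "rs4290270", , drop = FALSE]

  clone_id <- sprintf("%s_%s_c%04d", profile$id, region, seq_len(n))
  hap_idx <- sample.int(2L, n, replace = TRUE)
  allele <- profile$alleles_rs4290270[hap_idx]
  gated <- params$gating & allele != params$permissive_allele
  isoform <- ifelse(gated, "a",
                    ifelse(stats::runif(n) < params$splice_fraction_b, "b", "a"))
  seqs <- character(n)
  edited <- character(n)
  n_err <- integer(n)
  for (i in seq_len(n)) {
    iso <- isoform[i]
    p <- if (iso == "a") params$edit_prob_a else params$edit_prob_b
    idx_set <- if (gated[i]) integer(0) else which(stats::runif(4) < p)
    pv <- if (iso == "a") cat_a else cat_b
    pv <- pv[pv$editing_index %in% idx_set, , drop = FALSE]
    seq <- apply_variants(model, iso, pv)
    # place the originating haplotype's SNP alleles
    for (s in list(cbind(s936, allele = profile$alleles_rs7305115[hap_idx[i]]),
                   cbind(s1125, allele = allele[i]))) {
      if (nrow(s) == 0 || s$allele == s$ref) next
      pos <- if (iso == "b") a_to_b_pos(s$c_pos) else s$c_pos
      t_idx <- c_to_transcript(model, pos, iso)
      substr(seq, t_idx, t_idx) <- s$allele
    }
    # uniform substitution errors
    L <- nchar(seq)
    k <- stats::rbinom(1L, L, params$error_rate)
    if (k > 0) {
      at <- sample.int(L, k)
      for (j in at) {
        old <- substr(seq, j, j)
        substr(seq, j, j) <- sample(setdiff(bases, old), 1L)
      }
    }
    seqs[i] <- seq
    edited[i] <- paste(idx_set, collapse = ",")
    n_err[i] <- k
  }
  names(seqs) <- clone_id
  list(
    clones = seqs,
    manifest = data.frame(clone_id = clone_id, individual = profile$id,
                          group = profile$group, region = region,
                          stringsAsFactors = FALSE),
    truth = data.frame(clone_id = clone_id, allele_origin = allele,
                       isoform = isoform, edited = edited,
                       n_seq_errors = n_err, stringsAsFactors = FALSE)
  )
}

#' Michaelis-Menten and Haldane substrate-inhibition velocities
#'
#' `mm_velocity()` evaluates v = Vmax S / (Km + S); `si_velocity()` evaluates
#' the Haldane single-site substrate-inhibition form
#' v = Vmax S / (Km + S + S^2/Ki), whose maximum lies at S = sqrt(Km Ki).
#'
#' @param S Substrate (tryptophan) concentrations, uM.
#' @param km,vmax,ki Kinetic parameters (Km and Ki in uM, Vmax in velocity
#'   units).
#' @export
mm_velocity <- function(S, km, vmax) vmax * S / (km + S)

#' @rdname mm_velocity
#' @export
si_velocity <- function(S, km, vmax, ki) vmax * S / (km + S + S^2 / ki)

#' Generate a noisy saturation-kinetics dataset
#'
#' Simulates replicate substrate-velocity curves from the Michaelis-Menten or
#' Haldane substrate-inhibition model, with multiplicative lognormal noise of
#' a given coefficient of variation (mean 1, so noise is unbiased on the
#' velocity scale).
#'
#' @param model `"mm"` or `"si"`.
#' @param km,vmax True parameters (Km in uM).
#' @param ki Substrate-inhibition constant (uM); required when
#'   `model == "si"`.
#' @param s_grid Substrate concentrations (uM), all > 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicate curves to draw.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `S`, `v`, `replicate`.
#' @export
generate_kinetic_dataset <- function(model = c("mm", "si"), km, vmax, ki = NULL,
                                     s_grid, noise_cv = 0.05,
                                     n_replicates = 1L, seed = NULL) {
  model <- match.arg(model)
  if (km <= 0 || vmax <= 0 || any(s_grid <= 0) || noise_cv < 0) {
    stop("km, vmax and all substrate concentrations must be positive", call. = FALSE)
  }
  if (model == "si" && (is.null(ki) || ki <= 0)) {
    stop("substrate-inhibition model requires a positive Ki", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  mu <- if (model == "mm") mm_velocity(s_grid, km, vmax)
        else si_velocity(s_grid, km, vmax, ki)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_cv > 0) {
      stats::rlnorm(length(s_grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(s_grid))
    data.frame(S = s_grid, v = mu * noise, replicate = r)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a genotype cohort
#'
#' Draws diploid genotype counts for one cohort, either under Hardy-Weinberg
#' equilibrium at allele frequency `p` or from user-supplied genotype
#' probabilities.
#'
#' @param p Frequency of the first allele (used when `hwe = TRUE`).
#' @param n Cohort size.
#' @param seed Optional integer seed.
#' @param hwe Logical; draw genotypes as multinomial(p^2, 2p(1-p), (1-p)^2).
#' @param genotype_probs Length-3 probability vector (hom-ref, het, hom-alt)
#'   used when `hwe = FALSE`.
#' @return Named integer vector `c(AA, AB, BB)` of genotype counts.
#' @export
generate_genotype_cohort <- function(p, n, seed = NULL, hwe = TRUE,
                                     genotype_probs = NULL) {
  if (hwe && (is.na(p) || p < 0 || p > 1)) {
    stop("allele frequency p must lie in [0, 1]", call. = FALSE)
  }
  probs <- if (hwe) c(p^2, 2 * p * (1 - p), (1 - p)^2) else genotype_probs
  if (is.null(probs) || length(probs) != 3L || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-8) {
    stop("genotype probabilities must be a length-3 vector summing to 1",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  counts <- as.integer(stats::rmultinom(1L, n, probs))
  stats::setNames(counts, c("AA", "AB", "BB"))
}
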