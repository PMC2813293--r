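#' Stratified editing-frequency table
#'
#' Counts, for every stratum and editing position 1-4, how many QC-passing
#' clones carry the edit, and reports the percentage edited.  Denominators are
#' the QC-passing clones of that isoform and stratum; an empty stratum yields
#' `NA` (undefined) percentages, never 0.
#'
#' @param patterns Pattern table from [discriminate_clones()] (requires
#'   `isoform`, `indices`, `qc_pass`, plus the stratum columns).
#' @param strata Character vector of column names defining the strata
#'   (e.g. `c("region", "genotype")`); `isoform` is always included.
#' @param qc_only Count only QC-passing clones (default `TRUE`).
#' @return A data.frame with one row per stratum x isoform: the stratum
#'   columns, `n_clones`, `n_edited_1` .. `n_edited_4` and `pct_1` .. `pct_4`.
#' @export
editing_frequency_table <- function(patterns, strata = character(0),
                                    qc_only = TRUE) {
  missing_cols <- setdiff(strata, names(patterns))
  if (length(missing_cols)) {
    stop("config error: unknown stratum column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- patterns
  keys <- c(strata, "isoform")
  # strata are enumerated before QC filtering so that a stratum whose clones
  # all fail QC still appears, with n = 0 and undefined (NA) percentages
  all_key <- interaction(patterns[keys], drop = TRUE, sep = "\r")
  if (qc_only && "qc_pass" %in% names(df)) df <- df[df$qc_pass, , drop = FALSE]
  if (nrow(patterns) == 0) {
    out <- data.frame(matrix(character(0), 0, length(keys),
                             dimnames = list(NULL, keys)))
    out$n_clones <- integer(0)
    for (k in 1:4) out[[paste0("n_edited_", k)]] <- integer(0)
    for (k in 1:4) out[[paste0("pct_", k)]] <- numeric(0)
    return(out)
  }
  key <- factor(interaction(df[keys], drop = FALSE, sep = "\r"),
                levels = levels(all_key))
  rows <- lapply(levels(all_key), function(lv) {
    sub <- df[!is.na(key) & key == lv, , drop = FALSE]
    idx_sets <- lapply(strsplit(sub$indices, ","), function(x)
      as.integer(x[nzchar(x)]))
    n <- nrow(sub)
    n_ed <- vapply(1:4, function(k)
      sum(vapply(idx_sets, function(s) k %in% s, logical(1))), integer(1))
    meta <- if (n > 0) sub[1, keys, drop = FALSE] else {
      parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
      stats::setNames(as.data.frame(as.list(parts), stringsAsFactors = FALSE),
                      keys)
    }
    cbind(meta,
          data.frame(n_clones = n,
                     n_edited_1 = n_ed[1], n_edited_2 = n_ed[2],
                     n_edited_3 = n_ed[3], n_edited_4 = n_ed[4],
                     pct_1 = if (n > 0) 100 * n_ed[1] / n else NA_real_,
                     pct_2 = if (n > 0) 100 * n_ed[2] / n else NA_real_,
                     pct_3 = if (n > 0) 100 * n_ed[3] / n else NA_real_,
                     pct_4 = if (n > 0) 100 * n_ed[4] / n else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison of per-individual editing fractions
#'
#' Two-tailed two-sample t-test with unequal variances (Welch).  The unit of
#' replication is the individual (per-individual edited fraction), since a
#' test on pooled clone indicators would be pseudo-replication.  Degenerate
#' input (both groups constant) is flagged: equal constants give t = 0,
#' p = 1; unequal constants an undefined result.
#'
#' @param x,y Numeric vectors of per-individual edited fractions (length >= 2
#'   each).
#' @return A list with `t`, `df`, `p` and `flag` (`NA` or a degeneracy note).
#' @export
compare_editing <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 individuals", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  flag = "degenerate: zero variance in both groups"))
    }
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                flag = "undefined: zero variance, unequal means"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flag = NA_character_)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparing observed diploid genotype counts with the
#' expectation n*p^2, 2n*p(1-p), n*(1-p)^2 at the estimated allele frequency;
#' 1 degree of freedom.
#'
#' @param counts Length-3 numeric vector of genotype counts (hom-ref, het,
#'   hom-alt), in any naming.
#' @return A list with `chi_square`, `df`, `p`, `p_hat` (estimated allele
#'   frequency) and `warning` (`NA` or a note about zero expected counts).
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L)
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  warn <- NA_character_
  if (any(expected == 0)) {
    warn <- "zero expected count: chi-square restricted to non-degenerate cells"
    keep <- expected > 0
    chi <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  } else {
    chi <- sum((counts - expected)^2 / expected)
  }
  list(chi_square = chi, df = 1L,
       p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       p_hat = p_hat, warning = warn)
}

#' Genotype-association chi-square test between two cohorts
#'
#' Pearson chi-square on either the collapsed 2x2 table (homozygous AA
#' carriers versus the rest; df 1) or the full 2x3 genotype table (df 2),
#' without continuity correction.
#'
#' @param case_counts,control_counts Length-3 genotype count vectors
#'   (AA, het, other-homozygote).
#' @param mode `"AA_vs_rest"` or `"full_2x3"`.
#' @return A list with `chi_square`, `df`, `p` and `table`.
#' @export
genotype_association <- function(case_counts, control_counts,
                                 mode = c("AA_vs_rest", "full_2x3")) {
  mode <- match.arg(mode)
  case_counts <- as.numeric(case_counts)
  control_counts <- as.numeric(control_counts)
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L)
  if (sum(case_counts) == 0 || sum(control_counts) == 0) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  tab <- if (mode == "AA_vs_rest") {
    rbind(case = c(AA = case_counts[1], rest = sum(case_counts[2:3])),
          control = c(AA = control_counts[1], rest = sum(control_counts[2:3])))
  } else {
    rbind(case = case_counts, control = control_counts)
  }
  if (any(colSums(tab) == 0)) {
    return(list(chi_square = NA_real_, df = NA_integer_, p = NA_real_,
                table = tab, flag = "undefined: empty margin"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, flag = NA_character_)
}

#' In-silico NdeI restriction digest
#'
#' Cuts the amplicon at every CATATG occurrence between the second and third
#' base (CA^TATG) and returns the fragment lengths 5' to 3'.  Overlapping site
#' occurrences are all honoured; fragment lengths always sum to the amplicon
#' length.
#'
#' @param amplicon_seq Nucleotide string.
#' @return A list with `fragments` (integer vector of lengths, 5'->3') and
#'   `cut` (logical, `TRUE` when at least one site was found).
#' @export
ndei_rflp <- function(amplicon_seq) {
  if (nchar(amplicon_seq) == 0L) stop("amplicon must be non-empty", call. = FALSE)
  hits <- gregexpr("(?=CATATG)", amplicon_seq, perl = TRUE)[[1]]
  if (hits[1] == -1) {
    return(list(fragments = nchar(amplicon_seq), cut = FALSE))
  }
  cuts <- as.integer(hits) + 1L  # last base of the 5' fragment (CA^TATG)
  bounds <- c(0L, cuts, nchar(amplicon_seq))
  list(fragments = diff(bounds), cut = TRUE)
}

#' Synthetic rs4290270 RFLP amplicon
#'
#' Builds the allele-specific genotyping amplicon around rs4290270.  The
#' flanking genomic sequence of the assay is not part of the transcript model,
#' so the amplicon is synthetic: by default the T allele completes the NdeI
#' site CATATG (the SNP base sits at position 5 of the site, CATA[T]G) while
#' the A allele destroys it; `completing_allele` flips the convention.  Flanks
#' are deterministic and free of further NdeI sites.
#'
#' @param allele `"A"` or `"T"`.
#' @param flank_left,flank_right Flank lengths around the recognition site.
#' @param completing_allele Allele that completes the CATATG site.
#' @param seed Seed for the deterministic flanks.
#' @return A list with `seq` and `allele`.
#' @export
rflp_amplicon <- function(allele = c("T", "A"), flank_left = 120L,
                          flank_right = 80L, completing_allele = "T",
                          seed = 4290270L) {
  allele <- match.arg(allele)
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  draw_flank <- function(n) {
    repeat {
      fl <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
      if (!grepl("CATATG", fl)) return(fl)
    }
  }
  left <- draw_flank(flank_left)
  right <- draw_flank(flank_right)
  site_base <- if (allele == completing_allele) "T" else "A"
  core <- paste0("CATA", site_base, "G")
  seq <- paste0(left, core, right)
  # reject junction-created extra sites (possible across flank boundaries)
  if (lengths(regmatches(seq, gregexpr("CATATG", seq))) >
      as.integer(site_base == "T")) {
    return(rflp_amplicon(allele, flank_left, flank_right, completing_allele,
                         seed + 1L))
  }
  list(seq = seq, allele = allele)
}
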