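#' Default TPH2 variant catalogue
#'
#' The catalogue of coding-region variants observed on TPH2 cDNA clones: the
#' four editing positions carried by each splice isoform (mutually exclusive
#' a-pattern and b-pattern, editing indices 1-4) and the two genuine genomic
#' SNPs rs7305115 and rs4290270 shared by both isoforms.
#'
#' Coordinates are HGVS-like c. positions, 1-based from the A of the start
#' codon, negative values counting backward into the 5'-UTR.  Positions of
#' `scope == "a"` and `scope == "both"` entries are given in the TPH2a frame;
#' `scope == "b"` entries are given in the TPH2b frame (which gains 6 nt after
#' c.439).  The two frames coincide for positions up to c.439.
#'
#' @return A data.frame with columns `c_pos`, `ref`, `alt`, `scope`
#'   (`"a"`, `"b"` or `"both"`), `class` (`"editing"` or `"snp"`),
#'   `editing_index` (1-4 for editing sites, `NA` for SNPs) and `rs_id`.
#' @export
tph2_catalogue <- function() {
  data.frame(
    c_pos = c(-42L, 711L, 1297L, 1322L, 385L, 804L, 830L, 1403L, 936L, 1125L),
    ref   = c("T", "A", "A", "G",  "C", "A", "C", "A",  "A", "A"),
    alt   = c("C", "G", "G", "A",  "T", "G", "T", "G",  "G", "T"),
    scope = c(rep("a", 4), rep("b", 4), "both", "both"),
    class = c(rep("editing", 8), "snp", "snp"),
    editing_index = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, NA, NA),
    rs_id = c(rep(NA_character_, 8), "rs7305115", "rs4290270"),
    stringsAsFactors = FALSE
  )
}

# Codon-level sequence constraints (TPH2a frame) that reproduce the protein
# consequences of the catalogue variants: Q129X nonsense on C>T, R237 and K268
# synonymous A>G, P277L and R433G/R441H missense, Q468R missense, plus the
# Glu-rich hinge stretch interrupted by the Gly-Lys insertion.
.codon_constraints <- function() {
  c("1" = "ATG",
    "129" = "CAA",   # Gln; c.385C>T -> TAA stop
    "143" = "GAA", "144" = "GAA", "145" = "GAA", "146" = "GAA",
    "147" = "GAA",   # c.439 = G so the hexamer insertion reads Gly-Lys
    "237" = "CGA",   # Arg; c.711A>G synonymous
    "266" = "AAA",   # Lys; b-frame c.804A>G synonymous
    "275" = "CCA",   # Pro; b-frame c.830C>T -> Leu
    "312" = "CCA",   # Pro; rs7305115 c.936A>G synonymous
    "375" = "GCA",   # Ala; rs4290270 c.1125A>T synonymous
    "433" = "AGA",   # Arg; c.1297A>G -> Gly
    "441" = "CGT",   # Arg; c.1322G>A -> His
    "466" = "CAA")   # Gln; b-frame c.1403A>G -> Arg
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Use a seed without clobbering the caller's RNG stream: call as
#   old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE); set.seed(seed)
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Map a coding position to its codon
#'
#' @param c_pos Positive coding coordinate (1-based, A of ATG = 1).
#' @return A list with `codon` (1-based codon index) and `offset` (1-3,
#'   position within the codon).
#' @examples
#' c_to_codon(385)  # codon 129, first base
#' @export
c_to_codon <- function(c_pos) {
  if (any(c_pos < 1)) {
    stop("UTR positions have no codon: c_pos must be >= 1", call. = FALSE)
  }
  list(codon = (c_pos + 2L) %/% 3L, offset = ((c_pos - 1L) %% 3L) + 1L)
}

#' Convert coding positions between the TPH2a and TPH2b frames
#'
#' The TPH2b frame gains 6 nt (the GCAAGG hexamer) after c.439; positions up
#' to c.439 and all 5'-UTR positions coincide.  `b_to_a_pos()` returns `NA`
#' for b-frame positions 440-445, which lie inside the insertion and have no
#' TPH2a counterpart.
#'
#' @param c_pos Signed coding coordinate(s).
#' @return Integer vector of converted coordinates.
#' @export
a_to_b_pos <- function(c_pos) {
  ifelse(c_pos > 439L, c_pos + 6L, c_pos)
}

#' @rdname a_to_b_pos
#' @export
b_to_a_pos <- function(c_pos) {
  out <- ifelse(c_pos > 445L, c_pos - 6L, c_pos)
  out[c_pos >= 440L & c_pos <= 445L] <- NA_integer_
  as.integer(out)
}

#' Build the surrogate TPH2 reference model
#'
#' Generates a deterministic surrogate coding-sequence model for the two TPH2
#' splice isoforms.  All bases that are unconstrained by the variant catalogue
#' (and by the codon-level constraints that reproduce the catalogue's protein
#' consequences) are arbitrary but fixed by `seed`; the constrained bases are
#' imposed exactly, so every catalogue variant behaves as printed without any
#' external sequence download.  TPH2b is derived from TPH2a by inserting the
#' GCAAGG hexamer after c.439 (c.439_440insGCAAGG), which adds Gly-Lys to the
#' protein.
#'
#' @param catalogue Variant catalogue data.frame (see [tph2_catalogue()]).
#' @param utr5_length Length of the synthetic 5'-UTR (must be >= 42 so that
#'   c.-42 exists).
#' @param n_codons Number of amino-acid codons of TPH2a (the CDS additionally
#'   carries one terminal stop codon).
#' @param seed Integer seed fixing the unconstrained bases.
#' @return An object of class `tph2_reference`: a list with `utr5`, `cds_a`,
#'   `cds_b`, `insertion` (`after_c_pos`, `seq`), `intron3_context` and
#'   `catalogue`.
#' @export
build_reference <- function(catalogue = tph2_catalogue(), utr5_length = 42L,
                            n_codons = 490L, seed = 21173L) {
  stopifnot(utr5_length >= 42L, n_codons >= 470L)
  needed <- c("c_pos", "ref", "alt", "scope")
  if (!all(needed %in% names(catalogue))) {
    stop("catalogue must have columns c_pos, ref, alt, scope", call. = FALSE)
  }
  if (!"class" %in% names(catalogue)) catalogue$class <- "editing"
  if (!"editing_index" %in% names(catalogue)) catalogue$editing_index <- NA_integer_
  if (!"rs_id" %in% names(catalogue)) catalogue$rs_id <- NA_character_
  if (nrow(catalogue) > 0) {
    bad <- catalogue$class == "editing" & is.na(catalogue$editing_index)
    if (any(bad)) stop("editing sites must carry an editing_index", call. = FALSE)
    if (any(catalogue$class == "snp" & !is.na(catalogue$editing_index))) {
      stop("genomic SNPs must not carry an editing_index", call. = FALSE)
    }
  }

  # project every catalogue constraint into the TPH2a frame
  pos_a <- catalogue$c_pos
  if (nrow(catalogue) > 0) {
    b_rows <- catalogue$scope == "b" & catalogue$c_pos > 0
    pos_a[b_rows] <- b_to_a_pos(catalogue$c_pos[b_rows])
    if (any(is.na(pos_a))) {
      stop("b-frame catalogue position falls inside the insertion", call. = FALSE)
    }
  }

  cds_len <- 3L * (n_codons + 1L)
  if (nrow(catalogue) > 0) {
    if (any(pos_a > cds_len) || any(pos_a < -utr5_length)) {
      stop("catalogue position outside utr5/cds bounds", call. = FALSE)
    }
    cons <- data.frame(pos = pos_a, base = catalogue$ref)
    dup <- split(cons$base, cons$pos)
    if (any(vapply(dup, function(b) length(unique(b)) > 1L, logical(1)))) {
      stop("constraint conflict: differing reference bases at one position",
           call. = FALSE)
    }
  }

  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  utr5 <- sample(bases, utr5_length, replace = TRUE)

  sense <- setdiff(apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
                   .STOP_CODONS)
  codons <- sample(sense, n_codons + 1L, replace = TRUE)
  cc <- .codon_constraints()
  codons[as.integer(names(cc))] <- cc
  codons[n_codons + 1L] <- "TAA"
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]

  # impose single-base catalogue constraints, refusing to break codon
  # constraints and repairing any stop codon accidentally created
  fixed_codons <- as.integer(names(cc))
  if (nrow(catalogue) > 0) {
    for (i in seq_len(nrow(catalogue))) {
      p <- pos_a[i]
      want <- catalogue$ref[i]
      if (p < 0) {
        idx <- utr5_length + p + 1L
        utr5[idx] <- want
      } else {
        if (cds[p] == want) next
        ci <- c_to_codon(p)
        if (ci$codon %in% c(fixed_codons, n_codons + 1L)) {
          stop(sprintf("constraint conflict at c.%d: catalogue ref '%s' vs '%s'",
                       p, want, cds[p]), call. = FALSE)
        }
        cds[p] <- want
        start <- 3L * (ci$codon - 1L) + 1L
        codon <- paste(cds[start:(start + 2L)], collapse = "")
        if (codon %in% .STOP_CODONS) {
          free <- setdiff(start:(start + 2L), p)
          for (f in free) {
            for (b in bases) {
              cds[f] <- b
              codon <- paste(cds[start:(start + 2L)], collapse = "")
              if (!codon %in% .STOP_CODONS) break
            }
            if (!codon %in% .STOP_CODONS) break
          }
        }
      }
    }
  }

  cds_a <- paste(cds, collapse = "")
  insertion <- list(after_c_pos = 439L, seq = "GCAAGG")
  cds_b <- paste0(substr(cds_a, 1L, 439L), insertion$seq,
                  substr(cds_a, 440L, nchar(cds_a)))
  model <- structure(list(
    utr5 = paste(utr5, collapse = ""),
    cds_a = cds_a,
    cds_b = cds_b,
    insertion = insertion,
    # intron 3 opens with the non-canonical GC donor; the alternative GT donor
    # 6 nt downstream turns the intervening GCAAGG into exon 3b
    intron3_context = "GCAAGGGTAAGTAT",
    catalogue = catalogue,
    seed = seed
  ), class = "tph2_reference")

  stopifnot(nchar(model$cds_a) %% 3L == 0L,
            nchar(model$cds_b) == nchar(model$cds_a) + 6L)
  .validate_catalogue_bases(model)
  model
}

.validate_catalogue_bases <- function(model) {
  cat <- model$catalogue
  if (nrow(cat) == 0) return(invisible(TRUE))
  for (i in seq_len(nrow(cat))) {
    iso <- if (cat$scope[i] == "b") "b" else "a"
    idx <- c_to_transcript(model, cat$c_pos[i], iso)
    base <- substr(transcript_seq(model, iso), idx, idx)
    if (base != cat$ref[i]) {
      stop(sprintf("reference base at c.%d is %s, catalogue says %s",
                   cat$c_pos[i], base, cat$ref[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.tph2_reference <- function(x, ...) {
  cat("TPH2 surrogate reference model\n")
  cat(sprintf("  5'-UTR: %d nt; CDS a: %d nt; CDS b: %d nt\n",
              nchar(x$utr5), nchar(x$cds_a), nchar(x$cds_b)))
  cat(sprintf("  insertion: c.%d_%dins%s\n", x$insertion$after_c_pos,
              x$insertion$after_c_pos + 1L, x$insertion$seq))
  cat(sprintf("  catalogue: %d variants (%d editing, %d SNP)\n",
              nrow(x$catalogue), sum(x$catalogue$class == "editing"),
              sum(x$catalogue$class == "snp")))
  invisible(x)
}

#' Transcript sequence of a splice isoform
#'
#' Returns the 5'-UTR plus CDS of the requested isoform as a plain character
#' string; this is the sequence space in which cDNA clones live.
#'
#' @param model A `tph2_reference`.
#' @param isoform `"a"` or `"b"`.
#' @export
transcript_seq <- function(model, isoform = c("a", "b")) {
  isoform <- match.arg(isoform)
  paste0(model$utr5, if (isoform == "a") model$cds_a else model$cds_b)
}

#' Convert between c. coordinates and transcript indices
#'
#' `c_to_transcript()` maps a signed coding coordinate (in the frame of the
#' given isoform) to a 1-based index into [transcript_seq()];
#' `transcript_to_c()` is its inverse.
#'
#' @param model A `tph2_reference`.
#' @param c_pos Signed coding coordinate(s); no position 0 exists.
#' @param isoform `"a"` or `"b"`.
#' @export
c_to_transcript <- function(model, c_pos, isoform = c("a", "b")) {
  isoform <- match.arg(isoform)
  if (any(c_pos == 0)) stop("c. coordinate 0 does not exist", call. = FALSE)
  u <- nchar(model$utr5)
  as.integer(ifelse(c_pos > 0, u + c_pos, u + c_pos + 1L))
}

#' @rdname c_to_transcript
#' @param t_idx 1-based transcript index.
#' @export
transcript_to_c <- function(model, t_idx, isoform = c("a", "b")) {
  u <- nchar(model$utr5)
  as.integer(ifelse(t_idx > u, t_idx - u, t_idx - u - 1L))
}

#' Catalogue sites applicable to one isoform, in that isoform's frame
#'
#' Selects the catalogue rows whose scope is compatible with `isoform` and
#' reprojects shared (`scope == "both"`) positions, which are stored in the
#' TPH2a frame, into the requested frame.
#'
#' @inheritParams transcript_seq
#' @return The catalogue subset with an extra column `pos` (coding coordinate
#'   in the isoform's frame) and `t_idx` (transcript index).
#' @export
catalogue_for_isoform <- function(model, isoform = c("a", "b")) {
  isoform <- match.arg(isoform)
  cat <- model$catalogue
  keep <- cat$scope %in% c(isoform, "both")
  cat <- cat[keep, , drop = FALSE]
  pos <- cat$c_pos
  if (isoform == "b") {
    shared <- cat$scope == "both"
    pos[shared] <- a_to_b_pos(cat$c_pos[shared])
  }
  cat$pos <- as.integer(pos)
  cat$t_idx <- c_to_transcript(model, pos, isoform)
  cat
}

#' Apply a set of catalogue variants to an isoform transcript
#'
#' Substitutes the alternative base of each requested catalogue variant into
#' the isoform's transcript (5'-UTR + CDS).  Variants whose scope belongs to
#' the other isoform raise a mutual-exclusivity error; a catalogue `ref` that
#' does not match the model raises a reference-inconsistency error.
#'
#' @inheritParams transcript_seq
#' @param variants Either a data.frame with columns `c_pos`, `ref`, `alt`,
#'   `scope` (a subset of the catalogue), or a vector of c. positions looked
#'   up in the catalogue, or `NULL` for none.
#' @return The modified transcript as a character string.
#' @export
apply_variants <- function(model, isoform = c("a", "b"), variants = NULL) {
  isoform <- match.arg(isoform)
  if (is.null(variants) || (is.data.frame(variants) && nrow(variants) == 0) ||
      length(variants) == 0) {
    return(transcript_seq(model, isoform))
  }
  if (!is.data.frame(variants)) {
    idx <- match(variants, model$catalogue$c_pos)
    if (any(is.na(idx))) {
      stop("variant position(s) not in catalogue: ",
           paste(variants[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    variants <- model$catalogue[idx, , drop = FALSE]
  }
  bad <- !variants$scope %in% c(isoform, "both")
  if (any(bad)) {
    stop(sprintf("mutual-exclusivity error: variant(s) %s are %s-pattern, not applicable to isoform %s",
                 paste0("c.", variants$c_pos[bad], collapse = ", "),
                 paste(unique(variants$scope[bad]), collapse = "/"), isoform),
         call. = FALSE)
  }
  seq <- transcript_seq(model, isoform)
  pos <- variants$c_pos
  shared <- variants$scope == "both"
  if (isoform == "b") pos[shared] <- a_to_b_pos(variants$c_pos[shared])
  t_idx <- c_to_transcript(model, pos, isoform)
  for (i in seq_along(t_idx)) {
    if (substr(seq, t_idx[i], t_idx[i]) != variants$ref[i]) {
      stop(sprintf("reference inconsistency at c.%d: model has %s, variant ref is %s",
                   variants$c_pos[i], substr(seq, t_idx[i], t_idx[i]),
                   variants$ref[i]), call. = FALSE)
    }
    substr(seq, t_idx[i], t_idx[i]) <- variants$alt[i]
  }
  seq
}

#' Editing-pattern variants of one isoform
#'
#' @inheritParams transcript_seq
#' @param indices Editing indices (subset of 1:4) of the isoform's pattern.
#' @return The matching catalogue rows.
#' @export
pattern_variants <- function(model, isoform = c("a", "b"), indices = 1:4) {
  isoform <- match.arg(isoform)
  cat <- model$catalogue
  cat[cat$scope == isoform & cat$class == "editing" &
        cat$editing_index %in% indices, , drop = FALSE]
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation with premature-stop detection.  The
#' returned protein stops at the first in-frame stop codon (the stop itself is
#' not included); `premature_stop_codon` is its 1-based codon index when it
#' precedes the final codon, `NA` otherwise.
#'
#' @param cds Nucleotide string, length divisible by 3, A/C/G/T only.
#' @return A list with `protein` and `premature_stop_codon`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", cds)) stop("invalid sequence: non-ACGT symbol", call. = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  n <- nchar(aa)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  first_stop <- if (length(stops)) stops[1] else NA_integer_
  premature <- if (!is.na(first_stop) && first_stop < n) first_stop else NA_integer_
  protein <- if (is.na(first_stop)) aa else substr(aa, 1L, first_stop - 1L)
  list(protein = protein, premature_stop_codon = premature)
}

#' Scan an intron 5' context for splice-donor dinucleotides
#'
#' Reports the dinucleotide at the intron start (canonical GT or non-canonical
#' GC) and, for a non-GT primary donor, the offset of the first downstream GT
#' within 6 nt, which can act as an alternative donor.  A canonical GT primary
#' donor reports `NA` for the alternative offset (the field is reserved for
#' the alternative site).
#'
#' @param intron3_context First bases of the intron (length >= 8).
#' @return A list with `primary_dinucleotide` and `alternative_gt_offset`
#'   (`NA` when absent).
#' @export
scan_donor_sites <- function(intron3_context) {
  if (nchar(intron3_context) < 8L) {
    stop("intron context must be at least 8 nt", call. = FALSE)
  }
  primary <- substr(intron3_context, 1L, 2L)
  offset <- NA_integer_
  if (primary != "GT") {
    for (start in 2:7) {
      if (substr(intron3_context, start, start + 1L) == "GT") {
        offset <- start - 1L
        break
      }
    }
  }
  list(primary_dinucleotide = primary, alternative_gt_offset = offset)
}

#' Transition class of an RNA edit on the mRNA sense strand
#'
#' A>G substitutions are reported as A>I (inosine is read as guanosine) and
#' C>T as C>U, following editing-chemistry convention.
#'
#' @param ref,alt Single reference/observed bases (DNA alphabet).
#' @return One of `"A>I"`, `"C>U"`, `"U>C"`, `"G>A"`, `"other"`.
#' @export
edit_chemistry <- function(ref, alt) {
  key <- paste0(ref, ">", alt)
  map <- c("A>G" = "A>I", "C>T" = "C>U", "T>C" = "U>C", "G>A" = "G>A")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}
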