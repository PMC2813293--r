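# Scoring scheme shared by the full dynamic-programming aligner and the
# ungapped fast path: match +1, mismatch -1, gap open -5, gap extend -1
# (a gap of length k costs 5 + k).  N scores 0 against anything.
.MATCH <- 1L; .MISMATCH <- -1L; .GAP_OPEN <- 5L; .GAP_EXT <- 1L

.sub_matrix <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(.MISMATCH, 5, 5, dimnames = list(ab, ab))
  diag(m) <- .MATCH
  m["N", ] <- 0L
  m[, "N"] <- 0L
  m
}

.check_seq <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside the ACGTN alphabet", call. = FALSE)
  }
  invisible(x)
}

#' Globally align a clone to a reference sequence
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +1, mismatch -1, gap open -5, gap extension -1 per base;
#' N scores 0 against anything).
#'
#' @param clone_seq,ref_seq Nucleotide strings (ACGTN).
#' @return An object of class `tph2_alignment`: a list with the gapped
#'   `pattern` (clone) and `subject` (reference) strings and the alignment
#'   `score`.
#' @export
align_clone <- function(clone_seq, ref_seq) {
  .check_seq(clone_seq, "clone sequence")
  .check_seq(ref_seq, "reference sequence")
  pa <- Biostrings::pairwiseAlignment(
    clone_seq, ref_seq, type = "global",
    substitutionMatrix = .sub_matrix(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  structure(list(pattern = as.character(Biostrings::alignedPattern(pa)),
                 subject = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "tph2_alignment")
}

# Hamming mismatch count between equal-length strings; N never mismatches
# (it scores 0, accounted for separately by the fast scorer).
.hamming_parts <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n_count <- sum(av == "N" | bv == "N")
  list(mismatch = sum(av != bv & av != "N" & bv != "N"), n = n_count)
}

# Ungapped global score of equal-length sequences under the package scheme.
.ungapped_score <- function(a, b) {
  h <- .hamming_parts(a, b)
  nchar(a) - h$n + (.MISMATCH - .MATCH) * h$mismatch - 0L * h$n
}

#' Classify clones by splice isoform against both references
#'
#' Aligns each clone to the TPH2a and TPH2b transcripts and calls the
#' higher-scoring isoform; clones whose score margin falls below
#' `margin_threshold`, that fail the GCAAGG insertion-window check, or that
#' do not cover the c.430-c.450 decision window are returned as
#' `"unclassified"`.  A reverse-complement retry is attempted when the best
#' forward score is below half the maximal attainable score.
#'
#' For substitution-only clones whose length equals one transcript exactly and
#' that carry at most 6 mismatches, the ungapped alignment is provably optimal
#' under the scoring scheme (any gapped alignment pays at least 12), so a
#' vectorized ungapped scorer replaces the dynamic program; all other clones
#' fall back to the full affine-gap aligner.
#'
#' @param clones Named character vector (or `DNAStringSet`) of clone
#'   sequences.
#' @param model A `tph2_reference`.
#' @param margin_threshold Minimum score margin for a confident call.
#' @return A data.frame with columns `clone_id`, `isoform` (`"a"`, `"b"` or
#'   `"unclassified"`), `margin`, `score_a`, `score_b`, `revcomp`.
#' @export
classify_clones <- function(clones, model, margin_threshold = 3) {
  ids <- names(clones)
  clones <- as.character(clones)
  names(clones) <- if (is.null(ids)) sprintf("clone%04d", seq_along(clones)) else ids
  ta <- transcript_seq(model, "a")
  tb <- transcript_seq(model, "b")
  u <- nchar(model$utr5)
  La <- nchar(ta); Lb <- nchar(tb)
  win_b <- c(u + model$insertion$after_c_pos + 1L,
             u + model$insertion$after_c_pos + 6L)

  out <- data.frame(clone_id = names(clones), isoform = "unclassified",
                    margin = NA_real_, score_a = NA_real_, score_b = NA_real_,
                    revcomp = FALSE, stringsAsFactors = FALSE)
  slow <- logical(length(clones))
  for (i in seq_along(clones)) {
    s <- clones[[i]]
    L <- nchar(s)
    if (L == La) {
      h <- .hamming_parts(s, ta)
      if (h$mismatch <= 6L) {
        # exact transcript-a length: optimal TPH2b alignment deletes the
        # hexamer (cost 11) and meets the same residual mismatches
        out$score_a[i] <- .ungapped_score(s, ta)
        out$score_b[i] <- out$score_a[i] - (.GAP_OPEN + 6L * .GAP_EXT)
      } else slow[i] <- TRUE
    } else if (L == Lb) {
      h <- .hamming_parts(s, tb)
      if (h$mismatch <= 6L) {
        out$score_b[i] <- .ungapped_score(s, tb)
        stripped <- paste0(substr(s, 1L, win_b[1] - 1L),
                           substr(s, win_b[2] + 1L, Lb))
        out$score_a[i] <- .ungapped_score(stripped, ta) - (.GAP_OPEN + 6L * .GAP_EXT)
      } else slow[i] <- TRUE
    } else slow[i] <- TRUE
  }

  if (any(slow)) {
    dp <- .classify_dp(clones[slow], ta, tb, u)
    out$score_a[slow] <- dp$score_a
    out$score_b[slow] <- dp$score_b
    out$revcomp[slow] <- dp$revcomp
    covers <- rep(TRUE, length(clones))
    covers[slow] <- dp$covers_window
  } else {
    covers <- rep(TRUE, length(clones))
  }

  out$margin <- abs(out$score_a - out$score_b)
  for (i in seq_along(clones)) {
    if (!covers[i] || is.na(out$margin[i]) || out$margin[i] < margin_threshold) next
    if (out$score_b[i] > out$score_a[i]) {
      s <- if (out$revcomp[i]) .revcomp(clones[[i]]) else clones[[i]]
      window_ok <- nchar(s) >= win_b[2] &&
        substr(s, win_b[1], win_b[2]) == model$insertion$seq
      if (window_ok) out$isoform[i] <- "b"
    } else if (out$score_a[i] > out$score_b[i]) {
      out$isoform[i] <- "a"
    }
  }
  out
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Full dynamic-programming classification for clones the fast path cannot
# prove optimal (indels, truncations, heavy error loads, reverse orientation).
.classify_dp <- function(clones, ta, tb, u) {
  n <- length(clones)
  score_a <- score_b <- numeric(n)
  revcomp <- logical(n)
  covers <- logical(n)
  m <- .sub_matrix()
  aln_scores <- function(set, ref) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(set), ref, type = "global",
      substitutionMatrix = m, gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT,
      scoreOnly = TRUE)
  }
  set <- as.character(clones)
  sa <- aln_scores(set, ta)
  sb <- aln_scores(set, tb)
  need_rc <- pmax(sa, sb) < 0.5 * nchar(set)
  if (any(need_rc)) {
    rcs <- vapply(set[need_rc], .revcomp, character(1))
    sa_rc <- aln_scores(rcs, ta)
    sb_rc <- aln_scores(rcs, tb)
    better <- pmax(sa_rc, sb_rc) > pmax(sa[need_rc], sb[need_rc])
    idx <- which(need_rc)[better]
    sa[idx] <- sa_rc[better]
    sb[idx] <- sb_rc[better]
    revcomp[idx] <- TRUE
  }
  score_a <- sa; score_b <- sb
  # coverage of the c.430-c.450 decision window, judged on the better
  # reference: the window columns must align to clone bases, not terminal gaps
  for (i in seq_len(n)) {
    s <- if (revcomp[i]) .revcomp(clones[[i]]) else clones[[i]]
    ref <- if (score_b[i] > score_a[i]) tb else ta
    al <- align_clone(s, ref)
    covers[i] <- .covers_ref_window(al, u + 430L, u + 450L)
  }
  list(score_a = score_a, score_b = score_b, revcomp = revcomp,
       covers_window = covers)
}

.covers_ref_window <- function(alignment, from, to) {
  pat <- strsplit(alignment$pattern, "")[[1]]
  sub <- strsplit(alignment$subject, "")[[1]]
  ref_idx <- cumsum(sub != "-")
  cols <- which(ref_idx >= from & ref_idx <= to & sub != "-")
  length(cols) > 0 && any(pat[cols] != "-")
}

#' Classify a single clone's splice isoform
#'
#' @param clone_seq Nucleotide string.
#' @param model A `tph2_reference`.
#' @param margin_threshold Minimum score margin for a confident call.
#' @return A list with `isoform` and `margin`.
#' @export
classify_splice_isoform <- function(clone_seq, model, margin_threshold = 3) {
  res <- classify_clones(stats::setNames(clone_seq, "clone"), model,
                         margin_threshold)
  list(isoform = res$isoform[1], margin = res$margin[1])
}

#' Call substitution variants from a clone-reference alignment
#'
#' Emits every substitution column of the alignment (insertion/deletion
#' columns are excluded: the hexamer insertion is encoded in the isoform call,
#' not as variants) and annotates each call against the catalogue of the
#' called isoform.  N bases never produce calls.
#'
#' @param alignment A `tph2_alignment` of the clone against the transcript of
#'   its called isoform (or a raw clone string, which is compared directly
#'   when its length matches the transcript and aligned otherwise).
#' @param model A `tph2_reference`.
#' @param isoform The called isoform, `"a"` or `"b"`.
#' @return A data.frame with columns `c_pos` (isoform frame), `ref`, `obs`,
#'   `in_catalogue`, `editing_index`, `class`.
#' @export
call_variants <- function(alignment, model, isoform = c("a", "b")) {
  isoform <- match.arg(isoform)
  ref <- transcript_seq(model, isoform)
  if (is.character(alignment)) {
    if (nchar(alignment) == nchar(ref)) {
      alignment <- structure(list(pattern = alignment, subject = ref,
                                  score = .ungapped_score(alignment, ref)),
                             class = "tph2_alignment")
    } else {
      alignment <- align_clone(alignment, ref)
    }
  }
  pat <- strsplit(alignment$pattern, "")[[1]]
  sub <- strsplit(alignment$subject, "")[[1]]
  ref_idx <- cumsum(sub != "-")
  is_sub <- pat != "-" & sub != "-" & pat != sub & pat != "N" & sub != "N"
  cols <- which(is_sub)
  cat_iso <- catalogue_for_isoform(model, isoform)
  if (length(cols) == 0) {
    return(data.frame(c_pos = integer(0), ref = character(0),
                      obs = character(0), in_catalogue = logical(0),
                      editing_index = integer(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  c_pos <- transcript_to_c(model, ref_idx[cols], isoform)
  key <- paste(c_pos, pat[cols])
  cat_key <- paste(cat_iso$pos, cat_iso$alt)
  hit <- match(key, cat_key)
  data.frame(c_pos = c_pos, ref = sub[cols], obs = pat[cols],
             in_catalogue = !is.na(hit),
             editing_index = cat_iso$editing_index[hit],
             class = cat_iso$class[hit],
             stringsAsFactors = FALSE)
}

#' Indels of an alignment, canonicalized to their 3'-most position
#'
#' Extracts insertion/deletion runs from a `tph2_alignment` and shifts each to
#' its 3'-most equivalent placement (the HGVS normalization rule), so that an
#' insertion in a repetitive context is always named by the same coordinates.
#'
#' @param alignment A `tph2_alignment`.
#' @return A data.frame with columns `type` (`"insertion"` in the clone /
#'   `"deletion"` from the reference), `length`, `ref_pos` (last reference
#'   base before the event, 0 at the reference start) and `seq`.
#' @export
alignment_indels <- function(alignment) {
  pat <- strsplit(alignment$pattern, "")[[1]]
  sub <- strsplit(alignment$subject, "")[[1]]
  ref_seq <- paste(sub[sub != "-"], collapse = "")
  clone_seq <- paste(pat[pat != "-"], collapse = "")
  runs <- function(gapped) {
    r <- rle(gapped == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
  }
  out <- list()
  ref_idx <- cumsum(sub != "-")
  for (g in seq_len(nrow(runs(sub)))) {
    r <- runs(sub)[g, ]
    seqv <- paste(pat[r$start:r$end], collapse = "")
    pos <- ref_idx[r$start]  # last ref base before the insertion
    shifted <- .shift3(ref_seq, pos, seqv)
    out[[length(out) + 1L]] <- data.frame(type = "insertion",
                                          length = nchar(seqv),
                                          ref_pos = shifted$pos,
                                          seq = shifted$seq,
                                          stringsAsFactors = FALSE)
  }
  for (g in seq_len(nrow(runs(pat)))) {
    r <- runs(pat)[g, ]
    seqv <- paste(sub[r$start:r$end], collapse = "")
    pos <- ref_idx[r$start] - 1L
    shifted <- .shift3(ref_seq, pos, seqv, deletion = TRUE)
    out[[length(out) + 1L]] <- data.frame(type = "deletion",
                                          length = nchar(seqv),
                                          ref_pos = shifted$pos,
                                          seq = shifted$seq,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(type = character(0), length = integer(0),
                      ref_pos = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Rotate an indel rightward while the next reference base equals the first
# base of the event sequence (for deletions the event must track the
# reference; for insertions it is compared against the downstream reference).
.shift3 <- function(ref_seq, pos, seqv, deletion = FALSE) {
  L <- nchar(ref_seq)
  repeat {
    nxt_pos <- if (deletion) pos + nchar(seqv) + 1L else pos + 1L
    if (nxt_pos > L) break
    nxt <- substr(ref_seq, nxt_pos, nxt_pos)
    if (nxt != substr(seqv, 1L, 1L)) break
    seqv <- paste0(substr(seqv, 2L, nchar(seqv)), nxt)
    pos <- pos + 1L
  }
  list(pos = pos, seq = seqv)
}

#' QC filter on non-catalogue mismatches
#'
#' A clone passes QC when its number of substitutions that match no catalogue
#' entry (i.e. presumed sequencing errors) does not exceed
#' `max_noncatalogue`.
#'
#' @param n_noncatalogue Number of non-catalogue mismatch calls.
#' @param max_noncatalogue Maximum tolerated (default 5).
#' @return Logical.
#' @export
qc_filter <- function(n_noncatalogue, max_noncatalogue = 5L) {
  n_noncatalogue <= max_noncatalogue
}

#' Annotate a clone library: isoform calls, variant calls, QC
#'
#' Runs [classify_clones()] and [call_variants()] over a library and collects
#' per-clone annotations.  Unclassified clones receive no variant calls.
#'
#' @param clones Named character vector of clone sequences.
#' @param model A `tph2_reference`.
#' @param margin_threshold Isoform-call margin threshold.
#' @param max_noncatalogue QC threshold on non-catalogue mismatches.
#' @return A list with `annotations` (clone_id, isoform, margin,
#'   allele_rs4290270, n_noncatalogue, qc_pass) and `calls` (one row per
#'   variant call, with clone_id).
#' @export
annotate_clones <- function(clones, model, margin_threshold = 3,
                            max_noncatalogue = 5L) {
  cls <- classify_clones(clones, model, margin_threshold)
  calls <- vector("list", length(clones))
  allele <- rep(NA_character_, length(clones))
  n_noncat <- rep(NA_integer_, length(clones))
  for (i in seq_len(nrow(cls))) {
    iso <- cls$isoform[i]
    if (iso == "unclassified") next
    cv <- call_variants(clones[[i]], model, iso)
    cv$clone_id <- rep(cls$clone_id[i], nrow(cv))
    calls[[i]] <- cv
    n_noncat[i] <- sum(!cv$in_catalogue)
    # observed base at rs4290270 (c.1125 in the a frame)
    pos <- if (iso == "b") a_to_b_pos(1125L) else 1125L
    s <- if (cls$revcomp[i]) .revcomp(clones[[i]]) else clones[[i]]
    t_idx <- c_to_transcript(model, pos, iso)
    if (nchar(s) == nchar(transcript_seq(model, iso))) {
      allele[i] <- substr(s, t_idx, t_idx)
    }
  }
  ann <- data.frame(clone_id = cls$clone_id, isoform = cls$isoform,
                    margin = cls$margin, allele_rs4290270 = allele,
                    n_noncatalogue = n_noncat,
                    stringsAsFactors = FALSE)
  ann$qc_pass <- ifelse(is.na(ann$n_noncatalogue), FALSE,
                        qc_filter(ann$n_noncatalogue, max_noncatalogue))
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(c_pos = integer(0), ref = character(0),
                        obs = character(0), in_catalogue = logical(0),
                        editing_index = integer(0), class = character(0),
                        clone_id = character(0), stringsAsFactors = FALSE)
  }
  list(annotations = ann, calls = calls)
}
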