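# Shared fixtures: one reference model reused across test files (it is
# deterministic), plus small sequence utilities.

ref_model <- build_reference()

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force affine-gap global aligner (Gotoh recursion),
# used only as an oracle on short instances.  Scoring: match +1, mismatch -1,
# gap of length k costs 5 + k; N scores 0 against anything.
gotoh_score <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  subsc <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to '-')
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- subsc(av[i], bv[j])
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Mutate a sequence with k random substitutions (never silent).
mutate_seq <- function(seq, k) {
  L <- nchar(seq)
  at <- sample.int(L, k)
  for (j in at) {
    old <- substr(seq, j, j)
    substr(seq, j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}

norm_indices <- function(x) {
  vapply(strsplit(ifelse(is.na(x), "", x), ","), function(v)
    paste(sort(as.integer(v[nzchar(v)])), collapse = ","), character(1))
}
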