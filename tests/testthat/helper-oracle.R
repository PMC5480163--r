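# Independent test oracles, deliberately naive implementations.

# Exhaustive affine-gap Smith-Waterman best local score (match +1,
# mismatch -1, gap of length L costs open + L*ext). Pure dynamic
# programming over the full matrix; no heuristics.
sw_score_one <- function(read, subject, match = 1, mismatch = -1,
                         gap_open = 2, gap_ext = 1) {
  a <- strsplit(read, "")[[1L]]
  b <- strsplit(subject, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap consuming subject
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap consuming read
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      M[i, j] <- s + max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                     X[i, j - 1L] - gap_ext)
      Y[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                     Y[i - 1L, j] - gap_ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# best score over both strands
sw_score_both <- function(read, subject) {
  max(sw_score_one(read, subject), sw_score_one(revcomp_chr(read), subject))
}

# Spearman rho by explicit midranks + Pearson formula
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
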