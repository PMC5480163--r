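#' Quality-trim reads from the 3' end
#'
#' Bases are removed from the 3' end while the terminal base quality is below
#' `threshold` (the FASTX-style trimmer rule); reads trimmed to zero length
#' are discarded. Retained bases are never altered — the output is always a
#' prefix of the input read.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param threshold minimum terminal Phred quality (default 20).
#' @return A trimmed `QualityScaledDNAStringSet`; the number of discarded
#'   reads is `length(reads) - length(result)`.
#' @export
quality_trim <- function(reads, threshold = 20L) {
  if (!length(reads)) return(reads)
  q <- quality_ints(reads)
  keep_len <- vapply(q, function(x) {
    w <- which(x >= threshold)
    if (length(w)) w[length(w)] else 0L
  }, 0L)
  kept <- keep_len > 0L
  prefix_reads(reads[kept], keep_len[kept])
}

#' Remove a 3' sequencing adapter
#'
#' Finds the best occurrence of `adapter` in each read — either a full
#' internal match or a suffix overlap of at least `min_overlap` bases — with
#' mismatch fraction at most `max_err`, and removes it together with
#' everything 3' of it. Matching is substitution-only (semi-global suffix
#' alignment without indels); N bases count as mismatches. Among acceptable
#' occurrences the one with the most matching bases wins, ties broken toward
#' the longest removed suffix. All reads shorter than `min_len` after
#' trimming are discarded.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param adapter adapter sequence (default the Illumina TruSeq stem).
#' @param max_err maximum mismatch fraction per occurrence.
#' @param min_overlap minimum 3'-overlap length considered.
#' @param min_len minimum retained read length after trimming.
#' @return A trimmed, filtered `QualityScaledDNAStringSet`.
#' @export
adapter_trim <- function(reads, adapter = "AGATCGGAAGAGC", max_err = 0.05,
                         min_overlap = 1L, min_len = 100L) {
  if (!nchar(adapter)) stop("adapter must be non-empty")
  if (!length(reads)) return(reads)
  seqs <- as.character(as(reads, "DNAStringSet"))
  w <- nchar(seqs)
  la <- nchar(adapter)
  n <- length(seqs)
  best_matches <- rep(-1L, n)   # matching bases of best acceptable occurrence
  best_cut <- w + 1L            # adapter start position (1-based); keep prefix
  note <- function(idx, matches, cut) {
    upd <- matches > best_matches[idx] |
      (matches == best_matches[idx] & cut < best_cut[idx])
    best_matches[idx[upd]] <<- matches[upd]
    best_cut[idx[upd]] <<- cut[upd]
  }

  # full internal occurrences (overlap = la)
  kmax <- floor(max_err * la)
  mi <- Biostrings::vmatchPattern(adapter, as(reads, "DNAStringSet"),
                                  max.mismatch = kmax)
  starts <- IRanges::start(mi)
  hit <- which(lengths(starts) > 0L)
  for (i in hit) {
    st <- starts[[i]]
    mm <- vapply(st, function(p) {
      sum(strsplit(substr(seqs[i], p, p + la - 1L), "")[[1L]] !=
          strsplit(adapter, "")[[1L]])
    }, 0L)
    okc <- mm <= kmax
    if (any(okc)) {
      j <- which(okc)
      b <- j[order(mm[j], st[j])][1L]
      note(i, la - mm[b], st[b])
    }
  }

  # suffix overlaps (overlap o < la): adapter prefix vs read suffix
  o_max <- min(la - 1L, max(w))
  for (o in if (min_overlap <= o_max) seq.int(min_overlap, o_max) else
       integer()) {
    idx <- which(w >= o)
    if (!length(idx)) next
    ap <- substr(adapter, 1L, o)
    ss <- substring(seqs[idx], w[idx] - o + 1L, w[idx])
    mm <- integer(length(idx))
    for (j in seq_len(o)) {
      mm <- mm + (substring(ss, j, j) != substring(ap, j, j))
    }
    okc <- mm <= floor(max_err * o)
    if (any(okc)) {
      note(idx[okc], o - mm[okc], (w[idx] - o + 1L)[okc])
    }
  }

  new_len <- ifelse(best_matches >= 0L, best_cut - 1L, w)
  kept <- new_len >= min_len
  prefix_reads(reads[kept], new_len[kept])
}

#' Trim reads to a fixed length
#'
#' Truncates each read to its first `target_len` bases and discards reads
#' shorter than `target_len`, so that every retained read contributes the
#' same number of k-mers to a spectrum.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param target_len target length (default 100, the k-mer analysis length).
#' @return A `QualityScaledDNAStringSet` of uniform width `target_len`.
#' @export
fixed_trim <- function(reads, target_len = 100L) {
  if (target_len <= 0L) stop("target_len must be positive")
  if (!length(reads)) return(reads)
  kept <- Biostrings::width(reads) >= target_len
  prefix_reads(reads[kept], rep(as.integer(target_len), sum(kept)))
}

#' Run the standard read-preprocessing pipeline
#'
#' Quality trimming followed by adapter removal (in that order), with
#' book-keeping: the returned statistics conserve read counts across every
#' stage (`in = out + discarded`).
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param quality_threshold 3' quality-trim threshold.
#' @param kmer_trim optional fixed length for k-mer analysis; `NULL` skips
#'   the fixed trim.
#' @inheritParams adapter_trim
#' @return List with `reads` (processed set) and `stats` (per-stage counts).
#' @export
prep_reads <- function(reads, quality_threshold = 20L,
                       adapter = "AGATCGGAAGAGC", max_err = 0.05,
                       min_overlap = 1L, min_len = 100L, kmer_trim = NULL) {
  n_in <- length(reads)
  qt <- quality_trim(reads, quality_threshold)
  at <- adapter_trim(qt, adapter, max_err, min_overlap, min_len)
  out <- at
  stats <- list(n_in = n_in,
                quality_trim = list(out = length(qt),
                                    discarded = n_in - length(qt)),
                adapter_trim = list(out = length(at),
                                    discarded = length(qt) - length(at)))
  if (!is.null(kmer_trim)) {
    out <- fixed_trim(at, kmer_trim)
    stats$fixed_trim <- list(out = length(out),
                             discarded = length(at) - length(out))
  }
  stats$n_out <- length(out)
  list(reads = out, stats = stats)
}
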