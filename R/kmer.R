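#' Sample satellite reads for k-mer analysis
#'
#' Uniform sample without replacement of a fixed number of reads (the same
#' sampling depth for every sample makes copy-number spectra directly
#' comparable). The pool is expected to be pre-filtered to satellite reads
#' (e.g. alignment length >= 90 bp to the consensus dimer) and length-trimmed
#' with [fixed_trim()].
#'
#' @param reads a `QualityScaledDNAStringSet` or `DNAStringSet`.
#' @param n sample size (default 30000).
#' @param seed integer seed.
#' @return A read set of exactly `n` reads.
#' @export
sample_satellite_reads <- function(reads, n = 30000L, seed = NULL) {
  pool <- length(reads)
  if (pool < n) {
    stop(sprintf("satellite read pool too small: need %d, have %d (short by %d)",
                 n, pool, n - pool))
  }
  if (pool == n) return(reads)
  idx <- with_seed(seed, sample.int(pool, n))
  reads[idx]
}

#' Count k-mers in a read sample
#'
#' Every k-length substring of every read is counted. In
#' `"consensus"` orientation (default) minus-strand reads are
#' reverse-complemented before counting, so that all reads contribute k-mers
#' on the consensus strand of the circular repeat — mixing strands would
#' split each repeat k-mer over two apparent k-mers and halve apparent
#' homogenization. `"as-read"` counts reads as sequenced. k-mers containing
#' N are skipped and tallied separately.
#'
#' @param reads read set (all reads should have equal length; enforce with
#'   [fixed_trim()]). Reads shorter than `k` are excluded with a tally.
#' @param k k-mer length (default 50).
#' @param orientation `"consensus"` or `"as-read"`.
#' @param strand per-read strand (`"+"`/`"-"`) used by `"consensus"`
#'   orientation, e.g. the `strand` column of a hit table or simulation
#'   truth; `NULL` treats all reads as plus-strand.
#' @return An object of class `kmer_spectrum`: list with `k`, `n_reads`,
#'   `read_len`, `counts` (data.table: kmer, count), `total` (total counted
#'   k-mer positions), `n_distinct`, `n_skipped_n` (N-containing k-mers) and
#'   `n_short_reads`.
#' @export
count_kmers <- function(reads, k = 50L, orientation = c("consensus",
                                                        "as-read"),
                        strand = NULL) {
  orientation <- match.arg(orientation)
  seqs <- as(reads, "DNAStringSet")
  n_short <- sum(Biostrings::width(seqs) < k)
  if (n_short > 0L) {
    warning(sprintf("%d read(s) shorter than k = %d excluded", n_short, k))
    keep <- Biostrings::width(seqs) >= k
    if (!is.null(strand)) strand <- strand[keep]
    seqs <- seqs[keep]
  }
  if (orientation == "consensus" && !is.null(strand)) {
    stopifnot(length(strand) == length(seqs))
    minus <- strand == "-"
    if (any(minus)) {
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    }
  }
  if (!length(seqs)) {
    return(structure(list(k = k, n_reads = 0L, read_len = integer(),
                          counts = data.table::data.table(kmer = character(),
                                                          count = integer()),
                          total = 0L, n_distinct = 0L, n_skipped_n = 0L,
                          n_short_reads = n_short),
                     class = "kmer_spectrum"))
  }
  ch <- as.character(seqs)
  w <- nchar(ch)
  npos <- w - k + 1L
  starts <- sequence(npos)
  kmers <- substring(rep(ch, times = npos), starts, starts + k - 1L)
  has_n <- grepl("N", kmers, fixed = TRUE)
  n_skip <- sum(has_n)
  dt <- data.table::data.table(kmer = kmers[!has_n])
  counts <- dt[, .N, by = "kmer"]
  data.table::setnames(counts, "N", "count")
  data.table::setorder(counts, -count, kmer)
  structure(list(k = as.integer(k), n_reads = length(seqs),
                 read_len = unique(w),
                 counts = counts,
                 total = nrow(dt), n_distinct = nrow(counts),
                 n_skipped_n = n_skip, n_short_reads = n_short),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k=%d: %d reads, %d distinct k-mers, mean copy number %.1f\n",
              x$k, x$n_reads, x$n_distinct,
              if (x$n_distinct) x$total / x$n_distinct else NA_real_))
  invisible(x)
}

#' Analytic homogeneous-array k-mer baseline
#'
#' Expected mean copy number of a distinct k-mer when `n_reads` reads of
#' `read_len` bases are drawn from a perfectly homogeneous circular monomer
#' of `monomer_len` bases: each read carries `read_len - k + 1` k-mers and
#' the circle has exactly `monomer_len` distinct k-mer start positions, so
#' the expectation is `(read_len - k + 1) * n_reads / monomer_len`. Observed
#' spectra are compared against this homogeneous limit: polymorphic arrays
#' spread the same k-mer mass over many more distinct k-mers, collapsing
#' copy numbers far below the baseline.
#'
#' @param read_len read length (bp).
#' @param n_reads number of sampled reads.
#' @param k k-mer length.
#' @param monomer_len circular monomer length (bp).
#' @return Expected copies per distinct k-mer (real).
#' @examples
#' expected_homogeneous_copy(100, 30000, 50, 156)  # ~9808
#' @export
expected_homogeneous_copy <- function(read_len, n_reads, k, monomer_len) {
  stopifnot(k >= 1, monomer_len >= 1, n_reads >= 0)
  if (read_len < k) stop("read_len must be at least k")
  (read_len - k + 1) * n_reads / monomer_len
}

#' Copy-number histogram of a k-mer spectrum
#'
#' Fraction of distinct k-mers with copy number below each threshold, plus
#' the maximum copy number — the summary used to contrast polymorphic
#' satellite spectra (mass concentrated at low copy numbers) with the
#' homogeneous limit (all mass near the analytic baseline).
#'
#' @param spectrum a [count_kmers()] result.
#' @param thresholds copy-number thresholds (default `c(100, 2000)`).
#' @return List with `n_distinct`, `fraction_below` (named by threshold),
#'   `max_copy`, `mean_copy` and `empty` flag.
#' @export
copy_number_histogram <- function(spectrum, thresholds = c(100, 2000)) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (spectrum$n_distinct == 0L) {
    return(list(n_distinct = 0L,
                fraction_below = setNames(rep(NA_real_, length(thresholds)),
                                          thresholds),
                max_copy = NA_integer_, mean_copy = NA_real_, empty = TRUE))
  }
  cn <- spectrum$counts$count
  list(n_distinct = spectrum$n_distinct,
       fraction_below = setNames(
         vapply(thresholds, function(t) mean(cn < t), 0), thresholds),
       max_copy = max(cn),
       mean_copy = spectrum$total / spectrum$n_distinct,
       empty = FALSE)
}

#' Write a k-mer spectrum as TSV
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output path (columns: kmer, count).
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(spectrum$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
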