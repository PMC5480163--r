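#' Read and write FASTQ read sets
#'
#' Reads are carried through the pipeline as
#' [Biostrings::QualityScaledDNAStringSet] objects (sequence + per-base
#' Phred quality, offset 33 on disk).
#'
#' @param path FASTQ file path.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities)
  S4Vectors::mcols(x) <- NULL
  Biostrings::QualityScaledDNAStringSet(x, q)
}

#' @rdname read_fastq
#' @param reads a `QualityScaledDNAStringSet`.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

# build a read set from character sequences + constant or explicit qualities
make_reads <- function(seqs, quals = 35L, ids = NULL) {
  seqs <- as.character(seqs)
  if (is.numeric(quals)) {
    quals <- vapply(nchar(seqs), function(w)
      paste(rep(rawToChar(as.raw(33L + as.integer(quals[1L]))), w),
            collapse = ""), "")
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  if (!is.null(ids)) names(x) <- ids
  x
}

# narrow sequence and quality together (always from position 1)
prefix_reads <- function(reads, new_width) {
  stopifnot(length(new_width) == length(reads))
  s <- IRanges::narrow(as(reads, "DNAStringSet"), 1L, new_width)
  q <- IRanges::narrow(as(Biostrings::quality(reads), "BStringSet"),
                          1L, new_width)
  out <- Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(q))
  names(out) <- names(reads)
  out
}

quality_ints <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}
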