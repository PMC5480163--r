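# Shared fixtures: tiny consensuses, synthetic read/record builders.

toy_monomer <- "ACGTTGCAAGGCTTAACGGT"  # 20 bp, no internal self-similarity

toy_consensus <- function() repeat_consensus("toy", toy_monomer)

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

qreads <- function(seqs, quals = 35L, ids = NULL) {
  centsat:::make_reads(seqs, quals, ids %||% sprintf("r%04d", seq_along(seqs)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# phred string of given qualities
qstring <- function(q) {
  paste(vapply(q, function(v) rawToChar(as.raw(33L + v)), ""), collapse = "")
}

# alignment_records built directly from simulation truth (perfect mapper):
# lets downstream track/drift tests run without invoking an external aligner.
records_from_sim <- function(sim, seqlengths) {
  out <- data.frame(read_id = sim$truth$id, chrom = sim$truth$chrom,
                    start = sim$truth$start, strand = sim$truth$strand,
                    mapq = 60L, unique = TRUE)
  attr(out, "seqlengths") <- seqlengths
  class(out) <- c("alignment_records", "data.frame")
  out
}

# constructed enrichment track from a vector of per-bin enrichment values
make_track <- function(enrich, bin = 20000L, chrom = "chr1",
                       mask = rep("ok", length(enrich))) {
  n <- length(enrich)
  tr <- data.frame(chrom = chrom, start = (seq_len(n) - 1L) * bin,
                   end = seq_len(n) * bin,
                   chip = pmax(0, round(enrich * 100)), input = 100L,
                   enrichment = enrich, mask = mask)
  tr$enrichment[tr$mask != "ok"] <- NA_real_
  attr(tr, "bin") <- as.integer(bin)
  attr(tr, "seqlengths") <- setNames(n * bin, chrom)
  class(tr) <- c("enrichment_track", "data.frame")
  tr
}
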