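#' Map reads to a reference and keep uniquely mapping records
#'
#' Runs BWA-MEM on the reads and retains primary alignments; a record is
#' flagged `unique` when its mapping quality is at least `min_mapq` (the
#' operational definition of unique mapping used throughout: multi-mapping
#' reads — e.g. reads from inside homogeneous satellite arrays — get MAPQ 0
#' and are excluded from coverage).
#'
#' @param reads a `QualityScaledDNAStringSet`, `DNAStringSet`, or FASTQ path.
#' @param genome a `sim_genome`, named `DNAStringSet`, or FASTA path.
#' @param min_mapq MAPQ threshold defining unique mapping (default 20).
#' @param keep_nonunique keep primary records below the MAPQ threshold in the
#'   table (flagged `unique = FALSE`); they never enter coverage.
#' @return A data frame of class `alignment_records`: `read_id`, `chrom`,
#'   `start` (0-based), `strand`, `mapq`, `unique`; attribute `seqlengths`
#'   carries the reference chromosome lengths.
#' @export
map_reads <- function(reads, genome, min_mapq = 20L, keep_nonunique = TRUE) {
  bwa <- Sys.which("bwa")
  if (bwa == "") stop("bwa executable not found on PATH")
  td <- tempfile("map")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)

  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ref <- file.path(td, "ref.fa")
    file.copy(genome, ref)
  } else {
    gen <- if (inherits(genome, "sim_genome")) genome$genome else genome
    if (!length(gen)) stop("empty genome")
    ref <- file.path(td, "ref.fa")
    Biostrings::writeXStringSet(gen, ref)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- reads
  } else {
    fq <- file.path(td, "reads.fq")
    if (inherits(reads, "QualityScaledDNAStringSet")) {
      write_fastq(reads, fq)
    } else {
      fq <- file.path(td, "reads.fa")
      Biostrings::writeXStringSet(as(reads, "DNAStringSet"), fq)
    }
  }

  sam <- file.path(td, "aln.sam")
  system2(bwa, c("index", ref), stdout = FALSE, stderr = FALSE)
  status <- system2(bwa, c("mem", "-v", "1", ref, fq),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("bwa mem failed (exit status ", status, ")")
  recs <- read_alignments(sam, min_mapq = min_mapq,
                          keep_nonunique = keep_nonunique)
  attr(recs, "seqlengths") <- seqlens(if (inherits(genome, "sim_genome"))
    genome else Biostrings::readDNAStringSet(ref))
  recs
}

#' Ingest externally produced alignments (SAM/BAM)
#'
#' Applies the MAPQ-based uniqueness filter literally to primary alignments
#' from any mapper; secondary, supplementary and unmapped records are
#' dropped.
#'
#' @param path SAM or BAM file.
#' @inheritParams map_reads
#' @return An `alignment_records` data frame (see [map_reads()]).
#' @export
read_alignments <- function(path, min_mapq = 20L, keep_nonunique = TRUE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile("aln"), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flt <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flt, what = c("qname", "rname", "pos", "strand", "mapq")))[[1L]]
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  out <- data.frame(read_id = res$qname,
                    chrom = as.character(res$rname),
                    start = res$pos - 1L,
                    strand = as.character(res$strand),
                    mapq = mapq,
                    unique = mapq >= min_mapq)
  if (!keep_nonunique) out <- out[out$unique, , drop = FALSE]
  sl <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  attr(out, "seqlengths") <- sl
  class(out) <- c("alignment_records", "data.frame")
  out
}
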