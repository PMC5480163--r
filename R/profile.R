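#' Binned ChIP/input enrichment track with masking
#'
#' Counts uniquely mapping read starts per fixed-width bin in each channel
#' and computes the library-size-normalized enrichment ratio
#' `(chip_i / chip_total) / (input_i / input_total)`. Bins overlapping
#' annotated satellite positions are flagged `satellite` (enrichment there is
#' unreliable: unique mapping collapses inside arrays); bins with zero input
#' coverage are flagged `zero_input`. Enrichment is defined only for `ok`
#' bins.
#'
#' @param chip,input `alignment_records` from [map_reads()] or
#'   [read_alignments()], mapped to the same reference.
#' @param bin bin width in bp (default 20000).
#' @param satellite_mask optional satellite annotation: a data frame or
#'   `GRanges` with chrom/start/end (0-based half-open for data frames).
#' @param seqlengths named chromosome lengths; defaults to the records'
#'   `seqlengths` attribute.
#' @return A data frame of class `enrichment_track`: `chrom`, `start`, `end`
#'   (0-based half-open), `chip`, `input`, `enrichment`, `mask` (`ok`,
#'   `zero_input` or `satellite`); attribute `bin`.
#' @export
bin_enrichment <- function(chip, input, bin = 20000L, satellite_mask = NULL,
                           seqlengths = NULL) {
  sl <- seqlengths %||% attr(chip, "seqlengths") %||%
    attr(input, "seqlengths")
  if (is.null(sl)) stop("chromosome lengths unavailable")
  chip <- chip[chip$unique, , drop = FALSE]
  input <- input[input$unique, , drop = FALSE]
  if (!nrow(chip) || !nrow(input)) {
    stop("no uniquely mapping reads in one of the channels")
  }
  bins <- do.call(rbind, lapply(names(sl), function(nm) {
    s <- seq(0L, sl[[nm]] - 1L, by = bin)
    data.frame(chrom = nm, start = s, end = pmin(s + bin, sl[[nm]]))
  }))
  count_channel <- function(rec) {
    idx <- match(rec$chrom, names(sl))
    bin_idx <- rec$start %/% bin
    key <- paste(rec$chrom, bin_idx)
    tab <- table(key)
    cnt <- integer(nrow(bins))
    bk <- paste(bins$chrom, bins$start %/% bin)
    m <- match(names(tab), bk)
    cnt[m[!is.na(m)]] <- as.integer(tab[!is.na(m)])
    cnt
  }
  bins$chip <- count_channel(chip)
  bins$input <- count_channel(input)
  ct <- sum(bins$chip)
  it <- sum(bins$input)
  bins$enrichment <- (bins$chip / ct) / (bins$input / it)
  bins$mask <- "ok"
  bins$mask[bins$input == 0L] <- "zero_input"
  if (!is.null(satellite_mask)) {
    gr_mask <- as_granges0(satellite_mask)
    gr_bins <- GenomicRanges::GRanges(
      bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
    hit <- IRanges::overlapsAny(gr_bins, gr_mask)
    bins$mask[hit] <- "satellite"
  }
  bins$enrichment[bins$mask != "ok"] <- NA_real_
  attr(bins, "bin") <- as.integer(bin)
  attr(bins, "seqlengths") <- sl
  class(bins) <- c("enrichment_track", "data.frame")
  bins
}

# data frame (0-based half-open) or GRanges -> GRanges (1-based)
as_granges0 <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Annotate satellite repeat positions in a reference
#'
#' Finds all loci on both strands that share exact `word_size`-mers with the
#' consensus dimer, merges nearby seeds (gaps up to one monomer) into
#' candidate intervals, and verifies each candidate by local alignment
#' against the dimer. The resulting intervals mark positions where
#' unique-mapping enrichment values are unreliable and should be masked.
#'
#' @param genome a `sim_genome`, named `DNAStringSet` or FASTA path.
#' @param consensus a [repeat_consensus()].
#' @param word_size exact seed length.
#' @param min_width minimum reported interval width (default 125, matching
#'   the read-level quantification threshold).
#' @param min_identity minimum alignment identity for verification.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
annotate_reference_repeats <- function(genome, consensus, word_size = 12L,
                                       min_width = 125L,
                                       min_identity = 0.7) {
  gen <- if (inherits(genome, "sim_genome")) genome$genome
         else if (is.character(genome)) Biostrings::readDNAStringSet(genome)
         else genome
  L <- consensus$monomer_len
  words <- Biostrings::DNAStringSet(
    consensus$dimer, start = seq_len(2L * L - word_size + 1L),
    width = word_size)
  words <- unique(c(words, Biostrings::reverseComplement(words)))
  pd <- Biostrings::PDict(words)
  out <- list()
  for (nm in names(gen)) {
    m <- Biostrings::matchPDict(pd, gen[[nm]])
    ir <- unlist(IRanges::IRangesList(m))
    if (!length(ir)) next
    merged <- IRanges::reduce(ir, min.gapwidth = L)
    merged <- merged[IRanges::width(merged) >= min_width]
    if (!length(merged)) next
    keep <- vapply(seq_along(merged), function(i) {
      s <- IRanges::start(merged)[i]
      e <- min(IRanges::end(merged)[i], s + 600L)
      frag <- XVector::subseq(gen[[nm]], s, e)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(frag), consensus$dimer, type = "local",
        substitutionMatrix = blast_submat(), gapOpening = 2,
        gapExtension = 1)
      alr <- Biostrings::pairwiseAlignment(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(frag)),
        consensus$dimer, type = "local",
        substitutionMatrix = blast_submat(), gapOpening = 2,
        gapExtension = 1)
      len <- max(Biostrings::nchar(al), Biostrings::nchar(alr))
      idn <- max(Biostrings::nmatch(al) / Biostrings::nchar(al),
                 Biostrings::nmatch(alr) / Biostrings::nchar(alr))
      len >= min(min_width, 100L) && idn >= min_identity
    }, TRUE)
    merged <- merged[keep]
    if (length(merged)) {
      out[[nm]] <- data.frame(chrom = nm,
                              start = IRanges::start(merged) - 1L,
                              end = IRanges::end(merged))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call complex centromeres from an enrichment track
#'
#' A complex centromere is a CENH3 enrichment peak spanning more than
#' `min_len` bp of unique-mappable sequence. Peaks are maximal runs of
#' unmasked bins with enrichment at least `min_enrich`, tolerating up to
#' `max_gap_bins` consecutive interior sub-threshold or masked bins; the
#' reported span includes tolerated gaps. Per chromosome, multiple peaks
#' (potentially explained by heterozygosity) count as a single complex
#' centromere.
#'
#' @param track an [bin_enrichment()] track.
#' @param min_enrich minimum bin enrichment inside a peak (default 2).
#' @param min_len minimum peak span in bp; peaks must exceed this strictly
#'   (default 500000).
#' @param max_gap_bins tolerated consecutive interior gap bins (default 2).
#' @return List of class `centromere_calls`: `peaks` (data frame: chrom,
#'   start, end, length, mean_enrichment, n_bins), `chrom_counts` (named
#'   per-chromosome complex-centromere count, each `min(1, n_peaks)`) and
#'   `n_complex` (their sum).
#' @export
call_complex_centromeres <- function(track, min_enrich = 2, min_len = 500000L,
                                     max_gap_bins = 2L) {
  stopifnot(inherits(track, "enrichment_track"))
  peaks <- list()
  for (nm in unique(track$chrom)) {
    tr <- track[track$chrom == nm, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    good <- which(tr$mask == "ok" & !is.na(tr$enrichment) &
                  tr$enrichment >= min_enrich)
    if (!length(good)) next
    run_id <- cumsum(c(1L, diff(good) > max_gap_bins + 1L))
    for (r in unique(run_id)) {
      g <- good[run_id == r]
      start <- tr$start[g[1L]]
      end <- tr$end[g[length(g)]]
      if (end - start > min_len) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = nm, start = start, end = end, length = end - start,
          mean_enrichment = mean(tr$enrichment[g]),
          n_bins = length(g))
      }
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               length = numeric(), mean_enrichment = numeric(),
               n_bins = integer())
  counts <- table(factor(peaks$chrom, levels = unique(track$chrom)))
  chrom_counts <- setNames(pmin(1L, as.integer(counts)), names(counts))
  structure(list(peaks = peaks, chrom_counts = chrom_counts,
                 n_complex = sum(chrom_counts)),
            class = "centromere_calls")
}

#' @export
print.centromere_calls <- function(x, ...) {
  cat(sprintf("<centromere_calls> %d peak(s), %d complex centromere(s)\n",
              nrow(x$peaks), x$n_complex))
  invisible(x)
}

#' Correlate satellite abundance with complex-centromere counts
#'
#' Spearman rank correlation (midranks for ties) between per-sample satellite
#' fractions and per-sample complex-centromere counts; in genomes where large
#' satellite arrays are available, centromeres are expected to reside there,
#' so abundance should correlate negatively with detectable complex
#' centromeres.
#'
#' @param counts per-sample complex-centromere counts.
#' @param fractions per-sample satellite fractions (percent).
#' @return List with `rho`, `p_value` and a `table` of the paired values.
#' @export
correlate_abundance <- function(counts, fractions) {
  stopifnot(length(counts) == length(fractions))
  if (length(counts) < 3L) stop("need at least 3 paired samples")
  if (length(unique(counts)) == 1L || length(unique(fractions)) == 1L) {
    stop("rank correlation undefined for constant input")
  }
  ct <- suppressWarnings(cor.test(fractions, counts, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       table = data.frame(fraction = fractions, n_complex = counts))
}
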