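#' Quantify a satellite repeat in a read set
#'
#' Fraction of reads whose best local alignment to the consensus dimer spans
#' at least `min_aln` columns, plus the per-read identity distribution in 1%
#' bins. A read set can be quantified against several consensuses
#' independently (a read hitting two families counts for each — the reported
#' per-family fractions are not a partition of the reads).
#'
#' @inheritParams align_to_circular_consensus
#' @param channel optional label (`"chip"` or `"input"`) carried into the
#'   result.
#' @param hits optional precomputed [align_to_circular_consensus()] result
#'   for these reads (skips alignment).
#' @return An object of class `repeat_quant`: list with `consensus`,
#'   `channel`, `n_reads`, `n_hits`, `fraction` (percent of reads),
#'   `identity` (per-hit identities), `identity_hist` (counts in 1% bins,
#'   names = upper bin edge in percent) and `hits` (the hit table).
#' @export
quantify_repeat <- function(reads, consensus, min_aln = 125L,
                            channel = NA_character_, score_min = NULL,
                            prefilter = TRUE, hits = NULL) {
  n_reads <- length(as(reads, "DNAStringSet"))
  if (n_reads == 0L) stop("empty read set: nothing to quantify")
  if (is.null(hits)) {
    hits <- align_to_circular_consensus(reads, consensus, min_aln = min_aln,
                                        score_min = score_min,
                                        prefilter = prefilter)
  }
  idp <- hits$identity * 100
  breaks <- seq(0, 100, by = 1)
  hist_counts <- table(cut(idp, breaks = breaks, include.lowest = TRUE,
                           right = TRUE,
                           labels = sprintf("%d", seq(1, 100))))
  hist_counts <- setNames(as.integer(hist_counts), names(hist_counts))
  structure(list(consensus = consensus$name,
                 channel = channel,
                 n_reads = n_reads,
                 n_hits = nrow(hits),
                 fraction = 100 * nrow(hits) / n_reads,
                 identity = hits$identity,
                 identity_hist = hist_counts,
                 identity_bins = breaks,
                 hits = hits),
            class = "repeat_quant")
}

#' @export
print.repeat_quant <- function(x, ...) {
  cat(sprintf("<repeat_quant> %s%s: %d / %d reads (%.3f%%), mean identity %s\n",
              x$consensus,
              if (!is.na(x$channel)) paste0(" [", x$channel, "]") else "",
              x$n_hits, x$n_reads, x$fraction,
              if (x$n_hits) sprintf("%.1f%%", 100 * mean(x$identity))
              else "NA"))
  invisible(x)
}

#' Compare per-read identity distributions between two samples
#'
#' Used to ask whether CENH3-bound (ChIP) satellite copies resemble the
#' consensus more than genomic (input) copies do: reports the difference of
#' mean identities (percentage points, `a - b`) and the L1 distance between
#' the normalized 1%-bin identity histograms (in `[0, 2]`).
#'
#' @param a,b `repeat_quant` results for the same consensus.
#' @return List with `mean_identity_a`, `mean_identity_b`, `mean_diff`
#'   (percentage points) and `l1_distance`.
#' @export
compare_identity_distributions <- function(a, b) {
  stopifnot(inherits(a, "repeat_quant"), inherits(b, "repeat_quant"))
  if (!identical(a$consensus, b$consensus)) {
    stop("results quantify different consensuses")
  }
  if (a$n_hits == 0L || b$n_hits == 0L) {
    stop("identity distributions undefined: zero hits on one side")
  }
  ha <- a$identity_hist / sum(a$identity_hist)
  hb <- b$identity_hist / sum(b$identity_hist)
  list(mean_identity_a = 100 * mean(a$identity),
       mean_identity_b = 100 * mean(b$identity),
       mean_diff = 100 * (mean(a$identity) - mean(b$identity)),
       l1_distance = sum(abs(ha - hb)))
}

#' Refine a circular repeat consensus from reads
#'
#' Iterative majority-vote consensus: reads are aligned to the current
#' monomer's dimer, each aligned base votes for its position on the monomer
#' circle (alignment start modulo monomer length fixes the rotation), and
#' the column-wise majority base becomes the next monomer. Iteration stops
#' at a fixed point or after `max_iter` rounds. The result is reported in
#' canonical rotation (lexicographically minimal), with per-column read
#' support; columns supported by fewer than `min_support` reads keep the
#' seed base and are flagged.
#'
#' @param reads satellite reads (any representation accepted by
#'   [align_to_circular_consensus()]).
#' @param seed_monomer starting monomer (character or `DNAString`); its
#'   length fixes the monomer length (substitution-only model).
#' @param max_iter maximum refinement rounds.
#' @param min_aln minimum alignment columns for a read to vote (default half
#'   the monomer, capped by read length).
#' @param min_support minimum reads covering a column for a confident call.
#' @return A [repeat_consensus()] (name `"refined"`) with attributes
#'   `support` (per-column read counts, in canonical rotation),
#'   `low_support` (logical flags) and `iterations`.
#' @export
build_consensus <- function(reads, seed_monomer, max_iter = 10L,
                            min_aln = NULL, min_support = 3L) {
  seqs <- as(reads, "DNAStringSet")
  seedc <- repeat_consensus("seed", seed_monomer)
  L <- seedc$monomer_len
  if (is.null(min_aln)) {
    min_aln <- min(ceiling(L / 2), min(Biostrings::width(seqs)))
  }
  cur <- as.character(seedc$monomer)
  bases <- c("A", "C", "G", "T")
  support <- integer(L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cons <- repeat_consensus("refined", cur)
    hits <- align_to_circular_consensus(seqs, cons, min_aln = min_aln,
                                        score_min = 0L, prefilter = FALSE)
    if (!nrow(hits)) stop("no reads align to the seed monomer")
    votes <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
    mat <- blast_submat()
    oriented <- seqs[hits$read_idx]
    minus <- hits$strand == "-"
    if (any(minus)) {
      oriented[minus] <- Biostrings::reverseComplement(oriented[minus])
    }
    al <- Biostrings::pairwiseAlignment(oriented, cons$dimer, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    sstart <- IRanges::start(Biostrings::subject(al))
    for (r in seq_along(pa)) {
      pc <- strsplit(pa[r], "")[[1L]]
      sc <- strsplit(sa[r], "")[[1L]]
      spos <- sstart[r] - 1L            # 0-based position on dimer
      for (j in seq_along(pc)) {
        if (sc[j] != "-") {
          if (pc[j] %in% bases) {
            col <- (spos %% L) + 1L
            votes[pc[j], col] <- votes[pc[j], col] + 1L
          }
          spos <- spos + 1L
        }
      }
    }
    support <- colSums(votes)
    nxt <- vapply(seq_len(L), function(j) {
      if (support[j] == 0L) substr(cur, j, j)
      else bases[which.max(votes[, j])]
    }, "")
    nxt <- paste(nxt, collapse = "")
    if (nxt == cur || iter >= max_iter) {
      cur <- nxt
      break
    }
    cur <- nxt
  }
  low <- support < min_support
  # rotate support alongside the canonical rotation of the sequence
  canon <- as.character(canonical_rotation(cur))
  rot <- which(substring(paste0(cur, cur),
                         seq_len(nchar(cur)),
                         seq_len(nchar(cur)) + nchar(cur) - 1L) == canon)[1L]
  idx <- ((seq_len(L) - 1L + rot - 1L) %% L) + 1L
  out <- repeat_consensus("refined", canon)
  attr(out, "support") <- support[idx]
  attr(out, "low_support") <- low[idx]
  attr(out, "iterations") <- iter
  out
}
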