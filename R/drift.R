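#' Quantify positional drift between two CENH3 profiles
#'
#' Compares two enrichment tracks inside a window (typically a called
#' centromere plus flanks). Each profile is normalized to unit mass over the
#' jointly unmasked bins, then three complementary statistics are reported:
#' the centroid shift in bp (B minus A; signed, so symmetric drift cancels),
#' the L1 distance between the normalized profiles (0 for identical
#' profiles, at most 2 for disjoint ones), and the asymmetry delta (mass
#' right of the window midpoint minus mass left, B minus A — positive when
#' B's coverage has moved rightward relative to A's).
#'
#' @param track_a,track_b [bin_enrichment()] tracks on the same reference
#'   with the same bin size.
#' @param window list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open bp).
#' @param use what to compare per bin: `"enrichment"` (default) or raw
#'   `"chip"` counts.
#' @return An object of class `drift_report`: `window`, `centroid_a`,
#'   `centroid_b`, `centroid_shift` (bp, B − A), `l1_distance`,
#'   `asymmetry_a`, `asymmetry_b`, `asymmetry_delta` (B − A), `n_bins`.
#' @export
profile_distance <- function(track_a, track_b, window,
                             use = c("enrichment", "chip")) {
  use <- match.arg(use)
  stopifnot(inherits(track_a, "enrichment_track"),
            inherits(track_b, "enrichment_track"))
  if (!identical(attr(track_a, "bin"), attr(track_b, "bin"))) {
    stop("tracks have different bin sizes")
  }
  w <- as.list(window)
  sel <- function(tr) {
    tr$chrom == w$chrom & tr$start >= w$start & tr$end <= w$end
  }
  a <- track_a[sel(track_a), , drop = FALSE]
  b <- track_b[sel(track_b), , drop = FALSE]
  if (!nrow(a) || !nrow(b) || !identical(a$start, b$start)) {
    stop("tracks do not share bins inside the window")
  }
  ok <- a$mask == "ok" & b$mask == "ok"
  if (!any(ok)) stop("no jointly unmasked bins in window: tracks incomparable")
  va <- if (use == "enrichment") a$enrichment[ok] else a$chip[ok]
  vb <- if (use == "enrichment") b$enrichment[ok] else b$chip[ok]
  if (sum(va) <= 0 || sum(vb) <= 0) stop("zero profile mass in window")
  pa <- va / sum(va)
  pb <- vb / sum(vb)
  mid <- (a$start[ok] + a$end[ok]) / 2
  wmid <- (w$start + w$end) / 2
  centroid_a <- sum(pa * mid)
  centroid_b <- sum(pb * mid)
  structure(list(window = w,
                 centroid_a = centroid_a,
                 centroid_b = centroid_b,
                 centroid_shift = centroid_b - centroid_a,
                 l1_distance = sum(abs(pa - pb)),
                 asymmetry_a = sum(pa[mid > wmid]) - sum(pa[mid < wmid]),
                 asymmetry_b = sum(pb[mid > wmid]) - sum(pb[mid < wmid]),
                 asymmetry_delta = (sum(pb[mid > wmid]) - sum(pb[mid < wmid])) -
                   (sum(pa[mid > wmid]) - sum(pa[mid < wmid])),
                 n_bins = sum(ok)),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf(
    "<drift_report> %s:%d-%d  shift %+.0f bp  L1 %.4f  asym delta %+.4f (%d bins)\n",
    x$window$chrom, x$window$start, x$window$end,
    x$centroid_shift, x$l1_distance, x$asymmetry_delta, x$n_bins))
  invisible(x)
}

#' Technical-noise floor from split-sample concordance
#'
#' Splitting one ChIP sample in two and comparing the two half-sample tracks
#' against the same input measures pure sampling noise; biological drift
#' between individuals is judged against this floor.
#'
#' @param chip_half1,chip_half2 `alignment_records` for the two ChIP halves.
#' @param input `alignment_records` for the shared input.
#' @param window comparison window (see [profile_distance()]).
#' @param bin bin width in bp.
#' @param ... passed to [bin_enrichment()].
#' @return A `drift_report` comparing the two half-sample tracks.
#' @export
replicate_concordance <- function(chip_half1, chip_half2, input, window,
                                  bin = 20000L, ...) {
  if (!nrow(chip_half1) || !nrow(chip_half2)) {
    stop("empty ChIP half-sample")
  }
  t1 <- bin_enrichment(chip_half1, input, bin = bin, ...)
  t2 <- bin_enrichment(chip_half2, input, bin = bin, ...)
  profile_distance(t1, t2, window)
}

#' Default drift window from called peaks
#'
#' The union span of called peaks on a chromosome, padded on both sides.
#'
#' @param calls a [call_complex_centromeres()] result.
#' @param chrom chromosome name.
#' @param pad flank padding in bp (default 500000).
#' @param seqlength optional chromosome length to clip against.
#' @return A window list (`chrom`, `start`, `end`).
#' @export
window_from_peaks <- function(calls, chrom, pad = 500000L,
                              seqlength = NULL) {
  p <- calls$peaks[calls$peaks$chrom == chrom, , drop = FALSE]
  if (!nrow(p)) stop("no peaks on chromosome ", chrom)
  start <- max(0, min(p$start) - pad)
  end <- max(p$end) + pad
  if (!is.null(seqlength)) end <- min(end, seqlength)
  list(chrom = chrom, start = start, end = end)
}
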