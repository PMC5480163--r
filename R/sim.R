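#' Specify a synthetic genome with satellite arrays
#'
#' The simulator emulates the genomic structure the analysis assumes: long
#' chromosomes of unique (i.i.d. uniform) background sequence carrying tandem
#' satellite arrays whose copies deviate independently from a shared circular
#' consensus monomer. All coordinates are 0-based half-open.
#'
#' @param chromosomes data frame with columns `name` and `length` (bp), or a
#'   named numeric vector of lengths.
#' @param arrays optional data frame with columns `chrom`, `start` (0-based
#'   bp), `monomer` (consensus name), `copies` (monomer copy count) and
#'   `sub_rate` (per-base substitution probability in `[0,1]`).
#' @param seed integer seed making genome construction deterministic.
#' @return A `genome_spec` object.
#' @examples
#' genome_spec(c(chr1 = 2e6),
#'             data.frame(chrom = "chr1", start = 1e6, monomer = "CentC",
#'                        copies = 100, sub_rate = 0.04))
#' @export
genome_spec <- function(chromosomes, arrays = NULL, seed = 1L) {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  }
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(chromosomes$length >= 1))
  if (is.null(arrays)) {
    arrays <- data.frame(chrom = character(), start = numeric(),
                         monomer = character(), copies = integer(),
                         sub_rate = numeric())
  }
  stopifnot(all(c("chrom", "start", "monomer", "copies", "sub_rate")
                %in% names(arrays)))
  if (any(arrays$sub_rate < 0 | arrays$sub_rate > 1)) {
    stop("substitution rates must lie in [0, 1]")
  }
  if (!all(arrays$chrom %in% chromosomes$name)) {
    stop("array placed on unknown chromosome")
  }
  structure(list(chromosomes = chromosomes, arrays = arrays,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Mutate copies of a circular monomer
#'
#' Each base is substituted independently with probability `sub_rate`, always
#' to one of the three alternative bases (a substitution never reproduces the
#' original base), so the expected identity of a copy to the monomer is
#' exactly `1 - sub_rate`. Length is preserved: the default array model has no
#' indels, which keeps downstream alignment-length filters interpretable.
#'
#' @param monomer character string, `DNAString`, or `repeat_consensus`.
#' @param sub_rate per-base substitution probability in `[0,1]`.
#' @param n number of independent copies to draw.
#' @return Character vector of `n` mutated copies, with an `identity`
#'   attribute giving each copy's exact identity to the monomer.
#' @examples
#' set.seed(1)
#' copies <- mutate_copy("ACGTACGTACGT", 0.25, n = 3)
#' attr(copies, "identity")
#' @export
mutate_copy <- function(monomer, sub_rate, n = 1L) {
  if (inherits(monomer, "repeat_consensus")) monomer <- monomer$monomer
  s <- as.character(monomer)
  L <- nchar(s)
  if (L == 0L) stop("monomer must be non-empty")
  stopifnot(sub_rate >= 0, sub_rate <= 1, n >= 1)
  bases <- c("A", "C", "G", "T")
  orig <- match(strsplit(s, "")[[1L]], bases)
  if (anyNA(orig)) stop("monomer contains non-ACGT characters")
  m <- matrix(rep(orig, n), nrow = L)
  hit <- matrix(runif(L * n) < sub_rate, nrow = L)
  if (any(hit)) {
    shift <- sample(1:3, sum(hit), replace = TRUE)
    m[hit] <- ((m[hit] - 1L + shift) %% 4L) + 1L
  }
  out <- apply(m, 2L, function(col) paste(bases[col], collapse = ""))
  attr(out, "identity") <- 1 - colSums(hit) / L
  out
}

#' Build a synthetic genome and its truth set
#'
#' Background sequence is drawn i.i.d. uniform over A/C/G/T (guaranteeing
#' unique-mappability of non-array regions at desk scale); each array interval
#' is filled with concatenated [mutate_copy()] outputs. The returned truth set
#' records every array interval and every copy's identity to its consensus,
#' which downstream parameter-recovery tests compare against estimates.
#'
#' @param spec a [genome_spec()].
#' @param consensuses list of [repeat_consensus()] objects; arrays refer to
#'   them by name. Defaults to the bundled CentC and knob180 consensuses.
#' @return A `sim_genome` list: `genome` (a named `DNAStringSet`), `arrays`
#'   (data frame: chrom, start, end, monomer, copies, sub_rate; 0-based
#'   half-open), `copy_identities` (data frame with one row per planted copy)
#'   and `spec`.
#' @export
build_genome <- function(spec,
                         consensuses = list(centc_consensus(),
                                            knob180_consensus())) {
  stopifnot(inherits(spec, "genome_spec"))
  cons <- setNames(consensuses,
                   vapply(consensuses, function(x) x$name, ""))
  miss <- setdiff(unique(spec$arrays$monomer), names(cons))
  if (length(miss)) stop("no consensus supplied for: ",
                         paste(miss, collapse = ", "))
  arr <- spec$arrays
  arr$len <- if (nrow(arr)) {
    vapply(seq_len(nrow(arr)), function(i)
      arr$copies[i] * cons[[arr$monomer[i]]]$monomer_len, 0)
  } else numeric()
  arr$end <- arr$start + arr$len
  # bounds and overlap checks (per chromosome)
  for (i in seq_len(nrow(arr))) {
    clen <- spec$chromosomes$length[spec$chromosomes$name == arr$chrom[i]]
    if (arr$start[i] < 0 || arr$end[i] > clen) {
      stop("array ", i, " extends outside chromosome ", arr$chrom[i])
    }
  }
  if (nrow(arr) > 1L) {
    ir <- split(IRanges::IRanges(arr$start + 1L, arr$end), arr$chrom)
    if (any(vapply(ir, function(x)
      sum(IRanges::width(IRanges::reduce(x))) < sum(IRanges::width(x)),
      TRUE))) {
      stop("satellite arrays overlap")
    }
  }

  ids <- list()
  with_seed(spec$seed, {
    chroms <- lapply(seq_len(nrow(spec$chromosomes)), function(ci) {
      nm <- spec$chromosomes$name[ci]
      len <- spec$chromosomes$length[ci]
      seq <- Biostrings::DNAString(random_dna(len))
      rows <- which(arr$chrom == nm)
      for (i in rows) {
        cc <- cons[[arr$monomer[i]]]
        copies <- mutate_copy(cc$monomer, arr$sub_rate[i], arr$copies[i])
        ids[[length(ids) + 1L]] <<- data.frame(
          chrom = nm, array = i, monomer = arr$monomer[i],
          copy = seq_len(arr$copies[i]),
          start = arr$start[i] + (seq_len(arr$copies[i]) - 1L) * cc$monomer_len,
          end = arr$start[i] + seq_len(arr$copies[i]) * cc$monomer_len,
          identity = as.numeric(attr(copies, "identity")))
        seq <- Biostrings::replaceAt(
          seq, IRanges::IRanges(arr$start[i] + 1L, arr$end[i]),
          paste(copies, collapse = ""))
      }
      seq
    })
  })
  genome <- Biostrings::DNAStringSet(chroms)
  names(genome) <- spec$chromosomes$name
  copy_identities <- if (length(ids)) do.call(rbind, ids) else
    data.frame(chrom = character(), array = integer(), monomer = character(),
               copy = integer(), start = numeric(), end = numeric(),
               identity = numeric())
  structure(list(genome = genome,
                 arrays = arr[, c("chrom", "start", "end", "monomer",
                                  "copies", "sub_rate")],
                 copy_identities = copy_identities,
                 spec = spec),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %d satellite array(s), %.3g Mb\n",
              length(x$genome), nrow(x$arrays),
              sum(Biostrings::width(x$genome)) / 1e6))
  invisible(x)
}

#' Specify CENH3 domains for ChIP read simulation
#'
#' A domain is an interval whose positions are over-sampled in the ChIP
#' channel by `fold_enrichment` relative to background; `fold_enrichment = 1`
#' reproduces input statistics exactly.
#'
#' @param domains data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open bp).
#' @param fold_enrichment positive sampling weight of domain positions
#'   relative to non-domain positions.
#' @return A `cenh3_domains` object.
#' @export
cenh3_domains <- function(domains, fold_enrichment = 20) {
  stopifnot(is.data.frame(domains),
            all(c("chrom", "start", "end") %in% names(domains)),
            all(domains$end > domains$start),
            fold_enrichment > 0)
  structure(list(domains = domains, fold_enrichment = fold_enrichment),
            class = "cenh3_domains")
}

seqlens <- function(genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  setNames(Biostrings::width(genome), names(genome))
}

#' Simulate single-end ChIP or input reads
#'
#' Read start positions are drawn with per-position weight
#' `fold_enrichment` inside CENH3 domains (ChIP channel) or uniformly (input
#' channel); strands are uniform; sequencing errors are i.i.d. substitutions.
#' Base qualities are constant (optionally with a low-quality 3' tail for
#' exercising quality trimming). Deterministic given `seed`.
#'
#' @param genome a `sim_genome` or named `DNAStringSet`.
#' @param n_reads number of reads.
#' @param domains a [cenh3_domains()] (required for `channel = "chip"` unless
#'   enrichment is flat).
#' @param read_len read length in bp (default 150).
#' @param channel `"chip"` or `"input"`.
#' @param error_rate per-base sequencing error probability.
#' @param base_qual constant Phred quality for emitted bases.
#' @param tail_len,tail_qual optional low-quality 3' tail (length and Phred
#'   score) to exercise quality trimming.
#' @param seed integer seed.
#' @return A `sim_reads` list: `reads` (a `QualityScaledDNAStringSet`) and
#'   `truth` (data frame: id, chrom, start (0-based), strand, in_domain).
#' @export
simulate_reads <- function(genome, n_reads, domains = NULL, read_len = 150L,
                           channel = c("input", "chip"), error_rate = 0.002,
                           base_qual = 35L, tail_len = 0L, tail_qual = 10L,
                           seed = NULL) {
  channel <- match.arg(channel)
  sl <- seqlens(genome)
  gen <- if (inherits(genome, "sim_genome")) genome$genome else genome
  if (read_len > min(sl)) stop("read_len exceeds shortest chromosome")
  stopifnot(n_reads >= 0)
  dom <- NULL
  fold <- 1
  if (channel == "chip" && !is.null(domains)) {
    stopifnot(inherits(domains, "cenh3_domains"))
    dom <- domains$domains
    fold <- domains$fold_enrichment
    for (i in seq_len(nrow(dom))) {
      if (!dom$chrom[i] %in% names(sl) ||
          dom$start[i] < 0 || dom$end[i] > sl[[dom$chrom[i]]]) {
        stop("CENH3 domain outside genome bounds")
      }
    }
  }

  # piecewise-constant weights over valid start positions (0 .. L - read_len)
  segs <- do.call(rbind, lapply(names(sl), function(nm) {
    lim <- sl[[nm]] - read_len  # last valid 0-based start
    cuts <- c(0, lim + 1)
    if (!is.null(dom)) {
      d <- dom[dom$chrom == nm, , drop = FALSE]
      cuts <- sort(unique(c(cuts, pmin(pmax(d$start, 0), lim + 1),
                            pmin(d$end, lim + 1))))
    }
    s <- cuts[-length(cuts)]
    e <- cuts[-1L]
    w <- rep(1, length(s))
    if (!is.null(dom)) {
      d <- dom[dom$chrom == nm, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        w[s >= d$start[i] & e <= d$end[i]] <- fold
      }
    }
    data.frame(chrom = nm, s = s, e = e, w = w)
  }))
  segs$mass <- (segs$e - segs$s) * segs$w

  if (n_reads == 0L) {
    return(structure(list(
      reads = make_reads(character(0)),
      truth = data.frame(id = character(), chrom = character(),
                         start = numeric(), strand = character(),
                         in_domain = logical())), class = "sim_reads"))
  }
  with_seed(seed, {
    seg_idx <- sample.int(nrow(segs), n_reads, replace = TRUE,
                          prob = segs$mass)
    start0 <- segs$s[seg_idx] +
      floor(runif(n_reads) * (segs$e[seg_idx] - segs$s[seg_idx]))
    chrom <- segs$chrom[seg_idx]
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)

    seqs <- character(n_reads)
    for (nm in unique(chrom)) {
      j <- which(chrom == nm)
      v <- Biostrings::extractAt(
        gen[[nm]], IRanges::IRanges(start0[j] + 1L, width = read_len))
      seqs[j] <- as.character(v)
    }
    minus <- strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    seqs <- apply_seq_errors(seqs, error_rate)

    ids <- sprintf("%s_%07d", channel, seq_len(n_reads))
    qual <- paste(rep(rawToChar(as.raw(33L + as.integer(base_qual))),
                      read_len), collapse = "")
    if (tail_len > 0L) {
      substr(qual, read_len - tail_len + 1L, read_len) <-
        paste(rep(rawToChar(as.raw(33L + as.integer(tail_qual))), tail_len),
              collapse = "")
    }
    reads <- make_reads(seqs, rep(qual, n_reads), ids)
    in_domain <- rep(FALSE, n_reads)
    if (!is.null(dom)) {
      for (i in seq_len(nrow(dom))) {
        in_domain <- in_domain | (chrom == dom$chrom[i] &
                                  start0 >= dom$start[i] &
                                  start0 < dom$end[i])
      }
    }
    truth <- data.frame(id = ids, chrom = chrom, start = start0,
                        strand = strand, in_domain = in_domain)
    structure(list(reads = reads, truth = truth), class = "sim_reads")
  })
}

apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate reads drawn from a circular satellite monomer
#'
#' Emulates reads sequenced from within a long tandem array: each read starts
#' at a uniform rotation of the circular consensus and carries i.i.d. per-base
#' substitutions at `sub_rate` (the array polymorphism) plus sequencing errors
#' at `error_rate`. Used by the k-mer homogenization analysis, where the
#' `sub_rate = 0` limit realizes the perfectly homogeneous array whose
#' spectrum the analytic baseline [expected_homogeneous_copy()] predicts.
#'
#' @param consensus a [repeat_consensus()].
#' @param n number of reads.
#' @param read_len read length (default 100, the k-mer analysis length).
#' @param sub_rate per-base array substitution rate.
#' @param error_rate per-base sequencing error rate.
#' @param stranded if `TRUE` (default) reads come from both strands.
#' @inheritParams simulate_reads
#' @return A `sim_reads` list with truth columns `id`, `offset` (0-based
#'   rotation), `strand`.
#' @export
simulate_circular_reads <- function(consensus, n, read_len = 100L,
                                    sub_rate = 0, error_rate = 0,
                                    stranded = TRUE, base_qual = 35L,
                                    seed = NULL) {
  stopifnot(inherits(consensus, "repeat_consensus"), n >= 0)
  L <- consensus$monomer_len
  reps <- ceiling(read_len / L) + 1L
  circ <- paste(rep(as.character(consensus$monomer), reps), collapse = "")
  if (n == 0L) {
    return(structure(list(reads = make_reads(character(0)),
                          truth = data.frame(id = character(),
                                             offset = integer(),
                                             strand = character())),
                     class = "sim_reads"))
  }
  with_seed(seed, {
    off <- sample.int(L, n, replace = TRUE) - 1L
    seqs <- substring(circ, off + 1L, off + read_len)
    seqs <- apply_seq_errors(seqs, sub_rate)   # array polymorphism
    strand <- if (stranded) sample(c("+", "-"), n, replace = TRUE)
              else rep("+", n)
    minus <- strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    seqs <- apply_seq_errors(seqs, error_rate)
    ids <- sprintf("sat_%07d", seq_len(n))
    reads <- make_reads(seqs, base_qual, ids)
    structure(list(reads = reads,
                   truth = data.frame(id = ids, offset = off,
                                      strand = strand)),
              class = "sim_reads")
  })
}

#' Write a simulated genome and its truth files
#'
#' Emits the genome FASTA, the satellite-array truth BED, the per-copy
#' identity TSV and (optionally) the CENH3 domain BED — the artifacts
#' parameter-recovery tests consume.
#'
#' @param genome a `sim_genome`.
#' @param dir output directory (created if needed).
#' @param domains optional [cenh3_domains()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_truth <- function(genome, dir, domains = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             arrays = file.path(dir, "arrays.bed"),
             identities = file.path(dir, "copy_identities.tsv"))
  Biostrings::writeXStringSet(genome$genome, paths[["genome"]])
  arr <- genome$arrays
  arr$name <- arr$monomer
  write_bed(arr, paths[["arrays"]])
  write.table(genome$copy_identities, paths[["identities"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(domains)) {
    paths[["domains"]] <- file.path(dir, "cenh3_domains.bed")
    write_bed(domains$domains, paths[["domains"]])
  }
  invisible(paths)
}
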