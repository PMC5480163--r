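#' Repeat consensus monomer (circular) and its dimer
#'
#' A tandem-repeat consensus is a circular sequence: a sequencing read can
#' start at any rotation and span the monomer junction. Representing the
#' monomer as a head-to-tail dimer lets any junction-spanning read align over
#' its full length with an ordinary (linear) local aligner.
#'
#' @param name repeat family name, e.g. `"CentC"`.
#' @param monomer monomer sequence: a character string, [Biostrings::DNAString]
#'   or length-1 [Biostrings::DNAStringSet].
#' @return An object of class `repeat_consensus` with elements `name`,
#'   `monomer` (a `DNAString`), `dimer` (a `DNAString`, twice the monomer) and
#'   `monomer_len`.
#' @examples
#' cons <- repeat_consensus("toy", "ACGTACGTTGCAACGGTCA")
#' cons$monomer_len
#' @export
repeat_consensus <- function(name, monomer) {
  if (inherits(monomer, "DNAStringSet")) monomer <- monomer[[1L]]
  monomer <- Biostrings::DNAString(as.character(monomer))
  if (length(monomer) == 0L) stop("monomer must be non-empty")
  structure(list(
    name = as.character(name),
    monomer = monomer,
    dimer = Biostrings::xscat(monomer, monomer),
    monomer_len = length(monomer)
  ), class = "repeat_consensus")
}

#' @export
print.repeat_consensus <- function(x, ...) {
  cat(sprintf("<repeat_consensus> %s: %d-bp circular monomer (dimer %d bp)\n",
              x$name, x$monomer_len, 2L * x$monomer_len))
  invisible(x)
}

load_consensus_fasta <- function(path, name = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- name %||% sub("\\s.*$", "", names(ss)[1L])
  repeat_consensus(nm, ss[[1L]])
}

#' Bundled satellite consensus sequences
#'
#' The CentC (156-bp) and knob180 (180-bp) Zea satellite consensus monomers
#' shipped with the package.
#'
#' @return A `repeat_consensus`.
#' @export
centc_consensus <- function() {
  load_consensus_fasta(system.file("extdata", "centc_consensus.fa",
                                   package = "centsat"), "CentC")
}

#' @rdname centc_consensus
#' @export
knob180_consensus <- function() {
  load_consensus_fasta(system.file("extdata", "knob180_consensus.fa",
                                   package = "centsat"), "knob180")
}

# all rotations of a circular sequence; canonical = lexicographically minimal
canonical_rotation <- function(seq) {
  s <- as.character(seq)
  n <- nchar(s)
  d <- paste0(s, s)
  rots <- substring(d, seq_len(n), seq_len(n) + n - 1L)
  Biostrings::DNAString(min(rots))
}
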