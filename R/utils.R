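#' @import methods
#' @importFrom stats rbinom runif sd setNames weighted.mean cor.test rchisq
#'   pchisq quantile
#' @importFrom utils write.table packageVersion head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

.datatable.aware <- TRUE

#' Derive a stage seed from a root seed
#'
#' Named substreams keep per-stage randomness reproducible from one root seed
#' without coupling stages to each other. The result always fits in a 32-bit
#' integer.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  v <- as.numeric(utf8ToInt(stage))
  h <- sum(v * seq_along(v)) * 2654435
  as.integer((as.numeric(root_seed) + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# 0-based half-open BED writer (three cols + optional name)
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  write.table(df[, cols, drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an enrichment track as bedGraph
#'
#' Masked bins (no defined enrichment) are omitted, which is how genome
#' browsers expect gaps to be represented.
#'
#' @param track an `enrichment_track` data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  ok <- track$mask == "ok"
  write.table(data.frame(track$chrom[ok], track$start[ok], track$end[ok],
                         signif(track$enrichment[ok], 6)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
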