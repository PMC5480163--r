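#' Default pipeline configuration
#'
#' All stage parameters in one list, overridable via a YAML file or
#' [run_pipeline()]'s `...`. Seeds for every stage are derived from the one
#' root seed via named substreams, so a run is fully reproducible from
#' `seed` alone.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "centsat_out",
    simulate = list(
      chrom_length = 2e6,
      array_start = 1.4e6,   # satellite array inside the CENH3 domain
      array_copies = 200L,
      sub_rate = 0.04,
      monomer = "CentC",
      domain = list(start = 1.3e6, end = 1.9e6),
      fold_enrichment = 20,
      n_chip = 20000L,
      n_input = 20000L,
      read_len = 150L,
      error_rate = 0.002,
      base_qual = 35L
    ),
    prep = list(quality_threshold = 20L, adapter = "AGATCGGAAGAGC",
                max_err = 0.05, min_overlap = 1L, min_len = 100L),
    quantify = list(min_aln = 125L),
    kmer = list(min_aln = 90L, trim_len = 100L, n_sample = 30000L, k = 50L,
                sample_frac_fallback = TRUE),
    profile = list(bin = 20000L, min_enrich = 2, min_len = 500000L,
                   max_gap_bins = 2L),
    drift = list(pad = 500000L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' @param path YAML file with any subset of [default_config()] keys.
#' @return Full configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the simulate-analyze pipeline end to end
#'
#' Simulates a genome with a satellite array and a complex CENH3 domain,
#' simulates ChIP and input reads, preprocesses them, quantifies the
#' satellite in both channels, computes the k-mer spectrum of satellite
#' reads, maps reads, builds the masked enrichment track, calls complex
#' centromeres, and measures split-sample replicate concordance. All
#' artifacts (FASTA/FASTQ/BED/bedGraph/TSV/JSON plus a provenance log) are
#' written under `config$out_dir`. Deterministic given `config$seed`.
#'
#' @param config a configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param ... individual overrides merged into the configuration.
#' @return Invisibly, a result bundle: `genome`, `quant` (per channel),
#'   `identity_comparison`, `spectrum`, `histogram`, `track`, `calls`,
#'   `concordance`, `stats`, `paths`.
#' @export
run_pipeline <- function(config = default_config(), ...) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(config, list(...))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_logged <- cfg
  cfg_logged$out_dir <- NULL   # keep provenance independent of the run path
  log <- list(package = as.character(packageVersion("centsat")),
              seed = cfg$seed, config = cfg_logged, stages = list())
  paths <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## simulate
  sim <- stage("simulate", {
    sc <- cfg$simulate
    cons <- if (identical(sc$monomer, "CentC")) centc_consensus()
            else if (identical(sc$monomer, "knob180")) knob180_consensus()
            else repeat_consensus("custom", sc$monomer)
    spec <- genome_spec(
      setNames(sc$chrom_length, "chr1"),
      data.frame(chrom = "chr1", start = sc$array_start,
                 monomer = cons$name, copies = sc$array_copies,
                 sub_rate = sc$sub_rate),
      seed = stage_seed(cfg$seed, "genome"))
    genome <- build_genome(spec, list(cons))
    domains <- cenh3_domains(
      data.frame(chrom = "chr1", start = sc$domain$start,
                 end = sc$domain$end),
      fold_enrichment = sc$fold_enrichment)
    chip <- simulate_reads(genome, sc$n_chip, domains, sc$read_len, "chip",
                           sc$error_rate, sc$base_qual,
                           seed = stage_seed(cfg$seed, "chip"))
    input <- simulate_reads(genome, sc$n_input, NULL, sc$read_len, "input",
                            sc$error_rate, sc$base_qual,
                            seed = stage_seed(cfg$seed, "input"))
    paths <- c(paths, write_truth(genome, cfg$out_dir, domains))
    write_fastq(chip$reads, file.path(cfg$out_dir, "chip.fastq"))
    write_fastq(input$reads, file.path(cfg$out_dir, "input.fastq"))
    list(genome = genome, domains = domains, chip = chip, input = input,
         consensus = cons)
  })

  ## prep
  prep <- stage("prep", {
    pc <- cfg$prep
    chip <- prep_reads(sim$chip$reads, pc$quality_threshold, pc$adapter,
                       pc$max_err, pc$min_overlap, pc$min_len)
    input <- prep_reads(sim$input$reads, pc$quality_threshold, pc$adapter,
                        pc$max_err, pc$min_overlap, pc$min_len)
    list(chip = chip, input = input)
  })
  log$stages$prep <- list(chip = prep$chip$stats, input = prep$input$stats)

  ## quantify
  quant <- stage("quantify", {
    q <- list(
      chip = quantify_repeat(prep$chip$reads, sim$consensus,
                             cfg$quantify$min_aln, channel = "chip"),
      input = quantify_repeat(prep$input$reads, sim$consensus,
                              cfg$quantify$min_aln, channel = "input"))
    write.table(q$input$hits,
                file.path(cfg$out_dir, "input_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(q, function(x) x[c("consensus", "channel", "n_reads", "n_hits",
                                "fraction")]),
      file.path(cfg$out_dir, "quant.json"), auto_unbox = TRUE, digits = NA)
    q
  })
  idcmp <- if (quant$chip$n_hits > 0L && quant$input$n_hits > 0L) {
    compare_identity_distributions(quant$chip, quant$input)
  } else NULL

  ## kmer
  spectrum <- stage("kmer", {
    kc <- cfg$kmer
    hits90 <- align_to_circular_consensus(prep$input$reads, sim$consensus,
                                          min_aln = kc$min_aln)
    sat <- fixed_trim(prep$input$reads[hits90$read_idx], kc$trim_len)
    strand <- hits90$strand[Biostrings::width(
      prep$input$reads[hits90$read_idx]) >= kc$trim_len]
    n_take <- if (length(sat) >= kc$n_sample) kc$n_sample
              else if (isTRUE(kc$sample_frac_fallback)) length(sat)
              else kc$n_sample
    smp_idx <- with_seed(stage_seed(cfg$seed, "kmer"),
                         sample.int(length(sat), n_take))
    sp <- count_kmers(sat[smp_idx], kc$k, "consensus",
                      strand = strand[smp_idx])
    write_spectrum(sp, file.path(cfg$out_dir, "kmer_spectrum.tsv"))
    sp
  })
  khist <- copy_number_histogram(spectrum)
  jsonlite::write_json(khist, file.path(cfg$out_dir, "kmer_histogram.json"),
                       auto_unbox = TRUE, digits = NA)

  ## profile
  prof <- stage("profile", {
    pc <- cfg$profile
    chip_rec <- map_reads(prep$chip$reads, sim$genome)
    input_rec <- map_reads(prep$input$reads, sim$genome)
    mask <- annotate_reference_repeats(sim$genome, sim$consensus)
    track <- bin_enrichment(chip_rec, input_rec, pc$bin, mask)
    calls <- call_complex_centromeres(track, pc$min_enrich, pc$min_len,
                                      pc$max_gap_bins)
    write_bedgraph(track, file.path(cfg$out_dir, "enrichment.bedGraph"))
    write_bed(mask, file.path(cfg$out_dir, "satellite_mask.bed"))
    write_bed(calls$peaks, file.path(cfg$out_dir, "complex_peaks.bed"))
    jsonlite::write_json(
      list(chrom_counts = as.list(calls$chrom_counts),
           n_complex = calls$n_complex),
      file.path(cfg$out_dir, "complex_counts.json"), auto_unbox = TRUE,
      digits = NA)
    list(chip = chip_rec, input = input_rec, mask = mask, track = track,
         calls = calls)
  })

  ## drift: split-sample replicate concordance around the called centromere
  conc <- if (!nrow(prof$calls$peaks)) NULL else stage("drift", {
    half <- with_seed(stage_seed(cfg$seed, "split"), {
      n <- nrow(prof$chip)
      i <- sample.int(n, n %/% 2L)
      list(a = prof$chip[i, , drop = FALSE],
           b = prof$chip[-i, , drop = FALSE])
    })
    attr(half$a, "seqlengths") <- attr(prof$chip, "seqlengths")
    attr(half$b, "seqlengths") <- attr(prof$chip, "seqlengths")
    win <- window_from_peaks(prof$calls, prof$calls$peaks$chrom[1L],
                             cfg$drift$pad,
                             seqlens(sim$genome)[[prof$calls$peaks$chrom[1L]]])
    rep <- replicate_concordance(half$a, half$b, prof$input, win,
                                 bin = cfg$profile$bin,
                                 satellite_mask = prof$mask)
    jsonlite::write_json(unclass(rep),
                         file.path(cfg$out_dir, "replicate_concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  log$stages$quantify <- list(
    chip = quant$chip[c("n_reads", "n_hits", "fraction")],
    input = quant$input[c("n_reads", "n_hits", "fraction")])
  log$stages$kmer <- list(n_reads = spectrum$n_reads,
                          n_distinct = spectrum$n_distinct)
  log$stages$profile <- list(
    chip_unique = sum(prof$chip$unique),
    input_unique = sum(prof$input$unique),
    n_peaks = nrow(prof$calls$peaks),
    n_complex = prof$calls$n_complex)
  jsonlite::write_json(log, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(genome = sim$genome, quant = quant,
                 identity_comparison = idcmp, spectrum = spectrum,
                 histogram = khist, track = prof$track, calls = prof$calls,
                 concordance = conc, stats = log, paths = paths))
}
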