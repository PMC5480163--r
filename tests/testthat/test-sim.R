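test_that("mutate_copy boundary rates behave exactly", {
  cc <- centc_consensus()
  set.seed(1)
  same <- mutate_copy(cc, 0)
  expect_identical(as.character(same), as.character(cc$monomer))
  expect_equal(attr(same, "identity"), 1)

  flipped <- mutate_copy(cc, 1)
  expect_equal(attr(flipped, "identity"), 0)
  a <- strsplit(as.character(flipped), "")[[1]]
  b <- strsplit(as.character(cc$monomer), "")[[1]]
  expect_true(all(a != b))

  expect_error(mutate_copy("", 0.1), "non-empty")
  expect_error(mutate_copy(cc, 1.2))
})

test_that("mutate_copy at 4% yields ~96% identity and exact bookkeeping", {
  cc <- centc_consensus()
  set.seed(42)
  n <- 10000L
  copies <- mutate_copy(cc, 0.04, n)
  ids <- attr(copies, "identity")
  # reported identity equals the empirical mismatch fraction
  emp <- vapply(copies, function(s) {
    mean(strsplit(s, "")[[1]] == strsplit(as.character(cc$monomer), "")[[1]])
  }, 0, USE.NAMES = FALSE)
  expect_equal(ids, emp)
  se <- sqrt(0.04 * 0.96 / (156 * n))
  expect_lt(abs(mean(ids) - 0.96), 3 * se)
})

test_that("build_genome constructs stated lengths and exact array fractions", {
  spec <- genome_spec(
    data.frame(name = "chr1", length = 200000),
    data.frame(chrom = "chr1", start = 90000, monomer = "CentC",
               copies = 40, sub_rate = 0.04), seed = 3)
  g <- build_genome(spec)
  expect_equal(sum(Biostrings::width(g$genome)), 200000)
  expect_equal(g$arrays$end - g$arrays$start, 40 * 156)
  frac <- sum(g$arrays$end - g$arrays$start) / 200000
  expect_equal(frac, 40 * 156 / 200000)  # exact by construction
  expect_equal(nrow(g$copy_identities), 40)
  expect_true(all(g$copy_identities$identity >= 0 &
                  g$copy_identities$identity <= 1))
  # planted array really sits at its interval: copies align to the monomer
  seg <- XVector::subseq(g$genome[["chr1"]], 90001, 90156)
  expect_gt(mean(strsplit(as.character(seg), "")[[1]] ==
                 strsplit(as.character(centc_consensus()$monomer), "")[[1]]),
            0.85)
})

test_that("build_genome with no arrays gives empty truth; invalid specs error", {
  g0 <- build_genome(genome_spec(c(chr1 = 50000), seed = 1))
  expect_equal(nrow(g0$arrays), 0)
  expect_equal(nrow(g0$copy_identities), 0)

  overlapping <- genome_spec(
    c(chr1 = 100000),
    data.frame(chrom = "chr1", start = c(1000, 2000),
               monomer = "CentC", copies = c(10, 10),
               sub_rate = 0), seed = 1)
  expect_error(build_genome(overlapping), "overlap")

  outside <- genome_spec(
    c(chr1 = 5000),
    data.frame(chrom = "chr1", start = 4000, monomer = "CentC",
               copies = 10, sub_rate = 0), seed = 1)
  expect_error(build_genome(outside), "outside")

  expect_error(genome_spec(c(chr1 = 1000),
                           data.frame(chrom = "chr1", start = 0,
                                      monomer = "CentC", copies = 1,
                                      sub_rate = 1.5)), "\\[0, 1\\]")
})

test_that("genome construction is deterministic given the seed", {
  spec <- genome_spec(c(chr1 = 60000),
                      data.frame(chrom = "chr1", start = 10000,
                                 monomer = "CentC", copies = 20,
                                 sub_rate = 0.04), seed = 11)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$copy_identities, g2$copy_identities)
})

test_that("chip read starts follow the domain enrichment weights", {
  g <- build_genome(genome_spec(c(chr1 = 200000), seed = 5))
  read_len <- 150L
  nd <- 60000      # in-domain valid starts for domain [120000, 180000)
  nvalid <- 200000 - read_len + 1

  # fold 1 reproduces the uniform in-domain fraction
  dom1 <- cenh3_domains(data.frame(chrom = "chr1", start = 120000,
                                   end = 180000), fold_enrichment = 1)
  r1 <- simulate_reads(g, 5000, dom1, read_len, "chip", 0, seed = 2)
  p0 <- nd / nvalid
  expect_lt(abs(mean(r1$truth$in_domain) - p0),
            3 * sqrt(p0 * (1 - p0) / 5000))

  # fold 40: analytic weighted fraction
  dom40 <- cenh3_domains(data.frame(chrom = "chr1", start = 120000,
                                    end = 180000), fold_enrichment = 40)
  r40 <- simulate_reads(g, 5000, dom40, read_len, "chip", 0, seed = 2)
  p40 <- 40 * nd / (40 * nd + (nvalid - nd))
  expect_lt(abs(mean(r40$truth$in_domain) - p40),
            3 * sqrt(p40 * (1 - p40) / 5000))
})

test_that("read simulation edge cases and determinism", {
  g <- build_genome(genome_spec(c(chr1 = 10000), seed = 1))
  r0 <- simulate_reads(g, 0, NULL, 150, "input", 0, seed = 1)
  expect_equal(length(r0$reads), 0)
  expect_equal(nrow(r0$truth), 0)

  a <- simulate_reads(g, 500, NULL, 150, "input", 0.01, seed = 9)
  b <- simulate_reads(g, 500, NULL, 150, "input", 0.01, seed = 9)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$truth, b$truth)
  # byte-identical FASTQ output
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(a$reads, fa); write_fastq(b$reads, fb)
  expect_identical(readLines(fa), readLines(fb))

  dom_bad <- cenh3_domains(data.frame(chrom = "chr1", start = 5000,
                                      end = 20000), 10)
  expect_error(simulate_reads(g, 10, dom_bad, 150, "chip", 0),
               "outside genome bounds")
  expect_error(simulate_reads(g, 10, NULL, 20000, "input", 0),
               "shortest chromosome")
})

test_that("input reads on an array-free genome are uniform across bins", {
  g <- build_genome(genome_spec(c(chr1 = 100000), seed = 8))
  read_len <- 150L
  nvalid <- 100000 - read_len + 1
  bin <- 5000
  # expected bin masses account for the shorter last bin of valid starts
  starts <- seq(0, 95000, by = bin)
  exp_mass <- pmin(starts + bin, nvalid) - starts
  probs <- exp_mass / sum(exp_mass)
  fails <- 0L
  for (s in 1:20) {
    r <- simulate_reads(g, 4000, NULL, read_len, "input", 0, seed = 100 + s)
    obs <- tabulate(r$truth$start %/% bin + 1L, nbins = length(starts))
    p <- suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
    if (p < 0.001) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("circular read simulation covers rotations and respects sub_rate", {
  cc <- toy_consensus()
  r <- simulate_circular_reads(cc, 2000, read_len = 30, sub_rate = 0,
                               seed = 4)
  expect_equal(length(r$reads), 2000)
  expect_true(all(Biostrings::width(r$reads) == 30))
  expect_true(all(r$truth$offset >= 0 & r$truth$offset < cc$monomer_len))
  # plus-strand zero-rate reads are exact substrings of the repeated monomer
  circ <- paste(rep(toy_monomer, 3), collapse = "")
  plus <- r$truth$strand == "+"
  expect_true(all(mapply(function(s, o) {
    s == substr(circ, o + 1, o + 30)
  }, as.character(r$reads)[plus], r$truth$offset[plus])))
})

test_that("truth files round-trip to disk", {
  spec <- genome_spec(c(chr1 = 30000),
                      data.frame(chrom = "chr1", start = 5000,
                                 monomer = "CentC", copies = 10,
                                 sub_rate = 0.02), seed = 2)
  g <- build_genome(spec)
  dom <- cenh3_domains(data.frame(chrom = "chr1", start = 20000, end = 28000))
  td <- tempfile("truth")
  paths <- write_truth(g, td, dom)
  expect_true(all(file.exists(paths)))
  bed <- read.table(paths[["arrays"]], sep = "\t")
  expect_equal(bed$V2, 5000)
  expect_equal(bed$V3, 5000 + 10 * 156)
  ids <- read.table(paths[["identities"]], header = TRUE, sep = "\t")
  expect_equal(nrow(ids), 10)
})
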