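cc <- centc_consensus()

test_that("self-match and junction-spanning rotations align full length", {
  mono <- as.character(cc$monomer)
  hit <- align_to_circular_consensus(qreads(mono), cc, min_aln = 125)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length, 156)
  expect_equal(hit$identity, 1)
  expect_equal(hit$strand, "+")

  # rotation by half a monomer spans the junction yet aligns full length
  dimer <- paste0(mono, mono)
  rot <- substr(dimer, 79, 79 + 155)
  hrot <- align_to_circular_consensus(qreads(rot), cc, min_aln = 125)
  expect_equal(hrot$length, 156)
  expect_equal(hrot$identity, 1)
  expect_equal(hrot$monomer_offset, 78)
})

test_that("alignment-length filter excludes sub-threshold matches", {
  set.seed(3)
  mono <- as.character(cc$monomer)
  read <- paste0(substr(mono, 1, 120), random_read(30))
  none <- align_to_circular_consensus(qreads(read), cc, min_aln = 125)
  expect_equal(nrow(none), 0)
  some <- align_to_circular_consensus(qreads(read), cc, min_aln = 100)
  expect_equal(nrow(some), 1)
  expect_gte(some$length, 100)
})

test_that("random reads yield no hits", {
  set.seed(11)
  reads <- qreads(vapply(1:100, function(i) random_read(150), ""))
  hits <- align_to_circular_consensus(reads, cc, min_aln = 125)
  expect_equal(nrow(hits), 0)
})

test_that("alignment is strand-symmetric", {
  set.seed(5)
  reads <- simulate_circular_reads(cc, 20, read_len = 150, sub_rate = 0.04,
                                   stranded = FALSE, seed = 5)$reads
  fwd <- align_to_circular_consensus(reads, cc, min_aln = 125)
  rc <- Biostrings::reverseComplement(as(reads, "DNAStringSet"))
  names(rc) <- names(reads)
  rev <- align_to_circular_consensus(rc, cc, min_aln = 125)
  m <- match(fwd$read_id, rev$read_id)
  expect_false(anyNA(m))
  expect_equal(fwd$score, rev$score[m])
  expect_equal(fwd$identity, rev$identity[m])
  expect_true(all(fwd$strand == "+" & rev$strand[m] == "-"))
})

test_that("identity is invariant to monomer rotation", {
  set.seed(6)
  reads <- simulate_circular_reads(cc, 15, read_len = 150, sub_rate = 0.04,
                                   seed = 6)$reads
  rot_mono <- paste0(substr(as.character(cc$monomer), 50, 156),
                     substr(as.character(cc$monomer), 1, 49))
  cc_rot <- repeat_consensus("CentC", rot_mono)
  h1 <- align_to_circular_consensus(reads, cc, min_aln = 125, score_min = 0)
  h2 <- align_to_circular_consensus(reads, cc_rot, min_aln = 125,
                                    score_min = 0)
  m <- match(h1$read_id, h2$read_id)
  expect_false(anyNA(m))
  expect_equal(h1$identity, h2$identity[m])
  expect_equal(h1$score, h2$score[m])
})

test_that("quantify_repeat computes exact fractions on constructed sets", {
  set.seed(9)
  reads <- qreads(c(rep(as.character(cc$monomer), 10),
                    vapply(1:990, function(i) random_read(150), "")))
  q <- quantify_repeat(reads, cc, min_aln = 125, channel = "input")
  expect_equal(q$n_reads, 1000)
  expect_equal(q$n_hits, 10)
  expect_equal(q$fraction, 1.0)
  expect_equal(sum(q$identity_hist), q$n_hits)  # histogram mass = hits

  # invariant to read order and multiset duplication
  perm <- reads[sample(length(reads))]
  names(perm) <- sprintf("p%04d", seq_along(perm))
  expect_equal(quantify_repeat(perm, cc, 125)$fraction, 1.0)
  dup <- c(reads, reads, reads)
  names(dup) <- sprintf("d%04d", seq_along(dup))
  expect_equal(quantify_repeat(dup, cc, 125)$fraction, 1.0)

  expect_error(quantify_repeat(qreads(character(0)), cc), "empty")
})

test_that("estimated satellite fraction matches truth-overlap oracle", {
  spec <- genome_spec(c(chr1 = 300000),
                      data.frame(chrom = "chr1", start = 140000,
                                 monomer = "CentC", copies = 60,
                                 sub_rate = 0.04), seed = 21)
  g <- build_genome(spec)
  sim <- simulate_reads(g, 8000, NULL, 150, "input", 0.002, seed = 22)
  q <- quantify_repeat(sim$reads, cc, min_aln = 125, channel = "input")
  # truth: reads overlapping the array by >= 125 bp
  a0 <- g$arrays$start; a1 <- g$arrays$end
  ov <- pmin(sim$truth$start + 150, a1) - pmax(sim$truth$start, a0)
  p_truth <- mean(ov >= 125)
  se <- sqrt(p_truth * (1 - p_truth) / 8000)
  expect_lt(abs(q$fraction / 100 - p_truth), 3 * se)
})

test_that("chip exceeds input for satellite-resident enrichment", {
  spec <- genome_spec(c(chr1 = 300000),
                      data.frame(chrom = "chr1", start = 140000,
                                 monomer = "CentC", copies = 60,
                                 sub_rate = 0.04), seed = 31)
  g <- build_genome(spec)
  dom <- cenh3_domains(data.frame(chrom = "chr1", start = 140000,
                                  end = 140000 + 60 * 156), 20)
  chip <- simulate_reads(g, 4000, dom, 150, "chip", 0.002, seed = 32)
  inp <- simulate_reads(g, 4000, NULL, 150, "input", 0.002, seed = 33)
  qc <- quantify_repeat(chip$reads, cc, 125, channel = "chip")
  qi <- quantify_repeat(inp$reads, cc, 125, channel = "input")
  expect_gt(qc$fraction, qi$fraction)
})

test_that("identity-distribution comparison detects constructed preference", {
  set.seed(13)
  exact <- simulate_circular_reads(cc, 300, 150, sub_rate = 0, seed = 41)
  poly <- simulate_circular_reads(cc, 300, 150, sub_rate = 0.04, seed = 42)
  q_exact <- quantify_repeat(exact$reads, cc, 125, channel = "chip")
  q_poly <- quantify_repeat(poly$reads, cc, 125, channel = "input")

  same <- compare_identity_distributions(q_exact, q_exact)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$l1_distance, 0)

  pref <- compare_identity_distributions(q_exact, q_poly)
  expect_gt(pref$mean_diff, 2)  # ~4 percentage points by construction
  expect_gt(pref$l1_distance, 0)

  set.seed(14)
  rand <- quantify_repeat(qreads(vapply(1:50, function(i) random_read(150),
                                        "")), cc, 125)
  expect_error(compare_identity_distributions(q_exact, rand), "zero hits")
  q_other <- quantify_repeat(exact$reads, knob180_consensus(), 125)
  expect_error(compare_identity_distributions(q_exact, q_other),
               "different consensuses")
})

test_that("consensus refinement recovers the monomer up to rotation", {
  toy <- toy_consensus()
  truth_canon <- as.character(centsat:::canonical_rotation(toy$monomer))

  # noiseless 50x coverage, rotated seed -> exact fixed point
  clean <- simulate_circular_reads(toy, 60, read_len = 18, sub_rate = 0,
                                   seed = 51)
  rot_seed <- paste0(substr(toy_monomer, 8, 20), substr(toy_monomer, 1, 7))
  ref <- build_consensus(clean$reads, rot_seed, max_iter = 8)
  expect_equal(as.character(ref$monomer), truth_canon)

  # 4% polymorphic copies: majority vote still recovers the monomer
  noisy <- simulate_circular_reads(toy, 120, read_len = 18, sub_rate = 0.04,
                                   seed = 52)
  ref2 <- build_consensus(noisy$reads, rot_seed, max_iter = 8)
  expect_equal(as.character(ref2$monomer), truth_canon)

  # 1x coverage: result carries low-support flags
  single <- simulate_circular_reads(toy, 1, read_len = 18, sub_rate = 0,
                                    seed = 53)
  ref3 <- build_consensus(single$reads, toy_monomer, max_iter = 2,
                          min_support = 3)
  expect_true(any(attr(ref3, "low_support")))

  rand <- qreads(vapply(1:5, function(i) random_read(18), ""))
  expect_error(build_consensus(rand, toy_monomer, min_aln = 15),
               "no reads align")
})
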