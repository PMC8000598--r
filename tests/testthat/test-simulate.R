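test_that("template generation is deterministic and structurally sound", {
  locus <- generate_template(DEFAULT_REGIONS, seed = 7)
  expect_equal(locus$unit_length, 900L)
  expect_equal(sum(locus$region_lengths), locus$unit_length)

  # both copies extractable and identical
  g <- locus$genome_sequence
  sp <- locus$copy_spans
  c1 <- substr(g, sp[1, "start"] + 1L, sp[1, "end"])
  c2 <- substr(g, sp[2, "start"] + 1L, sp[2, "end"])
  expect_identical(c1, c2)
  expect_equal(nchar(c1), locus$unit_length)
  # no overlap between the copies
  expect_true(sp[1, "end"] <= sp[2, "start"])
  expect_match(g, "^[ACGT]+$")

  # same call twice: byte-identical genome
  locus2 <- generate_template(DEFAULT_REGIONS, seed = 7)
  expect_identical(locus$genome_sequence, locus2$genome_sequence)
  expect_false(identical(
    locus$genome_sequence,
    generate_template(DEFAULT_REGIONS, seed = 8)$genome_sequence))

  # region labels partition 1..unit_length in transcription order
  expect_equal(rle(locus$region)$values,
               c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2"))
  expect_equal(rle(locus$region)$lengths, unname(locus$region_lengths))
  expect_equal(unique(locus$region_type[locus$region == "18S"]), "gene")
  expect_equal(unique(locus$region_type[locus$region == "ITS2"]), "spacer")

  # errors name the offending region
  bad <- DEFAULT_REGIONS; bad[3] <- 0L
  expect_error(generate_template(bad, seed = 1), "ITS1")
  expect_error(generate_template(DEFAULT_REGIONS[-1], seed = 1), "7")
})

test_that("unit <-> genomic mapping follows the minus-strand gene geometry", {
  locus <- test_locus()
  u <- locus$unit_length
  # coordinate 1 (5' end of the transcript) maps to the highest genomic
  # position of each copy; coordinate u to the lowest
  expect_equal(unit_to_genomic(locus, 1, copy = 1),
               locus$copy_spans[1, "end"])
  expect_equal(unit_to_genomic(locus, u, copy = 1),
               locus$copy_spans[1, "start"] + 1L)
  # the sense base is the complement of the plus-strand base there
  g <- strsplit(locus$genome_sequence, "")[[1]]
  i <- c(1, 57, 900)
  expect_identical(
    chartr("ACGT", "TGCA", g[unit_to_genomic(locus, i, copy = 2)]),
    substring(locus$unit_seq, i, i))
  expect_error(unit_to_genomic(locus, 0), "outside")
})

test_that("occupancy truth is a probability distribution shaped by delta and beta", {
  locus <- test_locus()
  flat <- occupancy_truth(locus, strain_params())
  expect_equal(sum(flat$probability), 1)
  expect_true(all(flat$probability[!flat$eligible] == 0))
  # flat model: uniform over eligible positions
  el <- flat$probability[flat$eligible]
  expect_equal(el, rep(1 / sum(flat$eligible), length(el)))

  # delta tilts mass toward the 5' end: truth mean strictly smaller
  tw <- occupancy_truth(locus, strain_params(termination_prob = 5e-4))
  tm <- occupancy_truth(locus, strain_params(termination_prob = 3e-3))
  mean_of <- function(t) sum(t$coordinate * t$probability)
  expect_lt(mean_of(tm), mean_of(tw))

  # beta tilts mass toward G-rich-downstream positions
  g <- downstream_g_fraction(locus)
  tb <- occupancy_truth(locus, strain_params(pause_gc_weight = 2))
  expect_gt(sum(g * tb$probability), sum(g * flat$probability))

  expect_error(
    occupancy_truth(locus, strain_params(fragment_length_range = c(20, 5000))),
    "fragment")
})

test_that("simulated libraries are deterministic and follow the read format", {
  locus <- test_locus()
  params <- strain_params(termination_prob = 1e-3, duplicate_rate = 0.1,
                          offtarget_frac = 0.1)
  a <- simulate_reads(locus, params, 500, seed = 11)
  b <- simulate_reads(locus, params, 500, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$reads$sequence,
                         simulate_reads(locus, params, 500,
                                        seed = 12)$reads$sequence))

  # on-target reads carry the AG + UMI + TG prefix and the 3' linker
  on <- a$reads$sequence[a$reads$read_id %in% a$truth$read_lnt$read_id]
  expect_true(all(substr(on, 1, 2) == "AG" & substr(on, 11, 12) == "TG"))
  expect_true(all(grepl("CTGTAGGCACCAT", on, fixed = TRUE)))
  # off-target reads fail the 5' format filter by construction
  off <- setdiff(a$reads$read_id, a$truth$read_lnt$read_id)
  off_seq <- a$reads$sequence[a$reads$read_id %in% off]
  expect_false(any(substr(off_seq, 1, 2) == "AG" &
                     substr(off_seq, 11, 12) == "TG"))
  expect_error(simulate_reads(locus, params, 0, seed = 1), "positive")
})

test_that("flat model yields a uniform LNT histogram", {
  locus <- test_locus()
  sim <- simulate_reads(locus, strain_params(), 10000, seed = 3)
  lnt <- sim$truth$read_lnt$lnt
  el <- sim$truth$probabilities$eligible
  counts <- tabulate(lnt, nbins = locus$unit_length)[el]
  expect_equal(sum(counts), 10000)
  # chi-square against uniform; generous cut to keep the test stable
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 1e-4)
})

test_that("higher termination probability shifts sampled LNTs 5'-ward", {
  locus <- test_locus()
  wt <- simulate_reads(locus, strain_params(termination_prob = 5e-4),
                       20000, seed = 21)
  mut <- simulate_reads(locus, strain_params(termination_prob = 3e-3),
                        20000, seed = 22)
  m_wt <- mean(wt$truth$read_lnt$lnt)
  m_mut <- mean(mut$truth$read_lnt$lnt)
  expect_lt(m_mut, m_wt)
  # empirical means agree with the closed-form mean of the normalized
  # (1 - delta)^x distribution (the truth table)
  mean_of <- function(t) sum(t$coordinate * t$probability)
  expect_equal(m_wt, mean_of(wt$truth$probabilities), tolerance = 0.02)
  expect_equal(m_mut, mean_of(mut$truth$probabilities), tolerance = 0.02)
})

test_that("PCR duplicates are verbatim copies that dedup removes", {
  locus <- test_locus()
  sim <- simulate_reads(locus, strain_params(duplicate_rate = 0.5),
                        1000, seed = 31)
  expect_lt(length(unique(sim$reads$sequence)), 1000)
  dup <- sim$truth$read_lnt$is_duplicate
  expect_gt(sum(dup), 300)  # ~half the reads
})

test_that("positive beta enriches downstream G content of sampled LNTs", {
  locus <- test_locus()
  g <- downstream_g_fraction(locus)
  wt <- simulate_reads(locus, strain_params(), 20000, seed = 41)
  mut <- simulate_reads(locus, strain_params(pause_gc_weight = 1),
                        20000, seed = 42)
  g_wt <- mean(g[wt$truth$read_lnt$lnt])
  g_mut <- mean(g[mut$truth$read_lnt$lnt])
  # two-proportion-style margin well beyond sampling noise
  expect_gt(g_mut, g_wt + 0.01)
})

test_that("empirical LNT frequencies converge to the truth probabilities", {
  locus <- test_locus()
  params <- strain_params(termination_prob = 1e-3, pause_gc_weight = 0.5)
  tv <- vapply(c(2000, 50000), function(n) {
    sim <- simulate_reads(locus, params, n, seed = 51)
    emp <- tabulate(sim$truth$read_lnt$lnt, locus$unit_length) /
      nrow(sim$truth$read_lnt)
    sum(abs(emp - sim$truth$probabilities$probability)) / 2
  }, numeric(1))
  expect_lt(tv[2], tv[1])
})
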