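# Shared fixtures, built in code once per test run.

DEFAULT_REGIONS <- c(100L, 180L, 80L, 60L, 80L, 340L, 60L)

.fixture_env <- new.env(parent = emptyenv())

# one toy locus reused across test files (generation is deterministic)
test_locus <- function() {
  if (is.null(.fixture_env$locus))
    .fixture_env$locus <- generate_template(DEFAULT_REGIONS, seed = 7)
  .fixture_env$locus
}

# simulate -> preprocess -> normalized track, for one library
sim_track <- function(locus, params, n_reads, seed, strain = "s",
                      replicate = "rep1") {
  sim <- simulate_reads(locus, params, n_reads, seed = seed)
  pre <- preprocess_reads(sim$reads)
  occupancy_track(pre$reads, locus, strain = strain, replicate = replicate)
}

# a minimal locus stub when only the unit sequence matters
stub_locus <- function(unit_seq) {
  structure(list(unit_seq = unit_seq, unit_length = nchar(unit_seq)),
            class = "template_locus")
}

read_frame <- function(seqs) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}
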