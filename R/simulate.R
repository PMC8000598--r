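FORMAT_PREFIX_LEN <- 12L
LINKER_SEQ <- "CTGTAGGCACCAT"

#' Strain-level simulation parameters
#'
#' Parameters of the generative model for one strain's NET-seq libraries.
#' Polymerase occupancy weight at transcription-direction position `x` is
#' proportional to
#' \deqn{(1 - \delta)^x \exp(\beta \, g(x))}
#' where `delta` (`termination_prob`) is the per-nucleotide premature
#' termination probability, `beta` (`pause_gc_weight`) couples dwell time to
#' the G fraction `g(x)` of the 10 template positions downstream of `x`, and
#' weights are normalized to a probability distribution over eligible
#' positions. A processivity-impaired strain (larger `delta`) therefore shows
#' 5'-enriched, 3'-depleted occupancy; `beta > 0` enriches pause sites for
#' downstream G content.
#'
#' @param termination_prob per-nucleotide premature-termination probability,
#'   in `[0, 1)`.
#' @param pause_gc_weight coefficient on the downstream G fraction (0 = no
#'   sequence dependence).
#' @param duplicate_rate probability that an emitted read is a verbatim PCR
#'   copy of an earlier read, in `[0, 1)`.
#' @param offtarget_frac fraction of reads lacking the 5' library format,
#'   in `[0, 1)`.
#' @param fragment_length_range integer min/max insert length.
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(termination_prob = 0,
                          pause_gc_weight = 0,
                          duplicate_rate = 0,
                          offtarget_frac = 0,
                          fragment_length_range = c(20L, 40L)) {
  stopifnot(
    termination_prob >= 0, termination_prob < 1,
    duplicate_rate >= 0, duplicate_rate < 1,
    offtarget_frac >= 0, offtarget_frac < 1,
    length(fragment_length_range) == 2L
  )
  fragment_length_range <- as.integer(fragment_length_range)
  if (fragment_length_range[1L] < 1L ||
      fragment_length_range[1L] > fragment_length_range[2L])
    stop("'fragment_length_range' must satisfy 1 <= min <= max", call. = FALSE)
  structure(list(
    termination_prob = termination_prob,
    pause_gc_weight = pause_gc_weight,
    duplicate_rate = duplicate_rate,
    offtarget_frac = offtarget_frac,
    fragment_length_range = fragment_length_range
  ), class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf(
    "strain_params: delta=%g beta=%g dup=%g offtarget=%g fragments=%d..%d\n",
    x$termination_prob, x$pause_gc_weight, x$duplicate_rate,
    x$offtarget_frac, x$fragment_length_range[1L], x$fragment_length_range[2L]
  ))
  invisible(x)
}

#' Ground-truth per-position sampling probabilities
#'
#' Positions within one maximum fragment length of the unit's 5' edge are
#' ineligible as LNTs (a full insert could not be excised), so their
#' probability is 0; eligible positions get the normalized occupancy weight.
#'
#' @param locus a `template_locus`.
#' @param params a `strain_params`.
#' @return data.frame with columns `coordinate`, `probability`, `eligible`.
#' @export
occupancy_truth <- function(locus, params) {
  stopifnot(inherits(locus, "template_locus"),
            inherits(params, "strain_params"))
  u <- locus$unit_length
  frag_max <- params$fragment_length_range[2L]
  if (frag_max > u)
    stop("fragment length range exceeds the unit length", call. = FALSE)
  x <- seq_len(u)
  eligible <- x >= frag_max
  g <- downstream_g_fraction(locus)
  # log-weights for numerical stability at large x
  lw <- x * log1p(-params$termination_prob) + params$pause_gc_weight * g
  w <- exp(lw - max(lw[eligible]))
  w[!eligible] <- 0
  data.frame(
    coordinate = x,
    probability = w / sum(w),
    eligible = eligible
  )
}

#' Simulate one NET-seq library
#'
#' Draws LNT positions from the strain's occupancy distribution, excises the
#' insert (the last `len` transcribed nucleotides, ending at the LNT, which
#' by the locus geometry is a plus-strand genomic substring whose leftmost
#' coordinate is the LNT), and assembles reads as
#' `"AG" + UMI(8) + "TG" + insert + linker`. A fraction of reads are
#' off-target (random sequence failing the 5' format), and a fraction are
#' verbatim PCR duplicates of earlier reads. The returned truth records the
#' sampling distribution and every emitted on-target read's LNT.
#'
#' @param locus a `template_locus`.
#' @param params a `strain_params`.
#' @param n_reads number of reads to emit (> 0).
#' @param seed integer seed; fixes every emitted byte.
#' @param read_prefix prefix for read identifiers.
#' @return A list with `reads` (data.frame: `read_id`, `sequence`) and
#'   `truth` (list: `probabilities` data.frame from [occupancy_truth()],
#'   `read_lnt` data.frame of per-read true LNT positions with duplicate
#'   flags, `seed`).
#' @export
simulate_reads <- function(locus, params, n_reads, seed,
                           read_prefix = "read") {
  stopifnot(inherits(locus, "template_locus"),
            inherits(params, "strain_params"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L)
    stop("'n_reads' must be a positive integer", call. = FALSE)
  truth_probs <- occupancy_truth(locus, params)  # validates fragment range

  with_seed(seed, {
    frag_min <- params$fragment_length_range[1L]
    frag_max <- params$fragment_length_range[2L]
    mean_len <- FORMAT_PREFIX_LEN + floor((frag_min + frag_max) / 2) +
      nchar(LINKER_SEQ)

    is_dup <- runif(n_reads) < params$duplicate_rate
    is_dup[1L] <- FALSE
    orig <- which(!is_dup)
    n_orig <- length(orig)

    is_off <- logical(n_reads)
    is_off[orig] <- runif(n_orig) < params$offtarget_frac
    on <- orig[!is_off[orig]]
    off <- orig[is_off[orig]]

    seqs <- character(n_reads)
    lnt <- rep(NA_integer_, n_reads)

    if (length(on)) {
      lnt_on <- sample(truth_probs$coordinate, length(on), replace = TRUE,
                       prob = truth_probs$probability)
      len <- sample(seq.int(frag_min, frag_max), length(on), replace = TRUE)
      # plus-strand genomic 1-based start of the insert is the LNT position
      g1 <- unit_to_genomic(locus, lnt_on, copy = sample(1:2, length(on),
                                                         replace = TRUE))
      insert <- substring(locus$genome_sequence, g1, g1 + len - 1L)
      umi <- do.call(paste0, replicate(8L, sample(c("A", "C", "G", "T"),
                                                  length(on), replace = TRUE),
                                       simplify = FALSE))
      seqs[on] <- paste0("AG", umi, "TG", insert, LINKER_SEQ)
      lnt[on] <- lnt_on
    }
    if (length(off)) {
      bases <- sample(c("A", "C", "G", "T"), length(off) * mean_len,
                      replace = TRUE)
      s <- apply(matrix(bases, ncol = mean_len), 1L, paste, collapse = "")
      # guarantee the 5' format filter fails (postcondition of off-target)
      hit <- substr(s, 1L, 2L) == "AG" & substr(s, 11L, 12L) == "TG"
      substr(s[hit], 1L, 1L) <- "T"
      seqs[off] <- s
    }
    # PCR duplicates copy an earlier emitted read verbatim (UMI included)
    for (j in which(is_dup)) {
      src <- sample.int(j - 1L, 1L)
      seqs[j] <- seqs[src]
      lnt[j] <- lnt[src]
      is_off[j] <- is_off[src]
    }

    reads <- data.frame(
      read_id = sprintf("%s%06d", read_prefix, seq_len(n_reads)),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
    read_lnt <- data.frame(
      read_id = reads$read_id[!is_off],
      lnt = lnt[!is_off],
      is_duplicate = is_dup[!is_off],
      stringsAsFactors = FALSE
    )
    list(
      reads = reads,
      truth = list(probabilities = truth_probs, read_lnt = read_lnt,
                   seed = as.integer(seed))
    )
  })
}

#' Write simulation ground truth as TSV
#'
#' @param truth the `truth` element returned by [simulate_reads()].
#' @param path output path.
#' @param strain strain label recorded in the table.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path, strain = "strain") {
  df <- data.frame(
    coordinate = truth$probabilities$coordinate,
    strain = strain,
    probability = truth$probabilities$probability,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
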