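#' Exact-match alignment of preprocessed inserts
#'
#' Each insert is searched as an exact substring of the genome plus strand
#' and of its reverse complement (reported as minus strand). A read is
#' assigned to every matching location — in particular to both of the two
#' identical 35S copies — contributing one interval per location; copies are
#' summed later when the track is built. Inserts with no match (or containing
#' non-ACGT characters) are dropped and counted. The reverse complement is
#' only searched for inserts without a plus-strand match: NET-seq inserts are
#' strand-resolved, so an insert matching both strands would be a degenerate
#' ambiguity this toy aligner does not attempt to resolve. This is a deliberately
#' minimal stand-in for a genome aligner, adequate because the toy reference
#' is small and reads are simulated without sequencing errors.
#'
#' @param reads data.frame of preprocessed reads (`read_id`, `sequence`).
#' @param locus a `template_locus`.
#' @return data.frame of aligned intervals in BED convention (`chrom`,
#'   `start` 0-based inclusive, `end` 0-based exclusive, `strand`), one row
#'   per read-location pair, with attribute `n_unmatched`.
#' @export
align_exact <- function(reads, locus) {
  stopifnot(inherits(locus, "template_locus"))
  reads <- as_read_frame(reads)
  seqs <- reads$sequence
  genome_len <- nchar(locus$genome_sequence)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(seqs)) {
    attr(empty, "n_unmatched") <- 0L
    return(empty)
  }

  valid <- grepl("^[ACGT]+$", seqs)
  us <- unique(seqs[valid])
  mult <- tabulate(match(seqs[valid], us), nbins = length(us))

  subj_plus <- Biostrings::DNAString(locus$genome_sequence)

  # single variable-width dictionary with a trusted-band prefix; the part
  # outside the band is still verified exactly (max.mismatch = 0)
  match_dict <- function(patterns, subject) {
    dset <- Biostrings::DNAStringSet(patterns)
    pd <- Biostrings::PDict(dset, tb.start = 1L,
                            tb.end = min(Biostrings::width(dset)))
    Biostrings::startIndex(Biostrings::matchPDict(pd, subject,
                                                  max.mismatch = 0))
  }
  interval_rows <- function(hits, pat_idx, strand) {
    nh <- lengths(hits)
    p <- unlist(hits, use.names = FALSE)                # 1-based in subject
    if (!length(p)) return(NULL)
    pat <- rep(pat_idx, nh)
    w <- nchar(us)[pat]
    if (strand == "+") {
      start0 <- p - 1L
      end0 <- p - 1L + w
    } else {
      # position p in the reverse complement maps back to the plus strand
      start0 <- genome_len - (p - 1L) - w
      end0 <- genome_len - (p - 1L)
    }
    rep_i <- rep(seq_along(p), mult[pat])
    data.frame(chrom = "toy_rdna", start = start0[rep_i],
               end = end0[rep_i], strand = strand, stringsAsFactors = FALSE)
  }

  res <- list()
  matched <- logical(length(us))
  if (length(us)) {
    hits_plus <- match_dict(us, subj_plus)
    matched <- lengths(hits_plus) > 0L
    res$plus <- interval_rows(hits_plus, seq_along(us), "+")
    # only reads unmatched on the plus strand can be minus-strand reads
    todo <- which(!matched)
    if (length(todo)) {
      subj_minus <- Biostrings::reverseComplement(subj_plus)
      hits_minus <- match_dict(us[todo], subj_minus)
      matched[todo] <- lengths(hits_minus) > 0L
      res$minus <- interval_rows(hits_minus, todo, "-")
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  n_unmatched <- sum(!valid) + sum(mult[!matched])
  attr(out, "n_unmatched") <- as.integer(n_unmatched)
  out
}

#' Per-position counts of 5' read ends
#'
#' Implements single-base 5'-end coverage: a plus-strand interval increments
#' position `start + 1` (1-based) of the plus vector; a minus-strand interval
#' increments position `end` (1-based) of the minus vector — the genomic
#' 5' end of the read in both cases.
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open) and
#'   `strand`.
#' @param genome_length chromosome length.
#' @return list with integer vectors `plus` and `minus` of length
#'   `genome_length`; `sum(plus) + sum(minus)` equals `nrow(intervals)`.
#' @export
count_5prime_ends <- function(intervals, genome_length) {
  genome_length <- as.integer(genome_length)
  if (nrow(intervals)) {
    if (any(intervals$start < 0L | intervals$end > genome_length |
            intervals$start >= intervals$end))
      stop("interval out of bounds for genome of length ", genome_length,
           call. = FALSE)
    if (!all(intervals$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
  }
  is_plus <- intervals$strand == "+"
  list(
    plus = tabulate(intervals$start[is_plus] + 1L, nbins = genome_length),
    minus = tabulate(intervals$end[!is_plus], nbins = genome_length)
  )
}

#' Build the per-position occupancy data frame
#'
#' Maps genomic count vectors into transcription-direction coordinates and
#' combines the two 35S copies by summing their counts at each coordinate,
#' annotating nucleotide, region, and region type from the locus.
#'
#' @param count_vectors list with `plus` and `minus` genomic count vectors
#'   (from [count_5prime_ends()]).
#' @param locus a `template_locus`.
#' @param strain,replicate labels stored in the track.
#' @return An `occupancy_track` data.frame with columns `coordinate`,
#'   `nucleotide`, `region`, `region_type`, `strain`, `replicate`,
#'   `count_plus`, `count_minus`, `normalized` (NA until
#'   [normalize_track()]).
#' @export
build_track <- function(count_vectors, locus, strain = "strain",
                        replicate = "rep1") {
  stopifnot(inherits(locus, "template_locus"),
            is.list(count_vectors),
            all(c("plus", "minus") %in% names(count_vectors)))
  genome_len <- nchar(locus$genome_sequence)
  if (length(count_vectors$plus) != genome_len ||
      length(count_vectors$minus) != genome_len)
    stop("count vectors must cover the genome (length ", genome_len, ")",
         call. = FALSE)
  u <- locus$unit_length
  i <- seq_len(u)
  g1 <- unit_to_genomic(locus, i, copy = 1L)
  g2 <- unit_to_genomic(locus, i, copy = 2L)
  track <- data.frame(
    coordinate = i,
    nucleotide = strsplit(locus$unit_seq, "", fixed = TRUE)[[1L]],
    region = locus$region,
    region_type = locus$region_type,
    strain = strain,
    replicate = replicate,
    count_plus = count_vectors$plus[g1] + count_vectors$plus[g2],
    count_minus = count_vectors$minus[g1] + count_vectors$minus[g2],
    normalized = NA_real_,
    stringsAsFactors = FALSE
  )
  class(track) <- c("occupancy_track", "data.frame")
  track
}

#' Normalize an occupancy track by its plus-strand total
#'
#' Divides each plus-strand count by the total plus-strand count, so the
#' normalized column sums to 1. Minus-strand counts are retained for QC but
#' never normalized.
#'
#' @param track an `occupancy_track`.
#' @return The track with its `normalized` column filled in.
#' @export
normalize_track <- function(track) {
  validate_track(track, normalized = FALSE)
  total <- sum(track$count_plus)
  if (total <= 0)
    stop("cannot normalize: plus-strand total is zero", call. = FALSE)
  track$normalized <- track$count_plus / total
  track
}

#' Occupancy track straight from preprocessed reads
#'
#' Convenience wrapper: [align_exact()] then [count_5prime_ends()] then
#' [build_track()] then (optionally) [normalize_track()].
#'
#' @inheritParams align_exact
#' @inheritParams build_track
#' @param normalize whether to fill the `normalized` column.
#' @return An `occupancy_track`; attribute `n_unmatched` carries the number
#'   of reads with no exact match.
#' @export
occupancy_track <- function(reads, locus, strain = "strain",
                            replicate = "rep1", normalize = TRUE) {
  iv <- align_exact(reads, locus)
  cv <- count_5prime_ends(iv, nchar(locus$genome_sequence))
  track <- build_track(cv, locus, strain = strain, replicate = replicate)
  if (normalize) track <- normalize_track(track)
  attr(track, "n_unmatched") <- attr(iv, "n_unmatched")
  track
}

TRACK_COLUMNS <- c("coordinate", "nucleotide", "region", "region_type",
                   "strain", "replicate", "count_plus", "count_minus",
                   "normalized")

validate_track <- function(track, normalized = TRUE) {
  if (!is.data.frame(track) || !all(TRACK_COLUMNS %in% names(track)))
    stop("not an occupancy track: expected columns ",
         paste(TRACK_COLUMNS, collapse = ", "), call. = FALSE)
  if (!identical(as.integer(track$coordinate), seq_len(nrow(track))))
    stop("track coordinates must be contiguous from 1", call. = FALSE)
  if (normalized && anyNA(track$normalized))
    stop("track is not normalized", call. = FALSE)
  invisible(track)
}
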