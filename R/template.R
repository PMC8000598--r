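#' @importFrom stats cor ks.test median pt quantile runif setNames
#' @importFrom utils packageVersion read.delim write.table
NULL

REGION_NAMES <- c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2")
REGION_TYPES <- c(
  ETS1 = "spacer", `18S` = "gene", ITS1 = "spacer", `5.8S` = "gene",
  ITS2 = "spacer", `25S` = "gene", ETS2 = "spacer"
)

# Run code with a private RNG stream, leaving the caller's stream untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a toy two-copy rDNA locus
#'
#' Builds a small reference genome carrying two identical copies of a 35S-like
#' transcription unit (ETS1, 18S, ITS1, 5.8S, ITS2, 25S, ETS2 in transcription
#' order), embedded in random flanking sequence. The unit sits on the genomic
#' minus strand, so that NET-seq inserts — which cover the 3' end of the
#' nascent transcript up to the last incorporated nucleotide (LNT) — align to
#' the plus strand with their leftmost genomic coordinate equal to the LNT.
#' Transcription-direction coordinates run 1..unit_length starting at ETS1.
#'
#' @param region_lengths integer vector of length 7: lengths of ETS1, 18S,
#'   ITS1, 5.8S, ITS2, 25S, ETS2 in transcription order.
#' @param seed integer seed; the same seed yields a byte-identical locus.
#' @param flank length of random sequence placed before the first and after
#'   the second copy.
#' @param gap length of random sequence between the two copies.
#' @return An object of class `template_locus`: a list with `genome_sequence`,
#'   `copy_spans` (2x2 matrix of 0-based half-open genomic intervals),
#'   `gene_strand` (`"-"`), `region_lengths`, `unit_length`, `unit_seq`
#'   (sense-strand sequence in transcription direction), and per-coordinate
#'   `region` / `region_type` annotation.
#' @export
generate_template <- function(region_lengths, seed, flank = 200L, gap = 150L) {
  region_lengths <- as.integer(region_lengths)
  if (length(region_lengths) != 7L)
    stop("'region_lengths' must have exactly 7 entries (",
         paste(REGION_NAMES, collapse = ", "), ")", call. = FALSE)
  bad <- which(is.na(region_lengths) | region_lengths <= 0L)
  if (length(bad))
    stop("region length for ", REGION_NAMES[bad[1L]],
         " must be a positive integer", call. = FALSE)
  names(region_lengths) <- REGION_NAMES
  unit_length <- sum(region_lengths)

  with_seed(seed, {
    unit_seq <- random_dna(unit_length)
    flank_l <- random_dna(flank)
    flank_r <- random_dna(flank)
    gap_seq <- random_dna(gap)
    copy_seq <- revcomp(unit_seq)
    genome <- paste0(flank_l, copy_seq, gap_seq, copy_seq, flank_r)

    s1 <- flank
    s2 <- flank + unit_length + gap
    copy_spans <- matrix(
      c(s1, s1 + unit_length, s2, s2 + unit_length),
      nrow = 2L, byrow = TRUE,
      dimnames = list(c("copy1", "copy2"), c("start", "end"))
    )

    region <- rep(REGION_NAMES, times = region_lengths)
    locus <- structure(list(
      genome_sequence = genome,
      copy_spans = copy_spans,
      gene_strand = "-",
      region_lengths = region_lengths,
      unit_length = unit_length,
      unit_seq = unit_seq,
      region = region,
      region_type = unname(REGION_TYPES[region]),
      seed = as.integer(seed)
    ), class = "template_locus")
    locus
  })
}

#' @export
print.template_locus <- function(x, ...) {
  cat("template_locus: two-copy 35S unit, gene strand", x$gene_strand, "\n")
  cat("  unit length:", x$unit_length, "nt; genome:",
      nchar(x$genome_sequence), "nt\n")
  cat("  regions:", paste(sprintf("%s=%d", names(x$region_lengths),
                                  x$region_lengths), collapse = " "), "\n")
  invisible(x)
}

#' Sense-strand sequence of the transcription unit
#'
#' @param locus a `template_locus`.
#' @return Character string of length `unit_length`, 5' to 3' in
#'   transcription direction (position 1 = first base of ETS1).
#' @export
unit_sequence <- function(locus) {
  stopifnot(inherits(locus, "template_locus"))
  locus$unit_seq
}

#' Map transcription-direction coordinates to genomic positions
#'
#' The unit lies on the genomic minus strand, so transcription-direction
#' coordinate `i` of a copy spanning `[s, e)` (0-based half-open) maps to
#' 1-based genomic plus-strand position `e - i + 1`.
#'
#' @param locus a `template_locus`.
#' @param coords vector of transcription-direction coordinates in
#'   `1..unit_length`.
#' @param copy 1 or 2.
#' @return Integer vector of 1-based genomic positions.
#' @export
unit_to_genomic <- function(locus, coords, copy = 1L) {
  stopifnot(inherits(locus, "template_locus"))
  coords <- as.integer(coords)
  if (any(coords < 1L | coords > locus$unit_length))
    stop("coordinates outside 1..unit_length", call. = FALSE)
  e <- locus$copy_spans[copy, "end"]
  as.integer(e - coords + 1L)
}

#' Downstream G fraction used for pause weighting
#'
#' G fraction of the sense-strand template over the `width` positions
#' immediately downstream (transcription direction) of each coordinate;
#' positions beyond the unit end are excluded from the denominator, and the
#' final coordinate (no downstream template) gets 0.
#'
#' @param locus a `template_locus`.
#' @param width downstream window width (default 10, the +1..+10 region).
#' @return Numeric vector of length `unit_length`.
#' @export
downstream_g_fraction <- function(locus, width = 10L) {
  stopifnot(inherits(locus, "template_locus"))
  is_g <- as.integer(strsplit(locus$unit_seq, "", fixed = TRUE)[[1L]] == "G")
  u <- locus$unit_length
  cs <- cumsum(c(0L, is_g))
  x <- seq_len(u)
  hi <- pmin(x + width, u)
  n_down <- hi - x
  g <- ifelse(n_down > 0L, (cs[hi + 1L] - cs[x + 1L]) / n_down, 0)
  as.numeric(g)
}

#' Write / read the locus template as FASTA
#'
#' @param locus a `template_locus`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(locus, path) {
  stopifnot(inherits(locus, "template_locus"))
  dna <- Biostrings::DNAStringSet(locus$genome_sequence)
  names(dna) <- "toy_rdna"
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Write the per-coordinate region annotation as TSV
#'
#' @param locus a `template_locus`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_annotation <- function(locus, path) {
  stopifnot(inherits(locus, "template_locus"))
  df <- data.frame(
    coordinate = seq_len(locus$unit_length),
    nucleotide = strsplit(locus$unit_seq, "", fixed = TRUE)[[1L]],
    region = locus$region,
    region_type = locus$region_type,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
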