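#' Write reads as FASTQ
#'
#' Four-line records with constant quality `I`; gzip output is selected by a
#' `.gz` extension.
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_frame(reads)
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a read frame
#'
#' @param path FASTQ path (gzip autodetected).
#' @return data.frame with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path))
    stop("FASTQ file not found: ", path, call. = FALSE)
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(dna), sequence = as.character(dna),
             stringsAsFactors = FALSE, row.names = NULL)
}

output_header <- function(seed = NULL, config_hash = NULL) {
  c(
    paste0("# polinetseq_version=", as.character(packageVersion("polinetseq"))),
    if (!is.null(seed)) paste0("# seed=", seed),
    if (!is.null(config_hash)) paste0("# config=", config_hash)
  )
}

#' Write an occupancy track as TSV
#'
#' Tab-delimited with a `#`-prefixed header comment carrying the tool
#' version (and optionally the seed and config hash). The `normalized`
#' column is printed with 17 significant digits so that a round trip through
#' disk is value-identical.
#'
#' @param track an `occupancy_track`.
#' @param path output path.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, seed = NULL, config_hash = NULL) {
  validate_track(track, normalized = FALSE)
  out <- track[, TRACK_COLUMNS]
  out$normalized <- sprintf("%.17g", out$normalized)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy track from TSV
#'
#' @param path a TSV written by [write_track()].
#' @return An `occupancy_track` data.frame.
#' @export
read_track <- function(path) {
  if (!file.exists(path))
    stop("track file not found: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(nucleotide = "character",
                                  region = "character"))
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols))
    stop("malformed track header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!identical(as.integer(df$coordinate), seq_len(nrow(df))))
    stop("track coordinates are not contiguous from 1", call. = FALSE)
  df$normalized <- as.numeric(df$normalized)
  class(df) <- c("occupancy_track", "data.frame")
  df
}

#' Write aligned intervals as BED6
#'
#' @param intervals data.frame from [align_exact()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = sprintf("interval_%d", seq_len(nrow(intervals))),
    score = 0L,
    strand = intervals$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_tsv_with_header <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Write a difference-logo result as TSV
#'
#' One row per column: label, signed per-base contributions (positive =
#' overrepresented in the mutant), divergence height (bits), permutation
#' p-value, significance flag.
#'
#' @param result a `diff_logo_result`.
#' @param path output path.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_difflogo_tsv <- function(result, path, seed = NULL,
                               config_hash = NULL) {
  stopifnot(inherits(result, "diff_logo_result"))
  df <- cbind(
    data.frame(label = result$columns$label),
    as.data.frame(t(result$contributions)),
    result$columns[, c("height", "p_value", "significant")]
  )
  write_tsv_with_header(df, path, seed, config_hash)
}
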