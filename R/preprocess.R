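#' Remove exact PCR duplicates
#'
#' PCR duplicates are verbatim copies of a molecule, UMI included, so
#' collapsing identical full read sequences implements UMI-based
#' deduplication. The first occurrence is kept; input order is otherwise
#' preserved.
#'
#' After format filtering the UMI sits in its own column; it is then part of
#' the collapse key, so two molecules with different UMIs but the same insert
#' are kept apart and the pipeline stays idempotent.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @return list with `reads` (deduplicated data.frame) and `stats`
#'   (`n_input`, `n_after_dedup`).
#' @export
deduplicate <- function(reads) {
  reads <- as_read_frame(reads)
  key <- if ("umi" %in% names(reads))
    paste0(reads$umi, "|", reads$sequence) else reads$sequence
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(n_input = nrow(reads), n_after_dedup = nrow(out)))
}

#' Filter reads on the 5' library format and capture the UMI
#'
#' A read is on target iff it is at least 13 nt long, starts with `AG`, and
#' carries `TG` at positions 11-12 (the `AG NNNNNNNN TG` library prefix).
#' Positions 3-10 become the read's UMI; the first 12 nt are removed from the
#' retained sequence. Reads failing the pattern are discarded and counted.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `umi`) and
#'   `stats` (`n_on_target`, `n_discarded_format`).
#' @export
filter_on_target <- function(reads) {
  reads <- as_read_frame(reads)
  s <- reads$sequence
  ok <- nchar(s) >= 13L &
    substr(s, 1L, 2L) == "AG" & substr(s, 11L, 12L) == "TG"
  out <- reads[ok, , drop = FALSE]
  out$umi <- substr(out$sequence, 3L, 10L)
  out$sequence <- substr(out$sequence, 13L, nchar(out$sequence))
  rownames(out) <- NULL
  list(reads = out,
       stats = list(n_on_target = sum(ok),
                    n_discarded_format = sum(!ok)))
}

#' Trim the 3' library linker
#'
#' Truncates each read at the first occurrence of the 3' library sequence
#' `CTGTAGGCACCAT` (the linker and everything 3' of it are removed). Reads
#' with no occurrence pass unchanged; reads whose insert becomes empty are
#' discarded.
#'
#' @param reads data.frame of format-filtered reads.
#' @return list with `reads` and `stats` (`n_linker_trimmed`,
#'   `n_discarded_empty`).
#' @export
trim_linker <- function(reads) {
  reads <- as_read_frame(reads)
  pos <- regexpr(LINKER_SEQ, reads$sequence, fixed = TRUE)
  hit <- pos > 0L
  reads$sequence[hit] <- substr(reads$sequence[hit], 1L, pos[hit] - 1L)
  keep <- nchar(reads$sequence) > 0L
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(n_linker_trimmed = sum(hit),
                    n_discarded_empty = sum(!keep)))
}

#' Run the full three-step preprocessing
#'
#' Exact-duplicate removal, then 5' format filtering with 12-nt removal and
#' UMI capture, then 3' linker trimming.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @return list with `reads` (preprocessed inserts) and `stats`, a named
#'   list of the counts gathered at each step; always satisfies
#'   `n_on_target + n_discarded_format == n_after_dedup`.
#' @export
preprocess_reads <- function(reads) {
  d <- deduplicate(reads)
  f <- filter_on_target(d$reads)
  t <- trim_linker(f$reads)
  list(reads = t$reads, stats = c(d$stats, f$stats, t$stats))
}

as_read_frame <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "sequence") %in% names(reads)))
    stop("reads must be a data.frame with columns 'read_id' and 'sequence'",
         call. = FALSE)
  reads
}
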