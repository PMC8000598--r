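DNA_BASES <- c("A", "C", "G", "T")

#' Call top-quantile pause sites
#'
#' Pause sites are the positions whose median normalized occupancy is at or
#' above the `1 - top_fraction` quantile. Positions too close to the unit
#' edges for a full `±flank` sequence window are excluded before the
#' quantile is computed. All positions tied at the threshold value are
#' included, so the set can exceed `top_fraction` exactly at ties (with all
#' values equal, every eligible position is returned).
#'
#' @param median_values per-position median normalized occupancy.
#' @param top_fraction occupancy quantile (0.025 = top 2.5%).
#' @param flank logo half-width used for edge exclusion.
#' @param strain label carried along.
#' @return An object of class `pause_sites`: list with `coordinates`
#'   (ascending), `quantile_threshold`, `top_fraction`, `strain`.
#' @export
call_pause_sites <- function(median_values, top_fraction = 0.025,
                             flank = 30L, strain = "strain") {
  stopifnot(top_fraction > 0, top_fraction < 1, flank >= 1)
  u <- length(median_values)
  if (u < 2L * flank)
    stop("track (", u, " nt) is shorter than one full window (",
         2L * flank, " nt)", call. = FALSE)
  eligible <- seq.int(flank, u - flank)
  v <- median_values[eligible]
  threshold <- unname(quantile(v, 1 - top_fraction))
  structure(list(
    coordinates = eligible[v >= threshold],
    quantile_threshold = threshold,
    top_fraction = top_fraction,
    strain = strain
  ), class = "pause_sites")
}

#' @export
print.pause_sites <- function(x, ...) {
  cat(sprintf("pause_sites (%s): %d sites at or above %.3g (top %.3g%%)\n",
              x$strain, length(x$coordinates), x$quantile_threshold,
              100 * x$top_fraction))
  invisible(x)
}

#' Extract sequence windows around pause sites
#'
#' For a last incorporated nucleotide (LNT) at unit position `p`, the window
#' is the sense-strand template sequence at labels `-flank..-1` (ending at
#' `p`, so the LNT base sits at label -1) followed by `+1..+flank` (starting
#' at `p + 1`); there is no label 0.
#'
#' @param sites a `pause_sites` object (or vector of coordinates).
#' @param locus a `template_locus`.
#' @param flank half-width; total window length is `2 * flank`.
#' @return An object of class `window_set`: list with `windows` (character
#'   vector named by coordinate, ascending), `labels` (integer column
#'   labels), `flank`.
#' @export
extract_windows <- function(sites, locus, flank = 30L) {
  stopifnot(inherits(locus, "template_locus"))
  coords <- if (inherits(sites, "pause_sites")) sites$coordinates
            else as.integer(sites)
  coords <- sort(coords)
  if (length(coords) &&
      (min(coords) - flank + 1L < 1L ||
       max(coords) + flank > locus$unit_length))
    stop("site too close to a unit edge for a full window", call. = FALSE)
  w <- substring(locus$unit_seq, coords - flank + 1L, coords + flank)
  names(w) <- coords
  structure(list(
    windows = w,
    labels = c(seq.int(-flank, -1L), seq.int(1L, flank)),
    flank = as.integer(flank)
  ), class = "window_set")
}

#' Write a window set as FASTA
#'
#' @param window_set a `window_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(window_set, path) {
  dna <- Biostrings::DNAStringSet(window_set$windows)
  names(dna) <- paste0("lnt_", names(window_set$windows))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Build a position frequency / probability matrix
#'
#' Per-column base counts and maximum-likelihood probabilities over a set of
#' equal-length windows. No pseudocounts: zero cells are possible and are
#' handled downstream via the convention 0 log 0 = 0.
#'
#' @param windows a `window_set` or character vector of equal-length
#'   A/C/G/T strings.
#' @return An object of class `position_matrix`: list with `counts` and
#'   `probs` (4 x width matrices, rows A/C/G/T), `n_sequences`, `labels`.
#' @export
build_matrix <- function(windows) {
  labels <- NULL
  if (inherits(windows, "window_set")) {
    labels <- windows$labels
    windows <- windows$windows
  }
  if (!length(windows))
    stop("need at least one window", call. = FALSE)
  width <- unique(nchar(windows))
  if (length(width) != 1L)
    stop("windows must all have the same length", call. = FALSE)
  bad <- grep("[^ACGT]", windows)
  if (length(bad)) {
    nm <- if (!is.null(names(windows))) names(windows)[bad[1L]] else bad[1L]
    stop("window ", nm, " contains a non-ACGT character", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = width)
  counts <- do.call(rbind, lapply(DNA_BASES, function(b)
    rowSums(chars == b)))  # 4 x width, rows A/C/G/T
  rownames(counts) <- DNA_BASES
  if (is.null(labels)) labels <- seq_len(width)
  colnames(counts) <- labels
  structure(list(
    counts = counts,
    probs = counts / length(windows),
    n_sequences = length(windows),
    labels = labels
  ), class = "position_matrix")
}

# Jensen-Shannon divergence in bits between two probability vectors,
# with the 0 log 0 = 0 convention; symmetric, in [0, 1].
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    s <- a > 0
    sum(a[s] * log2(a[s] / m[s]))
  }
  (kl(p) + kl(q)) / 2
}

#' Permutation-tested difference logo
#'
#' For each column, the divergence height is the Jensen-Shannon divergence
#' (base 2) between the WT and mutant probability columns; per-base signed
#' contributions split the height in proportion to the probability
#' differences, positive toward the mutant. Column p-values come from
#' permutation: the pooled base observations of the column are reallocated
#' to the two strains (group sizes preserved), the divergence recomputed,
#' and the p-value is the fraction of permutations reaching the observed
#' divergence, with a +1/(n+1) correction so p is never 0.
#'
#' @param matrix_wt,matrix_mut `position_matrix` objects of equal width,
#'   each built from at least 2 sequences.
#' @param n_permutations number of label shuffles (>= 1).
#' @param seed integer seed for the permutations.
#' @param alpha significance level for the per-column flags.
#' @return An object of class `diff_logo_result`: list with `columns`
#'   (data.frame: `label`, `height`, `p_value`, `significant`),
#'   `contributions` (4 x width signed matrix; positive = overrepresented
#'   in the mutant), `alpha`, `n_permutations`.
#' @export
diff_logo <- function(matrix_wt, matrix_mut, n_permutations = 999L,
                      seed = 1L, alpha = 0.05) {
  stopifnot(inherits(matrix_wt, "position_matrix"),
            inherits(matrix_mut, "position_matrix"))
  if (ncol(matrix_wt$counts) != ncol(matrix_mut$counts))
    stop("matrices have different widths", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L)
    stop("need at least one permutation", call. = FALSE)
  if (matrix_wt$n_sequences < 2L || matrix_mut$n_sequences < 2L)
    stop("need at least 2 sequences per strain", call. = FALSE)

  width <- ncol(matrix_wt$counts)
  n1 <- matrix_wt$n_sequences
  n2 <- matrix_mut$n_sequences
  heights <- numeric(width)
  pvals <- numeric(width)
  contributions <- matrix(0, 4L, width,
                          dimnames = list(DNA_BASES, matrix_wt$labels))

  with_seed(seed, {
    for (j in seq_len(width)) {
      pw <- matrix_wt$probs[, j]
      pm <- matrix_mut$probs[, j]
      h <- js_divergence(pw, pm)
      heights[j] <- h
      d <- pm - pw
      tot <- sum(abs(d))
      if (tot > 0) contributions[, j] <- h * d / tot

      pooled <- rep.int(1:4, matrix_wt$counts[, j] + matrix_mut$counts[, j])
      n <- n1 + n2
      ge <- 0L
      for (b in seq_len(n_permutations)) {
        take <- sample.int(n, n1)
        c1 <- tabulate(pooled[take], 4L)
        c2 <- tabulate(pooled[-take], 4L)
        if (js_divergence(c1 / n1, c2 / n2) >= h - 1e-12) ge <- ge + 1L
      }
      pvals[j] <- (1L + ge) / (n_permutations + 1L)
    }
  })

  structure(list(
    columns = data.frame(
      label = matrix_wt$labels,
      height = heights,
      p_value = pvals,
      significant = pvals < alpha
    ),
    contributions = contributions,
    alpha = alpha,
    n_permutations = n_permutations
  ), class = "diff_logo_result")
}

#' @export
print.diff_logo_result <- function(x, ...) {
  sig <- x$columns$label[x$columns$significant]
  cat("diff_logo_result:", nrow(x$columns), "columns,",
      length(sig), "significant at alpha =", x$alpha, "\n")
  if (length(sig)) cat("  significant labels:", paste(sig, collapse = " "), "\n")
  invisible(x)
}

#' Pause-site sequence-context analysis, end to end
#'
#' Calls pause sites per strain on the median track, extracts `±flank`
#' windows, builds the position matrices, and computes the
#' permutation-tested difference logo.
#'
#' @param median_wt,median_mut per-position median normalized occupancy.
#' @param locus a `template_locus`.
#' @param config an [analysis_config()].
#' @return list with `sites_wt`, `sites_mut`, `windows_wt`, `windows_mut`,
#'   `matrix_wt`, `matrix_mut`, `difflogo`.
#' @export
pause_logo_analysis <- function(median_wt, median_mut, locus,
                                config = analysis_config()) {
  sites_wt <- call_pause_sites(median_wt, config$top_fraction, config$flank,
                               strain = "wt")
  sites_mut <- call_pause_sites(median_mut, config$top_fraction, config$flank,
                                strain = "mut")
  windows_wt <- extract_windows(sites_wt, locus, config$flank)
  windows_mut <- extract_windows(sites_mut, locus, config$flank)
  matrix_wt <- build_matrix(windows_wt)
  matrix_mut <- build_matrix(windows_mut)
  list(
    sites_wt = sites_wt, sites_mut = sites_mut,
    windows_wt = windows_wt, windows_mut = windows_mut,
    matrix_wt = matrix_wt, matrix_mut = matrix_mut,
    difflogo = diff_logo(matrix_wt, matrix_mut,
                         n_permutations = config$n_permutations,
                         seed = config$seed, alpha = config$alpha)
  )
}
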