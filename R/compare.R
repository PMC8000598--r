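#' Analysis configuration
#'
#' Tunable parameters shared by the comparison and pause-logo stages.
#'
#' @param alpha per-position and per-column significance level.
#' @param windows moving-average window sizes in base pairs. Windows larger
#'   than the analysed unit are skipped at run time.
#' @param top_fraction occupancy quantile defining pause sites (0.025 =
#'   top 2.5%).
#' @param flank half-width of the sequence window around the last
#'   incorporated nucleotide.
#' @param n_permutations label permutations for the difference-logo test.
#' @param seed integer seed used by permutation tests and simulation stages.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, windows = c(200L, 2000L),
                            top_fraction = 0.025, flank = 30L,
                            n_permutations = 999L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1,
            top_fraction > 0, top_fraction < 1,
            flank >= 1, all(windows >= 1), n_permutations >= 1)
  structure(list(
    alpha = alpha, windows = as.integer(windows),
    top_fraction = top_fraction, flank = as.integer(flank),
    n_permutations = as.integer(n_permutations), seed = as.integer(seed)
  ), class = "analysis_config")
}

track_values <- function(x) {
  if (is.data.frame(x)) {
    validate_track(x)
    x$normalized
  } else as.numeric(x)
}

#' Spearman concordance between two occupancy tracks
#'
#' Rank correlation of the two normalized occupancy vectors, with ties
#' handled by average ranks. A coefficient of 1 indicates identical rank
#' order (a track against itself); -1 indicates completely opposite rank
#' order.
#'
#' @param track_a,track_b `occupancy_track`s or numeric vectors of equal
#'   length (at least 2).
#' @return Spearman correlation coefficient in `[-1, 1]`.
#' @export
spearman_concordance <- function(track_a, track_b) {
  a <- track_values(track_a)
  b <- track_values(track_b)
  if (length(a) != length(b))
    stop("tracks have different lengths (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least two positions", call. = FALSE)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    stop("constant track: Spearman correlation is undefined", call. = FALSE)
  ra <- rank(a)
  rb <- rank(b)
  # identical rankings are exactly 1 by definition; bypass floating-point
  # round-off in the product-moment computation
  if (identical(ra, rb)) return(1)
  cor(ra, rb)
}

#' Per-position median across replicate tracks
#'
#' @param tracks list of normalized `occupancy_track`s (or numeric vectors)
#'   of equal length.
#' @return Numeric vector of per-position medians.
#' @export
median_track <- function(tracks) {
  vals <- lapply(tracks, track_values)
  if (length(unique(lengths(vals))) != 1L)
    stop("tracks have different lengths", call. = FALSE)
  m <- do.call(cbind, vals)
  apply(m, 1L, median)
}

# Vectorized two-sample t p-values, one test per row.
# Pooled-variance (Student) by default: at 3 replicates per strain the
# Satterthwaite df estimate is noisy enough to make Welch visibly
# conservative, while the pooled test holds its nominal size.
# Rows with no variation and equal means get NA (nothing to test); rows
# with no variation but unequal means get p = 0.
position_t_pvalues <- function(X, Y, var_equal = TRUE) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  ssx <- rowSums((X - mx)^2)
  ssy <- rowSums((Y - my)^2)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- (ssx + ssy) / df
    se2 <- sp2 * (1 / nx + 1 / ny)
  } else {
    vx <- ssx / (nx - 1); vy <- ssy / (ny - 1)
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p <- 2 * pt(-abs(mx - my) / sqrt(se2), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], NA_real_, 0)
  p
}

#' Per-position comparison of two strains
#'
#' At each transcription-direction coordinate, tests for a location
#' difference between the normalized replicate values of the two strains
#' (two-sided two-sample t-test; pooled variance by default, Welch with
#' `var_equal = FALSE`) and classifies the position as `increased` /
#' `decreased` occupancy in the mutant, or `none`. Positions where all
#' replicate values are identical across both strains carry `NA` p-values
#' and class `none`.
#'
#' @param wt_tracks,mut_tracks lists of at least 2 replicate tracks each.
#' @param config an [analysis_config()].
#' @param var_equal pool variances across strains (default) or use the
#'   Welch-Satterthwaite approximation.
#' @return data.frame with `coordinate`, `median_wt`, `median_mut`,
#'   `p_value`, `occupancy_class`.
#' @export
positionwise_comparison <- function(wt_tracks, mut_tracks,
                                    config = analysis_config(),
                                    var_equal = TRUE) {
  if (length(wt_tracks) < 2L || length(mut_tracks) < 2L)
    stop("need at least 2 replicates per strain", call. = FALSE)
  X <- do.call(cbind, lapply(wt_tracks, track_values))
  Y <- do.call(cbind, lapply(mut_tracks, track_values))
  if (nrow(X) != nrow(Y))
    stop("strains have different track lengths", call. = FALSE)
  med_wt <- apply(X, 1L, median)
  med_mut <- apply(Y, 1L, median)
  p <- position_t_pvalues(X, Y, var_equal = var_equal)
  cls <- rep("none", nrow(X))
  sig <- !is.na(p) & p < config$alpha
  cls[sig & med_mut > med_wt] <- "increased"
  cls[sig & med_mut < med_wt] <- "decreased"
  data.frame(
    coordinate = seq_len(nrow(X)),
    median_wt = med_wt,
    median_mut = med_mut,
    p_value = p,
    occupancy_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Centered moving average
#'
#' Rolling mean over full windows only: positions lacking a complete window
#' are omitted, so the output has `length(values) - window + 1` entries.
#'
#' @param values numeric vector.
#' @param window window size, `1 <= window <= length(values)`.
#' @return Numeric vector of window means.
#' @export
moving_average <- function(values, window) {
  window <- as.integer(window)
  if (window < 1L || window > length(values))
    stop("window must be between 1 and the track length (", length(values),
         ")", call. = FALSE)
  as.numeric(zoo::rollmean(values, window))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Sup distance between the empirical CDFs of two value sets, with the
#' asymptotic p-value. Used genome-wide on median tracks, on smoothed
#' profiles, and separately per rDNA region.
#'
#' @param values_wt,values_mut non-empty numeric vectors.
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(values_wt, values_mut) {
  if (!length(values_wt) || !length(values_mut))
    stop("empty input to the K-S comparison", call. = FALSE)
  kt <- suppressWarnings(ks.test(values_wt, values_mut, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Per-region K-S tests between two median tracks
#'
#' @param median_wt,median_mut per-position median normalized values.
#' @param locus a `template_locus` supplying the region partition.
#' @return data.frame with `region`, `ks_statistic`, `ks_p_value` in
#'   transcription order.
#' @export
region_ks <- function(median_wt, median_mut, locus) {
  stopifnot(inherits(locus, "template_locus"),
            length(median_wt) == locus$unit_length,
            length(median_mut) == locus$unit_length)
  rows <- lapply(names(locus$region_lengths), function(rg) {
    sel <- locus$region == rg
    kt <- ks_compare(median_wt[sel], median_mut[sel])
    data.frame(region = rg, ks_statistic = kt$statistic,
               ks_p_value = kt$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full WT-versus-mutant comparison
#'
#' Replicate concordance, per-position tests, moving-average profiles with
#' K-S tests, genome-wide and per-region K-S tests — the complete occupancy
#' comparison between two strains.
#'
#' @param wt_tracks,mut_tracks lists of normalized replicate tracks.
#' @param locus a `template_locus`.
#' @param config an [analysis_config()].
#' @param var_equal see [positionwise_comparison()].
#' @return list of class `strain_comparison` with elements `positions`,
#'   `regions`, `genomewide` (K-S on the median tracks), `smoothed` (one
#'   data.frame per usable window: `coordinate` of window center, `wt`,
#'   `mut`, plus attributes `ks`), `concordance` (within-strain Spearman
#'   matrices), and the medians `median_wt`, `median_mut`.
#' @export
compare_strains <- function(wt_tracks, mut_tracks, locus,
                            config = analysis_config(), var_equal = TRUE) {
  positions <- positionwise_comparison(wt_tracks, mut_tracks, config,
                                       var_equal = var_equal)
  med_wt <- positions$median_wt
  med_mut <- positions$median_mut
  u <- length(med_wt)

  usable <- config$windows[config$windows <= u]
  if (length(usable) < length(config$windows))
    message("skipping moving-average window(s) larger than the unit (",
            u, " nt): ",
            paste(setdiff(config$windows, usable), collapse = ", "))
  smoothed <- lapply(usable, function(w) {
    sm_wt <- moving_average(med_wt, w)
    sm_mut <- moving_average(med_mut, w)
    df <- data.frame(
      coordinate = seq_along(sm_wt) + (w - 1) / 2,
      wt = sm_wt, mut = sm_mut
    )
    attr(df, "window") <- w
    attr(df, "ks") <- ks_compare(sm_wt, sm_mut)
    df
  })
  names(smoothed) <- paste0("window_", usable)

  concordance <- function(tracks) {
    n <- length(tracks)
    m <- diag(1, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
      m[i, j] <- m[j, i] <- spearman_concordance(tracks[[i]], tracks[[j]])
    m
  }

  structure(list(
    positions = positions,
    regions = region_ks(med_wt, med_mut, locus),
    genomewide = ks_compare(med_wt, med_mut),
    smoothed = smoothed,
    concordance = list(wt = concordance(wt_tracks),
                       mut = concordance(mut_tracks)),
    median_wt = med_wt,
    median_mut = med_mut,
    alpha = config$alpha
  ), class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  n_inc <- sum(x$positions$occupancy_class == "increased")
  n_dec <- sum(x$positions$occupancy_class == "decreased")
  cat("strain_comparison over", nrow(x$positions), "positions\n")
  cat(sprintf("  increased: %d  decreased: %d (alpha = %g)\n",
              n_inc, n_dec, x$alpha))
  cat(sprintf("  genome-wide K-S: D = %.4f, p = %.3g\n",
              x$genomewide$statistic, x$genomewide$p_value))
  invisible(x)
}
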