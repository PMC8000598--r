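test_that("Spearman concordance matches the ranked-Pearson definition", {
  # self-comparison is exactly 1; reversal of a strictly increasing vector
  # is exactly -1
  x <- c(0.1, 0.4, 0.2, 0.9, 0.3)
  expect_identical(spearman_concordance(x, x), 1)
  inc <- sort(runif(50))
  expect_equal(spearman_concordance(inc, rev(inc)), -1)

  # brute-force oracle: average ranks then Pearson correlation
  brute <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  expect_equal(spearman_concordance(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)),
               brute(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  set.seed(103)
  for (i in 1:100) {
    a <- sample(0:5, 20, replace = TRUE)  # ties exercised
    b <- sample(0:5, 20, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(spearman_concordance(a, b), brute(a, b))
    # symmetry and invariance under strictly monotone transforms
    expect_equal(spearman_concordance(b, a), spearman_concordance(a, b))
    expect_equal(spearman_concordance(exp(a), 3 * b + 1),
                 spearman_concordance(a, b))
  }

  expect_error(spearman_concordance(1:5, 1:4), "length")
  expect_error(spearman_concordance(rep(1, 5), 1:5), "constant")
  expect_error(spearman_concordance(1, 1), "two positions")
})

test_that("per-position p-values match t.test and classes follow alpha", {
  set.seed(104)
  # oracle equivalence against stats::t.test on random instances
  for (i in 1:100) {
    x <- matrix(rnorm(3 * 3, sd = runif(1, 0.5, 2)), 3)
    y <- matrix(rnorm(3 * 3, mean = rnorm(1), sd = runif(1, 0.5, 2)), 3)
    got <- positionwise_comparison(
      split(x, col(x)), split(y, col(y)))
    for (j in 1:3) {
      expect_equal(got$p_value[j],
                   t.test(x[j, ], y[j, ], var.equal = TRUE)$p.value)
    }
  }

  # identical triplicates: nothing is classed
  tr <- runif(50)
  same <- positionwise_comparison(list(tr, tr, tr), list(tr, tr, tr))
  expect_true(all(same$occupancy_class == "none"))
  expect_true(all(is.na(same$p_value)))

  # a 10x shift across replicates is classed increased with p < 0.05
  wt_vals <- c(1e-4, 1.1e-4, 0.9e-4)
  pos <- positionwise_comparison(
    lapply(wt_vals, function(v) c(v, 0.5)),
    lapply(10 * wt_vals, function(v) c(v, 0.5)))
  expect_lt(pos$p_value[1], 0.05)
  expect_equal(pos$occupancy_class[1], "increased")
  ora <- t.test(wt_vals, 10 * wt_vals, var.equal = TRUE)$p.value
  expect_equal(pos$p_value[1], ora)

  # alpha = 1: every position with unequal medians (and any variation)
  # gets classed
  set.seed(105)
  wt <- replicate(3, runif(30), simplify = FALSE)
  mut <- replicate(3, runif(30), simplify = FALSE)
  all_cls <- positionwise_comparison(wt, mut, analysis_config(alpha = 1 - 1e-12))
  med_neq <- apply(do.call(cbind, wt), 1, median) !=
    apply(do.call(cbind, mut), 1, median)
  expect_true(all(all_cls$occupancy_class[med_neq] != "none"))

  expect_error(positionwise_comparison(list(tr), list(tr, tr)), "replicates")
})

test_that("moving averages drop incomplete windows", {
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(3, 10), 4), rep(3, 7))
  v <- rnorm(20)
  expect_equal(moving_average(v, 1), v)
  # brute-force oracle on random instances
  set.seed(106)
  for (i in 1:100) {
    n <- sample(5:30, 1); w <- sample(1:n, 1)
    x <- rnorm(n)
    brute <- vapply(seq_len(n - w + 1), function(j) mean(x[j:(j + w - 1)]),
                    numeric(1))
    expect_equal(moving_average(x, w), brute)
  }
  expect_error(moving_average(1:3, 4), "window")
  expect_error(moving_average(1:3, 0), "window")
})

test_that("K-S comparison equals the brute-force sup distance", {
  same <- ks_compare(1:10, 1:10)
  expect_equal(same$statistic, 0)
  disjoint <- ks_compare(runif(40), runif(40) + 2)
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_value, 1e-6)

  brute_ks <- function(a, b) {
    thr <- sort(unique(c(a, b)))
    max(abs(vapply(thr, function(t) mean(a <= t) - mean(b <= t),
                   numeric(1))))
  }
  set.seed(107)
  for (i in 1:100) {
    a <- round(rnorm(50), 1)  # rounding induces ties
    b <- round(rnorm(50, mean = runif(1, 0, 1)), 1)
    expect_equal(ks_compare(a, b)$statistic, brute_ks(a, b))
  }
  expect_error(ks_compare(numeric(), 1:3), "empty")
})

test_that("compare_strains assembles concordance, K-S tables and profiles", {
  locus <- test_locus()
  # sequence-dependent pausing in both strains gives the heterogeneous
  # occupancy landscape replicate concordance is meant to detect
  params_wt <- strain_params(termination_prob = 5e-4, pause_gc_weight = 1.5)
  params_mut <- strain_params(termination_prob = 3e-3, pause_gc_weight = 1.5)
  wt <- lapply(1:3, function(k)
    sim_track(locus, params_wt, 8000, seed = 200 + k, "wt",
              paste0("rep", k)))
  mut <- lapply(1:3, function(k)
    sim_track(locus, params_mut, 8000, seed = 300 + k, "mut",
              paste0("rep", k)))
  cfg <- analysis_config(windows = c(200))
  cmp <- compare_strains(wt, mut, locus, cfg)

  # replicates of the same strain are strongly rank-concordant
  expect_true(all(diag(cmp$concordance$wt) == 1))
  expect_true(all(cmp$concordance$wt[upper.tri(diag(3))] > 0.25))
  expect_equal(cmp$concordance$wt, t(cmp$concordance$wt))

  # strong processivity defect: genome-wide K-S significant, and the
  # classed positions lean increased at the 5' end, decreased at the 3' end
  expect_lt(cmp$genomewide$p_value, 0.01)
  inc <- cmp$positions$coordinate[cmp$positions$occupancy_class == "increased"]
  dec <- cmp$positions$coordinate[cmp$positions$occupancy_class == "decreased"]
  expect_gt(length(inc), 0)
  expect_gt(length(dec), 0)
  expect_lt(median(inc), median(dec))

  # smoothed profile: mutant above WT early, below late
  sm <- cmp$smoothed$window_200
  expect_equal(nrow(sm), locus$unit_length - 200 + 1)
  expect_gt(mean(head(sm$mut - sm$wt, 50)), 0)
  expect_lt(mean(tail(sm$mut - sm$wt, 50)), 0)

  # per-region table covers the seven regions in transcription order
  expect_equal(cmp$regions$region,
               c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2"))
  # an oversized window is skipped with a message
  expect_message(compare_strains(wt, mut, locus,
                                 analysis_config(windows = c(200, 2000))),
                 "skipping")
})
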