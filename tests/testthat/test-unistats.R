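test_that("rank-sum p-values match exact enumeration on small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  with_seed(5, {
    for (n in 2:8) {
      for (m in 2:8) {
        if (n + m > 12) next  # exact path covers combined n <= 12
        x <- rnorm(n); y <- rnorm(m, mean = 0.5)
        expect_equal(wilcoxon_rank_sum(x, y), enum_rank_sum_p(x, y),
                     tolerance = 1e-12,
                     label = sprintf("rank-sum n=%d m=%d", n, m))
      }
    }
  })
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), ">= 2")
})

test_that("rank-sum approximation tracks the exact value at moderate n", {
  with_seed(6, {
    diffs <- vapply(seq_len(20), function(i) {
      x <- rnorm(10); y <- rnorm(10, mean = 0.8)
      approx_p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      abs(enum_rank_sum_p(x, y) - approx_p)
    }, numeric(1))
    expect_lt(max(diffs), 0.02)
  })
})

test_that("signed-rank p-values match the dynamic-programming oracle", {
  # 6 pairs all shifted by +1: every sign pattern enumerable by hand
  expect_equal(as.numeric(wilcoxon_signed_rank(1:6, 1:6 + 1)), 2 / 64)
  # degenerate: identical pairs
  res <- wilcoxon_signed_rank(1:5, 1:5)
  expect_equal(as.numeric(res), 1)
  expect_true(attr(res, "degenerate"))
  expect_equal(attr(res, "n_zero"), 5L)
  with_seed(7, {
    for (n in 3:8) {
      pre <- rnorm(n); post <- pre + rnorm(n, 0.4)
      p_pkg <- as.numeric(wilcoxon_signed_rank(pre, post))
      expect_equal(p_pkg, dp_signed_rank_p(post - pre),
                   tolerance = 1e-12,
                   label = sprintf("signed-rank n=%d", n))
      # antisymmetry of the two-sided test
      expect_equal(p_pkg, as.numeric(wilcoxon_signed_rank(post, pre)))
    }
    # tied magnitudes still handled exactly via midranks
    pre <- c(1, 2, 3, 4, 5); post <- pre + c(1, 1, -1, 1, 1)
    expect_equal(as.numeric(wilcoxon_signed_rank(pre, post)),
                 dp_signed_rank_p(post - pre))
  })
  # untied small samples also agree with the reference implementation
  with_seed(8, {
    pre <- rnorm(9); post <- pre + rnorm(9, 0.5)
    expect_equal(as.numeric(wilcoxon_signed_rank(pre, post)),
                 stats::wilcox.test(post - pre, exact = TRUE)$p.value)
  })
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 6)), rep(1, 6))
  with_seed(9, {
    for (i in 1:10) {
      p <- runif(15)^2
      adj <- benjamini_hochberg(p)
      expect_equal(adj, bh_by_hand(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      # monotone in raw-p rank
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("-log2 fold change has the documented sign behaviour", {
  expect_equal(as.numeric(neg_log2_fold_change(c(1, 2, 3), c(1, 2, 3))),
               0)
  expect_equal(as.numeric(neg_log2_fold_change(c(2, 4, 6), c(1, 2, 3))),
               -1)
  with_seed(10, {
    a <- rlnorm(9); b <- rlnorm(9)
    expect_equal(as.numeric(neg_log2_fold_change(a, b)),
                 -as.numeric(neg_log2_fold_change(b, a)))
  })
  und <- neg_log2_fold_change(c(0, 0, 0), c(1, 2, 3))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("univariate screening flags the truly shifted metabolites", {
  # concentration-level simulation: 20 metabolites, 3 with a 2-fold
  # group effect, log-normal subject variation
  shifted <- c("lactate", "citrate", "alanine")
  d <- cohort_design(n_subjects_per_group = c(20, 20), paired = FALSE,
                     effect_table = list(LC = setNames(rep(2, 3), shifted)),
                     subject_sd = 0.15, seed = 31)
  coh <- simulate_cohort(d, render_spectra = FALSE)
  res <- univariate_screen(coh$truth, coh$annotation,
                           list(type = "group", levels = c("CRC", "LC")))
  expect_s3_class(res, "univariate_screen")
  expect_setequal(res$metabolite[res$significant], shifted)
  # direction: 2-fold higher in LC (=B) means positive -log2 FC of A/B
  expect_true(all(res$direction[res$significant] == "higher-in-LC"))
  expect_true(all(res$neg_log2_fc[res$significant] > 0))
})

test_that("paired screening uses the signed-rank route", {
  d <- cohort_design(n_subjects_per_group = c(10, 10), paired = TRUE,
                     anesthesia_decrease = 0.7, subject_sd = 0.1,
                     seed = 32)
  coh <- simulate_cohort(d, render_spectra = FALSE)
  res <- univariate_screen(coh$truth, coh$annotation,
                           list(type = "paired"))
  expect_true(all(res$test == "signed-rank"))
  # a uniform 0.7x post decrease is detected nearly everywhere
  expect_gt(mean(res$significant), 0.9)
  expect_true(all(res$direction[res$significant] == "higher-in-pre"))
  expect_error(univariate_screen(coh$truth, coh$annotation,
                                 list(type = "nope")), "contrast")
})

test_that("a single-metabolite family leaves p unadjusted", {
  d <- cohort_design(n_subjects_per_group = c(6, 6), paired = FALSE,
                     seed = 33)
  coh <- simulate_cohort(d, render_spectra = FALSE)
  one <- coh$truth[, "lactate", drop = FALSE]
  res <- univariate_screen(one, coh$annotation,
                           list(type = "group", levels = c("CRC", "LC")))
  expect_equal(res$adjusted_p, res$p_value)
})

test_that("quantification of rendered spectra matches concentration truth", {
  shifted <- c("formate", "histidine")  # isolated, resolved signals
  d <- quick_design(n_subjects_per_group = c(6, 6), paired = FALSE,
                    effect_table = list(LC = setNames(c(2, 0.5), shifted)),
                    subject_sd = 0, noise_sd = 0, seed = 34,
                    include_macromolecules = FALSE, include_water = FALSE,
                    include_ficoll = FALSE, axis_points = 8192)
  coh <- simulate_cohort(d)
  met <- quantify_metabolites(coh$spectra, coh$regions,
                              normalize = FALSE)
  grp <- coh$annotation$group
  for (m in shifted) {
    ratio <- median(met[grp == "LC", m]) / median(met[grp == "CRC", m])
    truth_ratio <- median(coh$truth[grp == "LC", m]) /
      median(coh$truth[grp == "CRC", m])
    expect_equal(ratio, truth_ratio, tolerance = 0.01)
  }
})
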