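make_two_class <- function(n_per = 10, p = 40, delta = 2, sd = 0.3,
                           seed = 1) {
  with_seed(seed, {
    x <- matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p,
                dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
    x[seq_len(n_per), 1:3] <- x[seq_len(n_per), 1:3] + delta
    list(x = x, labels = rep(c("A", "B"), each = n_per))
  })
}

test_that("PCA finds a dominant direction and centres scores", {
  with_seed(4, {
    base <- rnorm(30)
    x <- outer(base, rnorm(15)) + matrix(rnorm(450, sd = 1e-3), 30, 15)
  })
  fit <- pca_fit(x, n_components = 3)
  expect_gt(fit$explained_variance[1] / fit$total_variance, 0.99)
  expect_lte(sum(fit$explained_variance), fit$total_variance + 1e-8)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  expect_error(pca_fit(x, n_components = 40), "1\\.\\.")
})

test_that("PLS-CA separates well-separated classes and predicts consistently", {
  dat <- make_two_class(delta = 3, sd = 0.2)
  fit <- plsca(dat$x, dat$labels, ncomp = 2)
  expect_s3_class(fit, "plsca")
  expect_equal(as.character(fit$fitted), dat$labels)
  # a duplicate of a training sample predicts its own class
  expect_equal(as.character(predict(fit, dat$x[3, , drop = FALSE])),
               "A")
  # informative variables dominate the canonical loadings
  imp <- abs(coef(fit)[, 1])
  expect_true(all(rank(-imp)[1:3] <= 5))
  expect_error(plsca(dat$x, rep("A", 20)), "two classes")
})

test_that("inner cross-validation picks a workable component count", {
  dat <- make_two_class(n_per = 12, delta = 2.5, sd = 0.3, seed = 19)
  fit <- with_seed(20, plsca(dat$x, dat$labels))  # ncomp = NULL
  expect_gte(fit$ncomp, 1L)
  expect_lte(fit$ncomp, 10L)
  expect_gte(mean(as.character(fit$fitted) == dat$labels), 0.95)
})

test_that("PLS-CA agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  dat <- make_two_class(n_per = 12, delta = 1.5, sd = 0.5, seed = 6)
  fit <- plsca(dat$x, dat$labels, ncomp = 2)
  ref <- mixOmics::plsda(dat$x, factor(dat$labels), ncomp = 2,
                         scale = FALSE)
  # latent subspaces match: first scores correlate to |r| ~ 1
  r <- abs(cor(fit$scores[, 1], ref$variates$X[, 1]))
  expect_gt(r, 0.99)
  ref_pred <- predict(ref, dat$x)$class$max.dist[, 2]
  expect_gte(mean(as.character(fit$fitted) == ref_pred), 0.9)
})

test_that("permuted labels give chance-level canonical separation", {
  dat <- make_two_class(n_per = 10, delta = 0, sd = 1, seed = 8)
  # resubstitution on noise overfits, so the discriminative signal is
  # judged by the canonical eigenvalue against a strong real effect
  strong <- plsca(make_two_class(delta = 3, sd = 0.2)$x,
                  dat$labels, ncomp = 2)
  weak_eig <- median(vapply(seq_len(20), function(i) {
    with_seed(100 + i, {
      lab <- sample(dat$labels)
      plsca(dat$x, lab, ncomp = 2)$canonical$eigenvalues[1]
    })
  }, numeric(1)))
  expect_lt(weak_eig, strong$canonical$eigenvalues[1])
})

test_that("multilevel split obeys its exact algebra", {
  with_seed(3, {
    p <- 12; s <- 6
    pre <- matrix(rnorm(s * p), s, p)
    d <- rnorm(p)
    post <- pre + matrix(d, s, p, byrow = TRUE)
  })
  x <- rbind(pre, post)
  ann <- data.frame(subject_id = rep(sprintf("S%d", 1:s), 2),
                    timepoint = rep(c("pre", "post"), each = s))
  ml <- multilevel_split(x, ann)
  # uniform paired shift: within rows are exactly -d/2 (pre) and +d/2
  expect_equal(ml$within[1:s, ], matrix(-d / 2, s, p, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ml$within[(s + 1):(2 * s), ],
               matrix(d / 2, s, p, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # reconstruction: subject mean + within row = original row
  rebuilt <- ml$between[as.integer(factor(ann$subject_id)), ] + ml$within
  expect_lt(max(abs(rebuilt - x)), 1e-12)
  # identical pre/post: within part is all zeros
  ml0 <- multilevel_split(rbind(pre, pre), ann)
  expect_true(all(ml0$within == 0))
  # adding a constant profile to one subject's pair leaves within unchanged
  x2 <- x; x2[c(1, s + 1), ] <- x2[c(1, s + 1), ] + 5
  expect_equal(multilevel_split(x2, ann)$within, ml$within)
  # unpaired subject is named in the error
  expect_error(multilevel_split(x[-1, ], ann[-1, ]),
               class = "pairing_error")
  expect_error(multilevel_split(x[-1, ], ann[-1, ]), "S1")
})

test_that("MPLS classifies a uniform paired shift perfectly and flips with labels", {
  with_seed(13, {
    p <- 20; s <- 8
    pre <- matrix(rnorm(s * p), s, p)
    d <- rnorm(p)
    post <- pre + matrix(d, s, p, byrow = TRUE)
  })
  x <- rbind(pre, post)
  ann <- data.frame(subject_id = rep(sprintf("S%d", 1:s), 2),
                    timepoint = rep(c("pre", "post"), each = s))
  fit <- mpls(x, ann, ncomp = 1)
  expect_equal(as.character(fit$fitted), ann$timepoint)
  # swapping pre/post labels flips the canonical scores' sign pattern
  ann_swap <- ann
  ann_swap$timepoint <- ifelse(ann$timepoint == "pre", "post", "pre")
  fit_swap <- mpls(x, ann_swap, ncomp = 1)
  agree <- sign(fit$canonical_scores[, 1] * fit_swap$canonical_scores[, 1])
  expect_true(all(agree == agree[1]))
  expect_equal(as.character(fit_swap$fitted), ann_swap$timepoint)
})

test_that("Monte-Carlo CV books test counts correctly and respects stratification", {
  dat <- make_two_class(n_per = 10, delta = 3, sd = 0.2)
  cv <- monte_carlo_cv(dat$x, dat$labels, n_iterations = 40,
                       test_fraction = 0.2, ncomp = 2, seed = 21)
  expect_equal(sum(cv$confusion), 40 * 4)  # 2 per class per iteration
  expect_gte(cv$accuracy, 99)
  expect_error(monte_carlo_cv(dat$x, dat$labels, test_fraction = 1.2),
               "test_fraction")
  few <- c(1:3, 11:12)  # 3 of class A, 2 of class B
  expect_error(monte_carlo_cv(dat$x[few, ], dat$labels[few],
                              test_fraction = 0.4),
               "too few")
  # determinism under the seed
  cv2 <- monte_carlo_cv(dat$x, dat$labels, n_iterations = 40,
                        test_fraction = 0.2, ncomp = 2, seed = 21)
  expect_identical(cv$confusion, cv2$confusion)
})

test_that("subject-level CV never lets a pair straddle the split", {
  # with a within-subject shift plus huge between-subject offsets,
  # subject-level resampling still classifies perfectly at noise 0;
  # row-level leakage would not be needed for that
  with_seed(17, {
    p <- 15; s <- 10
    pre <- matrix(rnorm(s * p, sd = 5), s, p)  # big between-subject var
    d <- rnorm(p)
    post <- pre + matrix(d, s, p, byrow = TRUE)
  })
  x <- rbind(pre, post)
  ann <- data.frame(subject_id = rep(sprintf("S%d", 1:s), 2),
                    timepoint = rep(c("pre", "post"), each = s))
  cv <- monte_carlo_cv(x, ann, model_kind = "mpls", n_iterations = 30,
                       test_fraction = 0.2, ncomp = 1, seed = 3)
  expect_equal(cv$accuracy, 100)
  expect_equal(sum(cv$confusion), 30 * 2 * 2)  # 2 subjects x 2 rows
})

test_that("classification rates follow their standard definitions", {
  cm <- function(tp, fn, fp, tn) {
    matrix(c(tp, fp, fn, tn), 2, 2,
           dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  }
  expect_equal(unname(report_rates(cm(10, 0, 0, 10))), c(100, 100, 100))
  expect_equal(unname(report_rates(cm(5, 5, 5, 5))), c(50, 50, 50))
  expect_equal(unname(report_rates(cm(8, 2, 4, 6))), c(70, 80, 60))
  # positive-class convention is explicit and configurable
  expect_equal(report_rates(cm(8, 2, 4, 6), positive = "B")[["sensitivity"]],
               60)
  # zero denominator reports undefined, not zero
  degenerate <- matrix(c(0, 5, 0, 5), 2, 2,
                       dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(is.na(report_rates(degenerate)[["sensitivity"]]))
  expect_error(report_rates(matrix(0, 2, 2)), "positive total")
})
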