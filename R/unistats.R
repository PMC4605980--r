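#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with
#' midranks, tie correction and continuity correction.
#'
#' @param x,y numeric observations, each of length >= 2.
#' @return two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  min(1, p)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Tests within-pair differences; zero differences are dropped (the
#' classic Wilcoxon convention) and their count is reported in the
#' `"n_zero"` attribute. If every difference is zero the result is
#' degenerate with p = 1. With at most 12 nonzero differences the
#' p-value is computed by exact enumeration of all sign patterns
#' (midranks for tied magnitudes, so small tied samples are handled
#' exactly rather than approximated); larger samples use the normal
#' approximation with tie correction.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @return two-sided p-value with attributes `n_zero` and `degenerate`.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 1)
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  d <- post - pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) < 2L) {
    return(structure(1, n_zero = n_zero, degenerate = TRUE))
  }
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= 12L) {
    # enumerate all 2^n equally likely sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  } else {
    mu <- n * (n + 1) / 4
    tie <- tabulate(factor(r))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie^3 - tie) / 48
    z <- (abs(v_obs - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
  }
  structure(p, n_zero = n_zero, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the
#' i-th smallest p is `min over j >= i of p_(j) * m / j`, capped at 1,
#' returned in the input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) ||
      any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed -log2 fold change of group medians
#'
#' Computes `-log2(median(a) / median(b))`: zero for equal medians,
#' negative when group A's median exceeds group B's, and exactly
#' antisymmetric under swapping the groups. Non-positive medians make
#' the fold change undefined (`NA` with attribute `undefined = TRUE`).
#'
#' @param group_a,group_b numeric vectors of (normalized) intensities.
#' @return the signed value, or `NA` when undefined.
#' @export
neg_log2_fold_change <- function(group_a, group_b) {
  ma <- stats::median(group_a)
  mb <- stats::median(group_b)
  if (!is.finite(ma) || !is.finite(mb) || ma <= 0 || mb <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log2(ma / mb)
}

#' Quantify metabolites from spectra by signal integration
#'
#' Integrates each metabolite's region in every spectrum and (by
#' default) normalizes each sample's areas by the total integral of the
#' spectrum's retained (non-excluded) range, giving relative
#' concentrations comparable across samples.
#'
#' @param spectra list of `nmr_spectrum`.
#' @param regions data.frame with columns `metabolite`, `low`, `high`
#'   (e.g. from [quantification_regions()]).
#' @param normalize divide by the total retained-area per sample.
#' @param low,high,excluded_ranges definition of the retained range used
#'   for normalization.
#' @return samples x metabolites numeric matrix (a metabolite table).
#' @export
quantify_metabolites <- function(spectra, regions, normalize = TRUE,
                                 low = 0.20, high = 10.00,
                                 excluded_ranges = list(c(3.30, 6.00))) {
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  stopifnot(is.data.frame(regions),
            all(c("metabolite", "low", "high") %in% names(regions)))
  out <- t(vapply(spectra, function(sp) {
    areas <- mapply(function(lo, hi) integrate_signal(sp, c(lo, hi)),
                    regions$low, regions$high)
    if (normalize) {
      b <- exclude_regions(bucket(sp, low = low, high = high,
                                  width = 0.02), excluded_ranges)
      total <- sum(b$values)
      if (total <= 0) stop("non-positive total retained area",
                           call. = FALSE)
      areas <- areas / total
    }
    areas
  }, numeric(nrow(regions))))
  colnames(out) <- regions$metabolite
  rownames(out) <- vapply(spectra, `[[`, character(1), "sample_id")
  out
}

#' Univariate metabolite screening
#'
#' Runs, per metabolite, the Wilcoxon rank-sum test (unpaired group
#' contrast) or the signed-rank test on within-subject pre/post
#' differences (paired contrast), adjusts the whole family by
#' Benjamini-Hochberg, and reports the signed -log2 fold change of group
#' medians with a plain-language direction. Significance is called on
#' the adjusted p-value at `alpha` (default 0.05); the raw p is reported
#' alongside.
#'
#' The fold-change sign convention: `neg_log2_fc = -log2(median_A /
#' median_B)`, where groups A and B are named in the `contrast_a` /
#' `contrast_b` attributes of the result — negative values mean the
#' metabolite is higher in A.
#'
#' @param table samples x metabolites matrix (e.g. from
#'   [quantify_metabolites()]), rows aligned with `annotation`.
#' @param annotation data.frame carrying the contrast columns.
#' @param contrast either `list(type = "group", column = "group",
#'   levels = c("CRC", "LC"))` for an unpaired two-group comparison
#'   (optionally with `timepoint` to subset), or `list(type = "paired")`
#'   for the pre/post contrast within subjects.
#' @param alpha adjusted-p significance threshold.
#' @return a data.frame of class `univariate_screen` with one row per
#'   metabolite: `metabolite`, `test`, `p_value`, `adjusted_p`,
#'   `neg_log2_fc`, `direction`, `significant`, `n_a`, `n_b`.
#' @export
univariate_screen <- function(table, annotation, contrast,
                              alpha = 0.05) {
  table <- as.matrix(table)
  stopifnot(is.data.frame(annotation), nrow(table) == nrow(annotation))
  if (!is.list(contrast) || is.null(contrast$type) ||
      !contrast$type %in% c("group", "paired")) {
    stop("`contrast` must be list(type = 'group', ...) or list(type = 'paired')",
         call. = FALSE)
  }
  mets <- colnames(table)
  if (contrast$type == "group") {
    column <- if (is.null(contrast$column)) "group" else contrast$column
    if (!column %in% names(annotation)) {
      stop("unknown contrast column: ", column, call. = FALSE)
    }
    keep <- rep(TRUE, nrow(annotation))
    if (!is.null(contrast$timepoint)) {
      keep <- annotation$timepoint == contrast$timepoint
    }
    lv <- if (is.null(contrast$levels))
      sort(unique(annotation[[column]][keep])) else contrast$levels
    if (length(lv) != 2L) {
      stop("group contrasts need exactly two levels", call. = FALSE)
    }
    ia <- keep & annotation[[column]] == lv[1]
    ib <- keep & annotation[[column]] == lv[2]
    res <- lapply(mets, function(m) {
      a <- table[ia, m]; b <- table[ib, m]
      data.frame(metabolite = m, test = "rank-sum",
                 p_value = wilcoxon_rank_sum(a, b),
                 neg_log2_fc = as.numeric(neg_log2_fold_change(a, b)),
                 n_a = sum(ia), n_b = sum(ib),
                 stringsAsFactors = FALSE)
    })
    name_a <- lv[1]; name_b <- lv[2]
  } else {
    ml_ok <- all(c("subject_id", "timepoint") %in% names(annotation))
    if (!ml_ok) stop("paired contrast needs subject_id and timepoint",
                     call. = FALSE)
    pre <- annotation$timepoint == "pre"
    post <- annotation$timepoint == "post"
    ord_pre <- order(annotation$subject_id[pre])
    ord_post <- order(annotation$subject_id[post])
    if (!identical(sort(annotation$subject_id[pre]),
                   sort(annotation$subject_id[post]))) {
      stop(errorCondition("pre and post subjects do not pair up",
                          class = c("pairing_error", "error",
                                    "condition")))
    }
    res <- lapply(mets, function(m) {
      a <- table[pre, m][ord_pre]    # pre, subject-aligned
      b <- table[post, m][ord_post]  # post
      data.frame(metabolite = m, test = "signed-rank",
                 p_value = as.numeric(wilcoxon_signed_rank(a, b)),
                 neg_log2_fc = as.numeric(neg_log2_fold_change(a, b)),
                 n_a = sum(pre), n_b = sum(post),
                 stringsAsFactors = FALSE)
    })
    name_a <- "pre"; name_b <- "post"
  }
  out <- do.call(rbind, res)
  out$adjusted_p <- benjamini_hochberg(out$p_value)
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < alpha
  out$direction <- ifelse(is.na(out$neg_log2_fc), "undefined",
                   ifelse(out$neg_log2_fc < 0,
                          paste0("higher-in-", name_a),
                   ifelse(out$neg_log2_fc > 0,
                          paste0("higher-in-", name_b), "unchanged")))
  out <- out[, c("metabolite", "test", "p_value", "adjusted_p",
                 "neg_log2_fc", "direction", "significant",
                 "n_a", "n_b")]
  attr(out, "contrast_a") <- name_a
  attr(out, "contrast_b") <- name_b
  attr(out, "alpha") <- alpha
  class(out) <- c("univariate_screen", "data.frame")
  out
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat(sprintf(
    "Univariate screen: %s vs %s, %d metabolites, %d significant (BH-adjusted p < %.2g)\n",
    attr(x, "contrast_a"), attr(x, "contrast_b"), nrow(x),
    sum(x$significant), attr(x, "alpha")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
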