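#' Principal component analysis of a bucket matrix
#'
#' Mean-centred PCA (no unit-variance scaling, the convention for
#' total-area-normalized bucket data), used as a first unsupervised look
#' at a cohort.
#'
#' @param x a `bucket_matrix` or numeric matrix (samples x bins).
#' @param n_components number of components
#'   (<= `min(samples - 1, bins)`).
#' @return a list of class `nmr_pca`: `scores`, `loadings`,
#'   `explained_variance` (per component), `total_variance`, `center`.
#' @export
pca_fit <- function(x, n_components = 2) {
  x <- as_matrix_values(x)
  maxc <- min(nrow(x) - 1L, ncol(x))
  if (!is.numeric(n_components) || n_components < 1 ||
      n_components > maxc) {
    stop(sprintf("`n_components` must be in 1..%d", maxc), call. = FALSE)
  }
  n_components <- as.integer(n_components)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(scores = pr$x[, seq_len(n_components), drop = FALSE],
                 loadings = pr$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 explained_variance = pr$sdev[seq_len(n_components)]^2,
                 total_variance = sum(pr$sdev^2),
                 center = pr$center),
            class = "nmr_pca")
}

as_matrix_values <- function(x) {
  if (inherits(x, "bucket_matrix")) x <- x$values
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# NIPALS PLS2 against centred one-hot class response. Returns x-weights
# W, x-loadings P, y-loadings Q, scores T and the centring vector; the
# components are nested, so a fit at A components contains every smaller
# fit.
fit_pls <- function(X, Y, ncomp, tol = 1e-10, max_iter = 200) {
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, ncol(Yc), ncomp); Tm <- matrix(0, n, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    if (sum(u^2) < tol) break
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    if (sqrt(sum(w^2)) < tol || sum(tt^2) < tol) break
    pl <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tt
    a_used <- a
  }
  if (a_used == 0L) stop("PLS found no usable component", call. = FALSE)
  keep <- seq_len(a_used)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE], scores = Tm[, keep, drop = FALSE],
       x_mean = x_mean, ncomp = a_used)
}

pls_rotation <- function(fit, a = fit$ncomp) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W))
}

# Fisher canonical discriminant on a low-dimensional score space.
# Directions are scaled so the pooled within-class covariance becomes the
# identity, making nearest-class-mean in canonical coordinates the
# Mahalanobis rule.
fit_canonical <- function(scores, labels, ridge = 1e-8) {
  labels <- factor(labels)
  k <- nlevels(labels)
  d <- ncol(scores)
  mu <- rowsum(scores, labels) / as.vector(table(labels))
  Sw <- matrix(0, d, d)
  for (lv in levels(labels)) {
    sc <- scores[labels == lv, , drop = FALSE]
    cc <- sweep(sc, 2, mu[lv, ])
    Sw <- Sw + crossprod(cc)
  }
  Sw <- Sw / max(1L, nrow(scores) - k)
  Sw <- Sw + diag(ridge * (1 + mean(diag(Sw))), d)
  grand <- colMeans(scores)
  Sb <- matrix(0, d, d)
  for (lv in levels(labels)) {
    dm <- mu[lv, ] - grand
    Sb <- Sb + sum(labels == lv) * tcrossprod(dm)
  }
  es <- eigen(Sw, symmetric = TRUE)
  inv_sqrt <- es$vectors %*% diag(1 / sqrt(pmax(es$values, ridge)),
                                  d) %*% t(es$vectors)
  M <- inv_sqrt %*% Sb %*% inv_sqrt
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ncan <- min(k - 1L, d)
  V <- inv_sqrt %*% em$vectors[, seq_len(ncan), drop = FALSE]
  Z <- scores %*% V
  class_means <- rowsum(Z, labels) / as.vector(table(labels))
  list(V = V, class_means = class_means, levels = levels(labels),
       eigenvalues = em$values[seq_len(ncan)])
}

canonical_classify <- function(Z, class_means, levels) {
  d2 <- vapply(seq_len(nrow(class_means)), function(i) {
    rowSums(sweep(Z, 2, class_means[i, ])^2)
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1L) d2 <- matrix(d2, nrow = 1L)
  factor(levels[max.col(-d2, ties.method = "first")], levels = levels)
}

#' PLS with canonical discriminant analysis
#'
#' Fits partial least squares against the one-hot class response
#' (NIPALS, mean-centred columns, no unit-variance scaling), then a
#' Fisher linear discriminant on the latent scores; new samples are
#' classified to the nearest class mean in canonical space. When `ncomp`
#' is `NULL` the number of latent components is chosen by stratified
#' 5-fold cross-validation over `1:max_ncomp` inside the training data
#' (smallest component count on ties), which avoids the optimism of
#' fixing it after the fact.
#'
#' @param x a `bucket_matrix` or numeric matrix (samples x variables).
#' @param labels class labels (factor or character), >= 2 classes with
#'   >= 2 samples each.
#' @param ncomp number of PLS components, or `NULL` to select by inner
#'   cross-validation.
#' @param max_ncomp upper bound for component selection.
#' @return an object of class `plsca` with, among others, `scores`
#'   (PLS), `canonical_scores`, `class_means`, `ncomp` and the fitted
#'   training labels.
#' @seealso [predict.plsca()], [monte_carlo_cv()]
#' @export
plsca <- function(x, labels, ncomp = NULL, max_ncomp = 10) {
  X <- as_matrix_values(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("need at least two classes", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("need at least two samples per class", call. = FALSE)
  }
  if (length(labels) != nrow(X)) {
    stop("`labels` length must match rows of `x`", call. = FALSE)
  }
  cap <- max(1L, min(nrow(X) - 2L, ncol(X)))
  if (is.null(ncomp)) {
    ncomp <- select_ncomp(X, labels, max_ncomp = min(max_ncomp, cap))
  }
  ncomp <- min(as.integer(ncomp), cap)
  Y <- stats::model.matrix(~ labels - 1)
  fit <- fit_pls(X, Y, ncomp)
  can <- fit_canonical(fit$scores, labels)
  obj <- structure(list(
    x_mean = fit$x_mean, W = fit$W, P = fit$P, Q = fit$Q,
    rotation = pls_rotation(fit), scores = fit$scores,
    canonical = can,
    canonical_scores = fit$scores %*% can$V,
    class_means = can$class_means, levels = can$levels,
    labels = labels, ncomp = fit$ncomp,
    variable_names = colnames(X)), class = "plsca")
  obj$fitted <- predict(obj, X)
  obj
}

# inner stratified k-fold selection of the component count; one PLS fit
# per fold at the maximum, truncated fits evaluated from it (components
# are nested)
select_ncomp <- function(X, labels, max_ncomp, folds = 5L) {
  labels <- factor(labels)
  folds <- min(folds, min(table(labels)))
  if (folds < 2L) return(min(2L, max_ncomp))
  fold_id <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(
      length(idx))]
  }
  correct <- numeric(max_ncomp)
  total <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (any(table(labels[tr]) < 2L) || nlevels(droplevels(labels[tr])) <
        nlevels(labels)) next
    cap <- max(1L, min(sum(tr) - 2L, ncol(X)))
    amax <- min(max_ncomp, cap)
    Y <- stats::model.matrix(~ lab - 1,
                             data = data.frame(lab = labels[tr]))
    fit <- fit_pls(X[tr, , drop = FALSE], Y, amax)
    Xv <- sweep(X[!tr, , drop = FALSE], 2, fit$x_mean)
    total <- total + sum(!tr)
    for (a in seq_len(min(amax, fit$ncomp))) {
      R <- pls_rotation(fit, a)
      Ttr <- fit$scores[, seq_len(a), drop = FALSE]
      can <- fit_canonical(Ttr, labels[tr])
      pred <- canonical_classify(Xv %*% R %*% can$V, can$class_means,
                                 can$levels)
      correct[a] <- correct[a] + sum(pred == labels[!tr])
    }
  }
  if (total == 0L) return(min(2L, max_ncomp))
  which.max(correct)  # first (smallest) maximum wins ties
}

#' Predict method for PLS-CA models
#'
#' @param object a fitted [plsca()] model.
#' @param newdata matrix or `bucket_matrix` with the training variables.
#' @param type `"class"` for predicted labels, `"scores"` for PLS
#'   scores, `"canonical"` for canonical coordinates.
#' @param ... unused.
#' @return a factor of predicted classes, or a score matrix.
#' @export
predict.plsca <- function(object, newdata,
                          type = c("class", "scores", "canonical"),
                          ...) {
  type <- match.arg(type)
  X <- as_matrix_values(newdata)
  Xc <- sweep(X, 2, object$x_mean)
  Tn <- Xc %*% object$rotation
  if (type == "scores") return(Tn)
  Z <- Tn %*% object$canonical$V
  if (type == "canonical") return(Z)
  canonical_classify(Z, object$class_means, object$levels)
}

#' @export
print.plsca <- function(x, ...) {
  cat(sprintf("<plsca> %d components, classes: %s (n = %s)\n",
              x$ncomp, paste(x$levels, collapse = "/"),
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' @export
summary.plsca <- function(object, ...) {
  cm <- table(true = object$labels, predicted = object$fitted)
  cat(sprintf("PLS-CA model: %d latent components, %d variables\n",
              object$ncomp, length(object$x_mean)))
  cat("Resubstitution confusion matrix:\n")
  print(cm)
  cat(sprintf("Resubstitution accuracy: %.1f%%\n",
              100 * sum(diag(cm)) / sum(cm)))
  invisible(object)
}

#' Canonical loadings of a PLS-CA model
#'
#' Maps the canonical discriminant directions back to the original
#' variables (bins), giving one loading column per canonical dimension;
#' large absolute loadings mark the variables that drive the class
#' separation.
#'
#' @param object a fitted `plsca`.
#' @param ... unused.
#' @return variables x (classes - 1) matrix.
#' @export
coef.plsca <- function(object, ...) {
  out <- object$rotation %*% object$canonical$V
  rownames(out) <- object$variable_names
  out
}

#' @export
plot.plsca <- function(x, ...) {
  Z <- x$canonical_scores
  if (ncol(Z) == 1L) {
    graphics::stripchart(Z[, 1] ~ x$labels, vertical = TRUE,
                         method = "jitter", pch = 19,
                         ylab = "Canonical score", ...)
  } else {
    graphics::plot(Z[, 1], Z[, 2], col = as.integer(x$labels), pch = 19,
                   xlab = "Canonical 1", ylab = "Canonical 2", ...)
    graphics::legend("topright", legend = x$levels,
                     col = seq_along(x$levels), pch = 19, bty = "n")
  }
  invisible(x)
}

#' Split paired data into between- and within-subject parts
#'
#' For a paired pre/post design, subtracts each subject's mean profile
#' from that subject's rows (within part) and collects the subject means
#' (between part). The two rows of a subject in the within part are
#' exact negatives of each other, and subject mean + within row
#' reconstructs the original row exactly — the decomposition underlying
#' multilevel PLS, which removes between-subject variation so only
#' treatment-related within-subject changes remain.
#'
#' @param x `bucket_matrix` or matrix, rows aligned with `annotation`.
#' @param annotation data.frame with `subject_id` and `timepoint`
#'   columns (`pre`/`post`).
#' @return list with `within` (same shape as `x`), `between` (one row
#'   per subject), `subject_id`, `timepoint`.
#' @export
multilevel_split <- function(x, annotation) {
  X <- as_matrix_values(x)
  stopifnot(is.data.frame(annotation),
            all(c("subject_id", "timepoint") %in% names(annotation)))
  if (nrow(X) != nrow(annotation)) {
    stop("`x` rows must align with `annotation` rows", call. = FALSE)
  }
  tab <- table(annotation$subject_id, annotation$timepoint)
  bad <- rownames(tab)[!(rowSums(tab) == 2L &
                           apply(tab, 1, function(r) all(r <= 1L)))]
  need <- c("pre", "post")
  if (!all(need %in% colnames(tab))) {
    bad <- unique(c(bad, rownames(tab)))
  } else {
    bad <- unique(c(bad, rownames(tab)[tab[, "pre"] != 1L |
                                         tab[, "post"] != 1L]))
  }
  if (length(bad)) {
    stop(errorCondition(
      paste0("subjects without exactly one pre and one post sample: ",
             paste(bad, collapse = ", ")),
      class = c("pairing_error", "error", "condition")))
  }
  subj <- factor(annotation$subject_id)
  means <- rowsum(X, subj) / as.vector(table(subj))
  within <- X - means[as.integer(subj), , drop = FALSE]
  rownames(within) <- rownames(X)
  list(within = within, between = means,
       subject_id = annotation$subject_id,
       timepoint = annotation$timepoint)
}

#' Multilevel PLS for paired designs
#'
#' Applies [multilevel_split()] and fits a PLS-CA model on the
#' within-subject part with the timepoint as the class, capturing the
#' systematic pre-to-post change common across subjects.
#'
#' @inheritParams multilevel_split
#' @inheritParams plsca
#' @return an object of class `c("mpls", "plsca")`.
#' @export
mpls <- function(x, annotation, ncomp = NULL, max_ncomp = 10) {
  ml <- multilevel_split(x, annotation)
  obj <- plsca(ml$within, ml$timepoint, ncomp = ncomp,
               max_ncomp = max_ncomp)
  obj$multilevel <- ml
  class(obj) <- c("mpls", class(obj))
  obj
}

#' Classification rates from a 2x2 confusion matrix
#'
#' @param cm square confusion matrix, rows = true, columns = predicted,
#'   with matching label order.
#' @param positive label treated as positive for
#'   sensitivity/specificity; default the lexicographically first.
#' @return named vector `accuracy`, `sensitivity`, `specificity` in
#'   percent; a rate with zero denominator is `NA` (undefined), never 0.
#' @examples
#' report_rates(matrix(c(8, 4, 2, 6), 2, 2,
#'              dimnames = list(c("A", "B"), c("A", "B"))))
#' @export
report_rates <- function(cm, positive = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) <= 0) {
    stop("`cm` must be a square confusion matrix with positive total",
         call. = FALSE)
  }
  acc <- 100 * sum(diag(cm)) / sum(cm)
  if (nrow(cm) != 2L) {
    return(c(accuracy = acc, sensitivity = NA_real_,
             specificity = NA_real_))
  }
  labs <- rownames(cm)
  if (is.null(positive)) positive <- sort(labs)[1]
  if (!positive %in% labs) stop("unknown positive label", call. = FALSE)
  neg <- setdiff(labs, positive)
  tp <- cm[positive, positive]; fn <- cm[positive, neg]
  fp <- cm[neg, positive]; tn <- cm[neg, neg]
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Monte-Carlo cross-validation of a classifier
#'
#' Repeats random stratified train/test splits, refits the model on each
#' training set and pools test-set predictions into one confusion
#' matrix. For `"pls-ca"` the split is stratified by class; for
#' `"mpls"` the resampling unit is the subject, so a subject's pre/post
#' pair never straddles the train/test boundary, and the model is
#' refitted on the training subjects' within-part only.
#'
#' @param x `bucket_matrix` or matrix.
#' @param y class labels (for `"pls-ca"`) or an annotation data.frame
#'   with `subject_id` and `timepoint` (for `"mpls"`).
#' @param model_kind `"pls-ca"` or `"mpls"`.
#' @param n_iterations number of random splits (default 500).
#' @param test_fraction fraction held out per split, in (0, 1); default
#'   0.1.
#' @param ncomp fixed component count, or `NULL` for inner-CV selection
#'   within every training split.
#' @param positive positive-class label for the rate report.
#' @param seed RNG seed; the report is fully reproducible from it.
#' @return an object of class `cv_report`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity` (percent), `n_iterations`,
#'   `test_fraction`, `positive`, `seed`.
#' @export
monte_carlo_cv <- function(x, y, model_kind = c("pls-ca", "mpls"),
                           n_iterations = 500, test_fraction = 0.1,
                           ncomp = NULL, positive = NULL, seed = 1) {
  model_kind <- match.arg(model_kind)
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  X <- as_matrix_values(x)
  with_seed(seed, {
    if (model_kind == "pls-ca") {
      labels <- factor(y)
      lv <- levels(labels)
      idx_by_class <- lapply(lv, function(l) which(labels == l))
      n_test <- vapply(idx_by_class, function(ix) {
        max(1L, as.integer(round(test_fraction * length(ix))))
      }, integer(1))
      if (any(lengths(idx_by_class) - n_test < 2L)) {
        stop("too few samples per class for this test fraction",
             call. = FALSE)
      }
      confusion <- matrix(0L, length(lv), length(lv),
                          dimnames = list(true = lv, predicted = lv))
      for (it in seq_len(n_iterations)) {
        test <- unlist(mapply(function(ix, k) ix[sample.int(length(ix),
                                                            k)],
                              idx_by_class, n_test, SIMPLIFY = FALSE))
        train <- setdiff(seq_along(labels), test)
        fit <- plsca(X[train, , drop = FALSE], labels[train],
                     ncomp = ncomp)
        pred <- predict(fit, X[test, , drop = FALSE])
        confusion <- confusion + table(factor(labels[test], levels = lv),
                                       factor(pred, levels = lv))
      }
    } else {
      annotation <- y
      ml <- multilevel_split(X, annotation)  # validates pairing up front
      subjects <- unique(annotation$subject_id)
      n_test <- max(1L, as.integer(round(test_fraction *
                                           length(subjects))))
      if (length(subjects) - n_test < 2L) {
        stop("too few subjects for this test fraction", call. = FALSE)
      }
      lv <- sort(unique(as.character(annotation$timepoint)))
      confusion <- matrix(0L, length(lv), length(lv),
                          dimnames = list(true = lv, predicted = lv))
      for (it in seq_len(n_iterations)) {
        test_sub <- subjects[sample.int(length(subjects), n_test)]
        is_test <- annotation$subject_id %in% test_sub
        ml_tr <- multilevel_split(X[!is_test, , drop = FALSE],
                                  annotation[!is_test, , drop = FALSE])
        fit <- plsca(ml_tr$within, ml_tr$timepoint, ncomp = ncomp)
        ml_te <- multilevel_split(X[is_test, , drop = FALSE],
                                  annotation[is_test, , drop = FALSE])
        pred <- predict(fit, ml_te$within)
        confusion <- confusion +
          table(factor(ml_te$timepoint, levels = lv),
                factor(pred, levels = lv))
      }
    }
    rates <- report_rates(confusion, positive = positive)
    structure(list(confusion = confusion,
                   accuracy = rates[["accuracy"]],
                   sensitivity = rates[["sensitivity"]],
                   specificity = rates[["specificity"]],
                   n_iterations = n_iterations,
                   test_fraction = test_fraction,
                   positive = if (is.null(positive))
                     sort(rownames(confusion))[1] else positive,
                   model_kind = model_kind,
                   seed = seed),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s, %d Monte-Carlo splits (test fraction %.2f, seed %d)\n",
    x$model_kind, x$n_iterations, x$test_fraction, x$seed))
  print(x$confusion)
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  (positive class: %s)\n", x$positive))
  invisible(x)
}
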