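## population-signature statistics: assumption checks, Kruskal-Wallis +
## Dunn, PCA acoustic space, permuted discriminant function analysis,
## geography-projected hierarchical clustering

#' Normality and homoscedasticity checks for one feature
#'
#' Per-group normality by the Lilliefors-corrected Kolmogorov-Smirnov test
#' (the KS normality test with estimated mean and variance, which keeps
#' the nominal type-I rate) and homoscedasticity across groups by
#' Bartlett's test. Flags are raised at `alpha`.
#'
#' @param table a `feature_table`.
#' @param feature feature column name.
#' @param alpha significance level for the flags (default 0.05).
#' @return A list of class `assumption_check`: `ks` (data frame: group, n,
#'   statistic, p_value), `bartlett_p`, and flags `normality_rejected`
#'   (named logical per group) and `heteroscedastic` (with attribute
#'   `degenerate` when a group has zero variance).
#' @export
test_assumptions <- function(table, feature, alpha = 0.05) {
  x <- table[[feature]]
  g <- factor(table$group)
  if (nlevels(g) < 2L)
    stop_cavesong("need >= 2 groups", "cavesong_parameter_error")
  if (any(tapply(x, g, length) < 3L))
    stop_cavesong("each group needs >= 3 rows", "cavesong_parameter_error")
  ks <- do.call(rbind, lapply(levels(g), function(lv) {
    xi <- x[g == lv]
    if (length(xi) >= 4L && stats::sd(xi) > 0) {
      t <- nortest::lillie.test(xi)
      data.frame(group = lv, n = length(xi),
                 statistic = unname(t$statistic),
                 p_value = t$p.value)
    } else {
      data.frame(group = lv, n = length(xi), statistic = NA_real_,
                 p_value = if (stats::sd(xi) > 0) NA_real_ else 0)
    }
  }))
  vars <- tapply(x, g, stats::var)
  degenerate <- any(vars == 0)
  bp <- if (degenerate) 0 else stats::bartlett.test(x, g)$p.value
  hetero <- bp < alpha
  attr(hetero, "degenerate") <- degenerate
  structure(list(
    ks = ks, bartlett_p = bp,
    normality_rejected = stats::setNames(
      !is.na(ks$p_value) & ks$p_value < alpha, ks$group),
    heteroscedastic = hetero, alpha = alpha, feature = feature),
    class = "assumption_check")
}

#' @export
print.assumption_check <- function(x, ...) {
  cat(sprintf("<assumption_check> %s (alpha = %g)\n", x$feature, x$alpha))
  cat("  normality rejected:",
      if (any(x$normality_rejected))
        paste(names(which(x$normality_rejected)), collapse = ", ")
      else "none", "\n")
  cat(sprintf("  Bartlett p = %.4g%s\n", x$bartlett_p,
              if (x$heteroscedastic) " (heteroscedastic)" else ""))
  invisible(x)
}

# tie-corrected Kruskal-Wallis H (matches stats::kruskal.test$statistic)
kw_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  sums <- tapply(r, g, sum)
  sizes <- tapply(r, g, length)
  H <- 12 * sum(sums^2 / sizes) / (n * (n + 1)) - 3 * (n + 1)
  ties <- base::table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact permutation p-value of H by full enumeration of group labelings
kw_exact_p <- function(x, g) {
  g <- factor(g)
  sizes <- as.integer(base::table(g))
  h_obs <- kw_statistic(x, g)
  count <- 0L; total <- 0L
  recurse <- function(avail, remaining_sizes, labels) {
    if (length(remaining_sizes) == 1L) {
      lab <- labels
      lab[avail] <- length(sizes)
      total <<- total + 1L
      if (kw_statistic(x, lab) >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    k <- length(sizes) - length(remaining_sizes) + 1L
    picks <- utils::combn(avail, remaining_sizes[1L], simplify = FALSE)
    for (p in picks) {
      lab <- labels
      lab[p] <- k
      recurse(setdiff(avail, p), remaining_sizes[-1L], lab)
    }
  }
  recurse(seq_along(x), sizes, integer(length(x)))
  count / total
}

#' Kruskal-Wallis comparison of one feature across groups, with Dunn post
#' hoc tests
#'
#' Rank-based comparison (invariant under monotone transforms of the
#' feature): tie-corrected H with its chi-square p-value, followed by
#' Dunn's pairwise z-tests with multiplicity adjustment. For very small
#' samples (total n <= `exact_max_n`) the global p-value is computed
#' exactly by full enumeration of the permutation distribution of H.
#'
#' @param table a `feature_table`.
#' @param feature feature column name.
#' @param adjust p-value adjustment for the pairwise tests:
#'   `"bonferroni"` (default), `"holm"`, `"BH"` or `"none"`.
#' @param exact_max_n total-sample-size cutoff for the exact path.
#' @param check_assumptions also run [test_assumptions()] (needs >= 3 rows
#'   per group).
#' @return An object of class `group_comparison`: `H_statistic`,
#'   `p_value`, `df`, `pairwise` (data frame: group1, group2, z,
#'   p_unadjusted, p_adjusted), `exact`, and (optionally)
#'   `assumption_flags`.
#' @export
compare_groups <- function(table, feature,
                           adjust = c("bonferroni", "holm", "BH", "none"),
                           exact_max_n = 10L, check_assumptions = FALSE) {
  adjust <- match.arg(adjust)
  x <- table[[feature]]
  g <- factor(table$group)
  if (nlevels(g) < 2L)
    stop_cavesong("need >= 2 groups", "cavesong_parameter_error")
  if (any(tapply(x, g, length) < 2L))
    stop_cavesong("each group needs >= 2 rows", "cavesong_parameter_error")
  kt <- stats::kruskal.test(x, g)
  exact <- length(x) <= exact_max_n
  p_global <- if (exact) kw_exact_p(x, g) else kt$p.value
  if (is.nan(p_global)) p_global <- 1  # all values identical: H = 0

  # Dunn's z-tests on the pooled ranks, tie-corrected
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  ties <- base::table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
               (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    data.frame(group1 = i, group2 = j, z = z,
               p_unadjusted = 2 * stats::pnorm(-abs(z)))
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_unadjusted,
                                   method = if (adjust == "none") "none"
                                            else adjust)
  res <- list(feature = feature, H_statistic = unname(kt$statistic),
              df = unname(kt$parameter), p_value = p_global,
              pairwise = pw, adjust = adjust, exact = exact)
  if (check_assumptions)
    res$assumption_flags <- test_assumptions(table, feature)
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis H = %.4g (df %d), p = %.3g%s\n",
              x$feature, x$H_statistic, x$df, x$p_value,
              if (x$exact) " (exact)" else ""))
  cat(sprintf("  Dunn post hoc (%s):\n", x$adjust))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("    %s vs %s: z = %+.3f, p = %.3g\n",
                x$pairwise$group1[i], x$pairwise$group2[i],
                x$pairwise$z[i], x$pairwise$p_adjusted[i]))
  invisible(x)
}

#' Principal-component acoustic space with group confidence ellipses
#'
#' PCA of the (by default standardized) feature table; each sound becomes
#' a point in the space of the first `n_axes` principal axes, and each
#' group receives a confidence ellipse: the chi-square(2 df) quantile
#' contour of the Gaussian fitted to its scores on the first two axes.
#'
#' @param table a `feature_table`.
#' @param n_axes number of axes to keep (default 2).
#' @param confidence ellipse confidence level (default 0.95).
#' @param scale standardize features before the PCA (default TRUE;
#'   feature units differ by orders of magnitude).
#' @return An object of class `acoustic_space`: `scores` (n x n_axes),
#'   `loadings`, `explained_variance` (all axes, non-increasing),
#'   `ellipses` (per group: center, covariance, confidence), `groups`.
#' @export
acoustic_space <- function(table, n_axes = 2L, confidence = 0.95,
                           scale = TRUE) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(feats[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 1L)
    stop_cavesong("no non-constant features", "cavesong_parameter_error")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  n_axes <- min(n_axes, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  g <- factor(table$group)
  s2 <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  ellipses <- lapply(stats::setNames(levels(g), levels(g)), function(lv) {
    m <- s2[g == lv, , drop = FALSE]
    list(center = colMeans(m),
         covariance = if (nrow(m) > 2L) stats::cov(m) else
           diag(0, ncol(m)),
         confidence = confidence)
  })
  structure(list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
                 loadings = pc$rotation, explained_variance = ev,
                 ellipses = ellipses, groups = g, sdev = pc$sdev,
                 confidence = confidence, scaled = scale),
            class = "acoustic_space")
}

#' @export
print.acoustic_space <- function(x, ...) {
  cat(sprintf("<acoustic_space> %d sounds, %d group(s); PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nlevels(x$groups),
              100 * x$explained_variance[1L],
              if (length(x$explained_variance) > 1L)
                100 * x$explained_variance[2L] else 0))
  invisible(x)
}

#' Fraction of a group's points inside its own confidence ellipse
#'
#' @param space an `acoustic_space`.
#' @param group group label.
#' @return Fraction in \[0, 1\].
#' @export
ellipse_coverage <- function(space, group) {
  e <- space$ellipses[[group]]
  m <- space$scores[space$groups == group, 1:2, drop = FALSE]
  d <- stats::mahalanobis(m, e$center, e$covariance)
  mean(d <= stats::qchisq(e$confidence, df = 2))
}

## ---- linear discriminant core for the pDFA --------------------------------

# pooled-covariance linear discriminant classification of `newdata` given
# training data (X, y); proportional priors; optional ridge on the pooled
# covariance. Returns integer class indices.
lda_classify <- function(X, y, newdata = X, ridge = 0) {
  y <- as.integer(y)
  K <- max(y)
  p <- ncol(X)
  n <- nrow(X)
  M <- matrix(0, K, p)
  counts <- tabulate(y, K)
  for (k in seq_len(K)) M[k, ] <- colMeans(X[y == k, , drop = FALSE])
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    D <- sweep(X[y == k, , drop = FALSE], 2L, M[k, ])
    S <- S + crossprod(D)
  }
  W <- S / (n - K)
  if (ridge > 0) W <- W + ridge * mean(diag(W)) * diag(p)
  Wi <- solve(W)
  A <- M %*% Wi                        # K x p
  b <- -0.5 * rowSums(A * M) + log(counts / n)
  scores <- newdata %*% t(A) + matrix(b, nrow(newdata), K, byrow = TRUE)
  max.col(scores, ties.method = "first")
}

# leave-one-out predictions with exact mean/scatter downdating
loo_lda_predict <- function(X, y, ridge = 0) {
  y <- as.integer(y)
  K <- max(y)
  p <- ncol(X)
  n <- nrow(X)
  counts <- tabulate(y, K)
  if (any(counts < 2L))
    stop_cavesong("each group needs >= 2 members for leave-one-out",
                  "cavesong_parameter_error")
  M <- matrix(0, K, p)
  for (k in seq_len(K)) M[k, ] <- colMeans(X[y == k, , drop = FALSE])
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    D <- sweep(X[y == k, , drop = FALSE], 2L, M[k, ])
    S <- S + crossprod(D)
  }
  pred <- integer(n)
  reg_used <- FALSE
  ridge_eye <- diag(p)
  for (i in seq_len(n)) {
    g <- y[i]
    ng <- counts[g]
    v <- X[i, ] - M[g, ]
    Si <- S - (ng / (ng - 1)) * tcrossprod(v)
    Wi_mat <- Si / (n - 1 - K)
    Mi <- M
    Mi[g, ] <- (ng * M[g, ] - X[i, ]) / (ng - 1)
    ci <- counts; ci[g] <- ng - 1L
    Winv <- tryCatch(solve(Wi_mat), error = function(e) NULL)
    if (is.null(Winv) || ridge > 0) {
      reg_used <- reg_used || is.null(Winv)
      lam <- if (ridge > 0) ridge else 1e-6
      Winv <- solve(Wi_mat + lam * mean(diag(Wi_mat)) * ridge_eye)
    }
    A <- Mi %*% Winv
    b <- -0.5 * rowSums(A * Mi) + log(ci / (n - 1))
    pred[i] <- which.max(A %*% X[i, ] + b)
  }
  attr(pred, "regularized") <- reg_used
  pred
}

#' Permuted discriminant function analysis
#'
#' Quantifies how well groups separate in a score space (typically the
#' principal axes of an [acoustic_space()]): the observed statistic is the
#' leave-one-out cross-validated reclassification rate of a
#' pooled-covariance linear discriminant; its null distribution is built
#' by recomputing the same statistic under random permutations of the
#' group labels, and `p = (count(null >= observed) + 1) /
#' (n_permutations + 1)`. Singular within-group covariances are handled by
#' ridge regularization and flagged.
#'
#' @param scores numeric matrix of per-sound coordinates (or an
#'   `acoustic_space`, whose scores and groups are used).
#' @param labels group labels (ignored when `scores` is an
#'   `acoustic_space`).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return An object of class `pdfa`: `confusion` (true group x predicted
#'   group), `per_group_reclassification`, `overall_reclassification`,
#'   `null_distribution`, `p_value`, `n_permutations`, `seed`,
#'   `regularized`.
#' @export
pdfa <- function(scores, labels = NULL, n_permutations = 1000L, seed = 1L) {
  if (inherits(scores, "acoustic_space")) {
    labels <- scores$groups
    scores <- scores$scores
  }
  X <- as.matrix(scores)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop_cavesong("need >= 2 groups", "cavesong_parameter_error")
  if (any(base::table(y) < 3L))
    stop_cavesong("each group needs >= 3 sounds", "cavesong_parameter_error")
  yi <- as.integer(y)
  pred <- loo_lda_predict(X, yi)
  observed <- mean(pred == yi)
  confusion <- base::table(true = factor(levels(y)[yi], levels = levels(y)),
                           predicted = factor(levels(y)[pred],
                                              levels = levels(y)))
  per_group <- diag(confusion) / rowSums(confusion)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yp <- sample(yi)
      mean(loo_lda_predict(X, yp) == yp)
    }, numeric(1))
  })
  p <- (sum(null >= observed - 1e-12) + 1) / (n_permutations + 1)
  structure(list(confusion = confusion,
                 per_group_reclassification = per_group,
                 overall_reclassification = observed,
                 null_distribution = null, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 regularized = isTRUE(attr(pred, "regularized"))),
            class = "pdfa")
}

#' @export
print.pdfa <- function(x, ...) {
  cat(sprintf("<pdfa> overall reclassification %.1f%% (LOO), p = %.4g (%d permutations)\n",
              100 * x$overall_reclassification, x$p_value,
              x$n_permutations))
  cat("  per group:",
      paste(sprintf("%s %.0f%%", names(x$per_group_reclassification),
                    100 * x$per_group_reclassification), collapse = ", "),
      "\n")
  if (x$regularized) cat("  (ridge regularization was applied)\n")
  invisible(x)
}

#' Hierarchical clustering of group signatures with geographic projection
#'
#' Average-linkage clustering of the Euclidean distances between per-group
#' median standardized feature vectors. The tree can be serialized to
#' newick (merge heights as branch lengths) and plotted with its leaves
#' placed at the groups' geographical coordinates.
#'
#' @param table a `feature_table`.
#' @param coordinates data frame with columns `group`, `lon`, `lat` (or a
#'   2-column matrix with group rownames).
#' @return An object of class `geo_clustering`: `hclust`, `medians`,
#'   `coordinates`, `newick`.
#' @export
geo_cluster <- function(table, coordinates) {
  g <- factor(table$group)
  if (nlevels(g) < 2L)
    stop_cavesong("need >= 2 groups", "cavesong_parameter_error")
  if (is.matrix(coordinates))
    coordinates <- data.frame(group = rownames(coordinates),
                              lon = coordinates[, 1L],
                              lat = coordinates[, 2L])
  missing <- setdiff(levels(g), coordinates$group)
  if (length(missing))
    stop_cavesong(paste0("missing coordinates for group(s): ",
                         paste(missing, collapse = ", ")),
                  "cavesong_labeling_error")
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  med <- do.call(rbind, lapply(levels(g), function(lv)
    apply(Xs[g == lv, , drop = FALSE], 2L, stats::median)))
  rownames(med) <- levels(g)
  hc <- stats::hclust(stats::dist(med), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, medians = med,
                 coordinates = coordinates[match(levels(g),
                                                 coordinates$group), ],
                 newick = newick),
            class = "geo_clustering")
}

#' @export
print.geo_clustering <- function(x, ...) {
  cat("<geo_clustering>", length(x$hclust$labels), "groups\n")
  cat("  newick:", x$newick, "\n")
  invisible(x)
}
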