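test_that("the H statistic matches stats::kruskal.test, ties included", {
  set.seed(51)
  x <- round(stats::rnorm(60), 1)           # rounding forces ties
  g <- factor(rep(c("a", "b", "c"), each = 20))
  cmp <- compare_groups(sig_table(x, g), "v")
  ref <- stats::kruskal.test(x, g)
  expect_equal(cmp$H_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$df, unname(ref$parameter))
})

test_that("the exact small-sample p-value equals full enumeration done from scratch", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- factor(rep(c("a", "b"), each = 4))
  cmp <- compare_groups(sig_table(x, g), "v", exact_max_n = 10L)
  expect_true(cmp$exact)
  # independent brute force: all 70 assignments of 4 labels "a" among 8
  h_of <- function(lab) {
    r <- rank(x)
    sums <- tapply(r, lab, sum)
    sizes <- tapply(r, lab, length)
    n <- length(x)
    h <- 12 * sum(sums^2 / sizes) / (n * (n + 1)) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  h_obs <- h_of(g)
  hits <- 0L
  picks <- utils::combn(8, 4, simplify = FALSE)
  for (p in picks) {
    lab <- factor(ifelse(seq_len(8) %in% p, "a", "b"))
    if (h_of(lab) >= h_obs - 1e-12) hits <- hits + 1L
  }
  expect_equal(cmp$p_value, hits / length(picks))
  # the two most extreme assignments of {1,2,3,4} vs {10,11,12,13}
  expect_equal(cmp$p_value, 2 / 70)
})

test_that("group comparison is invariant under monotone transforms of the feature", {
  set.seed(52)
  x <- stats::rnorm(45)
  g <- factor(rep(c("a", "b", "c"), each = 15))
  c1 <- compare_groups(sig_table(x, g), "v")
  c2 <- compare_groups(sig_table(exp(x), g), "v")
  expect_equal(c1$H_statistic, c2$H_statistic, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  expect_equal(c1$pairwise$p_adjusted, c2$pairwise$p_adjusted,
               tolerance = 1e-12)
})

test_that("well separated groups are detected globally and pairwise", {
  set.seed(53)
  x <- c(stats::rnorm(30), stats::rnorm(30, 4), stats::rnorm(30, 8))
  g <- factor(rep(c("a", "b", "c"), each = 30))
  cmp <- compare_groups(sig_table(x, g), "v")
  expect_lt(cmp$p_value, 1e-6)
  expect_true(all(cmp$pairwise$p_adjusted < 0.01))
  expect_true(all(cmp$pairwise$p_adjusted >= cmp$pairwise$p_unadjusted))
})

test_that("assumption checks flag non-normal and heteroscedastic data", {
  set.seed(54)
  norm_tab <- sig_table(stats::rnorm(80), rep(c("a", "b"), each = 40))
  a1 <- test_assumptions(norm_tab, "v")
  expect_false(any(a1$normality_rejected))
  skew_tab <- sig_table(c(stats::rexp(40), stats::rexp(40) * 6),
                        rep(c("a", "b"), each = 40))
  a2 <- test_assumptions(skew_tab, "v")
  expect_true(any(a2$normality_rejected))
  expect_true(a2$heteroscedastic)
  const_tab <- sig_table(c(rep(1, 10), stats::rnorm(10)),
                         rep(c("a", "b"), each = 10))
  a3 <- test_assumptions(const_tab, "v")
  expect_true(attr(a3$heteroscedastic, "degenerate"))
})

test_that("the acoustic space reproduces principal components and draws one ellipse per group", {
  set.seed(55)
  n <- 60
  tab <- structure(
    data.frame(event_id = sprintf("e%d", 1:n),
               group = rep(c("a", "b"), each = n / 2),
               f1 = stats::rnorm(n), f2 = stats::rnorm(n, sd = 10),
               f3 = stats::rnorm(n, sd = 0.1)),
    class = c("feature_table", "data.frame"))
  sp <- acoustic_space(tab)
  pc <- stats::prcomp(as.matrix(tab[, c("f1", "f2", "f3")]),
                      center = TRUE, scale. = TRUE)
  expect_equal(abs(sp$scores[, 1L]), abs(pc$x[, 1L]), tolerance = 1e-9)
  expect_identical(names(sp$ellipses), c("a", "b"))
  expect_equal(sum(sp$explained_variance), 1)
  expect_true(all(diff(sp$explained_variance) <= 1e-12))
})

test_that("95 percent ellipses cover close to 95 percent of their own group", {
  set.seed(56)
  n <- 4000
  tab <- structure(
    data.frame(event_id = sprintf("e%d", 1:n), group = "a",
               f1 = stats::rnorm(n), f2 = stats::rnorm(n)),
    class = c("feature_table", "data.frame"))
  sp <- acoustic_space(tab)
  cov95 <- ellipse_coverage(sp, "a")
  expect_gt(cov95, 0.93)
  expect_lt(cov95, 0.97)
})

test_that("leave-one-out discriminant predictions match MASS::lda cross-validation", {
  set.seed(57)
  n <- 90
  X <- rbind(matrix(stats::rnorm(n, 0), ncol = 3),
             matrix(stats::rnorm(n, 1.5), ncol = 3),
             matrix(stats::rnorm(n, 3), ncol = 3))
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  ours <- cavesong:::loo_lda_predict(X, as.integer(y))
  ref <- MASS::lda(X, grouping = y, CV = TRUE)$class
  expect_identical(levels(y)[ours], as.character(ref))
})

test_that("pdfa separates distinct populations and is calibrated on exchangeable labels", {
  set.seed(58)
  X <- rbind(matrix(stats::rnorm(60, 0), ncol = 2),
             matrix(stats::rnorm(60, 2.5), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 30))
  sep <- pdfa(X, y, n_permutations = 199, seed = 3)
  expect_lte(sep$p_value, 0.01)
  expect_gt(sep$overall_reclassification, 0.9)
  expect_equal(sum(sep$confusion), 60)
  # identical seeds give identical permutations
  sep2 <- pdfa(X, y, n_permutations = 199, seed = 3)
  expect_identical(sep$null_distribution, sep2$null_distribution)
  # with exchangeable labels p is roughly uniform: not tiny
  Xn <- matrix(stats::rnorm(120), ncol = 2)
  nul <- pdfa(Xn, y, n_permutations = 199, seed = 4)
  expect_gt(nul$p_value, 0.05)
})

test_that("pdfa accepts an acoustic space directly", {
  set.seed(59)
  n <- 40
  tab <- structure(
    data.frame(event_id = sprintf("e%d", 1:n),
               group = rep(c("a", "b"), each = n / 2),
               f1 = c(stats::rnorm(n / 2), stats::rnorm(n / 2, 3)),
               f2 = stats::rnorm(n)),
    class = c("feature_table", "data.frame"))
  p <- pdfa(acoustic_space(tab), n_permutations = 99, seed = 5)
  expect_s3_class(p, "pdfa")
  expect_lte(p$p_value, 0.05)
})

test_that("geographic clustering groups nearby signatures and serializes to newick", {
  set.seed(60)
  n <- 30
  mk <- function(mu) stats::rnorm(n, mu, 0.1)
  tab <- structure(
    data.frame(event_id = sprintf("e%d", 1:(4 * n)),
               group = rep(c("g1", "g2", "g3", "g4"), each = n),
               f1 = c(mk(0), mk(0.2), mk(5), mk(5.2)),
               f2 = c(mk(1), mk(1.1), mk(8), mk(8.1))),
    class = c("feature_table", "data.frame"))
  coords <- data.frame(group = c("g1", "g2", "g3", "g4"),
                       lon = c(-99, -98.9, -98, -97.9),
                       lat = c(22, 22.1, 21, 21.1))
  gc <- geo_cluster(tab, coords)
  # g1/g2 and g3/g4 merge first
  first_two <- gc$hclust$merge[1:2, ]
  pairs <- apply(first_two, 1L, function(r)
    paste(sort(gc$hclust$labels[-r]), collapse = "+"))
  expect_setequal(pairs, c("g1+g2", "g3+g4"))
  tree <- ape::read.tree(text = gc$newick)
  expect_setequal(tree$tip.label, c("g1", "g2", "g3", "g4"))
  expect_error(geo_cluster(tab, coords[1:3, ]),
               class = "cavesong_labeling_error")
})
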