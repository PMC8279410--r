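test_that("log(x+1) transform maps 0 to 0, e-1 to 1, and rejects sentinels", {
  expect_equal(log1p_transform(c(0, exp(1) - 1)), c(0, 1))
  expect_error(log1p_transform(c(0.5, -1)), "sentinel|negative")
  expect_error(log1p_transform(c(0.5, NA)), "missing")
})

test_that("Kruskal-Wallis matches the hand rank-sum formula on the worked example", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(unname(kw$n_per_group), c(3L, 3L, 3L))
})

test_that("Kruskal-Wallis H agrees with an independent brute-force oracle on random small tables", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(2:4, 3, replace = TRUE)
    # mixture with duplicates to exercise the tie correction
    pool <- c(round(runif(6, 0, 3), 1))
    groups <- lapply(n, function(ni) sample(pool, ni, replace = TRUE))
    names(groups) <- c("a", "b", "c")
    if (length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    expect_equal(kw$H, kw_bruteforce(groups), tolerance = 1e-10)
  }
})

test_that("balanced identical groups give H ~ 0 and p ~ 1", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_lt(kw$H, 1e-10)
  expect_gt(kw$p, 0.99)
})

test_that("empty groups are reported by name", {
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())), "b")
})

test_that("exact Wilcoxon p-value on {1,2} vs {3,4} is 1/3 and Bonferroni uses m = 3 for three groups", {
  pw <- pairwise_wilcoxon_bonferroni(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(pw$comparisons$p_raw, 1 / 3, tolerance = 1e-12)
  expect_equal(pw$m, 1L)
  pw3 <- pairwise_wilcoxon_bonferroni(
    list(a = c(1, 2, 5), b = c(3, 4, 8), c = c(6, 7, 9)))
  expect_equal(pw3$m, 3L)
  expect_equal(nrow(pw3$comparisons), 3L)
  expect_equal(pw3$comparisons$p_adjusted,
               pmin(1, 3 * pw3$comparisons$p_raw))
})

test_that("identical groups give Wilcoxon p = 1 after adjustment capping", {
  pw <- pairwise_wilcoxon_bonferroni(
    list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(pw$comparisons$p_adjusted, 1)
})

test_that("permuted group labels yield uniform Kruskal-Wallis p-values", {
  set.seed(47)
  labels <- rep(c("a", "b", "c"), each = 10)
  p <- replicate(1000, {
    values <- rnorm(30)  # exchangeable across groups: the null holds
    kruskal_wallis(split(values, sample(labels)))$p
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stratified comparison runs per domain, equals the unstratified test on full_protein, and skips incomplete strata", {
  set.seed(53)
  tab <- data.frame(
    group = rep(c("population", "cancer", "NDD"), times = c(40, 15, 12)),
    domain = "FAT",
    rsa = c(runif(40, 0.2, 1), runif(15, 0.1, 0.8), runif(12, 0, 0.6))
  )
  tab$domain[1:10] <- "FATC"  # population-only stratum -> skipped
  res <- stratified_compare(tab)
  expect_true(all(c("full_protein", "FAT") %in% names(res)))
  expect_false("FATC" %in% names(res))
  skipped <- attr(res, "skipped")
  expect_equal(skipped$stratum, "FATC")
  expect_match(skipped$reason, "NDD")
  direct <- kruskal_wallis(split(log1p_transform(tab$rsa), tab$group))
  expect_equal(res$full_protein$kruskal$H, direct$H)
})

test_that("ROC with low-RSA-positive orientation: disjoint groups give AUC 1, full ties give 0.5", {
  tab <- data.frame(group = c("NDD", "NDD", "population", "population"),
                    rsa = c(0.1, 0.2, 0.3, 0.4))
  r <- roc_auc(tab, "NDD")
  expect_equal(r$auc, 1.0)
  expect_equal(r$score_orientation, "low_rsa_is_positive")
  tied <- data.frame(group = rep(c("NDD", "population"), each = 5),
                     rsa = rep(0.3, 10))
  expect_equal(roc_auc(tied, "NDD")$auc, 0.5)
})

test_that("ROC points form a monotone polygon from (0,0) to (1,1) whose trapezoid area equals the midrank AUC", {
  set.seed(61)
  for (k in 1:10) {
    tab <- data.frame(
      group = rep(c("NDD", "population"), times = c(12, 25)),
      rsa = round(c(runif(12, 0, 0.8), runif(25, 0.1, 1)), 1)  # with ties
    )
    r <- roc_auc(tab, "NDD")
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(auc_trapezoid(r$points), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under the log1p transform", {
  set.seed(67)
  tab <- data.frame(
    group = rep(c("NDD", "population"), times = c(30, 50)),
    rsa = c(rbeta(30, 1, 4), rbeta(50, 2, 2))
  )
  r1 <- roc_auc(tab, "NDD")
  tab$rsa <- log1p_transform(tab$rsa)
  r2 <- roc_auc(tab, "NDD")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  tab <- data.frame(
    group = rep(c("NDD", "population"), times = c(25, 60)),
    rsa = round(c(rbeta(25, 1.2, 4), rbeta(60, 2, 2)), 2)
  )
  r <- roc_auc(tab, "NDD")
  ref <- pROC::roc(response = tab$group == "NDD", predictor = -tab$rsa,
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC with an empty group errors", {
  tab <- data.frame(group = "population", rsa = 0.5)
  expect_error(roc_auc(tab, "NDD"), "empty")
})
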