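test_that("2x2 chi-squared matches the sum((O-E)^2/E) oracle", {
  chisq_oracle <- function(a, b, c, d) {
    o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }
  r <- two_by_two_chi_squared(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  fixtures <- list(c(20, 10, 10, 20), c(5, 1, 2, 9), c(100, 3, 40, 17),
                   c(1, 1, 1, 2), c(50, 50, 60, 40))
  for (f in fixtures) {
    r <- do.call(two_by_two_chi_squared, as.list(f))
    expect_equal(r$statistic, do.call(chisq_oracle, as.list(f)),
                 tolerance = 1e-12)
    expect_equal(r$p, pchisq(r$statistic, 1, lower.tail = FALSE))
    # swapping rows leaves the statistic unchanged
    sw <- do.call(two_by_two_chi_squared, as.list(f[c(3, 4, 1, 2)]))
    expect_equal(sw$statistic, r$statistic)
  }
  # degenerate margins are flagged, not silently computed
  r <- two_by_two_chi_squared(0, 0, 5, 5)
  expect_true(r$degenerate)
  expect_true(is.na(r$statistic))
  expect_error(two_by_two_chi_squared(-1, 2, 3, 4), "non-negative")
})

test_that("ANOVA F and Wilcoxon match direct computation", {
  # identical data in each group: zero between-group variance
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(anova_f(v, g)$statistic, 0)
  expect_true(anova_f(rep(5, 6), rep(c("a", "b"), 3))$degenerate)
  # classical F via explicit sums of squares
  set.seed(2)
  y <- rnorm(30); grp <- rep(1:3, 10)
  means <- tapply(y, grp, mean)
  ssb <- sum(10 * (means - mean(y))^2)
  ssw <- sum((y - means[as.character(grp)])^2)
  f_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(anova_f(y, grp)$statistic, f_oracle, tolerance = 1e-12)
  # Wilcoxon W by exhaustive pair counting
  w_oracle <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$statistic, w_oracle(1:3, 4:6))
  set.seed(6)
  x <- sample(1:10, 12, replace = TRUE)
  y <- sample(1:10, 9, replace = TRUE)
  expect_equal(unname(wilcoxon_rank_sum(x, y)$statistic), w_oracle(x, y))
  # permutation within samples changes nothing
  expect_equal(wilcoxon_rank_sum(sample(x), sample(y))$statistic,
               wilcoxon_rank_sum(x, y)$statistic)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("Benjamini-Hochberg step-up matches hand computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(benjamini_hochberg(0.037), 0.037)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6, 1)
  q <- benjamini_hochberg(p)
  # hand step-up: q_i = min over j >= i of m * p_j / j, capped at 1
  m <- length(p)
  hand <- rev(cummin(rev(pmin(1, m * p / seq_len(m)))))
  expect_equal(q, hand)
  expect_true(all(q >= p))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("subtype profiling flags planted features and skips constants", {
  # toy fixture: one feature present only inside subtype 1
  m <- cbind(planted = rep(c(1L, 0L), c(20, 20)),
             noise = rep(0:1, 20),
             allzero = 0L,
             allone = 1L)
  assign <- rep(c(1L, 2L), c(20, 20))
  prof <- profile_subtypes(m, assign, fdr_threshold = 0.001)
  expect_identical(attr(prof, "excluded"), c("allzero", "allone"))
  top1 <- prof[prof$subtype == 1, ]
  top1 <- top1[order(top1$q), ]
  expect_identical(top1$feature[1], "planted")
  expect_true(top1$significant[1])
  expect_false(any(prof$significant[prof$feature == "noise"]))
  expect_equal(prof$prop_in[prof$subtype == 1 &
                              prof$feature == "planted"], 1)
  expect_equal(prof$prop_out[prof$subtype == 1 &
                               prof$feature == "planted"], 0)
  # profile is invariant to patient order
  perm <- sample(40)
  prof2 <- profile_subtypes(m[perm, ], assign[perm], 0.001)
  o <- order(prof$subtype, prof$feature)
  o2 <- order(prof2$subtype, prof2$feature)
  expect_equal(prof$statistic[o], prof2$statistic[o2])
})

test_that("profiling recovers planted prevalence gaps on synthetic cohorts", {
  res <- simulate_and_featurize(600, separated_specs(), seed = 33)
  prof <- profile_subtypes(res$fm, as.integer(factor(res$truth)))
  sets <- enriched_features(prof)
  # every diagnosis concept with a >= 0.9 prevalence gap must be detected
  specs <- separated_specs()
  cc <- concept_catalog()
  labels <- sort(unique(res$truth))
  for (s in seq_along(labels)) {
    spec <- specs[[which(vapply(specs, `[[`, "", "label") == labels[s])]]
    high <- names(spec$feature_prevalences)[
      spec$feature_prevalences >= 0.9]
    high_dx <- intersect(high, cc$concept[cc$domain == "diagnosis"])
    expected_cols <- paste0(
      "phecode_",
      mapping_tables()$icd_to_phecode$phecode[
        match(cc$code[match(high_dx, cc$concept)],
              mapping_tables()$icd_to_phecode$code)])
    found <- sets[[as.character(s)]]
    expect_gt(length(intersect(expected_cols, found)),
              0.8 * length(expected_cols))
  }
})
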