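test_that("pooled t matches the closed form computed independently", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # independent closed-form oracle for the pooled-variance t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df_oracle <- length(a) + length(b) - 2
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)

  gc <- group_compare(a, b)
  expect_equal(gc$t_statistic, t_oracle)
  expect_equal(gc$t_statistic, -1.2247, tolerance = 1e-4)
  expect_equal(gc$df, 4)
  expect_equal(gc$p_value, p_oracle)
  expect_equal(gc$p_value, 0.2879, tolerance = 5e-4)
  expect_equal(gc$star_code, "ns")
  expect_equal(gc$ses, rep(sd(a) / sqrt(3), 2))
})

test_that("degenerate and identical samples are handled as specified", {
  same <- group_compare(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)
  flat <- group_compare(c(1, 1, 1), c(2, 2, 2))
  expect_true(flat$degenerate)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("t is antisymmetric under group swap and p invariant", {
  set.seed(21)
  a <- rnorm(15, 10, 2); b <- rnorm(12, 11, 2)
  ab <- group_compare(a, b); ba <- group_compare(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("a planted 5 s.d. effect is flagged *** almost always", {
  set.seed(22)
  hits <- 0
  for (i in 1:100) {
    a <- rnorm(20, 0, 1); b <- rnorm(20, 5, 1)
    if (group_compare(a, b)$star_code == "***") hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("star codes follow the printed thresholds", {
  expect_equal(significance_stars(c(1e-5, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
  # boundary p-values read with strict inequalities fall into the * band
  expect_equal(significance_stars(0.001), "*")
  expect_equal(significance_stars(0.01), "*")
  expect_equal(significance_stars(0.05), "ns")
})

test_that("percent difference is exact and signed", {
  expect_equal(percent_difference(1.0, 1.226), 22.6)
  expect_equal(percent_difference(100, 97), -3)
  expect_equal(percent_difference(5, 5), 0)
  set.seed(23)
  for (i in 1:20) {
    x <- runif(1, 0.1, 50); f <- runif(1, -90, 200)
    expect_equal(percent_difference(x, x * (1 + f / 100)), f)
  }
  expect_error(percent_difference(0, 1), "positive")
})

test_that("tidy and glance return the comparison as tibbles", {
  gc <- group_compare(c(1, 2, 3, 4), c(3, 4, 5, 6),
                      labels = c("control", "mutant"))
  td <- tidy(gc)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$group, c("control", "mutant"))
  expect_equal(td$mean, c(2.5, 4.5))
  gl <- glance(gc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$percent_difference, 80)
})

test_that("reports summarize groups and compare against the reference", {
  set.seed(24)
  tab <- tibble::tibble(
    genotype = rep(c("control", "mutant"), each = 12),
    ratio = c(rnorm(12, 1.1, 0.05), rnorm(12, 1.35, 0.05)))
  rep1 <- build_report(tab, group = "genotype")
  expect_equal(nrow(rep1$comparisons), 1)
  expect_equal(rep1$comparisons$metric, "ratio")
  # summary means equal brute-force means over rows
  for (g in c("control", "mutant")) {
    expect_equal(rep1$summary$mean[rep1$summary$genotype == g],
                 mean(tab$ratio[tab$genotype == g]))
  }
  # box-plot stats present for parity with the standard box-plot reporting style
  expect_true(all(c("median", "q1", "q3", "whisker_low", "whisker_high") %in%
                    names(rep1$summary)))
  expect_error(build_report(tab, group = "nope"), "unknown group")
  expect_error(build_report(tab, group = "genotype", metrics = "nope"),
               "unknown metric")
  expect_warning(build_report(tab[0, ], group = "genotype"), "empty")
  # unknown reference group is reported by name
  expect_error(build_report(tab, group = "genotype", reference = "wt"), "wt")
})

test_that("autoplot methods return ggplot objects", {
  gc <- group_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_s3_class(autoplot(gc), "ggplot")
  cen <- vesicle_census(c(rep("both", 6), rep("ch1_only", 2), "ch2_only"))
  expect_s3_class(autoplot(cen), "ggplot")
})
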