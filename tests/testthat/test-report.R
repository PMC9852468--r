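# Replicate/site aggregation, fold changes and t-tests.

toy_table <- function() {
  data.frame(
    site = rep(rep(c("s1", "s2", "s3"), each = 3), 2),
    platform = rep(c("PEn", "uPEn"), each = 9),
    value = c(10, 20, 30,  12, 14, 16,  8, 10, 12,     # PEn
              38, 43, 52,  40, 44, 48,  30, 33, 36))   # uPEn
}

test_that("per-site means/sd and per-platform medians are textbook", {
  agg <- aggregate_editing(toy_table())
  s1 <- agg$per_site[agg$per_site$site == "s1" &
                       agg$per_site$platform == "PEn", ]
  expect_equal(s1$mean, 20)
  expect_equal(s1$sd, 10)
  up <- agg$per_platform[agg$per_platform$platform == "uPEn", ]
  # uPEn site means: 44.333, 44, 33 -> median 44
  expect_equal(up$median, median(c(mean(c(38, 43, 52)), 44, 33)))
  # single-site platform: median equals that site's mean
  one <- aggregate_editing(data.frame(site = "sX", platform = "P",
                                      value = c(38, 43, 52)))
  expect_equal(one$per_platform$median, mean(c(38, 43, 52)))
})

test_that("fold changes normalize each site's baseline mean to 1", {
  df <- data.frame(site = rep(c("s1", "s2"), each = 4),
                   platform = rep(c("base", "new"), 4),
                   value = c(10, 45, 10, 45,   20, 52, 20, 56))
  fc <- fold_change(df, "base")
  expect_equal(fc$per_site$fold[fc$per_site$platform == "base"], c(1, 1))
  new_folds <- fc$per_site$fold[fc$per_site$platform == "new"]
  expect_equal(sort(new_folds), c(2.7, 4.5))
  expect_equal(fc$median$median_fold[fc$median$platform == "new"],
               median(c(4.5, 2.7)))
  expect_equal(fc$median$median_fold[fc$median$platform == "base"], 1)
  # two sites with folds 2.6 and 2.8 -> median 2.7
  df2 <- data.frame(site = rep(c("a", "b"), each = 2),
                    platform = rep(c("base", "new"), 2),
                    value = c(10, 26, 10, 28))
  expect_equal(fold_change(df2, "base")$median$median_fold[2], 2.7)
  # zero baseline: fold missing with a warning, excluded from the median
  df0 <- rbind(df, data.frame(site = "s3", platform = c("base", "new"),
                              value = c(0, 5)))
  expect_warning(fc0 <- fold_change(df0, "base"), "baseline mean is 0")
  expect_true(is.na(fc0$per_site$fold[fc0$per_site$site == "s3" &
                                        fc0$per_site$platform == "new"]))
  expect_equal(fc0$median$n_sites[fc0$median$platform == "new"], 2L)
})

test_that("platform comparisons match hand-computed Student's t", {
  # textbook 3 vs 3 equal-variance case, computed with the standard formula
  a <- c(10, 12, 14); b <- c(20, 21, 25)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  df <- data.frame(site = "s1", platform = rep(c("A", "B"), each = 3),
                   value = c(a, b))
  cp <- compare_platforms(df, "A", "B")
  expect_equal(cp$per_site$t, t_hand)
  expect_equal(cp$per_site$df, 4)
  expect_equal(cp$per_site$p, 2 * pt(t_hand, 4))

  # identical replicate sets: t = 0, p = 1
  df_id <- data.frame(site = "s1", platform = rep(c("A", "B"), each = 3),
                      value = rep(c(1, 2, 3), 2))
  cp_id <- compare_platforms(df_id, "A", "B")
  expect_equal(cp_id$per_site$t, 0)
  expect_equal(cp_id$per_site$p, 1)

  # folds all exactly 1: one-sample t = 0
  df_same <- data.frame(site = rep(c("s1", "s2"), each = 6),
                        platform = rep(rep(c("A", "B"), each = 3), 2),
                        value = c(5, 6, 7, 5, 6, 7, 9, 10, 11, 9, 10, 11))
  cp_same <- compare_platforms(df_same, "A", "B")
  expect_equal(cp_same$fold_test$t, 0)
  expect_equal(cp_same$fold_test$folds, c(1, 1))
})

test_that("aggregation is invariant under row permutation", {
  df <- toy_table()
  set.seed(8)
  df2 <- df[sample(nrow(df)), , drop = FALSE]
  expect_equal(aggregate_editing(df)$per_site,
               aggregate_editing(df2)$per_site)
  expect_equal(fold_change(df, "PEn")$median, fold_change(df2, "PEn")$median)
})
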