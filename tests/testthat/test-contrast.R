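test_that("range as percent of mean matches hand computations", {
  expect_equal(range_percent(c(1, 2, 3)), 100)
  expect_equal(range_percent(c(5, 5, 5)), 0)
  expect_equal(range_percent(c(2, 4, 6, 8)), 120)  # (8-2)/5 * 100
  expect_error(range_percent(3), "at least 2")
  expect_error(range_percent(c(-2, 1)), "positive")
})

test_that("site-type ratios equal ratios of geometric means", {
  type <- c(rep("S", 4), rep("UB", 4), rep("RB", 4))
  vals <- c(rep(2, 4), rep(1, 4), rep(0.5, 4))
  r <- site_type_ratios(vals, type)
  expect_equal(r$ratio[r$contrast == "S/UB"], 2)
  expect_equal(r$ratio[r$contrast == "RB/UB"], 0.5)
  expect_equal(r$ratio[r$contrast == "S/RB"], 4)

  # equal geometric means in every group -> all ratios 1
  same <- site_type_ratios(rep(c(3, 6), 6), rep(c("S", "UB", "RB"), each = 4))
  expect_equal(same$ratio, rep(1, 3), tolerance = 1e-12)

  # noisy case: closed-form geometric-mean ratio and ratio-of-ratios identity
  set.seed(11)
  vals2 <- exp(rnorm(12, mean = rep(c(1, 0.5, 0.2), each = 4), sd = 0.3))
  r2 <- site_type_ratios(vals2, rep(c("S", "UB", "RB"), each = 4))
  gm <- tapply(log(vals2), rep(c("S", "UB", "RB"), each = 4), mean)
  expect_equal(r2$ratio[r2$contrast == "S/UB"],
               exp(gm[["S"]] - gm[["UB"]]), tolerance = 1e-10)
  expect_equal(r2$ratio[r2$contrast == "S/UB"] / r2$ratio[r2$contrast == "RB/UB"],
               r2$ratio[r2$contrast == "S/RB"], tolerance = 1e-10)

  expect_error(site_type_ratios(c(-1, 1, 1, 1), rep(c("S", "UB"), 2)),
               "positive")
})

test_that("one-way ANOVA matches hand computation and the two-group t-test", {
  a <- anova_site_type(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 13.5)          # SSB = 13.5, SSW/4 = 1
  expect_equal(a$df, c(1, 4))

  set.seed(2)
  x <- rnorm(14)
  g <- rep(c("A", "B"), each = 7)
  a2 <- anova_site_type(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)

  # equal group means -> F = 0
  expect_equal(anova_site_type(c(1, 3, 1, 3), c("A", "A", "B", "B"))$F, 0)
  expect_error(anova_site_type(1:3, c("A", "A", "B")), ">= 2")
})

test_that("ANOVA p-values are approximately uniform under the null", {
  set.seed(33)
  x <- rnorm(18)
  g <- rep(c("A", "B", "C"), each = 6)
  p <- replicate(400, anova_site_type(x, sample(g))$p)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
})

test_that("squared Pearson matrix is symmetric, bounded and affine-invariant", {
  x <- c(1, 2, 3, 4, 5)
  m <- squared_pearson_matrix(data.frame(x = x, y = 3 * x + 1,
                                         z = c(2, 1, 4, 3, 5)))
  expect_equal(m["x", "y"], 1)
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))

  orth <- squared_pearson_matrix(data.frame(a = c(1, 0, -1, 0),
                                            b = c(0, 1, 0, -1)))
  expect_equal(orth["a", "b"], 0)

  set.seed(5)
  r <- as.data.frame(matrix(rnorm(60), ncol = 4))
  mr <- squared_pearson_matrix(r)
  expect_equal(mr, t(mr))
  expect_true(all(mr >= 0 & mr <= 1 + 1e-12))

  expect_error(squared_pearson_matrix(data.frame(a = rep(1, 5), b = 1:5)),
               "variance")
  expect_error(squared_pearson_matrix(data.frame(a = 1:2, b = 2:1)),
               "3 complete pairs")
})

test_that("pairwise-complete correlations use sites with both values present", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, 8, 100)
  m <- squared_pearson_matrix(data.frame(x = x, y = y))
  expect_equal(m["x", "y"], 1)  # the NA row (with y's outlier) is dropped
})

test_that("the contrast report bundles all Table-style statistics", {
  camp <- generate_campaign(campaign_config(seed = 8))
  pc <- prep_campaign(camp)
  rep_ <- contrast_report(pc$y$OP_ESR, camp$sites$site_type)
  expect_s3_class(rep_, "contrast_report")
  expect_equal(nrow(rep_$descriptives), 3)
  expect_true(all(rep_$ratios$ratio > 0))
  expect_gte(rep_$range_percent, 0)
  expect_output(print(rep_), "ANOVA")
})
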