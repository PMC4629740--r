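test_that("adjusted R2 follows the standard small-sample correction", {
  expect_equal(adjusted_r2(0.6, 40, 0), 0.6)
  expect_equal(adjusted_r2(0.6, 40, 4), 1 - 0.4 * 39 / 35)
  expect_equal(adjusted_r2(1, 40, 4), 1)
  expect_error(adjusted_r2(0.5, 5, 4), "degenerate")
})

test_that("zero-value screening drops predictors beyond the strict threshold", {
  n <- 40
  cols <- list(ok = runif(n) + 1,
               thirty = c(rep(0, 30), runif(10) + 1),
               thirtyone = c(rep(0, 31), runif(9) + 1))
  tab <- make_table(cols, c("+", "+", "+"))
  kept <- screen_predictors(tab, max_zero_sites = 30)
  expect_setequal(predictor_names(kept), c("ok", "thirty"))
  expect_error(screen_predictors(tab, max_zero_sites = -1), "all predictors")
  # default threshold generalizes 30-of-40
  expect_equal(ceiling(0.75 * n), 30)
})

test_that("forward selection finds an exact single-predictor model and stops", {
  set.seed(14)
  n <- 20
  x1 <- runif(n); x2 <- rnorm(n); x3 <- rnorm(n)
  tab <- make_table(list(x1 = x1, x2 = x2, x3 = x3), c("+", "+", "+"))
  m <- forward_select(2 * x1, tab)
  expect_equal(m$terms$predictor, "x1")
  expect_equal(m$terms$slope, 2, tolerance = 1e-10)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-10)
})

test_that("direction constraints exclude sign-contradicting candidates", {
  set.seed(15)
  x <- runif(12)
  tab <- make_table(list(x = x), "+")
  m <- forward_select(-3 * x + rnorm(12, 0, 0.01), tab)
  expect_equal(nrow(m$terms), 0)
  expect_equal(m$intercept, mean(m$y))
})

test_that("greedy steps match exhaustive candidate enumeration", {
  for (s in 1:6) {
    set.seed(100 + s)
    n <- 15
    cols <- list(a = runif(n), b = rnorm(n), c = rexp(n), d = rnorm(n))
    dirs <- c("+", "+", "-", "+")
    y <- 1 + 2 * cols$a - 0.5 * cols$c + rnorm(n, 0, 0.5)
    tab <- make_table(cols, dirs)
    m <- forward_select(y, tab)
    expect_identical(m$terms$predictor, greedy_oracle(y, tab))
  }
})

test_that("p-value pruning removes noise terms and recovers true slopes", {
  set.seed(16)
  n <- 25
  x1 <- runif(n); x2 <- runif(n); junk <- rnorm(n)
  y <- 1 + 2 * x1 + 3 * x2
  tab <- make_table(list(x1 = x1, x2 = x2, junk = junk), c("+", "+", "+"))
  m <- lur_model(y, tab, c("x1", "x2", "junk"))
  pruned <- prune_pvalues(m)
  expect_setequal(pruned$terms$predictor, c("x1", "x2"))
  expect_equal(sort(pruned$terms$slope), c(2, 3), tolerance = 1e-8)

  # models already satisfying the threshold are unchanged
  m2 <- forward_select(y, make_table(list(x1 = x1, x2 = x2), c("+", "+")))
  expect_identical(prune_pvalues(m2)$terms$predictor, m2$terms$predictor)

  # empty model passes through
  empty <- forward_select(rnorm(n), make_table(list(x1 = x1), "-"))
  expect_equal(nrow(prune_pvalues(empty)$terms), 0)
})

test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(17)
  # two predictors with known sample correlation: closed form 1/(1 - r^2)
  n <- 30
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
  v <- vif(data.frame(a = a, b = b))
  r2 <- cor(a, b)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)

  # orthogonal centered columns
  x <- matrix(rnorm(60), ncol = 3)
  x <- qr.Q(qr(scale(x, scale = FALSE)))
  expect_equal(unname(vif(as.data.frame(x))), rep(1, 3), tolerance = 1e-8)

  expect_equal(unname(vif(data.frame(a = a))), 1)
  expect_true(is.infinite(max(vif(data.frame(a = a, b = a)))))
})

test_that("VIF agrees with an independent implementation", {
  skip_if_not_installed("car")
  set.seed(18)
  d <- as.data.frame(matrix(rnorm(80), ncol = 4)) * rep(c(1, 5, 10, 2), each = 20)
  names(d) <- letters[1:4]
  d$b <- d$b + 2 * d$a
  y <- rnorm(20)
  ref <- car::vif(lm(y ~ a + b + c + d, data = cbind(d, y = y)))
  expect_equal(unname(vif(d)), unname(ref), tolerance = 1e-8)
})

test_that("VIF pruning redevelops the model without the collinear offender", {
  set.seed(19)
  n <- 30
  base <- runif(n)
  twin <- base + rnorm(n, 0, 0.02)       # near-duplicate, VIF >> 3
  other <- runif(n)
  y <- 1 + 2 * base + 1.5 * other + rnorm(n, 0, 0.1)
  tab <- make_table(list(base = base, twin = twin, other = other),
                    c("+", "+", "+"))
  m <- prune_pvalues(forward_select(y, tab, delta = 1e-6))
  out <- prune_vif(m, threshold = 3)
  if (length(out$terms$predictor) >= 2) {
    expect_lte(max(vif(out$table$data[, out$terms$predictor])), 3)
  }
  expect_false(all(c("base", "twin") %in% out$terms$predictor))

  # a clean model is untouched
  tab2 <- make_table(list(base = base, other = other), c("+", "+"))
  m2 <- prune_pvalues(forward_select(y, tab2))
  expect_identical(prune_vif(m2)$terms, m2$terms)
})

test_that("Cook's distance flags single gross outliers only", {
  set.seed(20)
  n <- 15
  x <- runif(n)
  yv <- 1 + 2 * x
  tab <- make_table(list(x = x), "+")
  clean <- forward_select(yv, tab)
  expect_equal(cooks_d(clean)$max, 0)

  y2 <- yv; y2[7] <- y2[7] + 10
  dirty <- lur_model(y2, tab, "x")
  cd <- cooks_d(dirty)
  expect_equal(unname(which.max(cd$d)), 7)
  expect_true(cd$flag)
})

test_that("standardized coefficients scale by the P90 - P10 spread", {
  vals <- seq(0, 1, length.out = 11)  # p10 = 0.1, p90 = 0.9
  tab <- make_table(list(x = vals), "+")
  m <- forward_select(2 * vals, tab)
  st <- standardize_coefficients(m)
  expect_equal(st$std_coef, 2 * 0.8, tolerance = 1e-9)
  expect_equal(st$p10, 0.1); expect_equal(st$p90, 0.9)

  degen <- make_table(list(x = vals, z = rep(5, 11)), c("+", "+"))
  m2 <- m; m2$terms$predictor <- "z"; m2$percentiles <- predictor_percentiles(degen)
  expect_error(standardize_coefficients(m2), "degenerate")
})

test_that("predictions obey OLS identities", {
  set.seed(22)
  n <- 20
  cols <- list(a = runif(n), b = runif(n))
  y <- 1 + cols$a + 2 * cols$b + rnorm(n, 0, 0.2)
  tab <- make_table(cols, c("+", "+"))
  m <- prune_pvalues(forward_select(y, tab, delta = 1e-9))
  # at the training rows, R2 against y equals model_r2
  pr <- predict(m, tab)
  expect_equal(cor(pr, m$y)^2, m$model_r2, tolerance = 1e-10)
  # at the predictor means, the prediction is the mean response
  centre <- data.frame(t(colMeans(tab$data[m$terms$predictor])))
  expect_equal(as.numeric(predict(m, centre)), mean(y), tolerance = 1e-10)
  # empty model predicts the training mean everywhere
  empty <- forward_select(rnorm(n), make_table(list(a = cols$a), "-"))
  expect_equal(as.numeric(predict(empty, tab)), rep(mean(empty$y), n))
  expect_error(predict(m, data.frame(a = 1)), "missing predictor")
})

test_that("selection path logs candidates with acceptance decisions", {
  set.seed(23)
  n <- 20
  cols <- list(a = runif(n), b = rnorm(n))
  y <- 2 * cols$a + rnorm(n, 0.1)
  m <- forward_select(y, make_table(cols, c("+", "+")))
  path <- m$selection_path
  expect_true(all(c("step", "candidate", "adj_r2", "eligible", "accepted")
                  %in% names(path)))
  expect_equal(sum(path$accepted), nrow(m$terms))
})
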