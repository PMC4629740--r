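test_that("blank correction is plain subtraction with flagged retention", {
  expect_equal(blank_correct(850, 850), 0)
  expect_equal(blank_correct(0.12, 0.12), 0)
  expect_equal(blank_correct(1.00, 0.12), 0.88)
  # negative results are retained, not clipped
  expect_equal(blank_correct(0.05, 0.12), -0.07)
  expect_error(blank_correct(1, -0.1), "blank_mean")
})

test_that("temporal adjustment subtracts the reference's signed deviation", {
  expect_equal(temporal_adjust(5, 6, 4), 3)
  expect_equal(temporal_adjust(5, 4, 4), 5)   # reference at its mean
  # corrections over the reference's own periods sum to zero
  ref <- c(2, 5, 8)
  corr <- ref - mean(ref)
  expect_equal(sum(corr), 0)
  expect_equal(mean(temporal_adjust(ref, ref, mean(ref))), mean(ref))
})

flat_reference <- function(periods, metric = "M", value = 1) {
  data.frame(period_id = periods, metric = metric, value = value,
             stringsAsFactors = FALSE)
}

test_that("annual averages are means of adjusted values", {
  meas <- data.frame(site_id = "a", period_id = c("P1", "P2", "P3"),
                     metric = "M", value = c(1, 2, 3))
  out <- adjusted_annual_averages(meas, flat_reference(c("P1", "P2", "P3")))
  expect_equal(out$value, 2)
  expect_equal(out$n_periods_used, 3L)

  # sites measured in a subset of periods use available periods only
  meas2 <- rbind(meas, data.frame(site_id = "b", period_id = "P2",
                                  metric = "M", value = 10))
  out2 <- adjusted_annual_averages(meas2, flat_reference(c("P1", "P2", "P3")))
  expect_equal(out2$n_periods_used[out2$site_id == "b"], 1L)
})

test_that("noiseless campaigns recover the true annual means exactly", {
  met <- default_metric_params(noise_sd = c(OP_DTT = 0, OP_ESR = 0))
  camp <- generate_campaign(campaign_config(seed = 9, metrics = met))
  pc <- prep_campaign(camp)
  for (m in c("OP_DTT", "OP_ESR")) {
    expect_equal(unname(pc$y[[m]]), camp$truth$annual_means[[m]],
                 tolerance = 1e-10)
  }
})

test_that("a period-wide shift moves all sites identically (contrasts invariant)", {
  camp <- generate_campaign(campaign_config(seed = 4))
  blanks <- c(OP_DTT = 0.12, OP_ESR = 850)
  base <- adjusted_annual_averages(camp$measurements, camp$reference, blanks)

  delta <- 100
  per <- camp$measurements$period_id[1]
  meas <- camp$measurements
  meas$value[meas$period_id == per] <- meas$value[meas$period_id == per] + delta
  ref <- camp$reference
  ref$value[ref$period_id == per] <- ref$value[ref$period_id == per] + delta
  shifted <- adjusted_annual_averages(meas, ref, blanks)

  for (m in c("OP_DTT", "OP_ESR")) {
    b <- base$value[base$metric == m]
    s <- shifted$value[shifted$metric == m]
    # every site moves by the same constant ...
    expect_equal(diff(range(s - b)), 0, tolerance = 1e-9)
    # ... so between-site contrasts are exactly unchanged
    expect_equal(s - mean(s), b - mean(b), tolerance = 1e-9)
  }

  # with the reference annual mean held at its full-year value, the
  # adjustment is exactly invariant
  ann_fixed <- vapply(names(blanks), function(m) {
    r <- camp$reference[camp$reference$metric == m, ]
    mean(r$value) - blanks[[m]]
  }, numeric(1))
  base_f <- adjusted_annual_averages(camp$measurements, camp$reference, blanks,
                                     reference_annual_means = ann_fixed)
  shifted_f <- adjusted_annual_averages(meas, ref, blanks,
                                        reference_annual_means = ann_fixed)
  expect_equal(shifted_f$value, base_f$value, tolerance = 1e-9)
})

test_that("record order does not change the outputs", {
  camp <- generate_campaign(campaign_config(seed = 6))
  blanks <- c(OP_DTT = 0.12, OP_ESR = 850)
  a <- adjusted_annual_averages(camp$measurements, camp$reference, blanks)
  set.seed(1)
  shuf <- camp$measurements[sample(nrow(camp$measurements)), ]
  b <- adjusted_annual_averages(shuf, camp$reference, blanks)
  key <- function(x) x[order(x$metric, x$site_id), c("site_id", "metric", "value")]
  expect_equal(key(a)$value, key(b)$value, tolerance = 1e-12)
})

test_that("blank correction commutes with temporal adjustment", {
  # correcting measurements and reference by the same blank before adjusting
  # equals adjusting raw values first and subtracting the blank afterwards
  v <- c(5, 7); refv <- c(6, 4); blank <- 0.5
  ann <- mean(refv)
  a <- temporal_adjust(v - blank, refv - blank, ann - blank)
  b <- temporal_adjust(v, refv, ann) - blank
  expect_equal(a, b)
})

test_that("schema violations in measurement input are rejected", {
  ref <- flat_reference(c("P1"))
  meas <- data.frame(site_id = "a", period_id = "P1", metric = "M", value = 1)
  expect_error(adjusted_annual_averages(rbind(meas, meas), ref), "duplicate")
  meas2 <- data.frame(site_id = "a", period_id = "P9", metric = "M", value = 1)
  expect_error(adjusted_annual_averages(meas2, ref), "P9")
  expect_error(adjusted_annual_averages(meas[0, ], ref), "no measurement")
})
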