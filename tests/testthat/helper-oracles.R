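# Independent, deliberately naive re-implementations used as oracles, plus
# small fixture builders shared across test files.

# Run a campaign through preprocessing and regional background, returning the
# pieces most tests need.
prep_campaign <- function(camp) {
  blanks <- vapply(camp$config$metrics, function(p) p$blank_mean, numeric(1))
  ann <- adjusted_annual_averages(camp$measurements, camp$reference,
                                  blank_means = blanks)
  w <- annual_wide(ann)
  w <- w[match(camp$sites$site_id, w$site_id), , drop = FALSE]
  reg <- regional_background(camp$sites, ann)
  tabs <- lapply(setNames(names(camp$config$metrics), names(camp$config$metrics)),
                 function(m) {
    rm_ <- reg[reg$metric == m, ]
    add_predictor(camp$predictors, paste0("regional_estimate_", m),
                  setNames(rm_$estimate, rm_$site_id), "+",
                  units = camp$config$metrics[[m]]$units)
  })
  list(annual = ann, wide = w, regional = reg, tables = tabs,
       y = lapply(setNames(names(tabs), names(tabs)),
                  function(m) setNames(w[[m]], w$site_id)))
}

# A small predictor table from a named list of columns and a direction vector.
make_table <- function(cols, directions, site_ids = NULL) {
  n <- length(cols[[1]])
  if (is.null(site_ids)) site_ids <- sprintf("s%02d", seq_len(n))
  data <- cbind(data.frame(site_id = site_ids, stringsAsFactors = FALSE),
                as.data.frame(cols))
  meta <- data.frame(name = names(cols), buffer = NA_real_,
                     direction = directions, units = "",
                     stringsAsFactors = FALSE)
  predictor_table(data, meta)
}

# Naive supervised forward selection: at every step enumerate all remaining
# candidates with lm(), keep those whose trial fit respects every a-priori
# direction, and take the largest adjusted R2 if it improves by more than
# delta. Written independently of the package internals (plain data frames,
# explicit loops, stats-only).
greedy_oracle <- function(y, table, delta = 0.01) {
  df <- table$data
  dirs <- setNames(ifelse(table$meta$direction == "+", 1, -1),
                   table$meta$name)
  chosen <- character(0)
  current <- 0
  n <- length(y)
  repeat {
    remaining <- setdiff(table$meta$name, chosen)
    if (!length(remaining)) break
    best <- NULL
    for (cand in sort(remaining)) {
      vars <- c(chosen, cand)
      fit <- lm(reformulate(sprintf("`%s`", vars), response = "yy"),
                data = cbind(df, yy = y))
      b <- coef(fit)[-1]
      if (anyNA(b)) next
      if (!all(sign(b) == dirs[vars])) next
      r2 <- summary(fit)$r.squared
      adj <- 1 - (1 - r2) * (n - 1) / (n - length(vars) - 1)
      co <- summary(fit)$coefficients
      rn <- gsub("`", "", rownames(co))
      tval <- abs(co[match(cand, rn), 3])
      if (is.null(best) || adj > best$adj + 1e-12 ||
          (abs(adj - best$adj) <= 1e-12 && tval > best$tval)) {
        best <- list(cand = cand, adj = adj, tval = tval)
      }
    }
    if (is.null(best) || best$adj - current <= delta) break
    chosen <- c(chosen, best$cand)
    current <- best$adj
  }
  chosen
}

# Naive leave-one-out loop: refit the fixed term set with lm() on n-1 rows.
loocv_oracle <- function(y, table, terms) {
  df <- table$data
  preds <- numeric(length(y))
  for (i in seq_along(y)) {
    fit <- lm(reformulate(sprintf("`%s`", terms), response = "yy"),
              data = cbind(df[-i, ], yy = y[-i]))
    preds[i] <- predict(fit, newdata = df[i, , drop = FALSE])
  }
  preds
}

# Brute-force Moran's I: explicit double sum.
morans_oracle <- function(residuals, w) {
  e <- residuals - mean(residuals)
  n <- length(e)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * e[i] * e[j]
  (n / sum(w)) * num / sum(e^2)
}

# A noiseless, trend-free configuration: the response is an exact linear
# function of the tabulated generating predictors.
exact_config <- function(seed) {
  met <- default_metric_params(noise_sd = c(OP_DTT = 0, OP_ESR = 0))
  for (m in names(met)) met[[m]]$trend_amplitude <- 0
  campaign_config(seed = seed, metrics = met)
}
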