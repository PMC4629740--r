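#' Leave-one-out cross-validation with fixed model structure
#'
#' For each site, the coefficients of the final model's fixed predictor set
#' are re-estimated on the other N-1 sites and the held-out site is
#' predicted. The primary LOOCV R-squared is the squared Pearson correlation
#' between observations and LOOCV predictions (the convention of the ESCAPE
#' LUR literature); the variance-explained alternative
#' `1 - SSE/SST` is reported alongside, with the RMSE of prediction.
#'
#' @param model A fitted [lur_model].
#' @return List with `predictions` (named per site), `observed`, `r2`
#'   (squared correlation), `r2_mse` (1 - SSE/SST), `rmse`, `skipped`
#'   (sites whose leave-out refit was singular).
#' @export
loocv <- function(model) {
  stopifnot(inherits(model, "lur_model"))
  y <- model$y
  table <- model$table
  terms <- model$terms$predictor
  n <- length(y)
  if (n < length(terms) + 3) stop("too few sites for LOOCV of this model")
  preds <- rep(NA_real_, n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    sub <- predictor_table(table$data[-i, , drop = FALSE],
                           table$meta[, c("name", "buffer", "direction", "units")])
    fit_i <- tryCatch({
      m <- new_lur_model(y[-i], sub, terms)
      if (anyNA(coef(m$fit))) stop("singular refit")
      m
    }, error = function(e) NULL)
    if (is.null(fit_i)) {
      skipped <- c(skipped, table$data$site_id[i])
      next
    }
    preds[i] <- unname(predict(fit_i, table$data[i, , drop = FALSE]))
  }
  ok <- !is.na(preds)
  if (length(skipped)) {
    warning("LOOCV refit singular for site(s): ",
            paste(skipped, collapse = ", "))
  }
  sse <- sum((y[ok] - preds[ok])^2)
  sst <- sum((y[ok] - mean(y[ok]))^2)
  ## an intercept-only structure predicts leave-one-out means, which are a
  ## degenerate affine function of the held-out values; its squared
  ## correlation carries no information, so it is reported as 0 by convention
  r2 <- if (length(terms) == 0 || var(preds[ok]) == 0) 0 else
    cor(y[ok], preds[ok])^2
  list(predictions = setNames(preds, model$site_ids), observed = y,
       r2 = r2, r2_mse = 1 - sse / sst,
       rmse = sqrt(mean((y[ok] - preds[ok])^2)), skipped = skipped)
}

## Deterministic per-split seed: derived from the master seed by a fixed
## counter, so adding splits never changes earlier splits. Kept within the
## 32-bit integer range.
split_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}

#' Stratified 50/50 holdout splits of a site roster
#'
#' @param sites Site roster (`site_id`, `site_type`).
#' @param n_splits Number of random splits.
#' @param train_fraction Fraction of each site type assigned to training
#'   (odd counts: training gets the floor).
#' @param seed Master seed.
#' @return List of lists with `train` and `test` site-id vectors.
#' @export
holdout_splits <- function(sites, n_splits = 10, train_fraction = 0.5,
                           seed = 1L) {
  tab <- table(sites$site_type)
  if (any(tab < 2)) stop("each site type needs >= 2 sites to stratify")
  lapply(seq_len(n_splits), function(k) {
    set.seed(split_seed(seed, k))
    train <- unlist(lapply(split(sites$site_id, sites$site_type), function(ids) {
      sample(ids, floor(length(ids) * train_fraction))
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(sites$site_id, train)))
  })
}

#' Stratified holdout validation with full model redevelopment
#'
#' Repeats `n_splits` times: draw a random training set stratified by site
#' type (50% of each type by default), redevelop a model from scratch on the
#' training half with the full supervised protocol (screening, forward
#' selection, p-value and VIF pruning), and score it on the held-out half.
#' The per-split test R-squared is the squared Pearson correlation between
#' observed and predicted values (recorded as 0 when the refit model predicts
#' a constant); `hv_mean` and `hv_se` summarise the splits as mean and
#' standard error (SD over splits divided by the square root of the number of
#' splits).
#'
#' @param y Adjusted annual averages named by `site_id`.
#' @param table Candidate [predictor_table()] covering all roster sites.
#' @param sites Site roster (`site_id`, `site_type`).
#' @param n_splits Number of random splits (default 10).
#' @param train_fraction Fraction of each type in training (default 0.5).
#' @param seed Master seed for the split draws.
#' @param ... Passed to [fit_lur()] (`delta`, `alpha`, `vif_threshold`, ...).
#' @return Object of class `holdout_validation`: list with `splits`
#'   (per-split train/test ids, refit term names, train_r2, test_r2,
#'   test_r2_mse), `hv_mean`, `hv_se`, `hv_mean_mse`, `seed`.
#' @export
holdout_validation <- function(y, table, sites, n_splits = 10,
                               train_fraction = 0.5, seed = 1L, ...) {
  stopifnot(inherits(table, "predictor_table"))
  if (is.null(names(y))) names(y) <- table$data$site_id
  splits <- holdout_splits(sites, n_splits, train_fraction, seed)
  meta_cols <- c("name", "buffer", "direction", "units")
  res <- lapply(seq_along(splits), function(k) {
    sp <- splits[[k]]
    tr_tab <- predictor_table(
      table$data[table$data$site_id %in% sp$train, , drop = FALSE],
      table$meta[, meta_cols])
    te_rows <- table$data[table$data$site_id %in% sp$test, , drop = FALSE]
    m <- fit_lur(y[tr_tab$data$site_id], tr_tab, ...)
    pred <- predict(m, te_rows)
    obs <- y[te_rows$site_id]
    test_r2 <- if (length(m$terms$predictor) == 0 || var(pred) == 0) 0 else
      cor(obs, pred)^2
    sse <- sum((obs - pred)^2)
    sst <- sum((obs - mean(obs))^2)
    list(train = sp$train, test = sp$test,
         terms = m$terms$predictor, train_r2 = m$model_r2,
         test_r2 = test_r2, test_r2_mse = 1 - sse / sst)
  })
  t_r2 <- vapply(res, `[[`, numeric(1), "test_r2")
  t_r2m <- vapply(res, `[[`, numeric(1), "test_r2_mse")
  structure(list(
    splits = res,
    hv_mean = mean(t_r2),
    hv_se = sd(t_r2) / sqrt(length(t_r2)),
    hv_mean_mse = mean(t_r2m),
    seed = seed
  ), class = "holdout_validation")
}

#' @export
print.holdout_validation <- function(x, ...) {
  cat(sprintf("Holdout validation over %d stratified splits\n",
              length(x$splits)))
  cat(sprintf("  HV R2 = %.2f +/- %.2f (mean +/- SE, squared correlation)\n",
              x$hv_mean, x$hv_se))
  cat(sprintf("  HV R2 (1 - SSE/SST) = %.2f\n", x$hv_mean_mse))
  invisible(x)
}

#' Full validation report for a fitted model
#'
#' Convenience wrapper returning both evaluation approaches side by side.
#'
#' @param model A fitted [lur_model].
#' @param sites Site roster for stratified splitting.
#' @param n_splits,seed Holdout settings.
#' @param ... Passed to [fit_lur()] during holdout redevelopment.
#' @return List with `loocv` and `holdout` components.
#' @export
validation_report <- function(model, sites, n_splits = 10, seed = 1L, ...) {
  list(loocv = loocv(model),
       holdout = holdout_validation(setNames(model$y, model$site_ids),
                                    model$table, sites,
                                    n_splits = n_splits, seed = seed, ...))
}
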