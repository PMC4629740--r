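#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` — the selection criterion of the
#' supervised forward procedure.
#'
#' @param r2 Model R-squared.
#' @param n_sites Number of observations.
#' @param n_predictors Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.6, 40, 4)  # 0.5543
adjusted_r2 <- function(r2, n_sites, n_predictors) {
  if (n_sites <= n_predictors + 1) {
    stop("degenerate degrees of freedom: n_sites must exceed n_predictors + 1")
  }
  1 - (1 - r2) * (n_sites - 1) / (n_sites - n_predictors - 1)
}

## Align a response vector with a predictor table's sites. y may be named by
## site_id (any order) or positional.
align_response <- function(y, table) {
  ids <- table$data$site_id
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) {
      stop("response lacks values for site(s): ",
           paste(setdiff(ids, names(y))[1:3], collapse = ", "))
    }
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop("unnamed response must have one value per site in the table")
  }
  unname(y)
}

ols_fit <- function(y, table, terms) {
  df <- table$data[, terms, drop = FALSE]
  df$.y <- y
  lm(.y ~ ., data = df)
}

## summary() of an exact fit warns about perfect fits; those are expected on
## noiseless fixtures and handled explicitly (p := 0), so keep them quiet.
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

## slope/se/p per term from an lm fit; rownames are backtick-free term names
term_stats <- function(fit, terms) {
  co <- quiet_summary(fit)$coefficients
  rn <- gsub("`", "", rownames(co))
  idx <- match(terms, rn)
  out <- data.frame(predictor = terms,
                    slope = co[idx, 1], se = co[idx, 2],
                    t = co[idx, 3], p = co[idx, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  ## a zero-residual (exact) fit yields NaN se/t/p; such slopes are exactly
  ## determined, so they count as maximally significant
  out$p[is.nan(out$p)] <- 0
  out$t[is.nan(out$t)] <- Inf
  out
}

direction_sign <- function(table, terms) {
  ifelse(table$meta$direction[match(terms, table$meta$name)] == "+", 1, -1)
}

signs_conform <- function(fit, table, terms) {
  st <- term_stats(fit, terms)
  all(sign(st$slope) == direction_sign(table, terms))
}

#' Supervised forward selection with a-priori direction constraints
#'
#' The ESCAPE-style greedy procedure: at each step every remaining candidate
#' is fitted by OLS alongside the current terms; a candidate is eligible only
#' if, in that trial fit, its own slope and all previously entered slopes
#' keep their a-priori directions. Among eligible candidates the one
#' maximizing adjusted R-squared enters, provided the gain exceeds `delta`
#' (default 0.01); otherwise selection stops. Ties (equal adjusted R-squared
#' to machine precision) are broken by the larger absolute t statistic of the
#' entrant, then predictor name.
#'
#' @param y Response: adjusted annual averages, named by `site_id` or aligned
#'   with `table$data`.
#' @param table Screened [predictor_table()] of candidates.
#' @param delta Minimum adjusted-R-squared gain to accept a step.
#' @param blacklist Candidate names excluded from consideration (used by the
#'   VIF rerun).
#' @return A [lur_model] (pre-pruning), with the selection path in
#'   `$selection_path`.
#' @export
forward_select <- function(y, table, delta = 0.01, blacklist = character(0)) {
  stopifnot(inherits(table, "predictor_table"))
  y <- align_response(y, table)
  candidates <- setdiff(predictor_names(table), blacklist)
  if (length(candidates) == 0) stop("empty candidate set")
  n <- length(y)

  terms <- character(0)
  current_adj <- 0
  path <- list()
  repeat {
    pool <- setdiff(candidates, terms)
    if (length(pool) == 0 || n <= length(terms) + 2) break
    trial <- lapply(pool, function(cand) {
      tt <- c(terms, cand)
      fit <- ols_fit(y, table, tt)
      st <- term_stats(fit, tt)
      ok <- !anyNA(st$slope) &&
        all(sign(st$slope) == direction_sign(table, tt))
      adj <- adjusted_r2(quiet_summary(fit)$r.squared, n, length(tt))
      list(cand = cand, ok = ok, adj = adj,
           t_ent = abs(st$t[st$predictor == cand]))
    })
    ok <- vapply(trial, `[[`, logical(1), "ok")
    adj <- vapply(trial, `[[`, numeric(1), "adj")
    tent <- vapply(trial, `[[`, numeric(1), "t_ent")
    for (tr in trial) {
      path[[length(path) + 1L]] <- data.frame(
        step = length(terms) + 1L, candidate = tr$cand,
        adj_r2 = tr$adj, eligible = tr$ok, accepted = FALSE,
        stringsAsFactors = FALSE)
    }
    if (!any(ok)) break
    best_adj <- max(adj[ok])
    if (best_adj - current_adj <= delta) break
    tie <- ok & (abs(adj - best_adj) < 1e-12)
    pick <- which(tie)[order(-tent[tie], pool[tie])[1]]
    accepted_row <- which(vapply(path, function(p)
      p$step == length(terms) + 1L && p$candidate == pool[pick], logical(1)))
    path[[accepted_row]]$accepted <- TRUE
    terms <- c(terms, pool[pick])
    current_adj <- best_adj
  }
  new_lur_model(y, table, terms,
                selection_path = do.call(rbind, path))
}

#' Prune model terms by p-value (and re-checked direction)
#'
#' Iteratively removes the term with the largest p-value above `alpha`
#' (default 0.10), refitting after each removal. Direction conformity is
#' re-checked after every refit; a term whose slope flips against its
#' a-priori direction is removed the same way.
#'
#' @param model A [lur_model].
#' @param alpha Significance threshold for retention.
#' @return The pruned [lur_model] (possibly empty).
#' @export
prune_pvalues <- function(model, alpha = 0.10) {
  stopifnot(inherits(model, "lur_model"))
  y <- model$y
  table <- model$table
  terms <- model$terms$predictor
  repeat {
    if (length(terms) == 0) break
    fit <- ols_fit(y, table, terms)
    st <- term_stats(fit, terms)
    bad_sign <- sign(st$slope) != direction_sign(table, terms)
    if (any(bad_sign)) {
      terms <- terms[-which(bad_sign)[which.max(st$p[bad_sign])]]
      next
    }
    if (any(st$p > alpha)) {
      terms <- terms[-which.max(st$p)]
      next
    }
    break
  }
  new_lur_model(y, table, terms, selection_path = model$selection_path)
}

#' Remove collinear terms and redevelop the model
#'
#' If any VIF of the final model exceeds `threshold` (default 3), the term
#' with the largest VIF is blacklisted and the whole supervised selection
#' (forward selection followed by p-value pruning) is rerun on the remaining
#' candidate pool; this repeats until all VIFs are at or below the threshold.
#'
#' @param model A [lur_model] produced by [forward_select()] /
#'   [prune_pvalues()].
#' @param threshold Maximum tolerated VIF.
#' @param delta,alpha Selection and pruning thresholds for the reruns.
#' @return A [lur_model] whose terms all have VIF at or below `threshold`.
#' @export
prune_vif <- function(model, threshold = 3, delta = 0.01, alpha = 0.10) {
  stopifnot(inherits(model, "lur_model"))
  blacklist <- character(0)
  repeat {
    terms <- model$terms$predictor
    if (length(terms) < 2) break
    v <- vif(model$table$data[, terms, drop = FALSE])
    if (max(v) <= threshold) break
    blacklist <- c(blacklist, names(v)[which.max(v)])
    model <- prune_pvalues(
      forward_select(model$y, model$table, delta = delta,
                     blacklist = blacklist),
      alpha = alpha)
  }
  model
}

#' Construct a LUR model from a prescribed term set
#'
#' Fits OLS for an explicitly ordered set of predictors — useful for applying
#' the pruning operations to a hand-specified model, or for refitting a known
#' structure on new data. [forward_select()] and [fit_lur()] build their
#' results through the same constructor.
#'
#' @param y Response, named by `site_id` or aligned with `table$data`.
#' @param table A [predictor_table()].
#' @param terms Character vector of predictor names, in entry order (may be
#'   empty for an intercept-only model).
#' @return A `lur_model`: intercept, per-term statistics (slope, SE, p,
#'   cumulative adjusted R2 at each entry step), fit measures, VIFs and the
#'   training data.
#' @export
lur_model <- function(y, table, terms = character(0)) {
  stopifnot(inherits(table, "predictor_table"))
  missing_terms <- setdiff(terms, predictor_names(table))
  if (length(missing_terms)) {
    stop("terms not in the predictor table: ",
         paste(missing_terms, collapse = ", "))
  }
  new_lur_model(align_response(y, table), table, terms)
}

## Internal worker: refits the final OLS for an ordered term set, computes
## per-term statistics, the cumulative adjusted R2 at each entry step (in
## final term order), fit measures and VIFs.
new_lur_model <- function(y, table, terms, selection_path = NULL) {
  n <- length(y)
  if (length(terms) == 0) {
    fit <- lm(y ~ 1, data = data.frame(y = y))
    tstats <- data.frame(predictor = character(0), slope = numeric(0),
                         se = numeric(0), t = numeric(0), p = numeric(0),
                         cum_adj_r2 = numeric(0))
    r2 <- 0
    adj <- 0
  } else {
    fit <- ols_fit(y, table, terms)
    tstats <- term_stats(fit, terms)
    tstats$cum_adj_r2 <- vapply(seq_along(terms), function(k) {
      f <- ols_fit(y, table, terms[seq_len(k)])
      adjusted_r2(quiet_summary(f)$r.squared, n, k)
    }, numeric(1))
    r2 <- quiet_summary(fit)$r.squared
    adj <- adjusted_r2(r2, n, length(terms))
  }
  vifs <- if (length(terms) >= 1) {
    vif(table$data[, terms, drop = FALSE])
  } else numeric(0)
  structure(list(
    intercept = unname(coef(fit)[1]),
    terms = tstats,
    model_r2 = r2,
    adjusted_r2 = adj,
    rmse = sqrt(mean(residuals(fit)^2)),
    n = n,
    site_ids = table$data$site_id,
    vif = vifs,
    percentiles = predictor_percentiles(table),
    y = y,
    table = table,
    fit = fit,
    selection_path = selection_path,
    diagnostics = NULL
  ), class = "lur_model")
}

#' Fit a complete supervised LUR model
#'
#' Runs the whole model-development protocol for one metric: zero-value
#' screening, direction-constrained forward selection, p-value pruning,
#' VIF-based redevelopment, and the influence (Cook's D) and spatial
#' autocorrelation (Moran's I) diagnostics.
#'
#' @param y Adjusted annual averages, named by `site_id` or aligned with
#'   `table$data`.
#' @param table Candidate [predictor_table()] (including any regional
#'   background estimate added via [add_predictor()]).
#' @param sites Optional site roster (for Moran's I of the residuals).
#' @param delta Minimum adjusted-R-squared gain per selection step.
#' @param alpha p-value threshold for term retention.
#' @param vif_threshold Maximum tolerated variance inflation factor.
#' @param max_zero_sites Zero-value screening threshold (see
#'   [screen_predictors()]).
#' @param weight_scheme Moran's I spatial weight scheme (see
#'   [spatial_weights()]).
#' @return A `lur_model` with `$diagnostics` filled in.
#' @export
fit_lur <- function(y, table, sites = NULL, delta = 0.01, alpha = 0.10,
                    vif_threshold = 3,
                    max_zero_sites = ceiling(0.75 * nrow(table$data)),
                    weight_scheme = "idw") {
  table <- screen_predictors(table, max_zero_sites)
  model <- forward_select(y, table, delta = delta)
  model <- prune_pvalues(model, alpha = alpha)
  model <- prune_vif(model, threshold = vif_threshold, delta = delta,
                     alpha = alpha)
  diags <- list(max_vif = if (length(model$vif)) max(model$vif) else NA_real_)
  if (length(model$terms$predictor) > 0) {
    cd <- cooks_d(model)
    diags$cooks_d <- cd$d
    diags$max_cooks_d <- cd$max
    diags$cooks_flag <- cd$flag
  }
  if (!is.null(sites)) {
    sites_ord <- sites[match(model$site_ids, sites$site_id), , drop = FALSE]
    res <- if (length(model$terms$predictor)) residuals(model$fit) else
      model$y - mean(model$y)
    diags$morans_i <- tryCatch(
      morans_i(res, sites_ord, weights = weight_scheme),
      error = function(e) NULL)
  }
  model$diagnostics <- diags
  model
}

#' Standardized coefficients (P90 minus P10 convention)
#'
#' Reports each raw slope multiplied by the difference between the 90th and
#' 10th percentile of its predictor over the training sites, so coefficients
#' express the concentration contrast associated with a typical predictor
#' range; standard errors are scaled identically and the intercept is
#' reported unscaled.
#'
#' @param model A [lur_model].
#' @param table Optional [predictor_table()] supplying the percentiles
#'   (defaults to the model's training table).
#' @return data.frame with columns `predictor`, `slope`, `se`, `p`,
#'   `p10`, `p90`, `std_coef`, `std_se`, `cum_adj_r2`.
#' @export
standardize_coefficients <- function(model, table = NULL) {
  stopifnot(inherits(model, "lur_model"))
  pct <- if (is.null(table)) model$percentiles else predictor_percentiles(table)
  st <- model$terms
  idx <- match(st$predictor, pct$name)
  if (anyNA(idx)) stop("percentiles missing for some model predictors")
  spread <- pct$p90[idx] - pct$p10[idx]
  if (any(spread == 0)) {
    stop("degenerate predictor (P90 == P10): ",
         paste(st$predictor[spread == 0], collapse = ", "))
  }
  data.frame(predictor = st$predictor, slope = st$slope, se = st$se,
             p = st$p, p10 = pct$p10[idx], p90 = pct$p90[idx],
             std_coef = st$slope * spread, std_se = st$se * spread,
             cum_adj_r2 = st$cum_adj_r2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict concentrations at receptor sites
#'
#' `intercept + sum(raw slope * predictor value)` for each receptor row.
#' Negative predicted concentrations are retained but flagged via the
#' `"negative"` attribute.
#'
#' @param object A [lur_model].
#' @param newdata A [predictor_table()] or data.frame containing all model
#'   predictor columns (ignored terms are fine).
#' @param ... Unused.
#' @return Numeric predictions (named by `site_id` when available), with
#'   attribute `negative` marking sites predicted below zero.
#' @export
predict.lur_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$table
  df <- if (inherits(newdata, "predictor_table")) newdata$data else newdata
  terms <- object$terms$predictor
  missing_col <- setdiff(terms, names(df))
  if (length(missing_col)) {
    stop("missing predictor column(s): ", paste(missing_col, collapse = ", "))
  }
  pred <- rep(object$intercept, nrow(df))
  for (k in seq_along(terms)) {
    pred <- pred + object$terms$slope[k] * df[[terms[k]]]
  }
  if (!is.null(df$site_id)) names(pred) <- df$site_id
  attr(pred, "negative") <- which(pred < 0)
  pred
}

#' @export
print.lur_model <- function(x, digits = 3, ...) {
  cat(sprintf("Supervised LUR model (n = %d sites)\n", x$n))
  if (nrow(x$terms) == 0) {
    cat("  <empty model: intercept only>\n")
    cat(sprintf("  intercept %.4g\n", x$intercept))
    return(invisible(x))
  }
  st <- standardize_coefficients(x)
  show <- data.frame(predictor = st$predictor,
                     std_coef = signif(st$std_coef, digits),
                     se = signif(st$std_se, digits),
                     p = signif(st$p, 2),
                     cum_adj_r2 = round(st$cum_adj_r2, 2))
  print(show, row.names = FALSE)
  cat(sprintf("  intercept %.4g (unscaled)\n", x$intercept))
  cat(sprintf("  Model R2 = %.2f; adjusted R2 = %.2f; RMSE = %.3g\n",
              x$model_r2, x$adjusted_r2, x$rmse))
  if (!is.null(x$diagnostics$max_vif) && !is.na(x$diagnostics$max_vif)) {
    cat(sprintf("  max VIF = %.2f", x$diagnostics$max_vif))
    if (!is.null(x$diagnostics$max_cooks_d)) {
      cat(sprintf("; max Cook's D = %.2f", x$diagnostics$max_cooks_d))
    }
    mi <- x$diagnostics$morans_i
    if (!is.null(mi)) {
      cat(sprintf("; Moran's I = %.3f (p = %.2f)", mi$I, mi$p))
    }
    cat("\n")
  }
  invisible(x)
}
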