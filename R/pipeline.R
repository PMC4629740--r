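#' Run the full campaign-to-model pipeline
#'
#' Chains every stage for each requested metric: obtain data (simulate a
#' synthetic campaign or read CSV tables), blank-correct and temporally
#' adjust to annual averages, compute site-type contrasts and the
#' between-metric correlation matrix, interpolate the regional background and
#' offer it as a candidate predictor, develop the supervised LUR model, and
#' validate it by LOOCV and stratified holdout. All artifacts are written to
#' `out_dir` when given, and a human-readable summary is printed.
#'
#' @param config A list (or path to a YAML file, parsed with the `yaml`
#'   package) with elements:
#'   \describe{
#'     \item{simulate}{list of [campaign_config()] arguments, or `TRUE` for
#'       defaults; mutually exclusive with `input_dir`.}
#'     \item{input_dir}{directory of campaign CSVs for [read_campaign()].}
#'     \item{metrics}{metrics to model (default: all present).}
#'     \item{delta, alpha, vif_threshold, max_zero_fraction}{selection and
#'       pruning thresholds (defaults 0.01, 0.10, 3, 0.75).}
#'     \item{n_splits}{holdout splits (default 10).}
#'     \item{seed}{master seed (default 1).}
#'     \item{out_dir}{optional artifact directory.}
#'   }
#' @param quiet Suppress the printed summary.
#' @return List with `campaign`, `annual`, `contrasts`, `correlations`,
#'   `regional`, `models`, `validation` (per metric), invisibly when printed.
#' @export
run_pipeline <- function(config = list(simulate = TRUE), quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  delta <- config$delta %||% 0.01
  alpha <- config$alpha %||% 0.10
  vif_threshold <- config$vif_threshold %||% 3
  zero_frac <- config$max_zero_fraction %||% 0.75
  n_splits <- config$n_splits %||% 10

  ## --- data stage -----------------------------------------------------
  campaign <- if (!is.null(config$input_dir)) {
    read_campaign(config$input_dir)
  } else {
    args <- if (isTRUE(config$simulate) || is.null(config$simulate)) {
      list()
    } else config$simulate
    if (is.null(args$seed)) args$seed <- seed
    generate_campaign(do.call(campaign_config, args))
  }
  blanks <- blank_levels(campaign)
  metrics <- config$metrics %||% unique(campaign$measurements$metric)

  ## --- preprocessing --------------------------------------------------
  annual <- adjusted_annual_averages(
    campaign$measurements[campaign$measurements$metric %in% metrics, ],
    campaign$reference, blank_means = blanks)
  wide <- annual_wide(annual)
  site_order <- campaign$sites$site_id
  wide <- wide[match(site_order, wide$site_id), , drop = FALSE]

  ## --- spatial contrast -----------------------------------------------
  contrasts <- lapply(setNames(metrics, metrics), function(m) {
    contrast_report(wide[[m]], campaign$sites$site_type)
  })
  correlations <- if (length(metrics) >= 2) {
    squared_pearson_matrix(wide[metrics])
  } else NULL

  ## --- regional background + candidate table --------------------------
  regional <- regional_background(campaign$sites, annual)
  tables <- lapply(setNames(metrics, metrics), function(m) {
    rm_ <- regional[regional$metric == m, ]
    add_predictor(campaign$predictors, paste0("regional_estimate_", m),
                  setNames(rm_$estimate, rm_$site_id),
                  direction = "+",
                  units = campaign$config$metrics[[m]]$units %||% "")
  })

  ## --- model development + validation ----------------------------------
  models <- list()
  validation <- list()
  for (m in metrics) {
    y <- setNames(wide[[m]], wide$site_id)
    models[[m]] <- fit_lur(y, tables[[m]], sites = campaign$sites,
                           delta = delta, alpha = alpha,
                           vif_threshold = vif_threshold,
                           max_zero_sites = ceiling(zero_frac * length(y)))
    validation[[m]] <- list(
      loocv = loocv(models[[m]]),
      holdout = holdout_validation(y, tables[[m]], campaign$sites,
                                   n_splits = n_splits, seed = seed,
                                   delta = delta, alpha = alpha,
                                   vif_threshold = vif_threshold))
  }

  out <- list(campaign = campaign, annual = annual, contrasts = contrasts,
              correlations = correlations, regional = regional,
              models = models, validation = validation)

  if (!is.null(config$out_dir)) write_artifacts(out, config$out_dir)
  if (!quiet) print_pipeline_summary(out)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Field-blank levels: from the generating config for synthetic campaigns,
## zero otherwise (user-supplied tables are assumed already blank-corrected
## unless blanks are passed through a simulate config).
blank_levels <- function(campaign) {
  mets <- unique(campaign$measurements$metric)
  if (!is.null(campaign$config)) {
    vapply(setNames(mets, mets), function(m) {
      b <- campaign$config$metrics[[m]]$blank_mean
      if (is.null(b)) 0 else b
    }, numeric(1))
  } else {
    setNames(rep(0, length(mets)), mets)
  }
}

write_artifacts <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$annual, file.path(dir, "annual_averages.csv"),
            row.names = FALSE)
  write.csv(out$regional, file.path(dir, "regional_background.csv"),
            row.names = FALSE)
  cr <- do.call(rbind, lapply(names(out$contrasts), function(m) {
    r <- out$contrasts[[m]]
    data.frame(metric = m, contrast = r$ratios$contrast,
               ratio = r$ratios$ratio, p_value = r$ratios$p_value,
               range_percent = r$range_percent,
               anova_F = r$anova$F, anova_p = r$anova$p)
  }))
  write.csv(cr, file.path(dir, "contrast_report.csv"), row.names = FALSE)
  if (!is.null(out$correlations)) {
    write.csv(out$correlations, file.path(dir, "correlations.csv"))
  }
  for (m in names(out$models)) {
    write_lur_model(out$models[[m]], file.path(dir, paste0("model_", m, ".json")))
    v <- out$validation[[m]]
    jsonlite::write_json(list(
      loocv = v$loocv[c("r2", "r2_mse", "rmse")],
      holdout = list(hv_mean = v$holdout$hv_mean, hv_se = v$holdout$hv_se,
                     hv_mean_mse = v$holdout$hv_mean_mse,
                     seed = v$holdout$seed)
    ), file.path(dir, paste0("validation_", m, ".json")),
    digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

print_pipeline_summary <- function(out) {
  cat("== OP LUR pipeline summary ==\n")
  for (m in names(out$contrasts)) {
    r <- out$contrasts[[m]]
    cat(sprintf("\n-- %s --\n", m))
    cat(sprintf("Spatial contrast: range %.0f%% of the mean; ANOVA p = %.3g\n",
                r$range_percent, r$anova$p))
    for (i in seq_len(nrow(r$ratios))) {
      cat(sprintf("  ratio %-6s = %.2f (p = %.3g)\n", r$ratios$contrast[i],
                  r$ratios$ratio[i], r$ratios$p_value[i]))
    }
    print(out$models[[m]])
    v <- out$validation[[m]]
    cat(sprintf("  Model R2 %.2f / LOOCV R2 %.2f / RMSE %.3g / HV R2 %.2f +/- %.2f\n",
                out$models[[m]]$model_r2, v$loocv$r2, v$loocv$rmse,
                v$holdout$hv_mean, v$holdout$hv_se))
  }
  if (!is.null(out$correlations)) {
    cat("\nSquared Pearson correlations between metrics:\n")
    print(round(out$correlations, 2))
  }
  invisible(out)
}
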