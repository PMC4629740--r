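#' Write a campaign to a directory of plain-text tables
#'
#' Writes `sites.csv`, `measurements.csv`, `predictors.csv`,
#' `predictor_meta.csv`, `reference.csv` and `truth.json` (UTF-8,
#' comma-separated, header row, "." decimal).
#'
#' @param campaign A [generate_campaign()] result (or a list with the same
#'   `sites`/`measurements`/`predictors`/`reference` elements).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(campaign$sites, "sites.csv")
  wr(campaign$measurements, "measurements.csv")
  wr(campaign$predictors$data, "predictors.csv")
  wr(campaign$predictors$meta, "predictor_meta.csv")
  wr(campaign$reference, "reference.csv")
  if (!is.null(campaign$truth)) {
    jsonlite::write_json(
      list(slopes = campaign$truth$slopes,
           intercepts = as.list(campaign$truth$intercepts),
           annual_means = campaign$truth$annual_means),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read and validate campaign tables
#'
#' Reads the standard CSV set written by [write_campaign()] (or prepared by
#' hand) and validates the schema: required columns, unique site ids, known
#' site types, measurements referencing known sites, and no duplicate
#' (site, period, metric) records. Errors name the offending rows or columns.
#'
#' @param dir Directory holding `sites.csv`, `measurements.csv`,
#'   `predictors.csv`, `predictor_meta.csv` and `reference.csv`.
#' @return List with `sites`, `measurements`, `predictors` (a
#'   [predictor_table()]) and `reference`.
#' @export
read_campaign <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    read.csv(path, stringsAsFactors = FALSE)
  }
  sites <- rd("sites.csv")
  need_site <- c("site_id", "site_type", "x", "y")
  if (!all(need_site %in% names(sites))) {
    stop("sites.csv must have columns ", paste(need_site, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id in sites.csv: ",
         sites$site_id[duplicated(sites$site_id)][1])
  }
  bad_type <- setdiff(unique(sites$site_type), c("RB", "UB", "S"))
  if (length(bad_type)) {
    stop("unknown site type(s) in sites.csv: ",
         paste(bad_type, collapse = ", "), " (expected RB, UB, S)")
  }

  meas <- rd("measurements.csv")
  need_meas <- c("site_id", "period_id", "metric", "value")
  if (!all(need_meas %in% names(meas))) {
    stop("measurements.csv must have columns ",
         paste(need_meas, collapse = ", "))
  }
  if (nrow(meas) == 0) stop("measurements.csv contains no records")
  unknown <- setdiff(unique(meas$site_id), sites$site_id)
  if (length(unknown)) {
    stop("measurement(s) reference unknown site id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  dup <- duplicated(meas[c("site_id", "period_id", "metric")])
  if (any(dup)) {
    stop("duplicate (site, period, metric) in measurements.csv, e.g. ",
         paste(meas[which(dup)[1], c("site_id", "period_id", "metric")],
               collapse = "/"))
  }
  if (!"below_lod" %in% names(meas)) meas$below_lod <- FALSE

  pred <- rd("predictors.csv")
  meta <- rd("predictor_meta.csv")
  pt <- predictor_table(pred, meta)

  ref <- rd("reference.csv")
  if (!all(c("period_id", "metric", "value") %in% names(ref))) {
    stop("reference.csv must have columns period_id, metric, value")
  }
  list(sites = sites, measurements = meas, predictors = pt, reference = ref)
}

#' Serialize a fitted LUR model to JSON
#'
#' Writes the intercept, ordered terms with raw and standardized slopes,
#' percentile spreads, fit measures and diagnostics — everything needed to
#' apply the model elsewhere via [read_lur_model()].
#'
#' @param model A [lur_model].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lur_model <- function(model, path) {
  st <- if (nrow(model$terms)) standardize_coefficients(model) else NULL
  mi <- model$diagnostics$morans_i
  jsonlite::write_json(list(
    intercept = model$intercept,
    terms = st,
    model_r2 = model$model_r2,
    adjusted_r2 = model$adjusted_r2,
    rmse = model$rmse,
    n = model$n,
    site_ids = model$site_ids,
    diagnostics = list(
      max_vif = model$diagnostics$max_vif,
      max_cooks_d = model$diagnostics$max_cooks_d,
      morans_i = if (!is.null(mi)) mi[c("I", "expectation", "p")]
    )
  ), path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized LUR model
#'
#' Restores a [lur_model] written by [write_lur_model()] to a functional
#' object supporting [predict.lur_model()] and [compare_predictions()] (the
#' training response and candidate table are not round-tripped; refitting
#' operations are unavailable on a restored model).
#'
#' @param path JSON path written by [write_lur_model()].
#' @return A `lur_model`.
#' @export
read_lur_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- if (is.null(j$terms)) {
    data.frame(predictor = character(0), slope = numeric(0), se = numeric(0),
               t = numeric(0), p = numeric(0), cum_adj_r2 = numeric(0))
  } else {
    data.frame(predictor = j$terms$predictor, slope = j$terms$slope,
               se = j$terms$se, t = NA_real_, p = j$terms$p,
               cum_adj_r2 = j$terms$cum_adj_r2, stringsAsFactors = FALSE)
  }
  structure(list(
    intercept = j$intercept, terms = terms, model_r2 = j$model_r2,
    adjusted_r2 = j$adjusted_r2, rmse = j$rmse, n = j$n,
    site_ids = j$site_ids, vif = NULL,
    percentiles = if (!is.null(j$terms))
      data.frame(name = j$terms$predictor, p10 = j$terms$p10,
                 p90 = j$terms$p90, stringsAsFactors = FALSE),
    y = NULL, table = NULL, fit = NULL, selection_path = NULL,
    diagnostics = j$diagnostics
  ), class = "lur_model")
}
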