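#' Construct a predictor table
#'
#' A predictor table pairs a site-by-predictor value matrix with per-predictor
#' metadata: the GIS buffer radius (if any), the a-priori direction of effect
#' that supervised selection must respect, units, and the number of sites with
#' an exact zero value (buffer variables are frequently zero-inflated).
#'
#' @param data data.frame with a `site_id` column followed by one numeric
#'   column per predictor.
#' @param meta data.frame with columns `name`, `buffer` (m, `NA` for
#'   non-buffer variables), `direction` (`"+"` or `"-"`), `units`. A
#'   `zero_count` column is (re)computed from `data`.
#' @return An object of class `predictor_table`: a list with elements `data`
#'   and `meta`.
#' @export
#' @examples
#' pt <- predictor_table(
#'   data.frame(site_id = c("a", "b"), road = c(100, 0)),
#'   data.frame(name = "road", buffer = 500, direction = "+", units = "m")
#' )
#' pt$meta$zero_count
predictor_table <- function(data, meta) {
  stopifnot(is.data.frame(data), is.data.frame(meta))
  if (!"site_id" %in% names(data)) stop("predictor data must have a site_id column")
  if (anyDuplicated(data$site_id)) stop("duplicate site_id in predictor data")
  vars <- setdiff(names(data), "site_id")
  if (anyDuplicated(vars)) stop("duplicate predictor column names")
  missing_meta <- setdiff(vars, meta$name)
  if (length(missing_meta)) {
    stop("predictors without metadata: ", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(vars, meta$name), , drop = FALSE]
  if (!all(meta$direction %in% c("+", "-"))) {
    stop("direction must be '+' or '-' for every predictor")
  }
  for (v in vars) {
    if (!is.numeric(data[[v]])) stop("predictor column ", v, " is not numeric")
    if (anyNA(data[[v]])) stop("missing values in predictor column ", v)
  }
  meta$zero_count <- vapply(vars, function(v) sum(data[[v]] == 0), integer(1))
  rownames(meta) <- NULL
  structure(list(data = data, meta = meta), class = "predictor_table")
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("Predictor table: %d sites x %d predictors\n",
              nrow(x$data), nrow(x$meta)))
  print(x$meta)
  invisible(x)
}

#' Predictor names of a predictor table
#' @param table A [predictor_table()].
#' @return Character vector of predictor column names.
#' @export
predictor_names <- function(table) {
  stopifnot(inherits(table, "predictor_table"))
  table$meta$name
}

#' Drop zero-inflated predictors
#'
#' Buffer variables that are zero at most monitoring sites carry almost no
#' contrast and destabilise selection; following the campaign protocol,
#' predictors with more than `max_zero_sites` exact zeros are removed before
#' model development. The default threshold generalises the classic
#' "more than 30 of 40 sites" rule to `ceiling(0.75 * N)`.
#'
#' @param table A [predictor_table()].
#' @param max_zero_sites Strict threshold: predictors with
#'   `zero_count > max_zero_sites` are dropped.
#' @return The screened `predictor_table`.
#' @export
screen_predictors <- function(table, max_zero_sites = ceiling(0.75 * nrow(table$data))) {
  stopifnot(inherits(table, "predictor_table"))
  keep <- table$meta$zero_count <= max_zero_sites
  if (!any(keep)) stop("all predictors dropped by the zero-value screen")
  predictor_table(table$data[, c("site_id", table$meta$name[keep]), drop = FALSE],
                  table$meta[keep, , drop = FALSE])
}

#' Per-predictor 10th and 90th percentiles
#'
#' Percentiles use the linear-interpolation quantile convention
#' (`stats::quantile`, type 7) over the table's sites; these feed the
#' standardized-coefficient convention (slope times P90 minus P10).
#'
#' @param table A [predictor_table()].
#' @return data.frame with columns `name`, `p10`, `p90`.
#' @export
predictor_percentiles <- function(table) {
  stopifnot(inherits(table, "predictor_table"))
  qs <- t(vapply(table$meta$name, function(v) {
    quantile(table$data[[v]], c(0.1, 0.9), names = FALSE, type = 7)
  }, numeric(2)))
  data.frame(name = table$meta$name, p10 = qs[, 1], p90 = qs[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Add a predictor column to a predictor table
#'
#' Used to offer derived candidates — most importantly the interpolated
#' regional background estimate — to the selection alongside the GIS
#' variables.
#'
#' @param table A [predictor_table()].
#' @param name Predictor name.
#' @param values Numeric values, one per site, in the order of
#'   `table$data$site_id` (or named by site id).
#' @param direction A-priori direction of effect, `"+"` or `"-"`.
#' @param units Units string.
#' @param buffer Buffer radius in meters, or `NA`.
#' @return The extended `predictor_table`.
#' @export
add_predictor <- function(table, name, values, direction, units = "", buffer = NA_real_) {
  stopifnot(inherits(table, "predictor_table"))
  if (name %in% table$meta$name) stop("predictor ", name, " already present")
  if (!is.null(names(values))) values <- values[table$data$site_id]
  if (length(values) != nrow(table$data)) {
    stop("values must have one entry per site")
  }
  d <- table$data
  d[[name]] <- unname(values)
  m <- rbind(table$meta[, c("name", "buffer", "direction", "units")],
             data.frame(name = name, buffer = buffer, direction = direction,
                        units = units, stringsAsFactors = FALSE))
  predictor_table(d, m)
}
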