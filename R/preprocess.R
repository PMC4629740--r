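#' Blank-correct a raw OP measurement
#'
#' Subtracts the mean field-blank level from a raw assay value. Negative and
#' below-detection results are retained (the campaign convention is to flag,
#' not drop, such values), so this is plain subtraction with a sanity check on
#' the blank.
#'
#' @param value Raw concentration(s), metric units.
#' @param blank_mean Mean field blank in the same units; must be >= 0.
#' @return `value - blank_mean`.
#' @export
#' @examples
#' blank_correct(850, 850)   # OP_ESR at the blank level -> 0
#' blank_correct(1.00, 0.12) # OP_DTT
blank_correct <- function(value, blank_mean) {
  if (any(blank_mean < 0)) stop("blank_mean must be >= 0")
  value - blank_mean
}

#' Temporally adjust a measurement against the reference site
#'
#' Each two-week measurement is corrected by the contemporaneous deviation of
#' the continuously monitored reference site from its annual mean:
#' `adjusted = value - (reference_value - reference_annual_mean)`. The
#' correction is a signed additive term — a period in which the reference ran
#' above its annual mean pulls co-measured sites down, and vice versa — so
#' corrections over the reference's own periods sum to zero.
#'
#' @param value Measurement value(s) (blank-corrected).
#' @param reference_value Reference-site value for the same period(s), on the
#'   same correction state (blank-corrected if `value` is).
#' @param reference_annual_mean Annual mean of the reference series.
#' @return Adjusted value(s).
#' @export
#' @examples
#' temporal_adjust(5, 6, 4)  # reference ran 2 above its mean -> 3
temporal_adjust <- function(value, reference_value, reference_annual_mean) {
  value - (reference_value - reference_annual_mean)
}

#' Build a reference series object
#'
#' @param reference data.frame with columns `period_id`, `metric`, `value`
#'   (raw reference measurements).
#' @param blank_means Named vector of per-metric blank levels to subtract
#'   (use 0 if the series is already corrected).
#' @return data.frame with columns `period_id`, `metric`, `value`
#'   (blank-corrected) plus an `annual_mean` attribute-free companion: the
#'   per-metric annual mean is recomputed where needed as the arithmetic mean
#'   of the period values.
#' @keywords internal
blank_correct_reference <- function(reference, blank_means) {
  reference$value <- reference$value -
    unname(blank_means[reference$metric])
  reference
}

#' Adjusted annual averages per site and metric
#'
#' Applies blank correction and reference-site temporal adjustment to every
#' measurement record, then averages the adjusted values per site and metric.
#' Records flagged below the limit of detection are retained. Sites with
#' measurements in only a subset of periods are averaged over the available
#' periods, with the count recorded.
#'
#' @param measurements data.frame with columns `site_id`, `period_id`,
#'   `metric`, `value` and optionally `below_lod`.
#' @param reference data.frame with columns `period_id`, `metric`, `value`:
#'   the reference-site series, raw (same blank convention as
#'   `measurements`). Must cover every period present in `measurements`.
#' @param blank_means Named numeric vector of per-metric field-blank levels
#'   (e.g. `c(OP_DTT = 0.12, OP_ESR = 850)`); defaults to zero for every
#'   metric.
#' @param reference_annual_means Optional named per-metric annual means of the
#'   blank-corrected reference series. By default the arithmetic mean of the
#'   supplied reference period values is used; pass explicit values when the
#'   reference's full-year mean is known from a longer series than supplied.
#' @return data.frame with columns `site_id`, `metric`, `value`,
#'   `n_periods_used`.
#' @export
adjusted_annual_averages <- function(measurements, reference,
                                     blank_means = NULL,
                                     reference_annual_means = NULL) {
  need <- c("site_id", "period_id", "metric", "value")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "))
  }
  if (!all(c("period_id", "metric", "value") %in% names(reference))) {
    stop("reference must have columns period_id, metric, value")
  }
  if (nrow(measurements) == 0) stop("no measurement records supplied")
  metrics <- unique(measurements$metric)
  if (is.null(blank_means)) {
    blank_means <- setNames(rep(0, length(metrics)), metrics)
  }
  missing_blank <- setdiff(metrics, names(blank_means))
  if (length(missing_blank)) {
    stop("no blank level for metric(s): ", paste(missing_blank, collapse = ", "))
  }
  dup <- duplicated(measurements[c("site_id", "period_id", "metric")])
  if (any(dup)) {
    stop("duplicate (site, period, metric) record(s), e.g. ",
         paste(measurements$site_id[dup][1], measurements$period_id[dup][1],
               measurements$metric[dup][1]))
  }

  ref <- blank_correct_reference(reference, blank_means)
  out <- list()
  for (m in metrics) {
    rm_ <- ref[ref$metric == m, ]
    ann <- if (!is.null(reference_annual_means) &&
               m %in% names(reference_annual_means)) {
      reference_annual_means[[m]]
    } else {
      mean(rm_$value)
    }
    mm <- measurements[measurements$metric == m, ]
    missing_per <- setdiff(unique(mm$period_id), rm_$period_id)
    if (length(missing_per)) {
      stop("reference series for ", m, " lacks period(s): ",
           paste(missing_per, collapse = ", "))
    }
    corrected <- blank_correct(mm$value, blank_means[[m]])
    adjusted <- temporal_adjust(
      corrected, rm_$value[match(mm$period_id, rm_$period_id)], ann)
    agg <- tapply(adjusted, mm$site_id, mean)
    cnt <- tapply(adjusted, mm$site_id, length)
    out[[m]] <- data.frame(site_id = names(agg), metric = m,
                           value = as.numeric(agg),
                           n_periods_used = as.integer(cnt),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape annual averages to one column per metric
#'
#' @param annual Output of [adjusted_annual_averages()].
#' @return data.frame with `site_id` and one numeric column per metric.
#' @export
annual_wide <- function(annual) {
  ids <- unique(annual$site_id)
  out <- data.frame(site_id = ids, stringsAsFactors = FALSE)
  for (m in unique(annual$metric)) {
    sub <- annual[annual$metric == m, ]
    out[[m]] <- sub$value[match(ids, sub$site_id)]
  }
  out
}
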