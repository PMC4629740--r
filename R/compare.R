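#' Compare model predictions at held-out receptor sites
#'
#' Applies two or more fitted LUR models to a common receptor set that was
#' used in none of their training rosters and returns the pairwise squared
#' Pearson correlation matrix of the prediction vectors — the standard way to
#' ask whether two exposure models can be disentangled in an epidemiological
#' analysis.
#'
#' @param models Named list of [lur_model] objects (>= 2).
#' @param receptors A [predictor_table()] or data.frame with `site_id` and
#'   all predictor columns any compared model uses. No receptor may appear in
#'   any model's training roster.
#' @return Squared-correlation matrix with model names on both dimensions.
#' @export
compare_predictions <- function(models, receptors) {
  if (length(models) < 2) stop("need at least 2 models to compare")
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  df <- if (inherits(receptors, "predictor_table")) receptors$data else receptors
  if (nrow(df) < 3) stop("need at least 3 receptor sites")
  if (!is.null(df$site_id)) {
    for (nm in names(models)) {
      overlap <- intersect(df$site_id, models[[nm]]$site_ids)
      if (length(overlap)) {
        stop("receptor(s) present in training roster of ", nm, ": ",
             paste(head(overlap, 3), collapse = ", "))
      }
    }
  }
  preds <- vapply(models, function(m) as.numeric(predict(m, df)),
                  numeric(nrow(df)))
  squared_pearson_matrix(preds)
}
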