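#' Inverse-distance-weighted estimate at a target site
#'
#' Interpolates a value at `target` from donor sites with weights
#' `d^-power` (squared distance by default), after removing the target itself
#' from the donor set if present (matched by `site_id`). Distances are
#' Euclidean on the planar coordinates. If a remaining donor coincides
#' exactly with the target (distance 0) the estimate is that donor's value
#' (the exact-interpolation limit); ties among several coincident donors
#' return their mean.
#'
#' @param target One-row data.frame with `x`, `y` and optionally `site_id`.
#' @param donors data.frame with columns `site_id`, `x`, `y`, `value`.
#' @param power Positive exponent of the inverse distance weight (2 = the
#'   classic inverse-distance-squared scheme).
#' @return List with `estimate` and `n_donors`.
#' @export
#' @examples
#' donors <- data.frame(site_id = c("a", "b"), x = c(1, 2), y = 0,
#'                      value = c(10, 40))
#' idw_estimate(data.frame(x = 0, y = 0), donors)$estimate  # 16
idw_estimate <- function(target, donors, power = 2) {
  if (power < 0) stop("power must be non-negative")
  if (!is.null(target$site_id) && "site_id" %in% names(donors)) {
    donors <- donors[donors$site_id != target$site_id, , drop = FALSE]
  }
  if (nrow(donors) == 0) stop("empty donor set after excluding the target")
  d <- sqrt((donors$x - target$x)^2 + (donors$y - target$y)^2)
  if (any(d == 0)) {
    return(list(estimate = mean(donors$value[d == 0]),
                n_donors = sum(d == 0)))
  }
  w <- d^(-power)
  list(estimate = sum(w * donors$value) / sum(w), n_donors = nrow(donors))
}

#' Regional background estimates for every site
#'
#' The regional background of a metric at each site is the
#' inverse-distance-squared interpolation of the annual averages measured at
#' the regional background sites, excluding the site itself when it is
#' regional. The estimate is offered downstream as an ordinary LUR candidate
#' predictor with a-priori direction `+`.
#'
#' @param sites Site roster (`site_id`, `site_type`, `x`, `y`).
#' @param annual Annual averages in long form (`site_id`, `metric`, `value`)
#'   as from [adjusted_annual_averages()].
#' @param power Inverse-distance exponent (default 2).
#' @return data.frame with columns `site_id`, `metric`, `estimate`,
#'   `n_donors`.
#' @export
regional_background <- function(sites, annual, power = 2) {
  rb <- sites[sites$site_type == "RB", , drop = FALSE]
  if (nrow(rb) == 0) stop("no regional background sites in the roster")
  out <- list()
  for (m in unique(annual$metric)) {
    am <- annual[annual$metric == m, ]
    donors <- merge(rb, am[, c("site_id", "value")], by = "site_id")
    if (nrow(donors) == 0) stop("no regional annual averages for metric ", m)
    est <- lapply(seq_len(nrow(sites)), function(i) {
      idw_estimate(sites[i, ], donors, power = power)
    })
    out[[m]] <- data.frame(
      site_id = sites$site_id, metric = m,
      estimate = vapply(est, `[[`, numeric(1), "estimate"),
      n_donors = vapply(est, `[[`, numeric(1), "n_donors"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
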