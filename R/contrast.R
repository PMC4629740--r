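#' Range as a percentage of the mean
#'
#' The campaign's summary of spatial contrast: `100 * (max - min) / mean`.
#'
#' @param values Numeric vector of site annual averages (>= 2 values, positive
#'   mean).
#' @return Percentage of the mean spanned by the range.
#' @export
#' @examples
#' range_percent(c(1, 2, 3))  # 100
range_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for a concentration range percent")
  100 * (max(values) - min(values)) / m
}

#' Site-type concentration ratios from a log-linear model
#'
#' Ratios between street (S), urban background (UB) and regional background
#' (RB) sites are estimated by regressing `log(value)` on site type and
#' exponentiating the slopes. With UB as the reference level, the S and RB
#' slopes give the S/UB and RB/UB ratios directly; the S/RB ratio comes from
#' a refit with RB as reference so it carries its own standard error.
#' p-values are two-sided t-tests on the log-scale slopes.
#'
#' @param values Positive annual averages, one per site.
#' @param site_type Character/factor of site types (`"RB"`, `"UB"`, `"S"`),
#'   aligned with `values`.
#' @return data.frame with columns `contrast`, `ratio`, `p_value`.
#' @export
site_type_ratios <- function(values, site_type) {
  if (any(values <= 0)) stop("all values must be positive (log ratio model)")
  site_type <- as.character(site_type)
  tab <- table(site_type)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 site types with >= 2 sites each")
  }
  fit_ref <- function(ref) {
    f <- factor(site_type, levels = c(ref, setdiff(unique(site_type), ref)))
    quiet_summary(lm(log(values) ~ f))$coefficients
  }
  rows <- list()
  grab <- function(coefs, level, ref) {
    rn <- paste0("f", level)
    if (!rn %in% rownames(coefs)) return(NULL)
    data.frame(contrast = paste0(level, "/", ref),
               ratio = exp(coefs[rn, 1]), p_value = coefs[rn, 4],
               stringsAsFactors = FALSE)
  }
  co_ub <- fit_ref("UB")
  rows$s_ub <- grab(co_ub, "S", "UB")
  rows$rb_ub <- grab(co_ub, "RB", "UB")
  if (all(c("S", "RB") %in% site_type)) {
    rows$s_rb <- grab(fit_ref("RB"), "S", "RB")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of annual averages across site types
#'
#' Fixed-effects one-way analysis of variance testing whether mean annual
#' OP differs between site types.
#'
#' @inheritParams site_type_ratios
#' @return List with elements `F`, `p`, `df` (numerator, denominator).
#' @export
anova_site_type <- function(values, site_type) {
  site_type <- as.character(site_type)
  tab <- table(site_type)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  a <- anova(lm(values ~ factor(site_type)))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df = c(a$Df[1], a$Df[2]))
}

#' Squared Pearson correlation matrix
#'
#' Pairwise squared Pearson correlations between aligned site-level vectors
#' (e.g. the two OP metrics plus co-measured pollutants), computed over sites
#' where both members of a pair are present. The diagonal is 1.
#'
#' @param columns data.frame or matrix of aligned numeric site-level vectors
#'   (one column per variable).
#' @return Symmetric matrix of squared correlations.
#' @export
squared_pearson_matrix <- function(columns) {
  x <- as.matrix(columns)
  if (!is.numeric(x)) stop("all columns must be numeric")
  npair <- crossprod(!is.na(x))
  if (any(npair < 3)) stop("need >= 3 complete pairs for every cell")
  vzero <- apply(x, 2, function(col) var(col, na.rm = TRUE) == 0)
  if (any(vzero)) {
    stop("zero variance in column(s): ",
         paste(colnames(x)[vzero], collapse = ", "))
  }
  r2 <- cor(x, use = "pairwise.complete.obs")^2
  diag(r2) <- 1
  r2
}

#' Site-type contrast report for one metric
#'
#' Bundles the descriptive statistics by site type, the overall spatial
#' contrast (range as a percentage of the mean), the one-way ANOVA and the
#' log-linear site-type ratios.
#'
#' @inheritParams site_type_ratios
#' @return Object of class `contrast_report`: list with `descriptives`
#'   (per-type mean/median/p25/p75/min/max/n), `range_percent`, `anova`,
#'   `ratios`.
#' @export
contrast_report <- function(values, site_type) {
  site_type <- as.character(site_type)
  desc <- do.call(rbind, lapply(split(values, site_type), function(v) {
    data.frame(n = length(v), mean = mean(v), median = median(v),
               p25 = quantile(v, 0.25, names = FALSE),
               p75 = quantile(v, 0.75, names = FALSE),
               min = min(v), max = max(v))
  }))
  desc <- cbind(site_type = rownames(desc), desc)
  rownames(desc) <- NULL
  structure(list(
    descriptives = desc,
    range_percent = range_percent(values),
    anova = anova_site_type(values, site_type),
    ratios = site_type_ratios(values, site_type)
  ), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, digits = 3, ...) {
  cat("Site-type contrast report\n")
  print(x$descriptives, digits = digits)
  cat(sprintf("Range: %.0f%% of the mean; ANOVA F(%d,%d) = %.2f, p = %.3g\n",
              x$range_percent, x$anova$df[1], x$anova$df[2], x$anova$F,
              x$anova$p))
  print(x$ratios, digits = digits)
  invisible(x)
}
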