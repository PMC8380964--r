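# Pearson correlation of region-mean NH with clinical variables within the
# patient group, with pairwise-complete deletion and the exact t-based
# two-sided p-value.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r on pairwise-complete observations and the two-sided p
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A perfect correlation returns the smallest positive representable p.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list: `r`, `p`, `n` (pairwise-complete count).
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, p = p, n = n)
}

#' Correlate region-mean NH with clinical variables
#'
#' One Pearson test per (region, variable) pair, within the subjects whose
#' group matches `group_filter` (the patient group by convention). Missing
#' phenotype values are dropped pairwise and the effective n recorded. No
#' multiple-testing adjustment is applied by default; `adjust = "BH"`
#' appends a Benjamini-Hochberg column.
#'
#' @param features Region feature table from [extract_region_means()]
#'   (column `subject_id` plus one numeric column per region).
#' @param pheno Phenotype data.frame with columns `subject_id`, `group`,
#'   and the clinical variables.
#' @param variables Character vector of phenotype columns to test.
#' @param group_filter Group label to keep (default "patient").
#' @param adjust "none" (default) or "BH".
#' @return A data.frame of class `correlation_table`: region, variable, n,
#'   r, p (and p_adj when requested).
#' @export
correlate_regions_with_clinical <- function(features, pheno, variables,
                                            group_filter = "patient",
                                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  missing_vars <- setdiff(variables, names(pheno))
  if (length(missing_vars))
    stop("unknown variable(s) ", paste(missing_vars, collapse = ", "),
         "; available: ",
         paste(setdiff(names(pheno), c("subject_id", "group")),
               collapse = ", "))
  merged <- merge(features, pheno, by = "subject_id", sort = FALSE)
  merged <- merged[merged$group == group_filter, , drop = FALSE]
  if (nrow(merged) < 3L)
    stop("fewer than 3 subjects remain after group filtering")
  regions <- setdiff(names(features), "subject_id")
  rows <- list()
  for (rg in regions) for (v in variables) {
    res <- pearson_with_pvalue(merged[[rg]], merged[[v]])
    rows[[length(rows) + 1L]] <-
      data.frame(region = rg, variable = v, n = res$n, r = res$r,
                 p = res$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("correlation_table", "data.frame")
  out
}
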