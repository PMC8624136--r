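## Pearson correlation screening of spectral indices against yields and
## stress tolerance indices.
##
## With n genotype-level observations, a sample correlation r is flagged
## significant at level alpha when |r| >= t* / sqrt(t*^2 + n - 2), the
## two-tailed critical value with t* the (1 - alpha/2) quantile of the t
## distribution on n - 2 degrees of freedom. At n = 64, alpha = 0.05 the
## threshold is 0.25 (2 d.p.). Significant correlations are banded as
## weak (< 0.50), moderate (0.50-0.70) and strong (>= 0.70) by |r|.

#' Critical two-tailed Pearson correlation
#'
#' @param n number of paired observations (>= 3).
#' @param alpha two-tailed significance level.
#' @return the smallest |r| significant at `alpha`.
#' @export
#' @examples
#' critical_r(64) # ~0.246 (0.25 at 2 d.p.)
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) halo_abort("need n >= 3", "halotype_bad_n")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Correlation strength category
#'
#' Bands a correlation by absolute value: `ns` below the critical
#' threshold for `n`, then `weak` (< 0.50), `moderate` (0.50 to < 0.70)
#' and `strong` (>= 0.70); boundaries fall in the higher category.
#'
#' @param r Pearson correlation(s), |r| <= 1.
#' @param n number of paired observations.
#' @param alpha significance level for the `ns` cut.
#' @return character vector in `{ns, weak, moderate, strong}`.
#' @export
strength_category <- function(r, n, alpha = 0.05) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    halo_abort("|r| must be <= 1", "halotype_bad_r")
  }
  rc <- critical_r(n, alpha)
  a <- abs(r)
  ifelse(is.na(a), NA_character_,
    ifelse(a < rc, "ns",
      ifelse(a < 0.50, "weak",
        ifelse(a < 0.70, "moderate", "strong")
      )
    )
  )
}

#' Genotype-mean SRI values within a scope
#'
#' Averages plot-level index values to one value per genotype for the
#' requested spectral-measurement treatment and year scope.
#'
#' @param sri long index table from [compute_sri()].
#' @param treatment spectral measurement treatment (`"control"` or
#'   `"salinity"`).
#' @param year a trial year, or `"combined"` for the mean across years.
#' @return wide data.frame: `genotype` then one column per index.
#' @export
sri_genotype_means <- function(sri, treatment = "control",
                               year = "combined") {
  check_treatment(treatment)
  d <- sri[sri$treatment == treatment, ]
  if (!identical(year, "combined")) d <- d[d$year == year, ]
  if (nrow(d) == 0L) {
    halo_abort("no index values in the requested scope", "halotype_bad_scope")
  }
  agg <- stats::aggregate(value ~ genotype + index, data = d, FUN = mean,
                          na.action = stats::na.omit)
  wide <- stats::reshape(agg, idvar = "genotype", timevar = "index",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$genotype), ]
}

#' Correlation table of indices against yield and tolerance targets
#'
#' Pearson correlations of genotype-mean index values (within the given
#' spectral scope) against each target column, with the critical-r
#' significance flag and strength category. A constant column yields an
#' undefined cell (`NA` with `note = "constant"`), never a silent zero.
#'
#' @param sri long index table from [compute_sri()].
#' @param targets data.frame with a `genotype` column and numeric target
#'   columns (e.g. an [sti_table()]).
#' @param treatment spectral measurement treatment of the scope.
#' @param year trial year or `"combined"`.
#' @param alpha significance level.
#' @return long data.frame: `index`, `target`, `r`, `n`, `significant`,
#'   `strength`, `note`, plus attributes `treatment` and `year`.
#' @export
correlation_table <- function(sri, targets, treatment = "control",
                              year = "combined", alpha = 0.05) {
  means <- sri_genotype_means(sri, treatment = treatment, year = year)
  merged <- merge(means, targets, by = "genotype")
  idx_names <- setdiff(names(means), "genotype")
  tgt_names <- setdiff(names(targets), "genotype")
  if (nrow(merged) < 3L) {
    halo_abort("need >= 3 paired genotype observations", "halotype_bad_n")
  }
  grid <- expand.grid(index = idx_names, target = tgt_names,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- merged[[grid$index[i]]]
    y <- merged[[grid$target[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(
        index = grid$index[i], target = grid$target[i],
        r = NA_real_, n = n, significant = NA, strength = NA_character_,
        note = if (n >= 3L) "constant" else "insufficient n"
      ))
    }
    r <- stats::cor(x, y)
    data.frame(
      index = grid$index[i], target = grid$target[i], r = r, n = n,
      significant = abs(r) >= critical_r(n, alpha),
      strength = strength_category(r, n, alpha),
      note = NA_character_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "treatment") <- treatment
  attr(out, "year") <- year
  out
}
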