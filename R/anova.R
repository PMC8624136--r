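## Per-year fixed-effects split-plot analysis of variance.
##
## The field layout is a randomized complete block design with a
## split-plot arrangement: salinity treatment on main plots within each
## block (replicate), genotypes on subplots. The classical balanced
## decomposition with r blocks, a main-plot levels and b subplot levels:
##
##   source      df               tested against
##   Rep         r - 1            Error_a
##   ST          a - 1            Error_a (Rep x ST)
##   Error_a     (r-1)(a-1)
##   G           b - 1            Error_b
##   ST x G      (a-1)(b-1)       Error_b
##   Error_b     a(r-1)(b-1)
##   Total       rab - 1
##
## Whole-plot effects are tested against the Rep x ST interaction
## (Error_a); subplot effects against the residual (Error_b).

#' Split-plot analysis of variance
#'
#' Computes the balanced split-plot decomposition for one response, with
#' the main-plot F test against Error_a and the subplot tests against
#' Error_b. Only balanced layouts (one observation per replicate x
#' treatment x genotype cell) are supported.
#'
#' @param data data.frame with columns `replicate` (block), `treatment`
#'   (main-plot factor), `genotype` (subplot factor) and the response.
#' @param response name of the response column (default `"grain_yield"`).
#' @return data.frame of class `splitplot_anova` with rows `Rep`, `ST`,
#'   `Error_a`, `G`, `ST:G`, `Error_b`, `Total` and columns `df`, `ss`,
#'   `ms`, `f`, `p`, `code`.
#' @export
#' @examples
#' d <- expand.grid(replicate = 1:2, treatment = c("control", "salinity"),
#'                  genotype = c("A", "B", "C"))
#' d$grain_yield <- rnorm(nrow(d), 5)
#' splitplot_anova(d)
splitplot_anova <- function(data, response = "grain_yield") {
  need <- c("replicate", "treatment", "genotype", response)
  if (!all(need %in% names(data))) {
    halo_abort(
      paste("data must have columns", paste(need, collapse = ", ")),
      "halotype_bad_layout"
    )
  }
  rep_f <- factor(data$replicate)
  st_f <- factor(data$treatment)
  g_f <- factor(data$genotype)
  y <- data[[response]]
  r <- nlevels(rep_f)
  a <- nlevels(st_f)
  b <- nlevels(g_f)
  counts <- table(rep_f, st_f, g_f)
  if (any(counts != 1L)) {
    halo_abort(
      "unbalanced layout: need exactly one observation per replicate x treatment x genotype cell",
      "halotype_unbalanced"
    )
  }
  n <- r * a * b
  ct <- sum(y)^2 / n
  ss_total <- sum(y^2) - ct
  sum_sq_means <- function(f, divisor) {
    sum(tapply(y, f, sum)^2) / divisor - ct
  }
  ss_rep <- sum_sq_means(rep_f, a * b)
  ss_st <- sum_sq_means(st_f, r * b)
  ss_ea <- sum_sq_means(interaction(rep_f, st_f), b) - ss_rep - ss_st
  ss_g <- sum_sq_means(g_f, r * a)
  ss_stg <- sum_sq_means(interaction(st_f, g_f), r) - ss_st - ss_g
  ss_eb <- ss_total - ss_rep - ss_st - ss_ea - ss_g - ss_stg
  df <- c(
    Rep = r - 1, ST = a - 1, Error_a = (r - 1) * (a - 1),
    G = b - 1, `ST:G` = (a - 1) * (b - 1),
    Error_b = a * (r - 1) * (b - 1), Total = n - 1
  )
  ss <- c(ss_rep, ss_st, ss_ea, ss_g, ss_stg, ss_eb, ss_total)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  ms[7] <- NA_real_ # no mean square for Total
  ms_ea <- ms[3]
  ms_eb <- ms[6]
  f <- c(
    Rep = ms[1] / ms_ea, ST = ms[2] / ms_ea, Error_a = NA,
    G = ms[4] / ms_eb, `ST:G` = ms[5] / ms_eb, Error_b = NA, Total = NA
  )
  err_df <- c(df[3], df[3], NA, df[6], df[6], NA, NA)
  p <- ifelse(
    is.na(f), NA_real_,
    stats::pf(f, df, err_df, lower.tail = FALSE)
  )
  out <- data.frame(
    source = names(df), df = as.integer(df), ss = ss, ms = ms,
    f = as.numeric(f), p = p, code = significance_code(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "response") <- response
  class(out) <- c("splitplot_anova", "data.frame")
  out
}

#' One-way randomized-complete-block analysis of variance
#'
#' Genotype effect on a per-replicate trait (e.g. a per-replicate stress
#' tolerance index), with replicates as blocks: sources `Rep`, `G`,
#' `Error`, `Total`; the genotype F test uses the residual.
#'
#' @param data data.frame with `replicate`, `genotype` and the response.
#' @param response name of the response column.
#' @return data.frame with columns `source`, `df`, `ss`, `ms`, `f`, `p`,
#'   `code`.
#' @export
rcbd_anova <- function(data, response) {
  rep_f <- factor(data$replicate)
  g_f <- factor(data$genotype)
  y <- data[[response]]
  r <- nlevels(rep_f)
  b <- nlevels(g_f)
  if (any(table(rep_f, g_f) != 1L)) {
    halo_abort(
      "unbalanced layout: need one observation per replicate x genotype",
      "halotype_unbalanced"
    )
  }
  n <- r * b
  ct <- sum(y)^2 / n
  ss_total <- sum(y^2) - ct
  ss_rep <- sum(tapply(y, rep_f, sum)^2) / b - ct
  ss_g <- sum(tapply(y, g_f, sum)^2) / r - ct
  ss_e <- ss_total - ss_rep - ss_g
  df <- c(Rep = r - 1, G = b - 1, Error = (r - 1) * (b - 1), Total = n - 1)
  ss <- c(ss_rep, ss_g, ss_e, ss_total)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  ms[4] <- NA_real_
  f <- c(ms[1] / ms[3], ms[2] / ms[3], NA, NA)
  p <- ifelse(is.na(f), NA_real_,
              stats::pf(f, df, df[3], lower.tail = FALSE))
  data.frame(
    source = names(df), df = as.integer(df), ss = ss, ms = ms,
    f = as.numeric(f), p = p, code = significance_code(p),
    stringsAsFactors = FALSE
  )
}
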