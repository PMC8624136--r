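## Stress tolerance indices (STIs) from control / salinity grain yields.
##
## For a genotype with mean grain yield GYc under control irrigation and
## GYs under saline irrigation (t/ha), and population mean yields mGYc,
## mGYs over all genotypes:
##
##   YSI = GYs / GYc                       (yield stability index)
##   SSI = (1 - GYs/GYc) / (1 - mGYs/mGYc) (stress susceptibility index)
##   STI = (GYc * GYs) / mGYc^2            (stress tolerance index)
##   TOL = GYc - GYs                       (tolerance index)
##   GMP = sqrt(GYc * GYs)                 (geometric mean productivity)
##
## Per-genotype GYc/GYs are means over years x replicates before any
## index is computed.

#' Population mean yields over all genotypes
#'
#' Per-genotype mean yields (over years and replicates) are averaged
#' across genotypes, separately per treatment. Genotypes missing either
#' treatment are excluded with a warning. A warning (not an error) is
#' raised if the salinity mean exceeds the control mean.
#'
#' @param yields data.frame with columns `genotype`, `treatment`
#'   (`"control"`/`"salinity"`), `year`, `replicate`, `grain_yield`
#'   (t/ha, positive).
#' @return list with `mean_gyc`, `mean_gys` and the per-genotype means
#'   table `genotype_means` (columns `genotype`, `gyc`, `gys`).
#' @export
population_means <- function(yields) {
  gm <- genotype_yield_means(yields)
  if (nrow(gm) == 0L) {
    halo_abort("no genotype has both treatments", "halotype_bad_yields")
  }
  out <- list(
    mean_gyc = mean(gm$gyc),
    mean_gys = mean(gm$gys),
    genotype_means = gm
  )
  if (out$mean_gys > out$mean_gyc) {
    halo_warn("population mean salinity yield exceeds control yield")
  }
  out
}

genotype_yield_means <- function(yields) {
  need <- c("genotype", "treatment", "grain_yield")
  if (!is.data.frame(yields) || !all(need %in% names(yields)) ||
    nrow(yields) == 0L) {
    halo_abort(
      "yields must be a non-empty data.frame with columns genotype, treatment, grain_yield",
      "halotype_bad_yields"
    )
  }
  check_treatment(yields$treatment)
  if (any(yields$grain_yield <= 0)) {
    halo_abort("grain_yield must be positive", "halotype_bad_yields")
  }
  agg <- stats::aggregate(
    grain_yield ~ genotype + treatment,
    data = yields, FUN = mean
  )
  wide <- stats::reshape(
    agg,
    idvar = "genotype", timevar = "treatment", direction = "wide"
  )
  names(wide) <- sub("grain_yield.control", "gyc", names(wide), fixed = TRUE)
  names(wide) <- sub("grain_yield.salinity", "gys", names(wide), fixed = TRUE)
  for (col in c("gyc", "gys")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- is.na(wide$gyc) | is.na(wide$gys)
  if (any(incomplete)) {
    halo_warn(sprintf(
      "%d genotype(s) missing a treatment; excluded: %s",
      sum(incomplete),
      paste(utils::head(wide$genotype[incomplete], 5), collapse = ", ")
    ))
    wide <- wide[!incomplete, ]
  }
  rownames(wide) <- NULL
  wide[order(wide$genotype), c("genotype", "gyc", "gys")]
}

#' Stress tolerance indices for one genotype
#'
#' Applies the five index formulas to one genotype's mean yields given
#' the population means. SSI is undefined when the population shows no
#' yield reduction (mGYs = mGYc).
#'
#' @param gyc genotype mean grain yield under control (t/ha, > 0).
#' @param gys genotype mean grain yield under salinity (t/ha, > 0).
#' @param means population means: a list with `mean_gyc`, `mean_gys`
#'   (as from [population_means()]).
#' @return one-row data.frame: `gyc`, `gys`, `ysi`, `ssi`, `sti`, `tol`,
#'   `gmp`.
#' @export
#' @examples
#' m <- list(mean_gyc = 5.670, mean_gys = 3.807)
#' compute_sti_row(6.23, 4.01, m)
compute_sti_row <- function(gyc, gys, means) {
  if (!is.numeric(gyc) || !is.numeric(gys) || gyc <= 0 || gys <= 0) {
    halo_abort("gyc and gys must be positive", "halotype_bad_yields")
  }
  if (means$mean_gyc <= 0 || means$mean_gys <= 0) {
    halo_abort("population means must be positive", "halotype_bad_yields")
  }
  denom <- 1 - means$mean_gys / means$mean_gyc
  if (denom == 0) {
    halo_abort(
      "SSI undefined: population mean yields are equal under both treatments",
      "halotype_undefined_ssi"
    )
  }
  data.frame(
    gyc = gyc,
    gys = gys,
    ysi = gys / gyc,
    ssi = (1 - gys / gyc) / denom,
    sti = (gyc * gys) / means$mean_gyc^2,
    tol = gyc - gys,
    gmp = sqrt(gyc * gys)
  )
}

#' Stress tolerance index table for a trial
#'
#' Computes per-genotype mean yields across years and replicates, the
#' population means, and the five stress tolerance indices for every
#' genotype with both treatments.
#'
#' @inheritParams population_means
#' @param round_digits if non-`NULL`, round the index columns half-up to
#'   this many decimals for reporting (internal values are unrounded by
#'   default).
#' @return data.frame with columns `genotype`, `gyc`, `gys`, `ysi`,
#'   `ssi`, `sti`, `tol`, `gmp`; the population means are attached as
#'   attribute `"population_means"`.
#' @export
sti_table <- function(yields, round_digits = NULL) {
  pm <- population_means(yields)
  gm <- pm$genotype_means
  rows <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
    compute_sti_row(gm$gyc[i], gm$gys[i], pm)
  }))
  out <- cbind(genotype = gm$genotype, rows)
  if (!is.null(round_digits)) {
    num <- setdiff(names(out), "genotype")
    out[num] <- lapply(out[num], round_half_up, digits = round_digits)
  }
  attr(out, "population_means") <- pm[c("mean_gyc", "mean_gys")]
  out
}

#' Per-replicate stress tolerance indices
#'
#' Pairs control and salinity plots within each genotype x year x
#' replicate cell and applies the index formulas to the paired plot
#' yields (population means from the whole table). Useful for a one-way
#' genotype analysis of variance on an index, which requires replication.
#'
#' @inheritParams population_means
#' @return data.frame: `genotype`, `year`, `replicate`, `gyc`, `gys`,
#'   `ysi`, `ssi`, `sti`, `tol`, `gmp`.
#' @export
sti_per_replicate <- function(yields) {
  pm <- population_means(yields)
  key <- c("genotype", "year", "replicate")
  ctl <- yields[yields$treatment == "control", c(key, "grain_yield")]
  sal <- yields[yields$treatment == "salinity", c(key, "grain_yield")]
  names(ctl)[4] <- "gyc"
  names(sal)[4] <- "gys"
  paired <- merge(ctl, sal, by = key)
  rows <- do.call(rbind, lapply(seq_len(nrow(paired)), function(i) {
    compute_sti_row(paired$gyc[i], paired$gys[i], pm)
  }))
  cbind(paired[key], rows)
}
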