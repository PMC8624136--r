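## Config-driven end-to-end analysis: spectra -> indices -> tolerance
## indices -> ANOVA -> grouping -> correlation screen -> stepwise
## selection -> per-group fits, plus descriptive statistics.

#' Descriptive statistics with histogram counts
#'
#' Min / max / mean of a value per group (e.g. treatment x year), plus
#' histogram bin counts for the pooled values at the given bin width.
#'
#' @param values numeric vector.
#' @param by data.frame (or list) of grouping columns aligned to
#'   `values`; `NULL` for a single group.
#' @param bin_width histogram bin width (same units as `values`).
#' @return list: `table` (one row per group: grouping columns + `min`,
#'   `max`, `mean`, `n`) and `histogram` (data.frame `bin_lo`, `bin_hi`,
#'   `count`).
#' @export
#' @examples
#' descriptive_stats(c(1, 2, 3))$table
descriptive_stats <- function(values, by = NULL, bin_width = 0.5) {
  if (length(values) == 0L) {
    halo_abort("no values", "halotype_bad_values")
  }
  if (is.null(by)) by <- data.frame(group = rep("all", length(values)))
  by <- as.data.frame(by)
  key <- interaction(by, drop = TRUE)
  if (any(tapply(values, key, length) == 0)) {
    halo_abort("empty group", "halotype_bad_values")
  }
  tab <- do.call(rbind, lapply(levels(key), function(k) {
    v <- values[key == k]
    cbind(
      unique(by[key == k, , drop = FALSE]),
      data.frame(min = min(v), max = max(v), mean = mean(v), n = length(v))
    )
  }))
  rownames(tab) <- NULL
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  list(
    table = tab,
    histogram = data.frame(
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1], count = counts
    )
  )
}

#' Run the full analysis pipeline
#'
#' Executes the analysis sequence on a trial: per-genotype stress
#' tolerance indices, Ward grouping with tolerance labels, descriptive
#' yield statistics, per-year split-plot ANOVA of grain yield, the 20
#' spectral indices, correlation screens per spectral scope, stepwise
#' index selection per category x spectral treatment for GYc and GYs, and
#' per-group best fits of the selected indices. If `output_dir` is given
#' the report tables are written as CSV plus a JSON run manifest.
#'
#' @param trial a `synth_trial` from [generate_trial()], or a list with
#'   elements `spectra` (a [spectra_set()]) and `yields` (plot yield
#'   data.frame).
#' @param k number of tolerance groups.
#' @param indices index names to compute (default: all registry entries).
#' @param alpha correlation significance level.
#' @param alpha_enter,alpha_remove stepwise thresholds.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return list of class `halotype_run`: `sti`, `grouping`,
#'   `descriptives`, `anova` (per year), `sri`, `correlations` (per
#'   scope), `smlr` (per category/treatment/dependent), `group_fits`.
#' @export
run_pipeline <- function(trial, k = 3, indices = NULL, alpha = 0.05,
                         alpha_enter = 0.05, alpha_remove = 0.10,
                         output_dir = NULL) {
  if (is.null(trial$spectra) || is.null(trial$yields)) {
    halo_abort("trial must provide spectra and yields", "halotype_bad_config")
  }
  if (!is.null(indices)) {
    bad <- setdiff(indices, sri_registry()$name)
    if (length(bad)) {
      halo_abort(
        paste("unknown indices:", paste(bad, collapse = ", ")),
        "halotype_unknown_index"
      )
    }
  }
  stage <- function(name, value) {
    message(sprintf("[%s] %s rows", name,
                    if (is.data.frame(value)) nrow(value) else length(value)))
    value
  }

  sti <- stage("sti", sti_table(trial$yields))
  grouping <- tolerance_groups(sti, k = k)
  message(sprintf("[grouping] %d groups", grouping$k))

  gy_means <- stats::aggregate(
    grain_yield ~ genotype + treatment + year, data = trial$yields,
    FUN = mean
  )
  desc <- descriptive_stats(
    gy_means$grain_yield, gy_means[c("treatment", "year")]
  )

  years <- sort(unique(trial$yields$year))
  anova_tables <- lapply(years, function(yr) {
    splitplot_anova(trial$yields[trial$yields$year == yr, ],
                    response = "grain_yield")
  })
  names(anova_tables) <- paste0("year", years)

  sri <- stage("sri", compute_sri(trial$spectra, indices = indices))

  scopes <- expand.grid(treatment = TREATMENTS, year = "combined",
                        stringsAsFactors = FALSE)
  correlations <- lapply(seq_len(nrow(scopes)), function(i) {
    correlation_table(sri, sti, treatment = scopes$treatment[i],
                      year = scopes$year[i], alpha = alpha)
  })
  names(correlations) <- scopes$treatment

  reg <- sri_registry()
  if (!is.null(indices)) reg <- reg[reg$name %in% indices, ]
  smlr_runs <- list()
  group_fits <- list()
  for (trt in TREATMENTS) {
    means <- sri_genotype_means(sri, treatment = trt, year = "combined")
    merged <- merge(means, sti, by = "genotype")
    for (cat in unique(reg$category)) {
      cand_names <- intersect(reg$name[reg$category == cat], names(merged))
      cand <- merged[cand_names]
      ok <- stats::complete.cases(cand)
      for (dep in c("gyc", "gys")) {
        key <- paste(cat, trt, dep, sep = ".")
        rep_ <- smlr(cand[ok, , drop = FALSE], merged[[dep]][ok],
                     dependent = dep, alpha_enter = alpha_enter,
                     alpha_remove = alpha_remove)
        smlr_runs[[key]] <- rep_
        lab <- grouping$genotype_labels %||% NULL
        for (sel in rep_$selected) {
          for (grp in unique(lab)) {
            gmask <- ok & !is.na(lab[merged$genotype]) &
              lab[merged$genotype] == grp
            if (sum(gmask) >= 4) {
              group_fits[[length(group_fits) + 1L]] <- best_group_fit(
                merged[[sel]][gmask], merged[[dep]][gmask],
                group = grp, x_name = sel, y_name = dep
              )
            }
          }
        }
      }
    }
  }
  group_fits <- if (length(group_fits)) {
    do.call(rbind, group_fits)
  } else {
    NULL
  }

  bundle <- structure(
    list(
      sti = sti, grouping = grouping, descriptives = desc,
      anova = anova_tables, sri = sri, correlations = correlations,
      smlr = smlr_runs, group_fits = group_fits
    ),
    class = "halotype_run"
  )
  if (!is.null(output_dir)) write_run_bundle(bundle, trial, output_dir)
  bundle
}

write_run_bundle <- function(bundle, trial, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$sti, file.path(output_dir, "sti.csv"),
                   row.names = FALSE)
  labels <- data.frame(
    genotype = names(bundle$grouping$genotype_labels %||% character(0)),
    group = unname(bundle$grouping$genotype_labels %||% character(0))
  )
  utils::write.csv(labels, file.path(output_dir, "groups.csv"),
                   row.names = FALSE)
  export_newick(bundle$grouping, file.path(output_dir, "dendrogram.nwk"))
  utils::write.csv(bundle$sri, file.path(output_dir, "sri.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$correlations)) {
    utils::write.csv(
      bundle$correlations[[nm]],
      file.path(output_dir, sprintf("correlations_%s.csv", nm)),
      row.names = FALSE
    )
  }
  for (nm in names(bundle$anova)) {
    utils::write.csv(
      bundle$anova[[nm]],
      file.path(output_dir, sprintf("anova_%s.csv", nm)),
      row.names = FALSE
    )
  }
  smlr_df <- do.call(rbind, lapply(names(bundle$smlr), function(k) {
    s <- bundle$smlr[[k]]
    data.frame(run = k, equation = s$equation, r_squared = s$r_squared,
               rmse = s$rmse, n = s$n)
  }))
  utils::write.csv(smlr_df, file.path(output_dir, "smlr.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$group_fits)) {
    utils::write.csv(bundle$group_fits,
                     file.path(output_dir, "group_fits.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "halotype",
    version = as.character(utils::packageVersion("halotype")),
    created = format(Sys.time(), tz = "UTC"),
    config = if (!is.null(trial$config)) unclass(trial$config) else NULL
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.halotype_run <- function(x, ...) {
  cat("<halotype_run>\n")
  cat(sprintf("  %d genotypes, %d index values\n",
              nrow(x$sti), nrow(x$sri)))
  cat(sprintf("  groups: %s\n",
              paste(x$grouping$labels %||% "unlabelled", collapse = ", ")))
  invisible(x)
}
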