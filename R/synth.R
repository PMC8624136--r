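## Synthetic field-trial generator.
##
## Emulates a two-year salinity trial: 64 genotypes planted in three
## latent tolerance groups, grown under control and saline irrigation in
## 3 replicate blocks. Genotype control yields and yield-stability ratios
## are drawn around the observed group means; plot yields add year and
## plot noise. Plot yields drive three latent canopy traits (chlorophyll
## c, biomass b, water w in (0, 1]), which shape a full-range reflectance
## curve: a logistic red-edge step from a visible shelf up to a NIR
## plateau (height increasing in b), a decline to a SWIR shelf
## (decreasing in w), Gaussian pigment absorption wells at 450/680 nm
## (depth scaled by c), water absorption wells at 970/1170/1450/1950 nm
## (depth scaled by w), a long-wavelength water absorption tail beyond
## 2200 nm, and smooth wavelength-correlated noise. The construction
## reproduces the qualitative signatures of group-structured canopies:
## valleys near 960/1170 nm, peaks near 1640/2200 nm, tolerant genotypes
## lowest in the visible and highest in the NIR.

#' Synthetic trial configuration
#'
#' Defaults emulate the study conditions: 64 genotypes in groups of
#' 25/19/20 (salt-tolerant / salt-sensitive / moderately salt-tolerant)
#' with group mean control yields 6.23/5.45/5.18 t/ha and salinity yields
#' 4.01/3.41/3.93 t/ha, two years, three replicates, control ~0.35 and
#' salinity 15 dS/m. Yield-stability draws are truncated to (0.40, 0.90).
#'
#' @param n_genotypes number of genotypes.
#' @param group_sizes integer vector summing to `n_genotypes`, in label
#'   order salt-tolerant, salt-sensitive, moderately salt-tolerant.
#' @param group_mean_gyc group mean control grain yields (t/ha).
#' @param group_mean_gys group mean salinity grain yields (t/ha).
#' @param sd_gyc between-genotype sd of control yield within a group.
#' @param sd_ysi between-genotype sd of the yield-stability ratio.
#' @param ysi_bounds truncation bounds for the yield-stability ratio.
#' @param years,replicates trial dimensions.
#' @param sd_year sd of genotype x treatment x year yield effects (t/ha).
#' @param sd_plot sd of plot-level yield noise (t/ha).
#' @param trait_c,trait_b,trait_w latent-trait links `c(a, b, d)`:
#'   trait = clip((a + b * gy) * (1 - d * salinity) + noise, 0.01, 1).
#' @param trait_noise_sd sd of latent-trait noise.
#' @param spectral_noise_sd sd of the smooth spectral noise (reflectance
#'   fraction).
#' @param seed default RNG seed for the generator entry points.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genotypes = 64L,
                         group_sizes = c(25L, 19L, 20L),
                         group_mean_gyc = c(6.23, 5.45, 5.18),
                         group_mean_gys = c(4.01, 3.41, 3.93),
                         sd_gyc = 0.12,
                         sd_ysi = 0.02,
                         ysi_bounds = c(0.40, 0.90),
                         years = 2L,
                         replicates = 3L,
                         sd_year = 0.10,
                         sd_plot = 0.18,
                         trait_c = c(0.05, 0.105, 0.08),
                         trait_b = c(0.10, 0.095, 0.05),
                         trait_w = c(0.08, 0.100, 0.12),
                         trait_noise_sd = 0.02,
                         spectral_noise_sd = 0.004,
                         seed = 1L) {
  if (sum(group_sizes) != n_genotypes) {
    halo_abort("group_sizes must sum to n_genotypes", "halotype_bad_config")
  }
  if (length(group_sizes) != 3L || length(group_mean_gyc) != 3L ||
    length(group_mean_gys) != 3L) {
    halo_abort("three groups expected", "halotype_bad_config")
  }
  sds <- c(sd_gyc, sd_ysi, sd_year, sd_plot, trait_noise_sd,
           spectral_noise_sd)
  if (any(sds < 0)) {
    halo_abort("all standard deviations must be >= 0", "halotype_bad_config")
  }
  structure(
    list(
      n_genotypes = as.integer(n_genotypes),
      group_sizes = as.integer(group_sizes),
      group_labels = TOLERANCE_LABELS,
      group_mean_gyc = group_mean_gyc,
      group_mean_gys = group_mean_gys,
      sd_gyc = sd_gyc, sd_ysi = sd_ysi, ysi_bounds = ysi_bounds,
      years = as.integer(years), replicates = as.integer(replicates),
      sd_year = sd_year, sd_plot = sd_plot,
      trait_c = trait_c, trait_b = trait_b, trait_w = trait_w,
      trait_noise_sd = trait_noise_sd,
      spectral_noise_sd = spectral_noise_sd,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate plot-level grain yields
#'
#' Draws genotype control yields `GYc_i ~ N(group mean, sd_gyc)`
#' (truncated positive) and yield-stability ratios `YSI_i ~ N(group YSI,
#' sd_ysi)` truncated to `ysi_bounds`, sets `GYs_i = YSI_i * GYc_i`, then
#' adds genotype x treatment x year effects and plot noise.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state, the default
#'   uses `config$seed`.
#' @return list: `yields` (data.frame `genotype`, `treatment`, `year`,
#'   `replicate`, `grain_yield`) and `genotypes` (data.frame `genotype`,
#'   `group`, `gyc_true`, `gys_true`, `ysi_true`).
#' @export
generate_yields <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_genotypes
  group <- rep(config$group_labels, times = config$group_sizes)
  mean_gyc <- rep(config$group_mean_gyc, times = config$group_sizes)
  mean_ysi <- rep(config$group_mean_gys / config$group_mean_gyc,
                  times = config$group_sizes)
  ids <- sprintf("G%03d", seq_len(n))
  gyc <- pmax(stats::rnorm(n, mean_gyc, config$sd_gyc), 0.05)
  ysi <- pmin(
    pmax(stats::rnorm(n, mean_ysi, config$sd_ysi), config$ysi_bounds[1]),
    config$ysi_bounds[2]
  )
  gys <- ysi * gyc
  genotypes <- data.frame(
    genotype = ids, group = group,
    gyc_true = gyc, gys_true = gys, ysi_true = ysi,
    stringsAsFactors = FALSE
  )
  plots <- expand.grid(
    replicate = seq_len(config$replicates),
    year = seq_len(config$years),
    treatment = TREATMENTS,
    genotype = ids,
    stringsAsFactors = FALSE
  )
  base <- ifelse(plots$treatment == "control",
                 gyc[match(plots$genotype, ids)],
                 gys[match(plots$genotype, ids)])
  ycell <- interaction(plots$genotype, plots$treatment, plots$year)
  year_eff <- stats::rnorm(nlevels(ycell), 0, config$sd_year)[ycell]
  plot_eff <- stats::rnorm(nrow(plots), 0, config$sd_plot)
  plots$grain_yield <- pmax(base + year_eff + plot_eff, 0.05)
  plots <- plots[c("genotype", "treatment", "year", "replicate",
                   "grain_yield")]
  list(yields = plots, genotypes = genotypes)
}

#' Latent canopy traits from plot yield
#'
#' Maps a plot grain yield and treatment to chlorophyll, biomass and
#' water proxies in (0, 1], affine-increasing in yield and reduced under
#' salinity by the configured factors.
#'
#' @param gy plot grain yield (t/ha, > 0); vectorized.
#' @param treatment `"control"` or `"salinity"`; recycled.
#' @param config a [synth_config()].
#' @param noise optional additive noise, a list with elements `c`, `b`,
#'   `w` (default 0, i.e. the closed-form traits).
#' @return data.frame with columns `c`, `b`, `w`.
#' @export
traits_from_yield <- function(gy, treatment, config,
                              noise = list(c = 0, b = 0, w = 0)) {
  if (any(gy <= 0)) halo_abort("gy must be positive", "halotype_bad_config")
  check_treatment(treatment)
  sal <- as.numeric(treatment == "salinity")
  link <- function(coef, eps) {
    pmin(pmax((coef[1] + coef[2] * gy) * (1 - coef[3] * sal) + eps, 0.01), 1)
  }
  data.frame(
    c = link(config$trait_c, noise$c),
    b = link(config$trait_b, noise$b),
    w = link(config$trait_w, noise$w)
  )
}

## Deterministic reflectance curve for one (c, b, w) triple over a
## wavelength vector. Returns the noise-free curve, unclipped.
canopy_curve <- function(c_, b_, w_, wavelength) {
  logistic <- function(x) 1 / (1 + exp(-x))
  gauss <- function(mu, sigma) exp(-((wavelength - mu)^2) / (2 * sigma^2))
  vis <- 0.28
  nir <- 0.25 + 0.35 * b_
  swir <- nir * (0.95 - 0.55 * w_)
  base <- vis +
    (nir - vis) * logistic((wavelength - 715) / 20) -
    (nir - swir) * logistic((wavelength - 1380) / 120)
  pigment <- 0.22 * (gauss(450, 35) + gauss(680, 28))
  water <- 0.06 * gauss(970, 25) + 0.09 * gauss(1170, 35) +
    0.28 * gauss(1450, 55) + 0.32 * gauss(1950, 75) +
    0.20 * gauss(2500, 120)
  base - c_ * pigment - w_ * water
}

## Smooth wavelength-correlated noise: white noise convolved with a
## Gaussian kernel (30-nm bandwidth), rescaled to sd = noise_sd.
## `n_spectra` columns are generated at once.
smooth_noise <- function(n_wavelength, n_spectra, noise_sd, step_nm = 1) {
  if (noise_sd == 0) return(matrix(0, n_wavelength, n_spectra))
  bw <- 30 / step_nm
  half <- ceiling(3 * bw)
  kern <- stats::dnorm(seq(-half, half), sd = bw)
  kern <- kern / sqrt(sum(kern^2)) # unit output sd for unit input sd
  z <- matrix(stats::rnorm(n_wavelength * n_spectra), n_wavelength)
  sm <- stats::filter(z, kern, method = "convolution", sides = 2,
                      circular = TRUE)
  matrix(as.numeric(sm), n_wavelength) * noise_sd
}

#' Generate one canopy reflectance spectrum
#'
#' Evaluates the canopy curve for one latent-trait triple, adds smooth
#' correlated noise, and clips to [0.01, 0.99].
#'
#' @param traits list or one-row data.frame with `c`, `b`, `w` in (0, 1].
#' @param grid a [wavelength_grid()].
#' @param noise_sd spectral noise sd (0 for the deterministic curve).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param genotype,treatment,year,replicate record keys.
#' @return a [spectrum_record()].
#' @export
generate_spectrum <- function(traits, grid, noise_sd = 0.004, seed = NULL,
                              genotype = "G000", treatment = "control",
                              year = 1L, replicate = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.null(seed)) set.seed(seed)
  curve <- canopy_curve(traits$c, traits$b, traits$w, grid$wavelength)
  eps <- smooth_noise(sample_count(grid), 1L, noise_sd, grid$step_nm)
  refl <- pmin(pmax(curve + as.numeric(eps), 0.01), 0.99)
  spectrum_record(grid, refl, genotype, treatment, year, replicate)
}

#' Generate a full synthetic trial
#'
#' Produces the complete factorial dataset (genotype x treatment x year x
#' replicate): plot yields, plot canopy spectra on the masked full-range
#' grid, and the planted tolerance labels for recovery tests.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (default `config$seed`).
#' @param mask_windows mask applied to the spectra grid.
#' @return list of class `synth_trial`: `spectra` (a [spectra_set()]),
#'   `yields` (plot yield data.frame), `genotypes` (planted labels and
#'   true yields), `config`.
#' @export
generate_trial <- function(config = synth_config(), seed = config$seed,
                           mask_windows = default_mask_windows()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  yd <- generate_yields(config, seed = NULL)
  grid <- wavelength_grid(350, 2500)
  if (length(mask_windows)) grid <- apply_mask(grid, mask_windows)
  plots <- yd$yields
  n_plot <- nrow(plots)
  tn <- config$trait_noise_sd
  noise <- list(
    c = stats::rnorm(n_plot, 0, tn),
    b = stats::rnorm(n_plot, 0, tn),
    w = stats::rnorm(n_plot, 0, tn)
  )
  traits <- traits_from_yield(plots$grain_yield, plots$treatment, config,
                              noise)
  nwl <- sample_count(grid)
  refl <- matrix(NA_real_, n_plot, nwl)
  for (i in seq_len(n_plot)) {
    refl[i, ] <- canopy_curve(traits$c[i], traits$b[i], traits$w[i],
                              grid$wavelength)
  }
  eps <- smooth_noise(nwl, n_plot, config$spectral_noise_sd, grid$step_nm)
  refl <- pmin(pmax(refl + t(eps), 0.01), 0.99)
  meta <- plots[c("genotype", "treatment", "year", "replicate")]
  structure(
    list(
      spectra = spectra_set(grid, meta, refl),
      yields = plots,
      genotypes = yd$genotypes,
      config = config
    ),
    class = "synth_trial"
  )
}

#' @export
print.synth_trial <- function(x, ...) {
  cat(sprintf(
    "<synth_trial> %d genotypes x %d treatments x %d years x %d reps = %d plots\n",
    x$config$n_genotypes, 2L, x$config$years, x$config$replicates,
    nrow(x$yields)
  ))
  invisible(x)
}
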