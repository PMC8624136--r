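test_that("config validation catches inconsistent group sizes and negative sds", {
  expect_error(synth_config(n_genotypes = 10, group_sizes = c(5, 3, 3)),
               class = "halotype_bad_config")
  expect_error(synth_config(sd_gyc = -1), class = "halotype_bad_config")
  cfg <- synth_config()
  expect_equal(sum(cfg$group_sizes), 64L)
})

test_that("yield generation is seed-reproducible and exact at zero variance", {
  cfg <- synth_config(seed = 42)
  y1 <- generate_yields(cfg)
  y2 <- generate_yields(cfg)
  expect_identical(y1, y2)
  y3 <- generate_yields(cfg, seed = 43)
  expect_false(identical(y1$yields$grain_yield, y3$yields$grain_yield))
  expect_true(all(y1$yields$grain_yield > 0))
  expect_equal(nrow(y1$yields), 64 * 2 * 2 * 3)

  cfg0 <- synth_config(sd_gyc = 0, sd_ysi = 0, sd_year = 0, sd_plot = 0)
  y0 <- generate_yields(cfg0)
  expect_equal(sort(unique(y0$genotypes$gyc_true)),
               sort(cfg0$group_mean_gyc))
  # plot yields equal the genotype truth exactly
  m <- merge(y0$yields[y0$yields$treatment == "control", ], y0$genotypes)
  expect_equal(m$grain_yield, m$gyc_true)
})

test_that("group mean control yields converge to their targets at large n", {
  cfg <- synth_config(
    n_genotypes = 32000L, group_sizes = c(12500L, 9500L, 10000L),
    years = 1L, replicates = 1L, seed = 99
  )
  g <- generate_yields(cfg)$genotypes
  means <- tapply(g$gyc_true, g$group, mean)
  expect_equal(unname(means[cfg$group_labels]), cfg$group_mean_gyc,
               tolerance = 0.05, ignore_attr = TRUE)
  ysi <- tapply(g$ysi_true, g$group, mean)
  expect_equal(unname(ysi[cfg$group_labels]),
               cfg$group_mean_gys / cfg$group_mean_gyc,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_true(all(g$ysi_true >= cfg$ysi_bounds[1] &
                    g$ysi_true <= cfg$ysi_bounds[2]))
})

test_that("latent traits increase with yield and drop under salinity", {
  cfg <- synth_config()
  gy <- seq(2, 7, by = 0.5)
  tc <- traits_from_yield(gy, "control", cfg)
  expect_true(all(diff(tc$c) >= 0 & diff(tc$b) >= 0 & diff(tc$w) >= 0))
  ts <- traits_from_yield(gy, "salinity", cfg)
  expect_true(all(ts$w <= tc$w))
  expect_true(all(ts$c <= tc$c))
  expect_true(all(tc$c > 0 & tc$c <= 1 & tc$w > 0 & tc$w <= 1))
  # closed form at zero noise
  expect_equal(tc$c, pmin(pmax(cfg$trait_c[1] + cfg$trait_c[2] * gy, 0.01), 1))
  expect_error(traits_from_yield(-1, "control", cfg),
               class = "halotype_bad_config")
})

test_that("generated spectra show the canonical absorption geometry", {
  g <- wavelength_grid(350, 2500)
  wl <- g$wavelength
  rec <- function(c_, b_, w_) {
    generate_spectrum(list(c = c_, b = b_, w = w_), g, noise_sd = 0)
  }
  lowc <- rec(0.2, 0.6, 0.5)$reflectance
  highc <- rec(1.0, 0.6, 0.5)$reflectance
  at <- function(r, nm) r[nm - 350 + 1]
  # more chlorophyll -> deeper red absorption; green peak above red valley
  expect_lt(at(highc, 680), at(lowc, 680))
  expect_gt(at(highc, 550), at(highc, 680))
  expect_gt(at(lowc, 550), at(lowc, 680))

  dry <- rec(0.6, 0.6, 0.2)$reflectance
  wet <- rec(0.6, 0.6, 0.9)$reflectance
  # wetter canopy: deeper valleys at the 960/1170 water bands
  local_min_near <- function(r, nm, halfwin = 60) {
    win <- wl >= nm - halfwin & wl <= nm + halfwin
    wl[win][which.min(r[win])]
  }
  expect_lt(at(wet, 970) - at(dry, 970), 0)
  expect_lt(at(wet, 1170) - at(dry, 1170), 0)
  expect_lt(abs(local_min_near(wet, 960, 100) - 970), 40)
  expect_lt(abs(local_min_near(wet, 1170) - 1170), 40)
  # peaks near 1640 and 2200 present in both
  local_max_near <- function(r, nm, halfwin) {
    win <- wl >= nm - halfwin & wl <= nm + halfwin
    wl[win][which.max(r[win])]
  }
  for (r in list(dry, wet)) {
    expect_lt(abs(local_max_near(r, 1640, 200) - 1640), 150)
    expect_lt(abs(local_max_near(r, 2200, 250) - 2200), 200)
  }
  # deterministic at zero noise regardless of RNG state
  set.seed(1)
  r1 <- rec(0.5, 0.5, 0.5)$reflectance
  set.seed(999)
  r2 <- rec(0.5, 0.5, 0.5)$reflectance
  expect_identical(r1, r2)
})

test_that("full trials are reproducible, bounded, and group-ordered in VIS/NIR", {
  tr <- generate_trial(synth_config(seed = 12))
  expect_true(all(tr$spectra$reflectance >= 0.01 &
                    tr$spectra$reflectance <= 0.99))
  expect_equal(nrow(tr$spectra$meta), nrow(tr$yields))

  tr2 <- generate_trial(synth_config(seed = 12))
  expect_identical(tr$spectra$reflectance, tr2$spectra$reflectance)
  expect_identical(tr$yields, tr2$yields)

  wl <- tr$spectra$grid$wavelength
  vis <- wl >= 400 & wl <= 700
  nir <- wl >= 750 & wl <= 1300
  grp <- tr$genotypes$group[match(tr$spectra$meta$genotype,
                                  tr$genotypes$genotype)]
  for (trt in c("control", "salinity")) {
    sel <- tr$spectra$meta$treatment == trt
    vis_means <- tapply(rowMeans(tr$spectra$reflectance[sel, vis]),
                        grp[sel], mean)
    nir_means <- tapply(rowMeans(tr$spectra$reflectance[sel, nir]),
                        grp[sel], mean)
    # tolerant vs sensitive: clearly separated in yield, hence in both bands
    expect_lt(vis_means["salt-tolerant"], vis_means["salt-sensitive"])
    expect_gt(nir_means["salt-tolerant"], nir_means["salt-sensitive"])
  }
})

test_that("a tiny trial runs every downstream stage end-to-end", {
  cfg <- synth_config(
    n_genotypes = 6L, group_sizes = c(2L, 2L, 2L), seed = 5
  )
  tr <- generate_trial(cfg)
  sti <- sti_table(tr$yields)
  expect_equal(nrow(sti), 6)
  sri <- suppressMessages(compute_sri(tr$spectra))
  expect_equal(nrow(sri), nrow(tr$spectra$meta) * 20)
  grp <- ward_cluster(as.matrix(sti[GROUP_FEATURES]), k = 3)
  expect_equal(length(unique(grp$membership)), 3)
  tab <- correlation_table(sri, sti, treatment = "salinity")
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
  a <- splitplot_anova(tr$yields[tr$yields$year == 1, ])
  expect_equal(sum(a$ss[1:6]), a$ss[7], tolerance = 1e-8)
})
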