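# Independent oracles and fixture builders used across the suite.

# Full-range masked grid shared by many tests.
full_grid <- function() apply_mask(wavelength_grid(350, 2500))

# A spectra set of n random smooth-ish spectra on the full grid.
random_spectra <- function(n, seed = 1) {
  set.seed(seed)
  g <- full_grid()
  nw <- sample_count(g)
  refl <- t(replicate(n, {
    # random positive smooth curve in (0.02, 0.95)
    x <- seq(0, 1, length.out = nw)
    y <- 0.3 + 0.2 * sin(2 * pi * runif(1) + 3 * x) +
      0.15 * sin(2 * pi * runif(1) + 11 * x) + rnorm(1, 0, 0.05)
    pmin(pmax(y, 0.02), 0.95)
  }))
  meta <- data.frame(
    genotype = sprintf("G%03d", seq_len(n)), treatment = "control",
    year = 1L, replicate = 1L
  )
  spectra_set(g, meta, refl)
}

# Direct-arithmetic SRI oracle: indexes the reflectance vector by
# wavelength position and spells out every formula by hand, with no use
# of the package's registry or evaluator.
oracle_sri <- function(refl, start_nm = 350) {
  R <- function(wl) refl[wl - start_nm + 1]
  nd <- function(a, b) (a - b) / (a + b)
  sq <- function(x) if (x > 0) sqrt(x) else NA_real_
  swsi1_den <- sq(R(1326) - R(1507))
  swsi2_den <- sq(R(905) - R(972))
  c(
    "NDVI-1" = nd(R(750), R(705)),
    "NDVI-2" = nd(R(780), R(715)),
    "BNDVI" = nd(R(970), R(420)),
    "GNDVI" = nd(R(940), R(550)),
    "RNDVI" = nd(R(990), R(680)),
    "Chl_green" = R(760) / R(550) - 1,
    "Chl_red-edge" = R(760) / R(710) - 1,
    "EVI" = 2.5 * (R(782) - R(675)) /
      (R(782) + 6 * R(675) - 7.5 * R(445) + 1),
    "MTVI" = 1.2 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))),
    "OSAVI" = 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16),
    "WI" = R(900) / R(970),
    "NWI-1" = nd(R(970), R(880)),
    "NWI-2" = nd(R(970), R(900)),
    "WBI" = nd(R(1500), R(531)),
    "NDWI" = nd(R(860), R(2270)),
    "NDMI" = nd(R(2200), R(1100)),
    "DMCI" = nd(R(2305), R(1495)),
    "NMDI" = (R(860) - (R(1640) - R(2130))) /
      (R(860) + (R(1640) - R(2130))),
    "SWSI-1" = if (is.na(swsi1_den)) NA_real_ else {
      (R(803) - R(681)) / swsi1_den
    },
    "SWSI-2" = if (is.na(swsi2_den)) NA_real_ else {
      (R(803) - R(681)) / swsi2_den
    }
  )
}

# Exhaustive best k-partition by total within-cluster sum of squares
# (feasible for n <= 8). Returns the membership of the minimizing
# partition, canonicalized by first appearance.
oracle_best_partition <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 8)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  canonical <- function(m) match(m, unique(m))
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(nrow(assignments))) {
    m <- assignments[i, ]
    if (length(unique(m)) != k) next
    ss <- sum(vapply(unique(m), function(g) {
      xg <- x[m == g, , drop = FALSE]
      sum(sweep(xg, 2, colMeans(xg))^2)
    }, numeric(1)))
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- canonical(m)
    }
  }
  best
}

# Direct covariance-formula Pearson correlation (no stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  sxy / (sx * sy)
}

# Normal-equations OLS oracle.
oracle_ols <- function(X, y) {
  Xm <- cbind(1, as.matrix(X))
  solve(t(Xm) %*% Xm, t(Xm) %*% y)[, 1]
}

# Small balanced split-plot layout with a response built from explicit
# effects, for ANOVA tests.
splitplot_data <- function(r = 3, a = 2, b = 64, seed = 1, sd = 0.5) {
  set.seed(seed)
  d <- expand.grid(
    replicate = seq_len(r),
    treatment = c("control", "salinity")[seq_len(a)],
    genotype = sprintf("G%02d", seq_len(b)),
    stringsAsFactors = FALSE
  )
  d$grain_yield <- rnorm(nrow(d), 5, sd)
  d
}

# Tiny yield table fixture: g genotypes, both treatments.
small_yields <- function(g = 4, years = 2, reps = 3, seed = 1) {
  set.seed(seed)
  d <- expand.grid(
    genotype = sprintf("G%02d", seq_len(g)),
    treatment = c("control", "salinity"),
    year = seq_len(years),
    replicate = seq_len(reps),
    stringsAsFactors = FALSE
  )
  base <- ifelse(d$treatment == "control", 5.5, 3.8)
  d$grain_yield <- base + rnorm(nrow(d), 0, 0.3)
  d
}
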