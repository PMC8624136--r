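table3_yields <- function() {
  # one genotype per printed group-mean pair, sized as the study groups
  sizes <- c(25, 19, 20)
  gyc <- c(6.23, 5.45, 5.18)
  gys <- c(4.01, 3.41, 3.93)
  data.frame(
    genotype = sprintf("G%02d", seq_len(sum(sizes))),
    gyc = rep(gyc, sizes),
    gys = rep(gys, sizes)
  )
}

as_long_yields <- function(wide) {
  rbind(
    data.frame(genotype = wide$genotype, treatment = "control",
               year = 1, replicate = 1, grain_yield = wide$gyc),
    data.frame(genotype = wide$genotype, treatment = "salinity",
               year = 1, replicate = 1, grain_yield = wide$gys)
  )
}

test_that("population means average per-genotype means, weighting groups by size", {
  one <- data.frame(genotype = "A",
                    treatment = c("control", "salinity"),
                    year = 1, replicate = 1, grain_yield = c(5, 3))
  pm <- population_means(one)
  expect_equal(pm$mean_gyc, 5)
  expect_equal(pm$mean_gys, 3)

  pm2 <- population_means(as_long_yields(table3_yields()))
  expect_equal(pm2$mean_gyc, (25 * 6.23 + 19 * 5.45 + 20 * 5.18) / 64,
               tolerance = 1e-12)
  expect_equal(round_half_up(pm2$mean_gyc, 3), 5.670)

  expect_error(population_means(data.frame()), class = "halotype_bad_yields")
  missing_trt <- data.frame(genotype = "A", treatment = "control",
                            year = 1, replicate = 1, grain_yield = 5)
  expect_warning(expect_error(population_means(missing_trt),
                              class = "halotype_bad_yields"),
                 "missing a treatment")
})

test_that("the five index formulas reproduce the worked group-mean values", {
  pm <- population_means(as_long_yields(table3_yields()))

  tolerant <- compute_sti_row(6.23, 4.01, pm)
  expect_equal(tolerant$tol, 2.22, tolerance = 1e-12)
  expect_equal(round_half_up(tolerant$sti, 2), 0.78)

  sensitive <- compute_sti_row(5.45, 3.41, pm)
  expect_equal(round_half_up(sensitive$ysi, 2), 0.63)
  expect_equal(round_half_up(sensitive$sti, 2), 0.58)

  moderate <- compute_sti_row(5.18, 3.93, pm)
  expect_equal(round_half_up(moderate$ysi, 2), 0.76)
  expect_equal(round_half_up(moderate$gmp, 2), 4.51)
  expect_equal(round_half_up(moderate$ssi, 2), 0.73)
})

test_that("degenerate and invalid inputs behave as specified", {
  pm <- list(mean_gyc = 5, mean_gys = 4)
  same <- compute_sti_row(4.2, 4.2, pm)
  expect_equal(same$tol, 0)
  expect_equal(same$ysi, 1)
  expect_equal(same$ssi, 0)

  expect_error(compute_sti_row(-1, 2, pm), class = "halotype_bad_yields")
  expect_error(compute_sti_row(5, 3, list(mean_gyc = 4, mean_gys = 4)),
               class = "halotype_undefined_ssi")
})

test_that("tol/ysi/gmp depend only on the genotype's own yields; ssi/sti only add the population means", {
  y <- as_long_yields(table3_yields())
  sti1 <- sti_table(y)
  # perturb an unrelated genotype's yields
  y2 <- y
  y2$grain_yield[y2$genotype == "G64"] <-
    y2$grain_yield[y2$genotype == "G64"] * 1.5
  sti2 <- sti_table(y2)
  g1 <- sti1[sti1$genotype == "G01", ]
  g2 <- sti2[sti2$genotype == "G01", ]
  expect_equal(g1[c("tol", "ysi", "gmp")], g2[c("tol", "ysi", "gmp")],
               ignore_attr = TRUE)
  # ssi and sti change because the population means moved
  expect_false(isTRUE(all.equal(g1$sti, g2$sti)))
  expect_false(isTRUE(all.equal(g1$ssi, g2$ssi)))
})

test_that("ssi and sti hit 1 at the population-matching configurations", {
  pm <- list(mean_gyc = 5.2, mean_gys = 3.9)
  # relative reduction equal to the population's -> ssi = 1
  row <- compute_sti_row(6.0, 6.0 * pm$mean_gys / pm$mean_gyc, pm)
  expect_equal(row$ssi, 1, tolerance = 1e-12)
  # gyc = gys = mean gyc -> sti = 1
  row2 <- compute_sti_row(pm$mean_gyc, pm$mean_gyc, pm)
  expect_equal(row2$sti, 1, tolerance = 1e-12)
})

test_that("holding gyc fixed, ysi/sti/gmp increase and ssi/tol decrease in gys", {
  pm <- list(mean_gyc = 5.5, mean_gys = 3.8)
  gys <- seq(2, 5.4, length.out = 25)
  rows <- do.call(rbind, lapply(gys, compute_sti_row, gyc = 5.5, means = pm))
  expect_true(all(diff(rows$ysi) > 0))
  expect_true(all(diff(rows$sti) > 0))
  expect_true(all(diff(rows$gmp) > 0))
  expect_true(all(diff(rows$ssi) < 0))
  expect_true(all(diff(rows$tol) < 0))
})

test_that("sti_table aggregates plots over years and replicates before indexing", {
  y <- small_yields(g = 4, seed = 7)
  tab <- sti_table(y)
  expect_equal(nrow(tab), 4)
  gm <- aggregate(grain_yield ~ genotype + treatment, y, mean)
  g1c <- gm$grain_yield[gm$genotype == "G01" & gm$treatment == "control"]
  g1s <- gm$grain_yield[gm$genotype == "G01" & gm$treatment == "salinity"]
  expect_equal(tab$gyc[tab$genotype == "G01"], g1c)
  expect_equal(tab$ysi[tab$genotype == "G01"], g1s / g1c)
  # invariants across the table
  expect_equal(tab$tol, tab$gyc - tab$gys)
  expect_equal(tab$ysi * tab$gyc, tab$gys)
  expect_equal(tab$gmp^2, tab$gyc * tab$gys)
  expect_true(all(tab$gmp > 0 & tab$sti > 0 & tab$ysi > 0))
  # rounded report variant
  tab2 <- sti_table(y, round_digits = 2)
  expect_equal(tab2$ysi, round_half_up(tab$ysi, 2))
})

test_that("per-replicate indices pair plots within genotype x year x replicate", {
  y <- small_yields(g = 3, years = 2, reps = 2, seed = 5)
  pr <- sti_per_replicate(y)
  expect_equal(nrow(pr), 3 * 2 * 2)
  i <- which(pr$genotype == "G02" & pr$year == 1 & pr$replicate == 2)
  gyc <- y$grain_yield[y$genotype == "G02" & y$year == 1 &
                         y$replicate == 2 & y$treatment == "control"]
  gys <- y$grain_yield[y$genotype == "G02" & y$year == 1 &
                         y$replicate == 2 & y$treatment == "salinity"]
  expect_equal(pr$tol[i], gyc - gys)
})
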