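make_record <- function(values_by_wl, fill = 0.5) {
  g <- full_grid()
  refl <- rep(fill, sample_count(g))
  for (wl in names(values_by_wl)) {
    refl[as.integer(wl) - 350 + 1] <- values_by_wl[[wl]]
  }
  spectrum_record(g, refl, "G1")
}

test_that("the registry holds 10 vegetation and 10 water indices, wavelengths consistent", {
  reg <- sri_registry()
  expect_equal(nrow(reg), 20)
  expect_equal(unname(table(reg$category)["vegetation"]), 10,
               ignore_attr = TRUE)
  expect_equal(unname(table(reg$category)["water"]), 10,
               ignore_attr = TRUE)
  # every wavelength cited by a formula appears in the wavelength list
  for (i in seq_len(nrow(reg))) {
    cited <- as.integer(sub("^R", "", regmatches(
      reg$formula[i], gregexpr("R[0-9]+", reg$formula[i])
    )[[1]]))
    expect_setequal(unique(cited), reg$wavelengths_nm[[i]])
  }
})

test_that("hand-computed index values are reproduced", {
  # NDVI-1 with R750 = 0.50, R705 = 0.25 -> 0.25/0.75
  r <- make_record(list(`750` = 0.50, `705` = 0.25))
  expect_equal(compute_index("NDVI-1", r)$value, 1 / 3, tolerance = 1e-12)

  # equal-band degenerate values
  r2 <- make_record(list(`900` = 0.4, `970` = 0.4))
  expect_equal(compute_index("WI", r2)$value, 1)
  r3 <- make_record(list(`760` = 0.3, `550` = 0.3))
  expect_equal(compute_index("Chl_green", r3)$value, 0)

  # NMDI: inner difference vanishes -> 1 under corrected parenthesization
  r4 <- make_record(list(`1640` = 0.33, `2130` = 0.33, `860` = 0.5))
  expect_equal(compute_index("NMDI", r4)$value, 1)
})

test_that("domain violations yield missing flags with reasons, never silent values", {
  # SWSI-1 with R1326 <= R1507: negative radicand
  r <- make_record(list(`1326` = 0.2, `1507` = 0.4))
  out <- compute_index("SWSI-1", r)
  expect_true(is.na(out$value))
  expect_equal(out$reason, "negative radicand")

  # zero denominator
  r2 <- make_record(list(`750` = 0, `705` = 0))
  out2 <- compute_index("NDVI-1", r2)
  expect_true(is.na(out2$value))
  expect_equal(out2$reason, "division by zero")
})

test_that("a constant spectrum collapses indices to their degenerate values", {
  g <- full_grid()
  set <- spectra_set(
    g, data.frame(genotype = "G1", treatment = "control", year = 1,
                  replicate = 1),
    matrix(0.5, 1, sample_count(g))
  )
  out <- suppressMessages(compute_sri(set))
  expect_equal(nrow(out), 20)
  expect_equal(sum(out$category == "vegetation"), 10)
  expect_equal(sum(out$category == "water"), 10)
  val <- setNames(out$value, out$index)
  nd_idx <- c("NDVI-1", "NDVI-2", "BNDVI", "GNDVI", "RNDVI", "NWI-1",
              "NWI-2", "WBI", "NDWI", "NDMI", "DMCI")
  expect_equal(unname(val[nd_idx]), rep(0, length(nd_idx)))
  expect_equal(unname(val["WI"]), 1)
  expect_equal(unname(val["NMDI"]), 1)
  expect_equal(unname(val[c("Chl_green", "Chl_red-edge")]), c(0, 0))
  # SWSI radicands are exactly zero -> flagged missing
  expect_true(all(is.na(val[c("SWSI-1", "SWSI-2")])))
})

test_that("a masked required band makes only the affected index missing", {
  g <- apply_mask(wavelength_grid(350, 2500), list(c(2100, 2160)))
  set.seed(5)
  refl <- runif(sample_count(g), 0.2, 0.6)
  # keep the square-root radicands positive so only the masked band fails
  refl[c(1326, 905) - 350 + 1] <- 0.6
  refl[c(1507, 972) - 350 + 1] <- 0.3
  refl <- matrix(refl, 1)
  set <- spectra_set(
    g, data.frame(genotype = "G1", treatment = "control", year = 1,
                  replicate = 1), refl
  )
  out <- suppressMessages(compute_sri(set))
  nmdi <- out[out$index == "NMDI", ]
  expect_true(is.na(nmdi$value))
  expect_match(nmdi$reason, "missing band 2130")
  expect_true(all(!is.na(out$value[out$index != "NMDI"])))
})

test_that("registry evaluation matches the direct-arithmetic oracle to 1e-12", {
  set <- random_spectra(100, seed = 11)
  out <- suppressMessages(compute_sri(set))
  wide <- reshape(out[c("genotype", "index", "value")],
                  idvar = "genotype", timevar = "index",
                  direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (i in seq_len(100)) {
    expected <- oracle_sri(set$reflectance[i, ])
    got <- unlist(wide[wide$genotype == set$meta$genotype[i],
                       names(expected)])
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  }
})

test_that("pure ratio and normalized-difference indices are scale invariant; additive-constant indices are not", {
  set.seed(21)
  base <- random_spectra(1, seed = 21)
  scaled <- base
  scaled$reflectance <- scaled$reflectance * 0.5
  o1 <- suppressMessages(compute_sri(base))
  o2 <- suppressMessages(compute_sri(scaled))
  v1 <- setNames(o1$value, o1$index)
  v2 <- setNames(o2$value, o2$index)
  invariant <- c("NDVI-1", "NDVI-2", "BNDVI", "GNDVI", "RNDVI",
                 "Chl_green", "Chl_red-edge", "WI", "NWI-1", "NWI-2",
                 "WBI", "NDWI", "NDMI", "DMCI", "NMDI")
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-10)
  non_invariant <- c("EVI", "MTVI", "OSAVI", "SWSI-1", "SWSI-2")
  for (nm in non_invariant) {
    if (!is.na(v1[nm]) && !is.na(v2[nm])) {
      expect_false(isTRUE(all.equal(v1[[nm]], v2[[nm]])), label = nm)
    }
  }
})

test_that("normalized differences of positive bands live in (-1, 1) and are antisymmetric", {
  nd <- function(a, b) (a - b) / (a + b)
  set.seed(31)
  a <- runif(200, 0.01, 0.99)
  b <- runif(200, 0.01, 0.99)
  expect_true(all(abs(nd(a, b)) < 1))
  expect_equal(nd(a, b), -nd(b, a))
})

test_that("the registry round-trips through JSON", {
  path <- tempfile(fileext = ".json")
  write_sri_registry(sri_registry(), path)
  back <- read_sri_registry(path)
  reg <- sri_registry()
  expect_equal(back$name, reg$name)
  expect_equal(back$formula, reg$formula)
  expect_equal(unclass(back$wavelengths_nm), unclass(reg$wavelengths_nm),
               ignore_attr = TRUE)
  # an imported registry evaluates like the built-in one
  set <- random_spectra(3, seed = 2)
  defs <- lapply(seq_len(nrow(back)), function(i) {
    d <- as.list(back[i, ])
    d$wavelengths_nm <- d$wavelengths_nm[[1]]
    d
  })
  o1 <- suppressMessages(compute_sri(set))
  o2 <- suppressMessages(compute_sri(set, .definitions = defs))
  expect_equal(o1$value, o2$value)
})

test_that("unknown index names are rejected up front", {
  set <- random_spectra(2, seed = 3)
  expect_error(compute_sri(set, indices = c("NDVI-1", "NOPE")),
               class = "halotype_unknown_index")
})
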