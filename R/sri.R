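## Spectral reflectance index (SRI) registry and evaluator.
##
## Each index is a small arithmetic formula over canopy reflectance at
## named wavelengths (R750, R550, ...). Ten indices track vegetation
## status (pigments, vigor, biomass) and ten track canopy water status.
## Formulas are stored as strings and evaluated against nearest-band
## reflectance, so users can register additional indices without code
## changes. Domain violations (masked band, division by zero, negative
## radicand under a square root) yield a missing value with a recorded
## reason -- never a silent zero.

SRI_DEFINITIONS <- list(
  # --- vegetation -------------------------------------------------------
  list("NDVI-1", "vegetation", c(750, 705),
       "(R750 - R705) / (R750 + R705)"),
  list("NDVI-2", "vegetation", c(780, 715),
       "(R780 - R715) / (R780 + R715)"),
  list("BNDVI", "vegetation", c(970, 420),
       "(R970 - R420) / (R970 + R420)"),
  list("GNDVI", "vegetation", c(940, 550),
       "(R940 - R550) / (R940 + R550)"),
  list("RNDVI", "vegetation", c(990, 680),
       "(R990 - R680) / (R990 + R680)"),
  list("Chl_green", "vegetation", c(760, 550),
       "(R760 / R550) - 1"),
  list("Chl_red-edge", "vegetation", c(760, 710),
       "(R760 / R710) - 1"),
  list("EVI", "vegetation", c(782, 675, 445),
       "2.5 * ((R782 - R675) / (R782 + 6 * R675 - 7.5 * R445 + 1))"),
  list("MTVI", "vegetation", c(800, 550, 670),
       "1.2 * (1.2 * (R800 - R550) - 2.5 * (R670 - R550))"),
  list("OSAVI", "vegetation", c(800, 670),
       "1.16 * (R800 - R670) / (R800 + R670 + 0.16)"),
  # --- water ------------------------------------------------------------
  list("WI", "water", c(900, 970), "R900 / R970"),
  list("NWI-1", "water", c(970, 880),
       "(R970 - R880) / (R970 + R880)"),
  list("NWI-2", "water", c(970, 900),
       "(R970 - R900) / (R970 + R900)"),
  list("WBI", "water", c(1500, 531),
       "(R1500 - R531) / (R1500 + R531)"),
  list("NDWI", "water", c(860, 2270),
       "(R860 - R2270) / (R860 + R2270)"),
  list("NDMI", "water", c(2200, 1100),
       "(R2200 - R1100) / (R2200 + R1100)"),
  list("DMCI", "water", c(2305, 1495),
       "(R2305 - R1495) / (R2305 + R1495)"),
  # NMDI uses the standard normalized multi-band drought form
  # (R860 - (R1640 - R2130)) / (R860 + (R1640 - R2130)).
  list("NMDI", "water", c(860, 1640, 2130),
       "(R860 - (R1640 - R2130)) / (R860 + (R1640 - R2130))"),
  list("SWSI-1", "water", c(803, 681, 1326, 1507),
       "(R803 - R681) / sqrt(R1326 - R1507)"),
  list("SWSI-2", "water", c(803, 681, 905, 972),
       "(R803 - R681) / sqrt(R905 - R972)")
)

#' The built-in SRI registry
#'
#' Declarative table of the 20 spectral reflectance indices: 10
#' vegetation indices (NDVI variants, chlorophyll indices, EVI, MTVI,
#' OSAVI) and 10 water indices (WI, NWI variants, WBI, NDWI, NDMI, DMCI,
#' NMDI, SWSI variants). Each row carries the index name, its category,
#' the wavelengths (nm) its formula reads, and the formula itself as a
#' string over `R<wavelength>` terms.
#'
#' @return data.frame with columns `name`, `category`, `wavelengths_nm`
#'   (list column of integer vectors) and `formula`.
#' @seealso [compute_index()], [compute_sri()], [read_sri_registry()]
#' @export
#' @examples
#' reg <- sri_registry()
#' table(reg$category)
sri_registry <- function() {
  data.frame(
    name = vapply(SRI_DEFINITIONS, `[[`, "", 1),
    category = vapply(SRI_DEFINITIONS, `[[`, "", 2),
    wavelengths_nm = I(lapply(SRI_DEFINITIONS, function(d) as.integer(d[[3]]))),
    formula = vapply(SRI_DEFINITIONS, `[[`, "", 4),
    stringsAsFactors = FALSE
  )
}

lookup_definition <- function(definition) {
  reg <- sri_registry()
  if (is.character(definition) && length(definition) == 1L) {
    i <- match(definition, reg$name)
    if (is.na(i)) {
      halo_abort(
        sprintf("unknown index '%s'", definition),
        "halotype_unknown_index"
      )
    }
    definition <- as.list(reg[i, ])
    definition$wavelengths_nm <- definition$wavelengths_nm[[1]]
  }
  need <- c("name", "category", "wavelengths_nm", "formula")
  if (!all(need %in% names(definition))) {
    halo_abort(
      paste("an index definition needs fields", paste(need, collapse = ", ")),
      "halotype_bad_definition"
    )
  }
  definition
}

## Evaluate one formula over a bands matrix (one column per required
## wavelength, named R<nm>). Guarded `/` and `sqrt` record per-element
## failure reasons instead of producing NaN/Inf.
eval_formula <- function(formula, bands) {
  n <- nrow(bands)
  reason <- rep(NA_character_, n)
  guard_div <- function(a, b) {
    z <- !is.na(b) & b == 0
    reason[z & is.na(reason)] <<- "division by zero"
    b[z] <- NA_real_
    a / b
  }
  guard_sqrt <- function(x) {
    bad <- !is.na(x) & x <= 0
    reason[bad & is.na(reason)] <<- "negative radicand"
    x[bad] <- NA_real_
    sqrt(x)
  }
  env <- as.list(as.data.frame(bands))
  env[["/"]] <- guard_div
  env[["sqrt"]] <- guard_sqrt
  value <- eval(str2lang(formula), envir = env, enclos = baseenv())
  value <- rep_len(as.numeric(value), n)
  value[!is.na(reason)] <- NA_real_
  list(value = value, reason = reason)
}

## Collect the R<nm> columns an index needs from a spectra set; a masked
## or absent band raises halotype_missing_band.
collect_bands <- function(set, wavelengths_nm, tolerance_nm = 3) {
  idx <- vapply(
    wavelengths_nm,
    function(wl) nearest_band_index(set$grid, wl, tolerance_nm),
    integer(1)
  )
  bands <- set$reflectance[, idx, drop = FALSE]
  colnames(bands) <- paste0("R", wavelengths_nm)
  bands
}

#' Compute one index for one spectrum
#'
#' Evaluates a single index definition against one plot spectrum. A
#' masked required band, a zero denominator or a non-positive radicand
#' yields `NA` with the reason recorded -- missingness is always explicit.
#'
#' @param definition an index name known to [sri_registry()], or a list
#'   with fields `name`, `category`, `wavelengths_nm`, `formula`.
#' @param record a [spectrum_record()].
#' @param tolerance_nm nearest-band lookup tolerance (nm).
#' @return one-row data.frame: `genotype`, `treatment`, `year`,
#'   `replicate`, `index`, `category`, `value`, `reason`.
#' @export
#' @examples
#' g <- wavelength_grid(350, 2500)
#' r <- spectrum_record(g, rep(0.5, sample_count(g)), "G01")
#' compute_index("WI", r)$value # 1
compute_index <- function(definition, record, tolerance_nm = 3) {
  stopifnot(inherits(record, "spectrum_record"))
  definition <- lookup_definition(definition)
  set <- spectra_set(
    record$grid,
    data.frame(
      genotype = record$genotype, treatment = record$treatment,
      year = record$year, replicate = record$replicate
    ),
    matrix(record$reflectance, nrow = 1)
  )
  out <- compute_sri(set, indices = NULL, tolerance_nm = tolerance_nm,
                     .definitions = list(definition))
  out
}

#' Compute spectral reflectance indices for a spectra set
#'
#' Evaluates registry indices for every plot spectrum. Indices whose
#' required bands are masked on this grid are returned as missing (with
#' reason) rather than dropped, so every record yields one row per
#' requested index.
#'
#' @param set a [spectra_set()].
#' @param indices character vector of index names (default: all 20).
#' @param tolerance_nm nearest-band lookup tolerance (nm).
#' @param .definitions internal: explicit definition list overriding
#'   `indices`.
#' @return long data.frame: `genotype`, `treatment`, `year`, `replicate`,
#'   `index`, `category`, `value`, `reason`.
#' @export
compute_sri <- function(set, indices = NULL, tolerance_nm = 3,
                        .definitions = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$meta) == 0L) {
    halo_abort("spectra set is empty", "halotype_bad_spectra_set")
  }
  if (is.null(.definitions)) {
    reg <- sri_registry()
    if (!is.null(indices)) {
      bad <- setdiff(indices, reg$name)
      if (length(bad)) {
        halo_abort(
          paste("unknown indices:", paste(bad, collapse = ", ")),
          "halotype_unknown_index"
        )
      }
      reg <- reg[match(indices, reg$name), ]
    }
    .definitions <- lapply(seq_len(nrow(reg)), function(i) {
      d <- as.list(reg[i, ])
      d$wavelengths_nm <- d$wavelengths_nm[[1]]
      d
    })
  }
  n <- nrow(set$meta)
  pieces <- lapply(.definitions, function(d) {
    res <- tryCatch(
      {
        bands <- collect_bands(set, d$wavelengths_nm, tolerance_nm)
        eval_formula(d$formula, bands)
      },
      halotype_missing_band = function(e) {
        list(
          value = rep(NA_real_, n),
          reason = rep(sprintf("missing band %s nm", e$wavelength), n)
        )
      }
    )
    data.frame(
      genotype = set$meta$genotype, treatment = set$meta$treatment,
      year = set$meta$year, replicate = set$meta$replicate,
      index = d$name, category = d$category,
      value = res$value, reason = res$reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  n_missing <- sum(is.na(out$value))
  if (n_missing > 0) {
    by_index <- table(out$index[is.na(out$value)])
    message(sprintf(
      "compute_sri: %d missing values (%s)",
      n_missing,
      paste(names(by_index), by_index, sep = "=", collapse = ", ")
    ))
  }
  out
}

#' Export / import an SRI registry
#'
#' The registry round-trips through JSON (`name`, `category`,
#' `wavelengths_nm`, `formula`) so additional indices can be supplied
#' without code changes.
#'
#' @param registry a registry data.frame as from [sri_registry()].
#' @param path file path.
#' @return `write_sri_registry()` returns `path` invisibly;
#'   `read_sri_registry()` returns a registry data.frame.
#' @export
write_sri_registry <- function(registry, path) {
  recs <- lapply(seq_len(nrow(registry)), function(i) {
    list(
      name = registry$name[i],
      category = registry$category[i],
      wavelengths_nm = registry$wavelengths_nm[[i]],
      formula = registry$formula[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sri_registry
#' @export
read_sri_registry <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  data.frame(
    name = vapply(recs, function(r) r$name, ""),
    category = vapply(recs, function(r) r$category, ""),
    wavelengths_nm = I(lapply(recs, function(r) {
      as.integer(unlist(r$wavelengths_nm))
    })),
    formula = vapply(recs, function(r) r$formula, ""),
    stringsAsFactors = FALSE
  )
}
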