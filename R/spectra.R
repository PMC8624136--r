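## Wavelength grids, spectrum records, masking and I/O.
##
## A field spectroradiometer delivers canopy reflectance resampled to a
## 1-nm grid over 350-2500 nm (2150 one-nm-width bands between 2151
## samples). Windows dominated by atmospheric water vapour / CO2
## absorption (1825-1915 nm and 2470-2500 nm) carry no canopy signal and
## are masked before any index is computed.

#' Default atmospheric mask windows
#'
#' Closed wavelength intervals (nm) dominated by atmospheric water-vapour
#' and CO2 absorption, removed from full-range canopy spectra before
#' index computation.
#'
#' @return list of length-2 integer vectors `c(lo_nm, hi_nm)`.
#' @export
default_mask_windows <- function() {
  list(c(1825L, 1915L), c(2470L, 2500L))
}

#' Build a wavelength grid
#'
#' Constructs the sampling grid a spectrum is aligned to. The standard
#' full-range grid is 350-2500 nm at 1 nm, giving 2151 samples spanning
#' 2150 one-nm-width bands. Coarser steps are rejected unless explicitly
#' allowed, because the index definitions assume 1-nm band access.
#'
#' @param start_nm first wavelength (integer nm).
#' @param end_nm last wavelength (integer nm), must exceed `start_nm`.
#' @param step_nm sampling step (integer nm, default 1).
#' @param allow_coarse permit `step_nm > 1` (default `FALSE`).
#' @return an object of class `wavelength_grid` with fields `start_nm`,
#'   `end_nm`, `step_nm`, `wavelength` (integer vector) and `masked`
#'   (logical vector, all `FALSE` until [apply_mask()] is used).
#' @seealso [apply_mask()], [band_count()], [sample_count()]
#' @export
#' @examples
#' g <- wavelength_grid(350, 2500)
#' band_count(g)   # 2150
#' sample_count(g) # 2151
wavelength_grid <- function(start_nm, end_nm, step_nm = 1L,
                            allow_coarse = FALSE) {
  start_nm <- as.integer(start_nm)
  end_nm <- as.integer(end_nm)
  step_nm <- as.integer(step_nm)
  if (is.na(step_nm) || step_nm < 1L) {
    halo_abort("step_nm must be a positive integer", "halotype_bad_grid")
  }
  if (step_nm > 1L && !allow_coarse) {
    halo_abort(
      "non-unit step_nm rejected: index wavelengths assume a 1-nm grid (set allow_coarse = TRUE to override)",
      "halotype_bad_grid"
    )
  }
  if (start_nm >= end_nm) {
    halo_abort("start_nm must be < end_nm", "halotype_bad_grid")
  }
  if ((end_nm - start_nm) %% step_nm != 0L) {
    halo_abort("grid span must be divisible by step_nm", "halotype_bad_grid")
  }
  wl <- seq.int(start_nm, end_nm, by = step_nm)
  structure(
    list(
      start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
      wavelength = wl, masked = rep(FALSE, length(wl))
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d-%d nm, step %d nm: %d samples (%d bands), %d masked\n",
    x$start_nm, x$end_nm, x$step_nm,
    sample_count(x), band_count(x), masked_count(x)
  ))
  invisible(x)
}

#' Grid sample, band and mask counts
#'
#' `sample_count()` is the number of grid points; `band_count()` the
#' number of `step_nm`-width bands between them (one fewer);
#' `masked_count()` how many samples are currently flagged unavailable.
#'
#' @param grid a [wavelength_grid()].
#' @return integer scalar.
#' @export
sample_count <- function(grid) length(grid$wavelength)

#' @rdname sample_count
#' @export
band_count <- function(grid) (grid$end_nm - grid$start_nm) %/% grid$step_nm

#' @rdname sample_count
#' @export
masked_count <- function(grid) sum(grid$masked)

#' Mask wavelength windows on a grid
#'
#' Flags every sample inside any of the given closed intervals as
#' unavailable. Masking is idempotent; windows entirely outside the grid
#' are ignored with a warning. On the full-range 1-nm grid the default
#' atmospheric windows mask 91 + 31 = 122 samples.
#'
#' @param grid a [wavelength_grid()].
#' @param windows list of closed integer intervals `c(lo_nm, hi_nm)`;
#'   defaults to [default_mask_windows()].
#' @return the grid with its `masked` flags updated.
#' @export
#' @examples
#' g <- apply_mask(wavelength_grid(350, 2500))
#' masked_count(g) # 122
apply_mask <- function(grid, windows = default_mask_windows()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  for (w in windows) {
    if (length(w) != 2L || w[1] > w[2]) {
      halo_abort(
        "each mask window must be c(lo_nm, hi_nm) with lo <= hi",
        "halotype_bad_mask"
      )
    }
    hit <- grid$wavelength >= w[1] & grid$wavelength <= w[2]
    if (!any(hit)) {
      halo_warn(sprintf(
        "mask window [%s, %s] lies outside the grid; ignored", w[1], w[2]
      ))
      next
    }
    grid$masked <- grid$masked | hit
  }
  grid
}

#' Create a single spectrum record
#'
#' One plot's reflectance vector aligned to a wavelength grid, keyed by
#' genotype, treatment, year and replicate. Values must be reflectance
#' fractions; inputs that look like percentages (any value > 1.5) are
#' divided by 100 with a warning.
#'
#' @param grid a [wavelength_grid()].
#' @param reflectance numeric vector, one value per grid sample.
#' @param genotype genotype identifier.
#' @param treatment `"control"` or `"salinity"`.
#' @param year trial year (small integer).
#' @param replicate replicate/block number.
#' @return an object of class `spectrum_record`.
#' @export
spectrum_record <- function(grid, reflectance, genotype,
                            treatment = "control", year = 1L,
                            replicate = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"))
  check_treatment(treatment)
  if (length(reflectance) != sample_count(grid)) {
    halo_abort(
      sprintf(
        "reflectance length %d != grid sample count %d",
        length(reflectance), sample_count(grid)
      ),
      "halotype_bad_spectrum"
    )
  }
  reflectance <- rescale_percent(reflectance)
  if (any(reflectance < 0 | reflectance > 1, na.rm = TRUE)) {
    halo_abort(
      "reflectance values must lie in [0, 1]",
      "halotype_bad_spectrum"
    )
  }
  structure(
    list(
      grid = grid, reflectance = as.numeric(reflectance),
      genotype = as.character(genotype), treatment = treatment,
      year = as.integer(year), replicate = as.integer(replicate)
    ),
    class = "spectrum_record"
  )
}

## Percent-scale detection: canopy reflectance fractions never exceed 1;
## a value above 1.5 signals percent input.
rescale_percent <- function(x) {
  if (any(x > 1.5, na.rm = TRUE)) {
    halo_warn("reflectance values > 1.5 detected; assuming percent scale, dividing by 100")
    x <- x / 100
  }
  x
}

#' Look up reflectance at (or near) a target wavelength
#'
#' Returns the value at the nearest unmasked grid sample within
#' `tolerance_nm` of the target. The 3-nm default matches the native
#' VIS-NIR sampling interval of field spectroradiometers. Ties between
#' two equally near samples resolve to the lower wavelength. If no
#' unmasked sample lies within tolerance a classed `halotype_missing_band`
#' error identifies the wavelength.
#'
#' @param record a [spectrum_record()].
#' @param target_nm wavelength to read (nm).
#' @param tolerance_nm maximum nearest-sample distance (nm, default 3).
#' @return reflectance fraction at the selected sample.
#' @export
reflectance_at <- function(record, target_nm, tolerance_nm = 3) {
  stopifnot(inherits(record, "spectrum_record"))
  idx <- nearest_band_index(record$grid, target_nm, tolerance_nm)
  record$reflectance[idx]
}

nearest_band_index <- function(grid, target_nm, tolerance_nm = 3) {
  d <- abs(grid$wavelength - target_nm)
  d[grid$masked] <- Inf
  i <- which.min(d) # which.min takes the first (lower-wavelength) tie
  if (!is.finite(d[i]) || d[i] > tolerance_nm) {
    halo_abort(
      sprintf(
        "no unmasked sample within %s nm of %s nm",
        tolerance_nm, target_nm
      ),
      "halotype_missing_band",
      wavelength = target_nm
    )
  }
  i
}

#' Average replicate scans of one plot
#'
#' Field protocols record several sequential scans per plot; the plot
#' spectrum is their element-wise arithmetic mean. All records must share
#' the same grid and (genotype, treatment, year, replicate) key; masked
#' samples stay masked.
#'
#' @param records list of [spectrum_record()]s sharing one key.
#' @return a single averaged [spectrum_record()].
#' @export
average_scans <- function(records) {
  if (length(records) < 1L) {
    halo_abort("need at least one record", "halotype_bad_spectrum")
  }
  first <- records[[1]]
  for (r in records[-1]) {
    if (!identical(r$grid$wavelength, first$grid$wavelength) ||
      !identical(r$grid$masked, first$grid$masked)) {
      halo_abort("records are on different grids", "halotype_bad_spectrum")
    }
    key_a <- c(r$genotype, r$treatment, r$year, r$replicate)
    key_b <- c(first$genotype, first$treatment, first$year, first$replicate)
    if (!identical(key_a, key_b)) {
      halo_abort("records have different plot keys", "halotype_bad_spectrum")
    }
  }
  mat <- do.call(rbind, lapply(records, `[[`, "reflectance"))
  out <- first
  out$reflectance <- colMeans(mat)
  out
}

#' Build a spectra set
#'
#' Container for a trial's plot spectra: one shared grid, a metadata
#' table (genotype, treatment, year, replicate) and a records x samples
#' reflectance matrix.
#'
#' @param grid a [wavelength_grid()].
#' @param meta data.frame with columns `genotype`, `treatment`, `year`,
#'   `replicate`.
#' @param reflectance numeric matrix, `nrow(meta)` rows, one column per
#'   grid sample.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(grid, meta, reflectance) {
  stopifnot(inherits(grid, "wavelength_grid"))
  need <- c("genotype", "treatment", "year", "replicate")
  if (!all(need %in% names(meta))) {
    halo_abort(
      paste("meta must have columns", paste(need, collapse = ", ")),
      "halotype_bad_spectra_set"
    )
  }
  check_treatment(meta$treatment)
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != nrow(meta) ||
    ncol(reflectance) != sample_count(grid)) {
    halo_abort(
      "reflectance matrix must be nrow(meta) x sample_count(grid)",
      "halotype_bad_spectra_set"
    )
  }
  reflectance <- rescale_percent(reflectance)
  key <- do.call(paste, c(meta[need], sep = "\r"))
  if (anyDuplicated(key)) {
    halo_abort(
      "duplicate (genotype, treatment, year, replicate) keys; average scans first",
      "halotype_bad_spectra_set"
    )
  }
  structure(
    list(grid = grid, meta = as.data.frame(meta), reflectance = reflectance),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d plot spectra on %d-%d nm grid (%d masked samples)\n",
    nrow(x$meta), x$grid$start_nm, x$grid$end_nm, masked_count(x$grid)
  ))
  invisible(x)
}

#' Extract one record from a spectra set
#'
#' @param set a [spectra_set()].
#' @param i row index.
#' @return a [spectrum_record()].
#' @export
get_record <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"))
  m <- set$meta[i, ]
  spectrum_record(
    set$grid, set$reflectance[i, ],
    genotype = m$genotype, treatment = m$treatment,
    year = m$year, replicate = m$replicate
  )
}

#' Read plot spectra from delimited text
#'
#' Accepts two dialects: wide (one row per plot; columns `genotype,
#' treatment, year, replicate` then one column per integer wavelength)
#' and long (`genotype, treatment, year, replicate, wavelength_nm,
#' reflectance`). The dialect is detected from the header unless given.
#'
#' @param path file path (CSV, or TSV when the header contains tabs).
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param mask_windows mask windows applied to the grid; defaults to
#'   [default_mask_windows()]; use `list()` for none.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, format = c("auto", "wide", "long"),
                         mask_windows = default_mask_windows()) {
  format <- match.arg(format)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (format == "auto") {
    format <- if ("wavelength_nm" %in% names(df)) "long" else "wide"
  }
  if (format == "long") {
    need <- c("genotype", "treatment", "year", "replicate",
              "wavelength_nm", "reflectance")
    if (!all(need %in% names(df))) {
      halo_abort(
        paste("long format needs columns", paste(need, collapse = ", ")),
        "halotype_bad_file"
      )
    }
    wl <- sort(unique(as.integer(df$wavelength_nm)))
    key_cols <- c("genotype", "treatment", "year", "replicate")
    key <- do.call(paste, c(df[key_cols], sep = "\r"))
    ukey <- unique(key)
    mat <- matrix(NA_real_, nrow = length(ukey), ncol = length(wl))
    row_i <- match(key, ukey)
    col_i <- match(as.integer(df$wavelength_nm), wl)
    mat[cbind(row_i, col_i)] <- df$reflectance
    meta <- df[match(ukey, key), key_cols]
  } else {
    wl_col <- suppressWarnings(as.integer(names(df)))
    is_wl <- !is.na(wl_col)
    if (sum(is_wl) < 2L) {
      halo_abort("wide format needs integer wavelength columns", "halotype_bad_file")
    }
    wl <- wl_col[is_wl]
    meta <- df[, !is_wl, drop = FALSE]
    names(meta)[names(meta) == "rep"] <- "replicate"
    mat <- as.matrix(df[, is_wl, drop = FALSE])
  }
  step <- unique(diff(wl))
  if (length(step) != 1L) {
    halo_abort("wavelengths do not form a regular grid", "halotype_bad_file")
  }
  grid <- wavelength_grid(min(wl), max(wl), step, allow_coarse = TRUE)
  if (length(mask_windows)) grid <- apply_mask(grid, mask_windows)
  rownames(mat) <- NULL
  spectra_set(grid, meta, mat)
}

#' Write a spectra set as wide delimited text
#'
#' @param set a [spectra_set()].
#' @param path output file (CSV).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  out <- cbind(
    set$meta[c("genotype", "treatment", "year", "replicate")],
    as.data.frame(set$reflectance)
  )
  names(out)[-(1:4)] <- set$grid$wavelength
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a spectra file
#'
#' Reads a spectra file and reports its grid, masked-sample count and any
#' out-of-range reflectance values.
#'
#' @param path file path.
#' @return a list with `grid`, `n_records`, `masked`, `out_of_range`.
#' @export
validate_spectra <- function(path) {
  set <- read_spectra(path)
  bad <- sum(set$reflectance < 0 | set$reflectance > 1, na.rm = TRUE)
  list(
    grid = set$grid,
    n_records = nrow(set$meta),
    masked = masked_count(set$grid),
    out_of_range = bad
  )
}
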