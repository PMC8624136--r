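#' @keywords internal
"_PACKAGE"

## Classed error helper so callers can distinguish failure modes
## (e.g. missing-band conditions caught by the index evaluator).
halo_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "halotype_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

halo_warn <- function(message, class = "halotype_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Report tables round to a fixed number of decimals with ties going up
#' (5.125 -> 5.13), matching how the study's tables are printed, rather
#' than R's default round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## p-value -> significance stars at the 0.05 / 0.01 / 0.001 thresholds.
significance_code <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns")
      )
    )
  )
}

TREATMENTS <- c("control", "salinity")

check_treatment <- function(treatment) {
  if (!all(treatment %in% TREATMENTS)) {
    halo_abort(
      sprintf(
        "treatment must be one of %s",
        paste(TREATMENTS, collapse = ", ")
      ),
      "halotype_bad_treatment"
    )
  }
  treatment
}
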