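## Stepwise multiple linear regression of yields / tolerance indices on
## spectral indices, plus per-group best linear/quadratic fits.
##
## Selection is the classical partial-F procedure: at each step the
## candidate whose entry has the smallest partial-F p-value is added if
## that p-value is below alpha_enter; then any included variable whose
## partial-F p-value exceeds alpha_remove is dropped. Entry ties resolve
## by candidate order. Reported fits are ordinary least squares with
## R^2 = 1 - SSE/SST and RMSE = sqrt(SSE/n).

ols_sse <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(sse = sum(fit$residuals^2), rank = fit$rank,
       coefficients = fit$coefficients)
}

#' Ordinary least squares fit report
#'
#' Fits y on the given predictors (intercept added) and reports the
#' coefficients, coefficient of determination and root mean squared
#' error. RMSE uses n in the denominator (not n - p). A constant
#' response (zero total sum of squares) leaves R^2 undefined (`NA`).
#'
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column), or `NULL` for an intercept-only fit.
#' @param y numeric response.
#' @return list: `coefficients` (named, intercept first), `r_squared`,
#'   `rmse`, `n`, `fitted`, `residuals`.
#' @export
#' @examples
#' fit_report(cbind(x = c(1, 2, 3)), c(1, 2, 4))
fit_report <- function(X, y) {
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    Xm <- cbind("(Intercept)" = 1, X)
  }
  if (nrow(Xm) != n) halo_abort("X and y lengths differ", "halotype_bad_fit")
  fit <- stats::lm.fit(Xm, y)
  if (fit$rank < ncol(Xm)) {
    halo_abort("rank-deficient design", "halotype_rank_deficient")
  }
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(
    coefficients = fit$coefficients,
    r_squared = if (sst == 0) NA_real_ else 1 - sse / sst,
    rmse = sqrt(sse / n),
    n = n,
    fitted = as.numeric(fit$fitted.values),
    residuals = as.numeric(fit$residuals)
  )
}

## Partial-F p-value for the change between a reduced and a full model
## differing by one term. Degenerate perfect-fit cases: an improvement on
## an already-perfect reduced model is impossible, and a term that brings
## SSE to (or keeps it at) ~0 has p ~ 0 unless it adds nothing.
partial_f_p <- function(sse_red, sse_full, df_full, sst) {
  tol <- 1e-12 * max(sst, 1)
  gain <- sse_red - sse_full
  if (sse_full <= tol) {
    return(if (gain <= tol) 1 else 0)
  }
  if (df_full < 1) return(NA_real_)
  f <- gain / (sse_full / df_full)
  stats::pf(f, 1, df_full, lower.tail = FALSE)
}

#' Stepwise multiple linear regression by partial F
#'
#' Forward selection with backward elimination over the candidate
#' columns, in column order. At each iteration the candidate with the
#' smallest entry p-value joins the model if p < `alpha_enter`; any
#' included variable whose p-value rises above `alpha_remove` is then
#' removed. The procedure stops when no variable enters or leaves, and
#' the final model is reported via [fit_report()]. Deterministic given
#' the data and candidate order; exact duplicates of an included
#' candidate can never enter (rank-deficiency is skipped).
#'
#' @param candidates data.frame or matrix of candidate predictors;
#'   column order is the tie-break order.
#' @param y numeric response.
#' @param dependent name of the response for reporting.
#' @param alpha_enter entry threshold (default 0.05).
#' @param alpha_remove removal threshold (default 0.10); must be >=
#'   `alpha_enter` or selection could cycle.
#' @return object of class `smlr_report`: list with `dependent`,
#'   `selected` (in entry order), `coefficients`, `r_squared`, `rmse`,
#'   `n`, `steps` (log of entries/removals) and `equation` (display
#'   string).
#' @export
smlr <- function(candidates, y, dependent = "y",
                 alpha_enter = 0.05, alpha_remove = 0.10) {
  if (alpha_remove < alpha_enter) {
    halo_abort(
      "alpha_remove must be >= alpha_enter (else selection can cycle)",
      "halotype_bad_alpha"
    )
  }
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0L) {
    halo_abort("no candidate predictors", "halotype_bad_candidates")
  }
  if (any(is.na(candidates)) || any(is.na(y))) {
    halo_abort("missing cells in candidates or response", "halotype_bad_fit")
  }
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  cand_names <- colnames(candidates)
  selected <- character(0)
  design <- function(vars) {
    cbind(1, as.matrix(candidates[vars]))
  }
  sse_of <- function(vars) {
    if (!length(vars)) return(list(sse = sst, rank = 1L))
    f <- ols_sse(design(vars), y)
    list(sse = f$sse, rank = f$rank)
  }
  steps <- list()
  repeat {
    changed <- FALSE
    cur <- sse_of(selected)
    # forward: best entering candidate by partial-F p
    pool <- setdiff(cand_names, selected)
    df_full <- n - (length(selected) + 2L)
    if (length(pool) && df_full >= 1) {
      pvals <- vapply(pool, function(v) {
        trial <- sse_of(c(selected, v))
        if (trial$rank < length(selected) + 2L) return(NA_real_) # collinear
        partial_f_p(cur$sse, trial$sse, df_full, sst)
      }, numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < alpha_enter) {
        best <- pool[which.min(pvals)] # first minimum = candidate order
        selected <- c(selected, best)
        steps[[length(steps) + 1L]] <- sprintf(
          "+ %s (p = %.3g)", best, min(pvals, na.rm = TRUE)
        )
        changed <- TRUE
      }
    }
    # backward: drop worst included variable while p > alpha_remove
    repeat {
      if (length(selected) < 1L) break
      full <- sse_of(selected)
      df_full <- n - (length(selected) + 1L)
      if (df_full < 1L) break
      pvals <- vapply(selected, function(v) {
        red <- sse_of(setdiff(selected, v))
        partial_f_p(red$sse, full$sse, df_full, sst)
      }, numeric(1))
      worst <- which.max(pvals)
      if (!is.na(pvals[worst]) && pvals[worst] > alpha_remove) {
        steps[[length(steps) + 1L]] <- sprintf(
          "- %s (p = %.3g)", selected[worst], pvals[worst]
        )
        selected <- selected[-worst]
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }
  report <- if (length(selected)) {
    fit_report(candidates[selected], y)
  } else {
    fit_report(NULL, y)
  }
  coefs <- report$coefficients
  eq <- if (length(selected)) {
    paste0(
      dependent, " = ", sprintf("%.3f", coefs[1]), " ",
      paste(
        sprintf("%+.3f(%s)", coefs[-1], selected),
        collapse = " "
      )
    )
  } else {
    paste0(dependent, " = ", sprintf("%.3f", coefs[1]))
  }
  structure(
    list(
      dependent = dependent, selected = selected,
      coefficients = coefs, r_squared = report$r_squared,
      rmse = report$rmse, n = report$n,
      steps = unlist(steps) %||% character(0), equation = eq
    ),
    class = "smlr_report"
  )
}

#' @export
print.smlr_report <- function(x, ...) {
  cat(sprintf(
    "<smlr_report> %s\n  R^2 = %.3f, RMSE = %.3f, n = %d\n",
    x$equation, x$r_squared, x$rmse, x$n
  ))
  invisible(x)
}

#' Best linear or quadratic fit for one group
#'
#' Fits both a linear (L) and quadratic (Q) model of `y` on `x` and keeps
#' the quadratic only when its R^2 exceeds the linear R^2 by more than
#' `margin` (parsimony tie-break). Significance stars come from the
#' chosen model's overall-F p-value at the 0.05 / 0.01 / 0.001 levels.
#'
#' @param x predictor (e.g. a genotype-mean index).
#' @param y response (e.g. grain yield).
#' @param group group label for reporting.
#' @param x_name,y_name variable names for reporting.
#' @param margin minimum R^2 gain for preferring the quadratic.
#' @return one-row data.frame: `group`, `x`, `y`, `form` (`"L"`/`"Q"`),
#'   `b0`, `b1`, `b2` (`NA` for L), `r_squared`, `code`.
#' @export
best_group_fit <- function(x, y, group = NA_character_,
                           x_name = "x", y_name = "y", margin = 0.01) {
  n <- length(x)
  if (n < 4L) halo_abort("need >= 4 points for the L/Q comparison",
                         "halotype_bad_fit")
  lin <- fit_report(cbind(x = x), y)
  qua <- fit_report(cbind(x = x, x2 = x^2), y)
  use_q <- !is.na(qua$r_squared) && !is.na(lin$r_squared) &&
    qua$r_squared > lin$r_squared + margin
  fit <- if (use_q) qua else lin
  k <- if (use_q) 2L else 1L
  r2 <- fit$r_squared
  p <- if (is.na(r2)) {
    NA_real_
  } else if (r2 >= 1) {
    0
  } else {
    f <- (r2 / k) / ((1 - r2) / (n - k - 1))
    stats::pf(f, k, n - k - 1, lower.tail = FALSE)
  }
  data.frame(
    group = group, x = x_name, y = y_name,
    form = if (use_q) "Q" else "L",
    b0 = unname(fit$coefficients[1]),
    b1 = unname(fit$coefficients[2]),
    b2 = if (use_q) unname(fit$coefficients[3]) else NA_real_,
    r_squared = r2,
    code = significance_code(p),
    stringsAsFactors = FALSE
  )
}
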