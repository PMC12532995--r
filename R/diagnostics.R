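# Pleiotropy and directionality diagnostics for a harmonised instrument set.

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the primary causal effect with each instrument excluded in
#' turn. An instrument is a "driver" when the full-set confidence interval
#' excludes zero but the interval without that instrument includes zero —
#' the signature of a signal carried by a single (potentially pleiotropic)
#' variant, as at hub loci such as ABO. If the full-set interval already
#' spans zero there is no signal to lose and no instrument can be a driver.
#'
#' @param insts \code{mr_instruments} with at least 2 rows (with exactly 2,
#'   each leave-one-out estimate is a Wald ratio).
#' @param alpha two-sided level for the "crosses the null" interval
#'   (default 0.05, i.e. the same 95\% CI used for headline estimates).
#' @return Object of class \code{loo_result}: list with \code{estimates}
#'   (data.frame: excluded_variant, theta, se, ci_low, ci_high, pvalue),
#'   \code{full} (the full-set \code{mr_estimate}), \code{drivers}
#'   (character vector) and \code{pass} (TRUE iff no drivers).
#' @export
leave_one_out <- function(insts, alpha = 0.05) {
  j <- nrow(insts)
  if (j < 2L) stop("LOO undefined for a single instrument", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  full <- primary_estimate(insts)
  full_excludes0 <- (full$theta - z * full$se) > 0 || (full$theta + z * full$se) < 0
  rows <- lapply(seq_len(j), function(k) {
    e <- primary_estimate(insts[-k, , drop = FALSE])
    data.frame(excluded_variant = insts$variant_id[k],
               theta = e$theta, se = e$se,
               ci_low = e$theta - z * e$se, ci_high = e$theta + z * e$se,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  includes0 <- est$ci_low <= 0 & est$ci_high >= 0
  drivers <- if (full_excludes0) est$excluded_variant[includes0] else character()
  structure(list(estimates = est, full = full, drivers = drivers,
                 pass = length(drivers) == 0L, alpha = alpha),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d instruments: %s\n", nrow(x$estimates),
              if (x$pass) "pass (no single-variant drivers)"
              else paste0("FAIL, driver(s): ", paste(x$drivers, collapse = ", "))))
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against the
#' variance they explain in the outcome: a valid instrument set should
#' explain more of the exposure (instrument -> protein -> disease, not the
#' reverse). For the case-control outcome the variance explained is an
#' observed-scale approximation weighted by the case fraction,
#' \eqn{2 p (1-p) \beta_{out}^2 \, n_{case} n_{control} / n^2}. The z-score
#' compares Fisher-transformed correlations with the respective sample sizes.
#'
#' @param insts \code{mr_instruments}.
#' @param n_exp exposure GWAS sample size.
#' @param n_case,n_control outcome case/control counts.
#' @return Object of class \code{steiger_result}: list with
#'   \code{r2_exposure}, \code{r2_outcome}, \code{direction_ok},
#'   \code{zscore}, \code{pvalue}.
#' @export
steiger_test <- function(insts, n_exp, n_case, n_control) {
  if (min(n_exp, n_case + n_control) <= 3)
    stop("sample sizes too small for the Steiger test", call. = FALSE)
  n_out <- n_case + n_control
  r2_exp <- sum(variance_explained(insts$beta_exp, insts$eaf))
  r2_out <- sum(2 * insts$eaf * (1 - insts$eaf) * insts$beta_out^2 *
                  (n_case * n_control / n_out^2))
  cap <- function(r2, side) {
    if (r2 >= 1) {
      warning(sprintf("summed r2 for the %s reached 1; capped", side), call. = FALSE)
      1 - 1e-12
    } else r2
  }
  r2_exp <- cap(r2_exp, "exposure"); r2_out <- cap(r2_out, "outcome")
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 direction_ok = r2_exp > r2_out,
                 zscore = z, pvalue = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2(exposure) = %.4g vs r2(outcome) = %.4g -> %s (z = %.2f, p = %.3g)\n",
              x$r2_exposure, x$r2_outcome,
              if (x$direction_ok) "exposure-first direction supported"
              else "direction NOT supported",
              x$zscore, x$pvalue))
  invisible(x)
}

#' Cis-only replication estimate
#'
#' Re-runs the primary estimator on the cis-flagged instruments only, a
#' replication under a reduced likelihood of pleiotropy (cis-pQTLs act near
#' the encoding gene and are less often pleiotropic than trans-pQTLs).
#'
#' @param insts \code{mr_instruments} carrying a logical \code{cis} column.
#' @return An \code{mr_estimate}, or \code{NULL} when no instrument is cis.
#' @export
cis_only_estimate <- function(insts) {
  cis <- insts[insts$cis %in% TRUE, , drop = FALSE]
  if (!nrow(cis)) return(NULL)
  primary_estimate(cis)
}

#' Per-instrument Wald ratio profile
#'
#' One Wald ratio per instrument, used to attribute a signal to individual
#' variants (e.g. confirming that only a hub variant carries an association).
#'
#' @param insts \code{mr_instruments} with at least 1 row.
#' @return data.frame: variant_id, theta, se, ci_low, ci_high, pvalue,
#'   ordered as the input.
#' @export
single_pqtl_profile <- function(insts) {
  if (!nrow(insts)) stop("no instruments", call. = FALSE)
  rows <- lapply(seq_len(nrow(insts)), function(k) {
    e <- wald_ratio(insts[k, , drop = FALSE])
    data.frame(variant_id = insts$variant_id[k], theta = e$theta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
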