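#' Fit the full two-sample MR model for one protein-outcome pair
#'
#' The central fitting function: given a harmonised instrument set it
#' computes the primary causal estimate (Wald ratio for one instrument, IVW
#' for two or more), the sensitivity estimators (MR-Egger, weighted median,
#' weighted mode) when three or more instruments allow, the leave-one-out
#' and Egger-intercept pleiotropy diagnostics, the Steiger directionality
#' test when sample sizes are supplied, and the cis-only replication when
#' cis flags are present.
#'
#' @param insts \code{mr_instruments} data.frame (from
#'   \code{\link{harmonise}} or \code{\link{mr_instruments}}).
#' @param n_exp exposure GWAS sample size (optional; enables the Steiger
#'   test together with \code{n_case}/\code{n_control}).
#' @param n_case,n_control outcome case/control counts (optional).
#' @param random_effects multiplicative random-effects IVW (default FALSE).
#' @param n_boot bootstrap replicates for median/mode SEs (default 1000).
#' @param phi weighted-mode bandwidth multiplier (default 1).
#' @param loo_alpha level for the leave-one-out interval (default 0.05).
#' @param seed integer seed for the bootstrap SEs.
#' @return Object of class \code{mr_fit}: list with elements
#'   \code{instruments}, \code{primary}, \code{egger}, \code{wmedian},
#'   \code{wmode}, \code{loo}, \code{steiger}, \code{cis_only},
#'   \code{n_snps}. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{confint} and \code{plot}.
#' @examples
#' ins <- mr_instruments(beta_exp = c(0.3, 0.5, 0.8),
#'                       se_exp = c(0.02, 0.02, 0.02),
#'                       beta_out = c(0.15, 0.25, 0.40),
#'                       se_out = c(0.1, 0.1, 0.1))
#' fit <- mr_fit(ins, seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(insts, n_exp = NULL, n_case = NULL, n_control = NULL,
                   random_effects = FALSE, n_boot = 1000, phi = 1,
                   loo_alpha = 0.05, seed = NULL) {
  j <- nrow(insts)
  if (j < 1L) stop("no instruments to fit", call. = FALSE)
  fit <- list(instruments = insts, n_snps = j,
              primary = primary_estimate(insts, random_effects = random_effects),
              egger = NULL, wmedian = NULL, wmode = NULL,
              loo = NULL, steiger = NULL, cis_only = NULL)
  if (j >= 3L) {
    fit$egger <- mr_egger(insts)
    fit$wmedian <- weighted_median(insts, n_boot = n_boot, seed = seed)
    fit$wmode <- weighted_mode(insts, phi = phi, n_boot = n_boot,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  }
  if (j >= 2L) fit$loo <- leave_one_out(insts, alpha = loo_alpha)
  if (!is.null(n_exp) && !is.null(n_case) && !is.null(n_control))
    fit$steiger <- steiger_test(insts, n_exp, n_case, n_control)
  if (any(insts$cis %in% TRUE)) fit$cis_only <- cis_only_estimate(insts)
  class(fit) <- "mr_fit"
  fit
}

mr_fit_estimates <- function(x) {
  ests <- list(primary = x$primary)
  if (!is.null(x$egger)) ests$egger <- x$egger$slope
  if (!is.null(x$wmedian)) ests$weighted_median <- x$wmedian
  if (!is.null(x$wmode)) ests$weighted_mode <- x$wmode
  if (!is.null(x$cis_only)) ests$cis_only <- x$cis_only
  ests
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit on %d instrument%s\n", x$n_snps,
              if (x$n_snps == 1) "" else "s"))
  print(x$primary)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  ests <- mr_fit_estimates(object)
  tab <- do.call(rbind, lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    or <- to_odds_scale(e)
    data.frame(method = if (nm == "primary") e$method else nm,
               n_snps = e$n_snps, theta = e$theta, se = e$se,
               or_point = or$or, or_low = or$or_low, or_high = or$or_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  }))
  out <- list(estimates = tab,
              egger_intercept = if (is.null(object$egger)) NULL
                else object$egger[c("intercept", "intercept_se", "intercept_p")],
              loo = object$loo, steiger = object$steiger)
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat("Causal estimates (log-odds per 1 SD higher exposure):\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (!is.null(x$egger_intercept))
    cat(sprintf("MR-Egger intercept: %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept$intercept, x$egger_intercept$intercept_se,
                x$egger_intercept$intercept_p))
  if (!is.null(x$loo)) print(x$loo)
  if (!is.null(x$steiger)) print(x$steiger)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  ests <- mr_fit_estimates(object)
  vapply(ests, function(e) e$theta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ests <- mr_fit_estimates(object)
  if (!missing(parm)) ests <- ests[parm]
  m <- t(vapply(ests, function(e) c(e$theta - z * e$se, e$theta + z * e$se),
                numeric(2)))
  colnames(m) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  m
}

#' Scatter plot of a two-sample MR fit
#'
#' Outcome effects against exposure effects (instruments oriented to a
#' positive exposure effect) with per-variant error bars, the IVW/Wald line
#' through the origin and, when available, the MR-Egger line.
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.mr_fit <- function(x, ...) {
  ins <- x$instruments
  flip <- ins$beta_exp < 0
  bx <- abs(ins$beta_exp)
  by <- ifelse(flip, -ins$beta_out, ins$beta_out)
  graphics::plot(bx, by, pch = 19,
                 xlim = range(0, bx + ins$se_exp),
                 ylim = range(by - 1.96 * ins$se_out, by + 1.96 * ins$se_out, 0),
                 xlab = "pQTL effect on protein (SD per allele)",
                 ylab = "Variant effect on outcome (log-odds per allele)",
                 ...)
  graphics::segments(bx, by - 1.96 * ins$se_out, bx, by + 1.96 * ins$se_out)
  graphics::segments(bx - ins$se_exp, by, bx + ins$se_exp, by)
  graphics::abline(0, x$primary$theta, lwd = 2)
  if (!is.null(x$egger))
    graphics::abline(x$egger$intercept, x$egger$slope$theta, lty = 2)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
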