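# Causal-effect estimators for two-sample MR on harmonised instruments.
# theta is always the log-odds (or outcome-unit) change per 1 SD higher
# exposure; 95% CIs use 1.96, p-values come from the normal except where a
# t reference is noted (MR-Egger).

new_mr_estimate <- function(method, theta, se, n_snps, df = NULL) {
  pvalue <- if (is.null(df)) {
    2 * stats::pnorm(-abs(theta / se))
  } else if (!is.finite(se) || se <= 0) {
    if (theta == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(theta / se), df = df)
  }
  if (is.nan(pvalue)) pvalue <- 1    # 0/0: no effect, no information
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
                 pvalue = pvalue, n_snps = as.integer(n_snps)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  or <- to_odds_scale(x)
  cat(sprintf("%s estimate (%d SNP%s): theta = %.*f (se %.*f), 95%% CI [%.*f, %.*f], p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              digits, x$theta, digits, x$se, digits, x$ci_low, digits, x$ci_high,
              x$pvalue))
  cat(sprintf("  OR %.2f, 95%% CI [%.2f, %.2f] per 1 SD higher exposure\n",
              or$or, or$or_low, or$or_high))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' theta = beta_out / beta_exp with first-order delta-method standard error
#' se_out / |beta_exp| (the exposure SE is ignored; a second-order SE that
#' propagates it is available via \code{second_order = TRUE}).
#'
#' @param insts a one-row \code{mr_instruments} data.frame.
#' @param second_order if TRUE, use the second-order delta-method SE.
#' @return An \code{mr_estimate} (method \code{"wald"}).
#' @export
wald_ratio <- function(insts, second_order = FALSE) {
  if (nrow(insts) != 1L) stop("wald_ratio needs exactly one instrument", call. = FALSE)
  bx <- insts$beta_exp; by <- insts$beta_out
  if (bx == 0) stop("undefined ratio: exposure effect is zero", call. = FALSE)
  theta <- by / bx
  se <- if (second_order) {
    sqrt(insts$se_out^2 / bx^2 + by^2 * insts$se_exp^2 / bx^4)
  } else {
    insts$se_out / abs(bx)
  }
  new_mr_estimate("wald", theta, se, 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Meta-analysis of per-instrument ratio estimates with weights
#' \eqn{1/se_{out}^2}; equivalent to a weighted least-squares regression of
#' outcome on exposure effects through the origin. Fixed-effect by default;
#' \code{random_effects = TRUE} inflates the SE by
#' \eqn{\max(1, \sqrt{Q/(J-1)})} (multiplicative random effects).
#'
#' @param insts \code{mr_instruments} with at least 2 rows.
#' @param random_effects logical.
#' @return An \code{mr_estimate} (method \code{"ivw"}).
#' @export
ivw <- function(insts, random_effects = FALSE) {
  if (nrow(insts) < 2L)
    stop("IVW needs at least 2 instruments; use wald_ratio for 1", call. = FALSE)
  bx <- insts$beta_exp; by <- insts$beta_out; w <- 1 / insts$se_out^2
  denom <- sum(bx^2 * w)
  theta <- sum(bx * by * w) / denom
  se <- sqrt(1 / denom)
  if (random_effects) {
    q <- sum(w * (by - theta * bx)^2)
    se <- se * max(1, sqrt(q / (nrow(insts) - 1)))
  }
  new_mr_estimate("ivw", theta, se, nrow(insts))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an unconstrained intercept, weights \eqn{1/se_{out}^2}, after
#' orienting every instrument to a non-negative exposure effect. A non-zero
#' intercept indicates directional horizontal pleiotropy; the slope is a
#' pleiotropy-adjusted causal estimate (valid under InSIDE). Inference uses
#' the t distribution with J - 2 degrees of freedom.
#'
#' @param insts \code{mr_instruments} with at least 3 rows.
#' @return Object of class \code{egger_result}: list with \code{slope} (an
#'   \code{mr_estimate}, method \code{"egger"}), \code{intercept},
#'   \code{intercept_se}, \code{intercept_p}, \code{n_snps}.
#' @export
mr_egger <- function(insts) {
  j <- nrow(insts)
  if (j < 3L) stop("insufficient instruments for Egger (need >= 3)", call. = FALSE)
  flip <- insts$beta_exp < 0
  bx <- abs(insts$beta_exp)
  by <- ifelse(flip, -insts$beta_out, insts$beta_out)
  fit <- stats::lm(by ~ bx, weights = 1 / insts$se_out^2)
  cf <- summary(fit)$coefficients
  slope <- cf["bx", "Estimate"]; slope_se <- cf["bx", "Std. Error"]
  icpt <- cf["(Intercept)", "Estimate"]; icpt_se <- cf["(Intercept)", "Std. Error"]
  tp <- function(est, se) {
    if (!is.finite(se) || se <= 0) return(if (est == 0) 1 else 0)
    2 * stats::pt(-abs(est / se), df = j - 2)
  }
  slope_est <- new_mr_estimate("egger", slope, slope_se, j, df = j - 2)
  structure(list(slope = slope_est,
                 intercept = icpt, intercept_se = icpt_se,
                 intercept_p = tp(icpt, icpt_se), n_snps = j),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept %.4f (se %.4f), p = %.3g [t, %d df]\n",
              x$intercept, x$intercept_se, x$intercept_p, x$n_snps - 2))
  invisible(x)
}

# per-instrument ratio estimates and their inverse-variance weights
ratio_weights <- function(insts) {
  theta_j <- insts$beta_out / insts$beta_exp
  w <- (insts$se_out / abs(insts$beta_exp))^-2
  list(theta = theta_j, w = w / sum(w))
}

weighted_median_point <- function(theta_j, w) {
  o <- order(theta_j)
  th <- theta_j[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[length(p)]) return(th[length(th)])
  stats::approx(p, th, xout = 0.5, ties = "ordered")$y
}

weighted_mode_point <- function(theta_j, w, phi = 1) {
  s <- stats::sd(theta_j)
  iqr <- stats::IQR(theta_j)
  h <- phi * 0.9 * min(s, iqr / 1.349) * length(theta_j)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta_j[1])   # all ratios identical
  d <- stats::density(theta_j, weights = w / sum(w), bw = h,
                      n = 512, from = min(theta_j) - 3 * h,
                      to = max(theta_j) + 3 * h)
  d$x[which.max(d$y)]
}

# parametric bootstrap SE for the ratio-based estimators: betas resampled
# from their reported sampling distributions
boot_se <- function(insts, point_fun, n_boot, seed) {
  est <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(insts), insts$beta_exp, insts$se_exp)
      by <- stats::rnorm(nrow(insts), insts$beta_out, insts$se_out)
      bx[bx == 0] <- 1e-300
      th <- by / bx
      w <- (insts$se_out / abs(bx))^-2
      point_fun(th, w / sum(w))
    }, numeric(1))
  })
  stats::sd(est)
}

#' Weighted-median MR estimate
#'
#' The inverse-variance weighted median of the per-instrument ratio
#' estimates: consistent when instruments carrying at least half the weight
#' are valid. The SE comes from a seeded parametric bootstrap that resamples
#' both exposure and outcome effects from their sampling distributions.
#'
#' @param insts \code{mr_instruments} with at least 3 rows.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (optional but recommended).
#' @return An \code{mr_estimate} (method \code{"weighted_median"}).
#' @export
weighted_median <- function(insts, n_boot = 1000, seed = NULL) {
  if (nrow(insts) < 3L) stop("weighted median needs >= 3 instruments", call. = FALSE)
  rw <- ratio_weights(insts)
  point <- weighted_median_point(rw$theta, rw$w)
  se <- boot_se(insts, weighted_median_point, n_boot, seed)
  new_mr_estimate("weighted_median", point, se, nrow(insts))
}

#' Weighted-mode MR estimate
#'
#' The mode of the Gaussian-kernel-smoothed, inverse-variance weighted
#' density of per-instrument ratios: consistent when the largest group of
#' instruments sharing the same ratio is valid (ZEMPA). Bandwidth follows a
#' modified Silverman rule, \eqn{\phi \cdot 0.9 \min(sd, IQR/1.349) J^{-1/5}}.
#'
#' @param insts \code{mr_instruments} with at least 3 rows.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An \code{mr_estimate} (method \code{"weighted_mode"}).
#' @export
weighted_mode <- function(insts, phi = 1, n_boot = 1000, seed = NULL) {
  if (nrow(insts) < 3L) stop("weighted mode needs >= 3 instruments", call. = FALSE)
  rw <- ratio_weights(insts)
  point <- weighted_mode_point(rw$theta, rw$w, phi = phi)
  se <- boot_se(insts, function(th, w) weighted_mode_point(th, w, phi = phi),
                n_boot, seed)
  new_mr_estimate("weighted_mode", point, se, nrow(insts))
}

#' Primary MR estimate with method dispatch
#'
#' Uses the Wald ratio for a single instrument and IVW for two or more.
#'
#' @param insts \code{mr_instruments} with at least 1 row.
#' @param random_effects passed to \code{\link{ivw}}.
#' @return An \code{mr_estimate}.
#' @export
primary_estimate <- function(insts, random_effects = FALSE) {
  if (nrow(insts) < 1L) stop("no instruments", call. = FALSE)
  if (nrow(insts) == 1L) wald_ratio(insts) else ivw(insts, random_effects)
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' @param est an \code{mr_estimate}.
#' @return list with \code{or}, \code{or_low}, \code{or_high} (exponentiated
#'   point estimate and 95% CI bounds).
#' @export
to_odds_scale <- function(est) {
  list(or = exp(est$theta), or_low = exp(est$ci_low), or_high = exp(est$ci_high))
}
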