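#' Scan configuration
#'
#' Collects every tunable of the proteome-wide scan with its default. All
#' randomness (bootstrap SEs, any simulation) flows from \code{seed}.
#'
#' @param p_max pQTL discovery significance threshold, strict (default
#'   1.7e-11).
#' @param f_min minimum instrument F-statistic (default 10).
#' @param cis_window_bp cis window around the encoding gene (default 1e6).
#' @param r2_min minimum LD r-squared for proxy substitution (default 0.8).
#' @param random_effects multiplicative random-effects IVW (default FALSE).
#' @param n_boot bootstrap replicates for median/mode SEs (default 1000).
#' @param phi weighted-mode bandwidth multiplier (default 1).
#' @param loo_alpha level for the leave-one-out "crosses the null" interval
#'   (default 0.05).
#' @param steiger_enabled run the Steiger directionality test (default TRUE).
#' @param fdr_alpha FDR level for the Benjamini-Hochberg step-up
#'   (default 0.05).
#' @param nominal_alpha nominal significance level for the suggestive tier
#'   (default 0.05). Must satisfy fdr_alpha <= nominal_alpha.
#' @param intercept_alpha level of the Egger-intercept pleiotropy gate
#'   (default 0.05; intercept p above it = no evidence of pleiotropy).
#' @param fdr_family \code{"pooled"} (one family across all protein-outcome
#'   tests) or \code{"per_outcome"}.
#' @param coloc_mode \code{"fdr_pass"} (colocalise FDR-passing, LOO-passing
#'   records; default), \code{"all"}, or \code{"none"}.
#' @param p1,p2,p12,prior_sd1,prior_sd2 colocalisation priors (see
#'   \code{\link{colocalise}}).
#' @param seed master integer seed (default 1).
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(p_max = 1.7e-11, f_min = 10, cis_window_bp = 1e6,
                        r2_min = 0.8, random_effects = FALSE, n_boot = 1000,
                        phi = 1, loo_alpha = 0.05, steiger_enabled = TRUE,
                        fdr_alpha = 0.05, nominal_alpha = 0.05,
                        intercept_alpha = 0.05,
                        fdr_family = c("pooled", "per_outcome"),
                        coloc_mode = c("fdr_pass", "all", "none"),
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        prior_sd1 = 0.15, prior_sd2 = 0.2, seed = 1L) {
  fdr_family <- match.arg(fdr_family)
  coloc_mode <- match.arg(coloc_mode)
  if (!(fdr_alpha > 0 && fdr_alpha <= nominal_alpha && nominal_alpha < 1))
    stop("need 0 < fdr_alpha <= nominal_alpha < 1", call. = FALSE)
  structure(list(p_max = p_max, f_min = f_min, cis_window_bp = cis_window_bp,
                 r2_min = r2_min, random_effects = random_effects,
                 n_boot = n_boot, phi = phi, loo_alpha = loo_alpha,
                 steiger_enabled = steiger_enabled, fdr_alpha = fdr_alpha,
                 nominal_alpha = nominal_alpha, intercept_alpha = intercept_alpha,
                 fdr_family = fdr_family, coloc_mode = coloc_mode,
                 p1 = p1, p2 = p2, p12 = p12,
                 prior_sd1 = prior_sd1, prior_sd2 = prior_sd2,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Read a scan configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file of config keys.
#' @return A \code{\link{scan_config}}.
#' @export
read_scan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scan_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(scan_config, vals)
}
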