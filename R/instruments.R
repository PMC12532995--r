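#' Classify a variant as cis or trans relative to the encoding gene
#'
#' A pQTL is cis when it lies on the same chromosome as the gene encoding the
#' protein and within \code{window_bp} of the nearest gene boundary (variants
#' inside the gene have distance 0); otherwise it is trans. Gene start and end
#' may be given in either order.
#'
#' @param chrom,pos variant coordinates (1-based).
#' @param gene_region list or named vector with \code{chrom}, \code{start},
#'   \code{end} (closed interval).
#' @param window_bp cis window in base pairs (default 1 Mb).
#' @return \code{"cis"} or \code{"trans"}.
#' @export
classify_cis_trans <- function(chrom, pos, gene_region, window_bp = 1e6) {
  gchrom <- as.character(gene_region[["chrom"]])
  lo <- min(as.numeric(gene_region[["start"]]), as.numeric(gene_region[["end"]]))
  hi <- max(as.numeric(gene_region[["start"]]), as.numeric(gene_region[["end"]]))
  if (as.character(chrom) != gchrom) return("trans")
  d <- if (pos >= lo && pos <= hi) 0 else min(abs(pos - lo), abs(pos - hi))
  if (d <= window_bp) "cis" else "trans"
}

#' Instrument strength F-statistic from effect and standard error
#'
#' Per-variant F equals the squared GWAS z-score, \eqn{(\beta/se)^2}. Variants
#' with F below 10 are conventionally considered weak instruments.
#'
#' @param beta,se effect size and its standard error (se > 0). Vectorised.
#' @return Numeric F-statistic(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  (beta / se)^2
}

#' F-statistic from variance explained
#'
#' The r-squared-based form \eqn{F = r^2 (n - 2) / (1 - r^2)}, useful for
#' bookkeeping against published variance-explained values.
#'
#' @param r2 fraction of trait variance explained, in [0, 1).
#' @param n sample size (> 2).
#' @return Numeric F-statistic(s).
#' @export
f_from_r2 <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(n <= 2)) stop("n must be > 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Variance in a standardised trait explained by one variant
#'
#' Under Hardy-Weinberg and a unit-variance phenotype,
#' \eqn{r^2 = 2 p (1 - p) \beta^2} with \eqn{p} the effect-allele frequency.
#' Capped just below 1.
#'
#' @param beta per-allele effect in SD units.
#' @param eaf effect-allele frequency in (0, 1).
#' @return Fraction of variance explained.
#' @export
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie in (0, 1)", call. = FALSE)
  pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12)
}

#' Select genetic instruments for one protein
#'
#' Filters harmonised instruments on the pQTL discovery significance
#' threshold (strict \code{pvalue < p_max}) and instrument strength
#' (\code{F >= f_min}), attaches cis/trans flags and per-variant variance
#' explained. Input variants are assumed already pruned to independent
#' signals by the pQTL provider.
#'
#' @param insts \code{mr_instruments} data.frame (from \code{\link{harmonise}}
#'   or \code{\link{mr_instruments}}). If it lacks a \code{pvalue_exp} column,
#'   exposure p-values are computed from the z-score.
#' @param protein_id protein identifier.
#' @param gene_region optional gene region (see
#'   \code{\link{classify_cis_trans}}); when supplied and the instruments
#'   carry no cis flag, flags are left as given.
#' @param p_max exposure significance threshold (default 1.7e-11, a
#'   proteome-wide discovery threshold).
#' @param f_min minimum F-statistic (default 10).
#' @return Object of class \code{instrument_set}: list with
#'   \code{protein_id}, \code{gene_region}, \code{instruments} (with columns
#'   \code{f_stat} and \code{r2_explained} added) and \code{n_dropped}.
#'   An empty selection is flagged via \code{no_valid_instruments = TRUE},
#'   not an error.
#' @export
select_instruments <- function(insts, protein_id, gene_region = NULL,
                               p_max = 1.7e-11, f_min = 10) {
  p_exp <- if ("pvalue_exp" %in% names(insts)) insts$pvalue_exp
           else 2 * stats::pnorm(-abs(insts$beta_exp / insts$se_exp))
  f <- if (nrow(insts)) f_statistic(insts$beta_exp, insts$se_exp) else numeric()
  keep <- p_exp < p_max & f >= f_min
  kept <- insts[keep, , drop = FALSE]
  kept$f_stat <- f[keep]
  kept$r2_explained <- if (nrow(kept)) variance_explained(kept$beta_exp, kept$eaf)
                       else numeric()
  rownames(kept) <- NULL
  class(kept) <- c("mr_instruments", "data.frame")
  structure(list(protein_id = protein_id,
                 gene_region = gene_region,
                 instruments = kept,
                 n_dropped = sum(!keep),
                 no_valid_instruments = nrow(kept) == 0L),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d instruments (%d cis), %d dropped\n",
              x$protein_id, nrow(x$instruments),
              sum(x$instruments$cis %in% TRUE), x$n_dropped))
  if (x$no_valid_instruments) cat("  [no valid instruments]\n")
  invisible(x)
}
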