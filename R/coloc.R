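# Approximate-Bayes-factor colocalisation under the five-hypothesis
# decomposition (H0 no association; H1/H2 one trait only; H3 both traits,
# distinct causal variants; H4 both traits, shared causal variant).

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's approximate Bayes factor comparing an association with prior
#' effect SD \code{prior_sd} against the null, computed from the variant's
#' estimate and standard error. With \eqn{V = se^2}, \eqn{W = prior\_sd^2},
#' \eqn{r = W/(V+W)} and \eqn{z = beta/se}:
#' \deqn{\log ABF = 0.5 \log(1 - r) + 0.5 z^2 r.}
#'
#' @param beta,se estimate and standard error (se > 0). Vectorised.
#' @param prior_sd prior standard deviation of the true effect (> 0).
#' @return Log Bayes factor(s), alternative vs null.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (prior_sd <= 0) stop("prior_sd must be > 0", call. = FALSE)
  v <- se^2
  r <- prior_sd^2 / (v + prior_sd^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Construct a region pair for colocalisation
#'
#' Holds per-variant summary statistics for the same ordered variant set in
#' two traits. Variants present in only one trait are dropped (intersection)
#' and logged in the \code{dropped} attribute.
#'
#' @param variant_id shared variant identifiers.
#' @param beta1,se1 trait 1 effects and SEs.
#' @param beta2,se2 trait 2 effects and SEs.
#' @return data.frame of class \code{region_pair}.
#' @export
region_pair <- function(variant_id, beta1, se1, beta2, se2) {
  if (!length(variant_id)) stop("a region needs at least 1 variant", call. = FALSE)
  if (any(se1 <= 0) || any(se2 <= 0)) stop("SEs must be positive", call. = FALSE)
  d <- data.frame(variant_id = as.character(variant_id),
                  beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                  stringsAsFactors = FALSE)
  class(d) <- c("region_pair", "data.frame")
  d
}

#' Build a region pair from two association tables
#'
#' Intersects the two tables on variant id (order from the first table);
#' variants missing from either trait are dropped and reported.
#'
#' @param t1,t2 \code{\link{assoc_table}} objects.
#' @return A \code{\link{region_pair}} with attribute \code{dropped} listing
#'   excluded variant ids.
#' @export
region_from_tables <- function(t1, t2) {
  shared <- intersect(t1$records$variant_id, t2$records$variant_id)
  dropped <- setdiff(union(t1$records$variant_id, t2$records$variant_id), shared)
  if (!length(shared)) stop("no shared variants between the two traits", call. = FALSE)
  i1 <- match(shared, t1$records$variant_id)
  i2 <- match(shared, t2$records$variant_id)
  rp <- region_pair(shared,
                    t1$records$beta[i1], t1$records$se[i1],
                    t2$records$beta[i2], t2$records$se[i2])
  attr(rp, "dropped") <- dropped
  rp
}

#' Approximate-Bayes-factor colocalisation
#'
#' Computes posterior probabilities of the five hypotheses for one genomic
#' region and two traits, assuming at most one causal variant per trait.
#' Per-variant log-ABFs are combined in log space (log-sum-exp throughout;
#' regions of 100+ variants overflow otherwise) with per-hypothesis priors:
#' \code{p1}/\code{p2} a variant is causal for trait 1/2 only, \code{p12}
#' causal for both. For a single-variant region H3 (distinct causal
#' variants) is impossible and its posterior is exactly 0.
#'
#' @param region a \code{\link{region_pair}}.
#' @param p1,p2 per-variant prior for association with trait 1 / 2 only
#'   (default 1e-4 each).
#' @param p12 per-variant prior for shared association (default 1e-5).
#' @param prior_sd1 prior effect SD, trait 1 (default 0.15, quantitative).
#' @param prior_sd2 prior effect SD, trait 2 (default 0.2, case-control).
#' @return Object of class \code{coloc_result}: list with \code{pph0} ...
#'   \code{pph4}, \code{n_variants}, \code{interpretation} (see
#'   \code{\link{interpret_coloc}}).
#' @export
colocalise <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd1 = 0.15, prior_sd2 = 0.2) {
  l1 <- log_abf(region$beta1, region$se1, prior_sd1)
  l2 <- log_abf(region$beta2, region$se2, prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  L <- c(h0 = 0,
         h1 = log(p1) + s1,
         h2 = log(p2) + s2,
         h3 = if (nrow(region) == 1L) -Inf
              else log(p1) + log(p2) + logdiff(s1 + s2, s12),
         h4 = log(p12) + s12)
  post <- exp(L - logsumexp(L))
  res <- structure(list(pph0 = post[["h0"]], pph1 = post[["h1"]],
                        pph2 = post[["h2"]], pph3 = post[["h3"]],
                        pph4 = post[["h4"]], n_variants = nrow(region),
                        interpretation = NA_character_),
                   class = "coloc_result")
  res$interpretation <- interpret_coloc(res)
  res
}

#' Interpret a colocalisation posterior
#'
#' Band labels on the shared-causal-variant posterior PPH4:
#' above 0.8 \code{"high"} support for colocalisation, between 0.5 and 0.8
#' \code{"suggestive"}, otherwise \code{"weak"}. Both inequalities are
#' strict, so PPH4 of exactly 0.5 is \code{"weak"} and exactly 0.8 is
#' \code{"suggestive"}.
#'
#' @param result a \code{coloc_result}, or a bare PPH4 value.
#' @return \code{"high"}, \code{"suggestive"} or \code{"weak"}.
#' @export
interpret_coloc <- function(result) {
  pph4 <- if (inherits(result, "coloc_result")) result$pph4 else result
  if (pph4 > 0.8) "high" else if (pph4 > 0.5) "suggestive" else "weak"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d variants:\n", x$n_variants))
  cat(sprintf("  PPH0 %.3f | PPH1 %.3f | PPH2 %.3f | PPH3 %.3f | PPH4 %.3f\n",
              x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  cat(sprintf("  shared-variant support: %s\n", x$interpretation))
  invisible(x)
}
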