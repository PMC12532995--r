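# Proteome x outcome scan orchestration: pooled FDR, tier classification,
# results serialisation.

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR over a family of p-values. q-values come from
#' \code{stats::p.adjust(method = "BH")}; the rejection threshold p* is the
#' largest p whose rank-scaled bound holds, and the rejection set is every
#' p at or below p*.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Object of class \code{fdr_outcome}: list with \code{q} (aligned
#'   to the input), \code{p_star} (NA when nothing is rejected),
#'   \code{reject} (logical vector), \code{n_rejected}, \code{m},
#'   \code{alpha}.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (!m)
    return(structure(list(q = numeric(), p_star = NA_real_, reject = logical(),
                          n_rejected = 0L, m = 0L, alpha = alpha),
                     class = "fdr_outcome"))
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- stats::p.adjust(pvalues, method = "BH")
  sp <- sort(pvalues)
  ok <- which(sp <= seq_len(m) / m * alpha)
  p_star <- if (length(ok)) sp[max(ok)] else NA_real_
  reject <- if (is.na(p_star)) rep(FALSE, m) else pvalues <= p_star
  structure(list(q = q, p_star = p_star, reject = reject,
                 n_rejected = sum(reject), m = m, alpha = alpha),
            class = "fdr_outcome")
}

#' @export
print.fdr_outcome <- function(x, ...) {
  cat(sprintf("BH FDR at alpha = %g over %d tests: %d rejected (p* = %s)\n",
              x$alpha, x$m, x$n_rejected,
              if (is.na(x$p_star)) "none" else format(x$p_star, digits = 3)))
  invisible(x)
}

#' Classify one protein-outcome signal
#'
#' Decision rules, in order: no instruments -> insufficient_instruments;
#' FDR-rejected with a failing leave-one-out -> pleiotropy_driven (the
#' signal is carried by a single, likely pleiotropic variant); FDR-rejected
#' and passing every available pleiotropy test -> robust; nominally
#' significant below the FDR bar and passing every available pleiotropy
#' test -> suggestive; otherwise null. A test that cannot be run (Egger
#' intercept needs 3+ instruments, leave-one-out needs 2+) is skipped
#' rather than failed; callers should annotate such records as
#' "pleiotropy tests not evaluable".
#'
#' @param n_snps number of instruments used.
#' @param fdr_rejected was the primary p-value rejected by the pooled BH
#'   step-up?
#' @param pvalue primary p-value.
#' @param loo_pass leave-one-out pass flag, or NA when not evaluable.
#' @param intercept_p Egger intercept p-value, or NA when not evaluable.
#' @param nominal_alpha nominal significance level (default 0.05).
#' @param intercept_alpha Egger-intercept gate level (default 0.05).
#' @return One of \code{"robust"}, \code{"suggestive"},
#'   \code{"pleiotropy_driven"}, \code{"insufficient_instruments"},
#'   \code{"null"}.
#' @export
classify_signal <- function(n_snps, fdr_rejected, pvalue, loo_pass = NA,
                            intercept_p = NA, nominal_alpha = 0.05,
                            intercept_alpha = 0.05) {
  if (n_snps < 1L) return("insufficient_instruments")
  loo_ok <- if (is.na(loo_pass)) TRUE else isTRUE(loo_pass)
  int_ok <- if (is.na(intercept_p)) TRUE else intercept_p > intercept_alpha
  if (isTRUE(fdr_rejected)) {
    if (!is.na(loo_pass) && !isTRUE(loo_pass)) return("pleiotropy_driven")
    if (loo_ok && int_ok) return("robust")
    return("null")
  }
  if (!is.na(pvalue) && pvalue < nominal_alpha && loo_ok && int_ok)
    return("suggestive")
  "null"
}

scan_tiers <- c("robust", "suggestive", "pleiotropy_driven",
                "insufficient_instruments", "null")

#' Run the proteome-wide MR scan
#'
#' For every protein x outcome pair: harmonise the pQTL instruments with the
#' outcome GWAS, select instruments, compute the primary estimate (Wald
#' ratio or IVW by instrument count), run the sensitivity estimators and
#' Egger intercept where 3+ instruments allow, leave-one-out where 2+
#' allow, the Steiger directionality test and the cis-only replication;
#' then apply Benjamini-Hochberg FDR across the pooled family of tests,
#' classify every signal, and optionally colocalise the qualifying records
#' over their instrument region. Deterministic given \code{config$seed};
#' results are invariant to the order proteins are supplied in (rows are
#' emitted in sorted protein order).
#'
#' @param exposures named list of \code{\link{assoc_table}} objects, one per
#'   protein (names are protein ids; the table's trait_id is used when
#'   names are absent).
#' @param outcomes named list of \code{\link{assoc_table}} objects, one per
#'   outcome.
#' @param annotation data.frame with columns \code{protein_id},
#'   \code{gene_symbol}, \code{chrom}, \code{start}, \code{end} locating
#'   each protein's encoding gene.
#' @param proxies optional \code{\link{proxy_table}}.
#' @param config a \code{\link{scan_config}}.
#' @return Object of class \code{mr_scan}: list with \code{results} (one
#'   data.frame row per protein x outcome), \code{records} (per-pair detail
#'   objects), \code{fdr} (\code{fdr_outcome}), \code{summary}
#'   (classification counts) and \code{config}.
#' @export
run_scan <- function(exposures, outcomes, annotation, proxies = NULL,
                     config = scan_config()) {
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, function(t) t$trait_id, character(1))
  if (is.null(names(outcomes)))
    names(outcomes) <- vapply(outcomes, function(t) t$trait_id, character(1))
  protein_ids <- sort(names(exposures))
  outcome_ids <- names(outcomes)

  records <- list()
  for (pid in protein_ids) {
    ann <- annotation[annotation$protein_id == pid, , drop = FALSE]
    gene_region <- if (nrow(ann)) list(chrom = as.character(ann$chrom[1]),
                                       start = ann$start[1], end = ann$end[1])
                   else NULL
    for (oid in outcome_ids) {
      records[[paste(pid, oid, sep = "\r")]] <-
        scan_one(exposures[[pid]], outcomes[[oid]], pid, oid,
                 gene_region, proxies, config)
    }
  }

  pvals <- vapply(records, function(r) r$pvalue %||% NA_real_, numeric(1))
  testable <- !is.na(pvals)
  q <- rep(NA_real_, length(records))
  rejected <- rep(FALSE, length(records))
  if (config$fdr_family == "pooled") {
    fdr <- bh_fdr(pvals[testable], alpha = config$fdr_alpha)
    q[testable] <- fdr$q
    rejected[testable] <- fdr$reject
  } else {
    oid_of <- vapply(records, function(r) r$outcome_id, character(1))
    fdr <- list()
    for (oid in outcome_ids) {
      sel <- testable & oid_of == oid
      f <- bh_fdr(pvals[sel], alpha = config$fdr_alpha)
      q[sel] <- f$q
      rejected[sel] <- f$reject
      fdr[[oid]] <- f
    }
  }

  for (k in seq_along(records)) {
    r <- records[[k]]
    r$fdr_q <- q[k]
    r$fdr_rejected <- rejected[k]
    r$classification <- classify_signal(
      n_snps = r$n_snps, fdr_rejected = rejected[k], pvalue = r$pvalue,
      loo_pass = if (is.null(r$loo)) NA else r$loo$pass,
      intercept_p = if (is.null(r$egger)) NA else r$egger$intercept_p,
      nominal_alpha = config$nominal_alpha,
      intercept_alpha = config$intercept_alpha)
    run_coloc <- switch(config$coloc_mode,
      none = FALSE,
      all = r$n_snps >= 1L,
      fdr_pass = rejected[k] && (is.null(r$loo) || r$loo$pass) && r$n_snps >= 1L)
    if (run_coloc) {
      ins <- r$instruments
      r$coloc <- colocalise(
        region_pair(ins$variant_id, ins$beta_exp, ins$se_exp,
                    ins$beta_out, ins$se_out),
        p1 = config$p1, p2 = config$p2, p12 = config$p12,
        prior_sd1 = config$prior_sd1, prior_sd2 = config$prior_sd2)
    }
    records[[k]] <- r
  }

  results <- do.call(rbind, lapply(records, scan_record_row))
  rownames(results) <- NULL
  tier_counts <- table(factor(results$classification, levels = scan_tiers))
  structure(list(results = results, records = unname(records),
                 fdr = fdr, summary = tier_counts, config = config),
            class = "mr_scan")
}

# One protein x outcome analysis (everything except FDR/classification,
# which need the whole family).
scan_one <- function(exposure, outcome, protein_id, outcome_id,
                     gene_region, proxies, config) {
  h <- harmonise(exposure, outcome, proxies = proxies,
                 gene_region = gene_region,
                 r2_min = config$r2_min, cis_window_bp = config$cis_window_bp)
  iset <- select_instruments(h$instruments, protein_id, gene_region,
                             p_max = config$p_max, f_min = config$f_min)
  ins <- iset$instruments
  j <- nrow(ins)
  rec <- list(protein_id = protein_id, outcome_id = outcome_id,
              n_snps = j, instruments = ins, exclusions = h$exclusions,
              pvalue = NA_real_, pleiotropy_evaluable = j >= 3L)
  if (j == 0L) return(rec)

  rec$primary <- primary_estimate(ins, random_effects = config$random_effects)
  rec$pvalue <- rec$primary$pvalue
  seed0 <- derive_seed(config$seed, paste(protein_id, outcome_id))
  if (j >= 3L) {
    rec$egger <- mr_egger(ins)
    rec$wmedian <- weighted_median(ins, n_boot = config$n_boot, seed = seed0)
    rec$wmode <- weighted_mode(ins, phi = config$phi,
                               n_boot = config$n_boot, seed = seed0 + 1L)
  }
  if (j >= 2L) rec$loo <- leave_one_out(ins, alpha = config$loo_alpha)
  if (config$steiger_enabled) {
    orec <- outcome$records
    has_cc <- all(c("n_case", "n_control") %in% names(orec)) &&
      any(!is.na(orec$n_case))
    if (has_cc && "n_exp" %in% names(ins)) {
      rec$steiger <- steiger_test(
        ins, n_exp = stats::median(ins$n_exp),
        n_case = stats::median(orec$n_case, na.rm = TRUE),
        n_control = stats::median(orec$n_control, na.rm = TRUE))
    }
  }
  rec$cis_only <- cis_only_estimate(ins)
  rec
}

scan_record_row <- function(r) {
  est <- function(e, what) if (is.null(e)) NA_real_ else e[[what]]
  or <- if (is.null(r$primary)) list(or = NA_real_, or_low = NA_real_,
                                     or_high = NA_real_)
        else to_odds_scale(r$primary)
  data.frame(
    protein_id = r$protein_id, outcome_id = r$outcome_id, n_snps = r$n_snps,
    n_cis = sum(r$instruments$cis %in% TRUE),
    method = if (is.null(r$primary)) NA_character_ else r$primary$method,
    theta = est(r$primary, "theta"), se = est(r$primary, "se"),
    ci_low = est(r$primary, "ci_low"), ci_high = est(r$primary, "ci_high"),
    pvalue = est(r$primary, "pvalue"),
    or_point = or$or, or_low = or$or_low, or_high = or$or_high,
    egger_theta = if (is.null(r$egger)) NA_real_ else r$egger$slope$theta,
    egger_se = if (is.null(r$egger)) NA_real_ else r$egger$slope$se,
    egger_intercept = if (is.null(r$egger)) NA_real_ else r$egger$intercept,
    egger_intercept_p = if (is.null(r$egger)) NA_real_ else r$egger$intercept_p,
    wmedian_theta = est(r$wmedian, "theta"), wmedian_se = est(r$wmedian, "se"),
    wmode_theta = est(r$wmode, "theta"), wmode_se = est(r$wmode, "se"),
    loo_pass = if (is.null(r$loo)) NA else r$loo$pass,
    loo_drivers = if (is.null(r$loo)) NA_character_
                  else paste(r$loo$drivers, collapse = ","),
    steiger_ok = if (is.null(r$steiger)) NA else r$steiger$direction_ok,
    steiger_p = if (is.null(r$steiger)) NA_real_ else r$steiger$pvalue,
    cis_theta = est(r$cis_only, "theta"), cis_se = est(r$cis_only, "se"),
    coloc_pph4 = if (is.null(r$coloc)) NA_real_ else r$coloc$pph4,
    coloc_band = if (is.null(r$coloc)) NA_character_ else r$coloc$interpretation,
    fdr_q = r$fdr_q, fdr_rejected = r$fdr_rejected,
    pleiotropy_evaluable = r$pleiotropy_evaluable,
    classification = r$classification,
    stringsAsFactors = FALSE)
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("Proteome-wide MR scan: %d protein-outcome tests\n",
              nrow(x$results)))
  cat("Classification counts:\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.mr_scan <- function(object, ...) {
  hits <- object$results[object$results$classification %in%
                           c("robust", "suggestive", "pleiotropy_driven"), ,
                         drop = FALSE]
  out <- list(n_tests = nrow(object$results),
              tier_counts = object$summary,
              p_star = if (inherits(object$fdr, "fdr_outcome"))
                object$fdr$p_star else NA_real_,
              hits = hits[order(hits$pvalue),
                          c("protein_id", "outcome_id", "n_snps", "method",
                            "or_point", "or_low", "or_high", "pvalue",
                            "fdr_q", "classification")])
  class(out) <- "summary.mr_scan"
  out
}

#' @export
print.summary.mr_scan <- function(x, ...) {
  cat(sprintf("Proteome-wide MR scan over %d tests (BH p* = %s)\n", x$n_tests,
              if (is.na(x$p_star)) "none" else format(x$p_star, digits = 3)))
  print(x$tier_counts)
  if (nrow(x$hits)) {
    cat("\nTop signals:\n")
    print(utils::head(x$hits, 20), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write scan results to disk
#'
#' Writes one TSV row per protein x outcome with estimates on both the
#' log-odds and odds-ratio scales (full numeric precision, round-trip safe)
#' and a machine-readable JSON summary alongside
#' (\code{<path>_summary.json}).
#'
#' @param scan an \code{mr_scan}.
#' @param path output TSV path.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(scan, path) {
  df <- scan$results
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = NA))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  json_path <- paste0(sub("\\.tsv$", "", path), "_summary.json")
  jsonlite::write_json(
    list(n_tests = nrow(df),
         tier_counts = as.list(scan$summary),
         p_star = if (inherits(scan$fdr, "fdr_outcome")) scan$fdr$p_star
                  else NA_real_),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(tsv = path, json = json_path))
}

#' Read back a results TSV written by \code{\link{write_results}}
#' @param path TSV path.
#' @return data.frame with the original column types.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE)
}
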