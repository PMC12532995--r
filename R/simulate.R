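# Summary-statistics simulator with known causal truth. Emulates the
# structure the pipeline assumes: per-protein sets of independent pQTL
# instruments from a large discovery cohort (effects in SD units) and a
# case-control outcome GWAS on the log-odds scale, including hub-style
# horizontal pleiotropy (one strong trans variant shared by many proteins
# that also affects the outcome directly).

NON_PALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "G", "A", "C", "A",
                                  "T", "G", "T", "C", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Define a simulation scenario
#'
#' Named presets fix the causal structure; every size defaults to the study
#' conditions the pipeline targets: exposure discovery n = 34557, outcome
#' 25509 cases / 40941 controls, around 5 instruments per protein,
#' per-variant instrument strength F around 45, causal effect
#' theta = log(2.41) on the log-odds scale where a causal signal exists.
#'
#' Presets: \code{"null"} (theta = 0, no pleiotropy), \code{"causal"}
#' (theta = log 2.41), \code{"directional_pleiotropy"} (theta = 0, direct
#' variant-outcome effects alpha_j ~ N(0.05, 0.02^2)),
#' \code{"hub_pleiotropy"} (theta = 0; the last instrument is a strong hub
#' variant, F target 4000, with direct outcome effect 0.10), and
#' \code{"mixed_scan"} (a miniature proteome: 50 proteins x 2 outcomes,
#' 3 truly causal proteins, a 5-protein hub cluster sharing one trans
#' variant, the rest null; instrument F target 120 so simulated discovery
#' p-values clear the 1.7e-11 selection threshold).
#'
#' @param name one of the preset names.
#' @param ... overrides for any scenario field (\code{n_proteins}, \code{J},
#'   \code{n_exp}, \code{n_case}, \code{n_control}, \code{theta},
#'   \code{f_target}, \code{mu_alpha}, \code{sigma_alpha},
#'   \code{hub_f_target}, \code{hub_alpha}, \code{n_causal}, \code{n_hub},
#'   \code{outcome_spec}).
#' @return list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(name = c("null", "causal", "directional_pleiotropy",
                                  "hub_pleiotropy", "mixed_scan"), ...) {
  name <- match.arg(name)
  sc <- list(name = name, n_proteins = 1L, J = 5L,
             n_exp = 34557L, n_case = 25509L, n_control = 40941L,
             theta = 0, f_target = 45, mu_alpha = 0, sigma_alpha = 0,
             hub_f_target = 4000, hub_alpha = 0.10,
             n_causal = 0L, n_hub = 0L, outcome_spec = NULL)
  preset <- switch(name,
    null = list(),
    causal = list(theta = log(2.41)),
    directional_pleiotropy = list(mu_alpha = 0.05, sigma_alpha = 0.02),
    hub_pleiotropy = list(),
    mixed_scan = list(
      n_proteins = 50L, J = NULL, f_target = 120,
      theta = log(2.41), n_causal = 3L, n_hub = 5L,
      outcome_spec = data.frame(
        outcome_id = c("oc_all", "oc_serous"),
        n_case = c(25509L, 14049L),
        n_control = c(40941L, 40941L),
        stringsAsFactors = FALSE)))
  sc[names(preset)] <- preset
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sc[names(dots)] <- dots
  if (any(unlist(sc[c("n_exp", "n_case", "n_control")]) <= 0))
    stop("sample sizes must be positive", call. = FALSE)
  class(sc) <- "sim_scenario"
  sc
}

# number of instruments for one protein: 3 + Binomial(4, 1/2), median 5
draw_j <- function(scenario) {
  if (!is.null(scenario$J)) return(as.integer(scenario$J))
  3L + stats::rbinom(1L, 4L, 0.5)
}

case_control_se <- function(eaf, n_case, n_control) {
  n <- n_case + n_control
  1 / sqrt(2 * eaf * (1 - eaf) * n_case * n_control / n)
}

# two-sided normal p with a floor at the smallest positive normalised
# double: published tables report tiny p-values, never exactly 0
sim_pvalue <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), 2.3e-308)
}

# variant scaffolding shared by the single-protein and scan generators:
# one cis variant inside the gene, the rest trans on another chromosome
sim_variants <- function(scenario, protein_id, j, gene_region, hub = FALSE) {
  eaf <- stats::runif(j, 0.05, 0.95)
  pair <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS), j,
                                           replace = TRUE), , drop = FALSE]
  se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * scenario$n_exp)
  f_tgt <- rep(scenario$f_target, j)
  chrom <- rep("15", j)
  pos <- 1e6 * seq_len(j) + 12345
  chrom[1] <- gene_region$chrom
  pos[1] <- (gene_region$start + gene_region$end) / 2
  id <- paste0("rs", sub("^P", "", protein_id), "0", seq_len(j))
  is_hub <- rep(FALSE, j)
  if (hub) {
    # the shared hub variant: fixed identity, frequency and alleles so all
    # affected proteins and the outcome table agree on it
    id[j] <- "rs9000001"
    chrom[j] <- "9"; pos[j] <- 136131188
    eaf[j] <- 0.35
    pair[j, ] <- c("A", "G")
    se_x[j] <- 1 / sqrt(2 * eaf[j] * (1 - eaf[j]) * scenario$n_exp)
    f_tgt[j] <- scenario$hub_f_target
    is_hub[j] <- TRUE
  }
  beta_x_true <- sample(c(-1, 1), j, replace = TRUE) * sqrt(f_tgt) * se_x
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = pair[, 1], other_allele = pair[, 2],
             eaf = eaf, se_x = se_x, beta_x_true = beta_x_true,
             is_hub = is_hub, protein_id = protein_id,
             stringsAsFactors = FALSE)
}

#' Simulate one protein's pQTL discovery summary statistics
#'
#' Draws effect-allele frequencies uniformly on [0.05, 0.95], sets true
#' per-variant effects so the expected F-statistic matches the scenario's
#' target (observed F then follows a noncentral chi-squared with mean
#' target + 1), and adds sampling noise with the analytic SE
#' \eqn{1/\sqrt{2 p (1-p) n}}. The first variant is placed inside the
#' encoding gene (cis); the rest are trans. In the hub scenario the last
#' variant is the shared hub variant.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param protein_id protein identifier (default \code{"P1"}).
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with \code{table} (\code{\link{assoc_table}},
#'   continuous), \code{truth} (data.frame of true per-variant effects,
#'   frequencies and hub flags) and \code{gene_region}.
#' @export
simulate_protein_gwas <- function(scenario, protein_id = "P1", seed = NULL) {
  with_seed(seed, {
    gene_region <- list(chrom = "1", start = 1e6, end = 1.1e6)
    j <- draw_j(scenario)
    tr <- sim_variants(scenario, protein_id, j, gene_region,
                       hub = scenario$name == "hub_pleiotropy")
    beta_hat <- stats::rnorm(j, tr$beta_x_true, tr$se_x)
    rec <- data.frame(variant_id = tr$variant_id, chrom = tr$chrom,
                      pos = tr$pos, effect_allele = tr$effect_allele,
                      other_allele = tr$other_allele, eaf = tr$eaf,
                      beta = beta_hat, se = tr$se_x,
                      pvalue = sim_pvalue(beta_hat / tr$se_x),
                      n = scenario$n_exp, stringsAsFactors = FALSE)
    list(table = assoc_table(rec, trait_id = protein_id,
                             trait_type = "continuous"),
         truth = tr, gene_region = gene_region)
  })
}

# true direct variant-outcome effects (horizontal pleiotropy) for one
# protein's instrument set, per scenario. Directional pleiotropy acts on
# the exposure-increasing allele (the usual convention: a shared pathway
# pushes the outcome the same way wherever the variant raises the protein),
# so the sign follows the instrument's exposure effect.
draw_alpha <- function(truth, scenario) {
  alpha <- rep(0, nrow(truth))
  if (scenario$name == "directional_pleiotropy")
    alpha <- sign(truth$beta_x_true) *
      stats::rnorm(nrow(truth), scenario$mu_alpha, scenario$sigma_alpha)
  alpha[truth$is_hub] <- scenario$hub_alpha
  alpha
}

#' Simulate outcome (case-control) summary statistics for known truth
#'
#' Each variant's true log-odds effect is
#' \eqn{\beta_Y = \theta \beta_X + \alpha} where \eqn{\alpha} is the direct
#' (pleiotropic) effect dictated by the scenario: zero under the null and
#' causal scenarios, drawn from N(mu_alpha, sigma_alpha^2) under
#' directional pleiotropy, and concentrated on the hub variant under hub
#' pleiotropy. Sampling noise uses the effective-sample-size log-odds SE
#' \eqn{1/\sqrt{2 p (1-p)\, n_{case} n_{control} / n}}.
#'
#' @param truth the \code{truth} slice from
#'   \code{\link{simulate_protein_gwas}}.
#' @param scenario the \code{\link{sim_scenario}}.
#' @param seed integer seed.
#' @param trait_id outcome identifier (default \code{"outcome"}).
#' @return An \code{\link{assoc_table}} (case_control) with attribute
#'   \code{"alpha"} holding the per-variant direct effects used.
#' @export
simulate_outcome_gwas <- function(truth, scenario, seed = NULL,
                                  trait_id = "outcome") {
  with_seed(seed, {
    alpha <- draw_alpha(truth, scenario)
    beta_y_true <- scenario$theta * truth$beta_x_true + alpha
    se_y <- case_control_se(truth$eaf, scenario$n_case, scenario$n_control)
    beta_hat <- stats::rnorm(nrow(truth), beta_y_true, se_y)
    n <- scenario$n_case + scenario$n_control
    rec <- data.frame(variant_id = truth$variant_id, chrom = truth$chrom,
                      pos = truth$pos, effect_allele = truth$effect_allele,
                      other_allele = truth$other_allele, eaf = truth$eaf,
                      beta = beta_hat, se = se_y,
                      pvalue = sim_pvalue(beta_hat / se_y),
                      n = n, n_case = scenario$n_case,
                      n_control = scenario$n_control, stringsAsFactors = FALSE)
    tab <- assoc_table(rec, trait_id = trait_id, trait_type = "case_control")
    attr(tab, "alpha") <- alpha
    tab
  })
}

#' Build a miniature proteome scan fixture with known classification truth
#'
#' Generates a complete input set for \code{\link{run_scan}}: per-protein
#' exposure tables, per-outcome case-control tables over the union of all
#' instrument variants, a gene-annotation table placing one cis variant
#' inside each gene window, and the intended classification tier of every
#' protein x outcome pair. The default \code{mixed_scan} scenario contains
#' truly causal proteins (expected \code{robust}), a hub-pleiotropy cluster
#' whose shared trans variant drives the outcome directly (expected
#' \code{pleiotropy_driven}) and null proteins (expected \code{null}).
#'
#' @param scenario a \code{\link{sim_scenario}}, normally
#'   \code{sim_scenario("mixed_scan")}.
#' @param seed integer seed; equal seeds give identical fixtures.
#' @return list with \code{exposures} (named list of assoc_tables),
#'   \code{outcomes} (named list), \code{annotation} (data.frame),
#'   \code{truth} (data.frame protein_id, outcome_id, tier, theta) and
#'   \code{variant_truth} (per-variant true effects).
#' @export
make_scan_fixture <- function(scenario = sim_scenario("mixed_scan"),
                              seed = NULL) {
  outcome_spec <- scenario$outcome_spec
  if (is.null(outcome_spec))
    outcome_spec <- data.frame(outcome_id = "outcome",
                               n_case = scenario$n_case,
                               n_control = scenario$n_control,
                               stringsAsFactors = FALSE)
  with_seed(seed, {
    np <- scenario$n_proteins
    tier <- rep("null", np)
    if (scenario$n_causal > 0) tier[seq_len(scenario$n_causal)] <- "causal"
    if (scenario$n_hub > 0)
      tier[scenario$n_causal + seq_len(scenario$n_hub)] <- "hub"
    protein_ids <- sprintf("P%03d", seq_len(np))

    exposures <- list()
    annotation <- list()
    truth_rows <- list()
    for (i in seq_len(np)) {
      pid <- protein_ids[i]
      gene_region <- list(chrom = as.character((i - 1) %% 8 + 1),
                          start = 1e6 + i * 3e6, end = 1.1e6 + i * 3e6)
      j <- draw_j(scenario)
      tr <- sim_variants(scenario, pid, j, gene_region,
                         hub = tier[i] == "hub")
      beta_hat <- stats::rnorm(j, tr$beta_x_true, tr$se_x)
      rec <- data.frame(variant_id = tr$variant_id, chrom = tr$chrom,
                        pos = tr$pos, effect_allele = tr$effect_allele,
                        other_allele = tr$other_allele, eaf = tr$eaf,
                        beta = beta_hat, se = tr$se_x,
                        pvalue = sim_pvalue(beta_hat / tr$se_x),
                        n = scenario$n_exp, stringsAsFactors = FALSE)
      exposures[[pid]] <- assoc_table(rec, trait_id = pid,
                                      trait_type = "continuous")
      annotation[[pid]] <- data.frame(protein_id = pid,
                                      gene_symbol = paste0("GENE", i),
                                      chrom = gene_region$chrom,
                                      start = gene_region$start,
                                      end = gene_region$end,
                                      stringsAsFactors = FALSE)
      tr$theta <- if (tier[i] == "causal") scenario$theta else 0
      tr$tier <- tier[i]
      truth_rows[[pid]] <- tr
    }
    variant_truth <- do.call(rbind, truth_rows)

    # union of variants for the outcome tables; the hub variant appears once
    # with its direct effect, every other variant inherits its protein's theta
    uniq <- variant_truth[!duplicated(variant_truth$variant_id), , drop = FALSE]
    beta_y_true <- uniq$theta * uniq$beta_x_true
    beta_y_true[uniq$is_hub] <- scenario$hub_alpha

    outcomes <- list()
    for (k in seq_len(nrow(outcome_spec))) {
      oid <- outcome_spec$outcome_id[k]
      nca <- outcome_spec$n_case[k]; nco <- outcome_spec$n_control[k]
      se_y <- case_control_se(uniq$eaf, nca, nco)
      beta_hat <- stats::rnorm(nrow(uniq), beta_y_true, se_y)
      rec <- data.frame(variant_id = uniq$variant_id, chrom = uniq$chrom,
                        pos = uniq$pos, effect_allele = uniq$effect_allele,
                        other_allele = uniq$other_allele, eaf = uniq$eaf,
                        beta = beta_hat, se = se_y,
                        pvalue = sim_pvalue(beta_hat / se_y),
                        n = nca + nco, n_case = nca, n_control = nco,
                        stringsAsFactors = FALSE)
      outcomes[[oid]] <- assoc_table(rec, trait_id = oid,
                                     trait_type = "case_control")
    }

    tier_map <- c(causal = "robust", hub = "pleiotropy_driven", null = "null")
    truth <- expand.grid(protein_id = protein_ids,
                         outcome_id = outcome_spec$outcome_id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$tier <- tier_map[tier[match(truth$protein_id, protein_ids)]]
    truth$theta <- ifelse(truth$tier == "robust", scenario$theta, 0)

    list(exposures = exposures, outcomes = outcomes,
         annotation = do.call(rbind, annotation), truth = truth,
         variant_truth = variant_truth)
  })
}

#' Simulate a colocalisation region pair
#'
#' A dense region (default 50 variants) with one causal variant per trait:
#' the same variant when \code{shared = TRUE} (the H4 configuration) or two
#' different variants otherwise (H3). Null variants have zero true effect.
#' Per-variant SEs use the analytic exposure and case-control formulas at
#' the default study sizes.
#'
#' @param n_variants region size (default 50).
#' @param shared do the two traits share their causal variant?
#' @param z_causal true causal-variant z-score (default 8).
#' @param n_exp,n_case,n_control sample sizes.
#' @param seed integer seed.
#' @return A \code{\link{region_pair}} with attributes
#'   \code{"causal1"}/\code{"causal2"} naming the causal variants.
#' @export
simulate_coloc_region <- function(n_variants = 50, shared = TRUE,
                                  z_causal = 8, n_exp = 34557,
                                  n_case = 25509, n_control = 40941,
                                  seed = NULL) {
  with_seed(seed, {
    eaf <- stats::runif(n_variants, 0.05, 0.95)
    se1 <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se2 <- case_control_se(eaf, n_case, n_control)
    c1 <- sample.int(n_variants, 1)
    c2 <- if (shared || n_variants == 1L) c1
          else sample(setdiff(seq_len(n_variants), c1), 1)
    b1 <- rep(0, n_variants); b1[c1] <- z_causal * se1[c1]
    b2 <- rep(0, n_variants); b2[c2] <- z_causal * se2[c2]
    rp <- region_pair(paste0("rv", seq_len(n_variants)),
                      stats::rnorm(n_variants, b1, se1), se1,
                      stats::rnorm(n_variants, b2, se2), se2)
    attr(rp, "causal1") <- paste0("rv", c1)
    attr(rp, "causal2") <- paste0("rv", c2)
    rp
  })
}

#' Write a scan fixture to TSV files
#'
#' Serialises a \code{\link{make_scan_fixture}} result into the TSV dialects
#' the readers consume (one exposure file per protein, one outcome file per
#' outcome, a gene-annotation file) plus the truth table as JSON.
#'
#' @param fixture result of \code{\link{make_scan_fixture}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scan_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (pid in names(fixture$exposures))
    wr(fixture$exposures[[pid]]$records, paste0("exposure_", pid, ".tsv"))
  for (oid in names(fixture$outcomes))
    wr(fixture$outcomes[[oid]]$records, paste0("outcome_", oid, ".tsv"))
  wr(fixture$annotation, "annotation.tsv")
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
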