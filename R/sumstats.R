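#' Construct a validated association table
#'
#' An association table holds per-variant GWAS summary statistics for one
#' trait: a continuous trait (e.g. a plasma protein level, effects in SD
#' units) or a case-control trait (effects on the log-odds scale). Rows that
#' violate the record invariants are removed and logged, never kept silently.
#'
#' @param records data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pvalue}, \code{n} and, for case-control
#'   traits, \code{n_case} and \code{n_control}.
#' @param trait_id character identifier of the trait.
#' @param trait_type \code{"continuous"} or \code{"case_control"}.
#' @return An object of class \code{assoc_table}: a list with elements
#'   \code{trait_id}, \code{trait_type}, \code{records} (the validated
#'   data.frame) and \code{rejections} (data.frame of dropped rows with a
#'   per-row reason).
#' @export
assoc_table <- function(records, trait_id, trait_type = c("continuous", "case_control")) {
  trait_type <- match.arg(trait_type)
  needed <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue", "n")
  if (trait_type == "case_control") needed <- c(needed, "n_case", "n_control")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  num_cols <- c("pos", "eaf", "beta", "se", "pvalue", "n")
  if (trait_type == "case_control") num_cols <- c(num_cols, "n_case", "n_control")
  reasons <- character(nrow(records))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(records[[cl]]))
    bad <- is.na(v) & !is.na(records[[cl]])
    reasons[bad & reasons == ""] <- paste0("unparsable numeric: ", cl)
    records[[cl]] <- v
  }

  ok_alleles <- records$effect_allele %in% VALID_ALLELES &
    records$other_allele %in% VALID_ALLELES &
    records$effect_allele != records$other_allele
  reasons[reasons == "" & !ok_alleles] <- "invalid alleles"
  chk <- function(cond, why) reasons[reasons == "" & !(cond %in% TRUE)] <<- why
  chk(records$se > 0, "se must be > 0")
  chk(records$eaf > 0 & records$eaf < 1, "eaf outside (0,1)")
  chk(records$pvalue > 0 & records$pvalue <= 1, "pvalue outside (0,1]")
  chk(records$n > 0, "n must be > 0")
  if (trait_type == "case_control")
    chk(abs(records$n_case + records$n_control - records$n) < 0.5,
        "n_case + n_control != n")
  dup <- duplicated(records$variant_id)
  reasons[reasons == "" & dup] <- "duplicate variant_id"

  keep <- reasons == ""
  rejections <- data.frame(variant_id = records$variant_id[!keep],
                           reason = reasons[!keep],
                           stringsAsFactors = FALSE)
  out <- list(trait_id = as.character(trait_id),
              trait_type = trait_type,
              records = records[keep, , drop = FALSE],
              rejections = rejections)
  rownames(out$records) <- NULL
  class(out) <- "assoc_table"
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Association table '%s' (%s): %d variants, %d rejected rows\n",
              x$trait_id, x$trait_type, nrow(x$records), nrow(x$rejections)))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The file must carry a header row; \code{"."} denotes a missing value.
#' Columns may use arbitrary names if \code{column_map} maps each canonical
#' field name to the column carrying it. Rows failing validation (non-positive
#' SE, allele codes outside A/C/G/T, unparsable numbers, ...) are dropped and
#' recorded in the returned table's \code{rejections} log.
#'
#' @param path path to a TSV file.
#' @param trait_id trait identifier stored on the table.
#' @param trait_type \code{"continuous"} or \code{"case_control"}.
#' @param column_map optional named character vector mapping canonical field
#'   names (e.g. \code{beta}) to the file's column names (e.g. \code{"b"}).
#' @return An \code{\link{assoc_table}}.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("continuous", "case_control"),
                          column_map = NULL) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                           colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("column_map names missing column '%s'", src), call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  assoc_table(raw, trait_id = trait_id, trait_type = trait_type)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G variants are strand-ambiguous: their alleles read the same on
#' both strands, so exposure and outcome reports cannot be aligned from
#' alleles alone. Such variants are excluded during harmonisation.
#'
#' @param effect_allele,other_allele single-nucleotide allele codes.
#' @return Logical (vectorised over the inputs).
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!all(effect_allele %in% VALID_ALLELES) || !all(other_allele %in% VALID_ALLELES))
    stop("alleles must be one of A, C, G, T", call. = FALSE)
  complement_allele(effect_allele) == other_allele
}

#' Construct an LD-proxy table
#'
#' Each entry links two variants with their LD r-squared and the allele
#' correspondence between them. Entries are symmetric: a lookup for either
#' partner finds the other.
#'
#' @param entries data.frame with columns \code{variant_a}, \code{variant_b},
#'   \code{r2}, \code{a_allele1}, \code{b_allele1}, \code{a_allele2},
#'   \code{b_allele2}; \code{a_allele1} corresponds to \code{b_allele1} etc.
#' @return Object of class \code{proxy_table}.
#' @export
proxy_table <- function(entries) {
  needed <- c("variant_a", "variant_b", "r2",
              "a_allele1", "b_allele1", "a_allele2", "b_allele2")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("proxy table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$r2 <- as.numeric(entries$r2)
  if (any(entries$r2 < 0 | entries$r2 > 1, na.rm = TRUE))
    stop("r2 must lie in [0, 1]", call. = FALSE)
  for (cl in c("a_allele1", "b_allele1", "a_allele2", "b_allele2"))
    entries[[cl]] <- toupper(as.character(entries[[cl]]))
  structure(list(entries = entries), class = "proxy_table")
}

#' Read an LD-proxy table from a TSV file
#' @param path TSV with columns variant_a, variant_b, r2, a_allele1,
#'   b_allele1, a_allele2, b_allele2.
#' @return A \code{\link{proxy_table}}.
#' @export
read_proxies <- function(path) {
  proxy_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                colClasses = "character", check.names = FALSE))
}

#' Find the best LD proxy present in an outcome table
#'
#' Used when an instrument variant is absent from the outcome GWAS: the
#' partner with the highest r-squared at or above \code{r2_min} that is
#' present in the outcome table is substituted. Ties on r-squared break
#' lexicographically on the partner id.
#'
#' @param variant_id the missing variant.
#' @param outcome an \code{\link{assoc_table}} for the outcome trait.
#' @param proxies a \code{\link{proxy_table}}.
#' @param r2_min minimum r-squared for an acceptable proxy (default 0.8).
#' @return \code{NULL} if no partner qualifies, else a list with
#'   \code{proxy_id}, \code{r2} and \code{allele_map} (named character vector
#'   mapping the original variant's alleles to the proxy's alleles).
#' @export
find_proxy <- function(variant_id, outcome, proxies, r2_min = 0.8) {
  if (is.null(proxies)) return(NULL)
  e <- proxies$entries
  hits_a <- e[e$variant_a == variant_id, , drop = FALSE]
  hits_b <- e[e$variant_b == variant_id, , drop = FALSE]
  cand <- data.frame(
    partner = c(hits_a$variant_b, hits_b$variant_a),
    r2 = c(hits_a$r2, hits_b$r2),
    from1 = c(hits_a$a_allele1, hits_b$b_allele1),
    from2 = c(hits_a$a_allele2, hits_b$b_allele2),
    to1 = c(hits_a$b_allele1, hits_b$a_allele1),
    to2 = c(hits_a$b_allele2, hits_b$a_allele2),
    stringsAsFactors = FALSE)
  cand <- cand[cand$r2 >= r2_min & cand$partner %in% outcome$records$variant_id, ,
               drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$r2, cand$partner), , drop = FALSE]
  best <- cand[1L, ]
  allele_map <- stats::setNames(c(best$to1, best$to2), c(best$from1, best$from2))
  list(proxy_id = best$partner, r2 = best$r2, allele_map = allele_map)
}

# Reconcile outcome alleles with exposure alleles.
# Resolution order: exact match -> swap -> complement -> complement+swap.
# Returns "exact", "swap", "comp", "comp_swap" or "mismatch"; "swap"-type
# matches mean the outcome effect refers to the exposure's other allele.
match_alleles <- function(ea_x, oa_x, ea_y, oa_y) {
  if (ea_y == ea_x && oa_y == oa_x) return("exact")
  if (ea_y == oa_x && oa_y == ea_x) return("swap")
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  if (cea == ea_x && coa == oa_x) return("comp")
  if (cea == oa_x && coa == ea_x) return("comp_swap")
  "mismatch"
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns each exposure (pQTL) instrument with the outcome GWAS so both
#' effects refer to the same effect allele. Palindromic variants are dropped.
#' Variants absent from the outcome are replaced by their best LD proxy
#' (r-squared at or above \code{r2_min}) when one is available, otherwise
#' excluded. When the outcome reports the opposite allele order the outcome
#' beta is negated; strand mismatches are resolved by complementing before
#' declaring a variant irreconcilable. Every exclusion is logged with a
#' reason, so input variants = surviving pairs + exclusions, exactly.
#'
#' @param exposure \code{\link{assoc_table}} holding one protein's instruments.
#' @param outcome \code{\link{assoc_table}} for the outcome trait.
#' @param proxies optional \code{\link{proxy_table}}.
#' @param gene_region optional list/vector with \code{chrom}, \code{start},
#'   \code{end} of the protein-encoding gene, used to set the cis flag.
#' @param r2_min minimum proxy r-squared (default 0.8).
#' @param cis_window_bp cis window around the gene (default 1e6).
#' @return A list with \code{instruments} (data.frame of class
#'   \code{mr_instruments}: variant_id, used_proxy, beta_exp, se_exp,
#'   beta_out, se_out, eaf, pvalue_exp, n_exp, cis) and \code{exclusions}
#'   (data.frame variant_id, reason).
#' @export
harmonise <- function(exposure, outcome, proxies = NULL, gene_region = NULL,
                      r2_min = 0.8, cis_window_bp = 1e6) {
  ex <- exposure$records
  out_rec <- outcome$records
  rows <- vector("list", nrow(ex))
  excl <- list()
  for (i in seq_len(nrow(ex))) {
    r <- ex[i, ]
    if (is_palindromic(r$effect_allele, r$other_allele)) {
      excl[[length(excl) + 1L]] <- c(r$variant_id, "palindromic")
      next
    }
    used_proxy <- NA_character_
    target_id <- r$variant_id
    ea_x <- r$effect_allele; oa_x <- r$other_allele
    if (!target_id %in% out_rec$variant_id) {
      px <- find_proxy(r$variant_id, outcome, proxies, r2_min = r2_min)
      if (is.null(px)) {
        excl[[length(excl) + 1L]] <- c(r$variant_id, "missing from outcome, no proxy")
        next
      }
      used_proxy <- px$proxy_id
      target_id <- px$proxy_id
      # express the exposure alleles in the proxy's allele coding
      if (!all(c(ea_x, oa_x) %in% names(px$allele_map))) {
        excl[[length(excl) + 1L]] <- c(r$variant_id, "allele mismatch")
        next
      }
      ea_x <- unname(px$allele_map[ea_x])
      oa_x <- unname(px$allele_map[oa_x])
    }
    o <- out_rec[match(target_id, out_rec$variant_id), ]
    act <- match_alleles(ea_x, oa_x, o$effect_allele, o$other_allele)
    if (act == "mismatch") {
      excl[[length(excl) + 1L]] <- c(r$variant_id, "allele mismatch")
      next
    }
    flip <- act %in% c("swap", "comp_swap")
    beta_out <- if (flip) -o$beta else o$beta
    cis <- NA
    if (!is.null(gene_region))
      cis <- classify_cis_trans(r$chrom, r$pos,
                                gene_region, window_bp = cis_window_bp) == "cis"
    rows[[i]] <- data.frame(
      variant_id = r$variant_id, used_proxy = used_proxy,
      beta_exp = r$beta, se_exp = r$se,
      beta_out = beta_out, se_out = o$se,
      eaf = r$eaf, pvalue_exp = r$pvalue, n_exp = r$n,
      cis = cis, stringsAsFactors = FALSE)
  }
  instruments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(instruments))
    instruments <- data.frame(variant_id = character(), used_proxy = character(),
                              beta_exp = numeric(), se_exp = numeric(),
                              beta_out = numeric(), se_out = numeric(),
                              eaf = numeric(), pvalue_exp = numeric(),
                              n_exp = numeric(), cis = logical(),
                              stringsAsFactors = FALSE)
  rownames(instruments) <- NULL
  class(instruments) <- c("mr_instruments", "data.frame")
  exclusions <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(variant_id = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(variant_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  list(instruments = instruments, exclusions = exclusions)
}

#' Assemble a harmonised instrument data.frame directly
#'
#' Convenience constructor for already-aligned effect pairs (both effects on
#' the same effect allele), as used by the estimators and in simulations.
#'
#' @param beta_exp,se_exp exposure effect and SE (SD units of protein).
#' @param beta_out,se_out outcome effect and SE (log-odds for case-control).
#' @param eaf effect-allele frequency.
#' @param variant_id optional ids.
#' @param cis optional logical cis flags.
#' @return data.frame of class \code{mr_instruments}.
#' @export
mr_instruments <- function(beta_exp, se_exp, beta_out, se_out,
                           eaf = rep(0.5, length(beta_exp)),
                           variant_id = paste0("v", seq_along(beta_exp)),
                           cis = rep(NA, length(beta_exp))) {
  if (any(se_exp <= 0) || any(se_out <= 0))
    stop("standard errors must be positive", call. = FALSE)
  d <- data.frame(variant_id = variant_id, used_proxy = NA_character_,
                  beta_exp = beta_exp, se_exp = se_exp,
                  beta_out = beta_out, se_out = se_out,
                  eaf = eaf, cis = cis, stringsAsFactors = FALSE)
  class(d) <- c("mr_instruments", "data.frame")
  d
}
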