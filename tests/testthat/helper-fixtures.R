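# Shared fixtures built in code.

# canonical association record data.frame
make_records <- function(n = 3, beta = seq(0.1, by = 0.1, length.out = n),
                         se = rep(0.02, n), eaf = rep(0.3, n),
                         effect_allele = rep("A", n), other_allele = rep("G", n),
                         chrom = rep("1", n), pos = seq(1e6, by = 1e5, length.out = n),
                         pvalue = rep(1e-20, n), n_samp = rep(34557, n)) {
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n_samp,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a random exposure/outcome table pair for harmonisation property tests;
# outcome records are randomly allele-swapped, strand-complemented, or made
# palindromic/missing relative to the exposure
random_harmonisation_case <- function(n = 8) {
  pairs <- matrix(c("A", "G", "A", "C", "G", "A", "C", "A",
                    "T", "G", "T", "C", "G", "T", "C", "T",
                    "A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  ex <- make_records(n, beta = rnorm(n, 0, 0.2), se = runif(n, 0.005, 0.05),
                     eaf = runif(n, 0.05, 0.95),
                     effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2])
  out <- ex
  out$beta <- rnorm(n, 0, 0.05)
  out$se <- runif(n, 0.005, 0.05)
  out$n <- 66450
  out$n_case <- 25509
  out$n_control <- 40941
  # random allele transformations on the outcome side
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n)) {
    op <- sample(c("exact", "swap", "comp", "comp_swap"), 1)
    if (op %in% c("swap", "comp_swap")) {
      tmp <- out$effect_allele[i]
      out$effect_allele[i] <- out$other_allele[i]
      out$other_allele[i] <- tmp
      out$beta[i] <- -out$beta[i]
      out$eaf[i] <- 1 - out$eaf[i]
    }
    if (op %in% c("comp", "comp_swap")) {
      out$effect_allele[i] <- comp[[out$effect_allele[i]]]
      out$other_allele[i] <- comp[[out$other_allele[i]]]
    }
  }
  drop <- sample.int(n, size = sample(0:2, 1))
  out <- out[setdiff(seq_len(n), drop), , drop = FALSE]
  list(exposure = assoc_table(ex, "prot", "continuous"),
       outcome = assoc_table(out, "oc", "case_control"))
}

# independent step-up BH oracle: naive double loop over ranks
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  k <- 0
  for (i in seq_len(m)) if (sp[i] <= i / m * alpha) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, sp[j] * m / j)
    qs[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- qs
  list(reject = reject, n_rejected = sum(reject), q = q)
}

# brute-force interpolated weighted median (independent of the package path)
wmedian_oracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  p <- cumsum(ww) - ww / 2
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[length(p)]) return(th[length(th)])
  i <- max(which(p < 0.5))
  th[i] + (th[i + 1] - th[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# enumeration oracle for ABF colocalisation on small regions: sums the
# unnormalised posterior over every causal-variant configuration
coloc_oracle <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        prior_sd1 = 0.15, prior_sd2 = 0.2) {
  bf1 <- exp(log_abf(region$beta1, region$se1, prior_sd1))
  bf2 <- exp(log_abf(region$beta2, region$se2, prior_sd2))
  q <- nrow(region)
  s0 <- 1
  s1 <- p1 * sum(bf1)
  s2 <- p2 * sum(bf2)
  s3 <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) if (i != j)
    s3 <- s3 + p1 * p2 * bf1[i] * bf2[j]
  s4 <- p12 * sum(bf1 * bf2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(pph0 = s0, pph1 = s1, pph2 = s2, pph3 = s3, pph4 = s4) / tot
}
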