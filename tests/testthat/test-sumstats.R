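test_that("read_sumstats parses well-formed files and honours column_map", {
  rec <- make_records(3)
  tab <- read_sumstats(write_tsv(rec), "prot", "continuous")
  expect_s3_class(tab, "assoc_table")
  expect_equal(nrow(tab$records), 3)
  expect_equal(nrow(tab$rejections), 0)
  expect_equal(tab$records$beta, rec$beta)

  # renamed beta column parses identically through column_map
  rec2 <- rec
  names(rec2)[names(rec2) == "beta"] <- "b"
  tab2 <- read_sumstats(write_tsv(rec2), "prot", "continuous",
                        column_map = c(beta = "b"))
  expect_equal(tab2$records, tab$records)
})

test_that("invalid rows are rejected with reasons, not silently dropped", {
  rec <- make_records(4)
  rec$se[2] <- 0                       # invariant violation
  rec$beta[3] <- "not_a_number"        # unparsable numeric
  tab <- read_sumstats(write_tsv(rec), "prot", "continuous")
  expect_equal(nrow(tab$records), 2)
  expect_equal(nrow(tab$rejections), 2)
  expect_setequal(tab$rejections$variant_id, c("rs2", "rs3"))
  expect_match(tab$rejections$reason[tab$rejections$variant_id == "rs2"], "se")
  expect_match(tab$rejections$reason[tab$rejections$variant_id == "rs3"],
               "unparsable")
})

test_that("missing mandatory columns raise a schema error", {
  rec <- make_records(2)
  rec$se <- NULL
  expect_error(read_sumstats(write_tsv(rec), "prot", "continuous"), "se")
  cc <- make_records(2)
  expect_error(assoc_table(cc, "oc", "case_control"), "n_case")
})

test_that("case-control tables require consistent case/control counts", {
  rec <- make_records(2)
  rec$n <- 100; rec$n_case <- 40; rec$n_control <- 60
  tab <- assoc_table(rec, "oc", "case_control")
  expect_equal(nrow(tab$records), 2)
  rec$n_control[2] <- 10
  tab2 <- assoc_table(rec, "oc", "case_control")
  expect_equal(nrow(tab2$records), 1)
  expect_match(tab2$rejections$reason, "n_case")
})

test_that("palindromic detection follows the strand-ambiguity definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "alleles")
})

test_that("find_proxy returns the best qualifying partner", {
  out <- assoc_table(make_records(3), "oc", "continuous")
  px <- proxy_table(data.frame(
    variant_a = c("rsX", "rsX", "rsX"),
    variant_b = c("rs1", "rs2", "rs9"),
    r2 = c(0.85, 0.95, 0.99),
    a_allele1 = "A", b_allele1 = "A", a_allele2 = "G", b_allele2 = "G",
    stringsAsFactors = FALSE))
  # rs9 has top r2 but is absent from the outcome: rs2 (0.95) wins over rs1
  hit <- find_proxy("rsX", out, px)
  expect_equal(hit$proxy_id, "rs2")
  expect_equal(hit$r2, 0.95)
  expect_equal(unname(hit$allele_map[c("A", "G")]), c("A", "G"))
  # below the r2 threshold -> no proxy
  expect_null(find_proxy("rsX", out, px, r2_min = 0.96))
  # symmetric lookup: entry stored with the query as variant_b
  px2 <- proxy_table(data.frame(variant_a = "rs1", variant_b = "rsY", r2 = 0.9,
                                a_allele1 = "A", b_allele1 = "T",
                                a_allele2 = "G", b_allele2 = "C",
                                stringsAsFactors = FALSE))
  hit2 <- find_proxy("rsY", out, px2)
  expect_equal(hit2$proxy_id, "rs1")
  expect_equal(unname(hit2$allele_map[c("T", "C")]), c("A", "G"))
})

test_that("find_proxy breaks exact r2 ties lexicographically", {
  out <- assoc_table(make_records(3), "oc", "continuous")
  px <- proxy_table(data.frame(
    variant_a = "rsX", variant_b = c("rs3", "rs1"), r2 = c(0.9, 0.9),
    a_allele1 = "A", b_allele1 = "A", a_allele2 = "G", b_allele2 = "G",
    stringsAsFactors = FALSE))
  expect_equal(find_proxy("rsX", out, px)$proxy_id, "rs1")
})

test_that("harmonise aligns effect alleles, flipping the outcome beta", {
  ex <- assoc_table(make_records(1, beta = 0.5, effect_allele = "A",
                                 other_allele = "G"), "prot", "continuous")
  # outcome reports the same variant for allele G: beta must flip sign
  out_rec <- make_records(1, beta = -0.2, effect_allele = "G", other_allele = "A")
  out <- assoc_table(out_rec, "oc", "continuous")
  h <- harmonise(ex, out)
  expect_equal(h$instruments$beta_exp, 0.5)
  expect_equal(h$instruments$beta_out, 0.2)
  expect_equal(nrow(h$exclusions), 0)
})

test_that("harmonise resolves strand flips by complementing", {
  ex <- assoc_table(make_records(1, beta = 0.5, effect_allele = "A",
                                 other_allele = "G"), "prot", "continuous")
  # outcome on the opposite strand: T/C complements to A/G, no sign flip
  out1 <- assoc_table(make_records(1, beta = 0.3, effect_allele = "T",
                                   other_allele = "C"), "oc", "continuous")
  expect_equal(harmonise(ex, out1)$instruments$beta_out, 0.3)
  # opposite strand and swapped order: C/T -> G/A -> flip
  out2 <- assoc_table(make_records(1, beta = 0.3, effect_allele = "C",
                                   other_allele = "T"), "oc", "continuous")
  expect_equal(harmonise(ex, out2)$instruments$beta_out, -0.3)
  # irreconcilable alleles
  out3 <- assoc_table(make_records(1, effect_allele = "A", other_allele = "C"),
                      "oc", "continuous")
  h3 <- harmonise(ex, out3)
  expect_equal(nrow(h3$instruments), 0)
  expect_equal(h3$exclusions$reason, "allele mismatch")
})

test_that("harmonise excludes palindromic variants and logs missing ones", {
  rec <- make_records(3)
  rec$effect_allele <- c("A", "A", "C")
  rec$other_allele <- c("T", "G", "T")
  ex <- assoc_table(rec, "prot", "continuous")
  out <- assoc_table(rec[2, , drop = FALSE], "oc", "continuous")
  h <- harmonise(ex, out)
  expect_equal(h$instruments$variant_id, "rs2")
  expect_equal(h$exclusions$reason[h$exclusions$variant_id == "rs1"],
               "palindromic")
  expect_match(h$exclusions$reason[h$exclusions$variant_id == "rs3"],
               "missing")
})

test_that("harmonise substitutes a proxy and records it", {
  ex <- assoc_table(make_records(2, beta = c(0.5, 0.4)), "prot", "continuous")
  # rs1 absent from the outcome; its proxy rsP carries the outcome effect,
  # with alleles mapped A->T, G->C
  out_rec <- rbind(
    within(make_records(1, beta = 0.25, effect_allele = "T",
                        other_allele = "C"), variant_id <- "rsP"),
    make_records(2, beta = c(0, 0.1))[2, ])
  out <- assoc_table(out_rec, "oc", "continuous")
  px <- proxy_table(data.frame(variant_a = "rs1", variant_b = "rsP", r2 = 0.9,
                               a_allele1 = "A", b_allele1 = "T",
                               a_allele2 = "G", b_allele2 = "C",
                               stringsAsFactors = FALSE))
  h <- harmonise(ex, out, proxies = px)
  expect_equal(nrow(h$instruments), 2)
  got <- h$instruments[h$instruments$variant_id == "rs1", ]
  expect_equal(got$used_proxy, "rsP")
  expect_equal(got$beta_out, 0.25)
  expect_equal(h$instruments$used_proxy[h$instruments$variant_id == "rs2"],
               NA_character_)
})

test_that("allele-flip invariance and exclusion accounting hold on random fixtures", {
  set.seed(401)
  for (rep in 1:60) {
    cs <- random_harmonisation_case()
    h <- harmonise(cs$exposure, cs$outcome)
    # exact accounting: every input variant is a pair or a logged exclusion
    expect_equal(nrow(cs$exposure$records),
                 nrow(h$instruments) + nrow(h$exclusions))
    # rewriting every outcome record with swapped alleles / negated beta /
    # complemented eaf leaves the harmonised pairs identical
    flipped <- cs$outcome$records
    tmp <- flipped$effect_allele
    flipped$effect_allele <- flipped$other_allele
    flipped$other_allele <- tmp
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    h2 <- harmonise(cs$exposure,
                    assoc_table(flipped, cs$outcome$trait_id, "case_control"))
    expect_equal(h2$instruments, h$instruments)
    expect_equal(h2$exclusions, h$exclusions)
  }
})

test_that("harmonise is idempotent on an already-aligned pair set", {
  set.seed(402)
  cs <- random_harmonisation_case()
  h1 <- harmonise(cs$exposure, cs$outcome)
  # rebuild exposure/outcome tables from the harmonised pairs and re-run
  ids <- h1$instruments$variant_id
  ex2 <- cs$exposure$records[match(ids, cs$exposure$records$variant_id), ]
  out2 <- ex2
  out2$beta <- h1$instruments$beta_out
  out2$se <- h1$instruments$se_out
  h2 <- harmonise(assoc_table(ex2, "prot", "continuous"),
                  assoc_table(out2, "oc", "continuous"))
  expect_equal(h2$instruments$beta_out, h1$instruments$beta_out)
  expect_equal(h2$instruments$beta_exp, h1$instruments$beta_exp)
  expect_equal(nrow(h2$exclusions), 0)
})
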