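test_that("Wald ratio follows the delta-method formula", {
  ins <- mr_instruments(0.5, 0.1, 0.2, 0.05)
  e <- wald_ratio(ins)
  expect_equal(e$method, "wald")
  expect_equal(e$theta, 0.4)
  expect_equal(e$se, 0.1)
  expect_equal(e$ci_low, 0.4 - 1.96 * 0.1)
  expect_equal(e$ci_high, 0.4 + 1.96 * 0.1)
  expect_equal(e$pvalue, 2 * pnorm(-4))
  # null outcome effect
  expect_equal(wald_ratio(mr_instruments(0.5, 0.1, 0, 0.05))$theta, 0)
  # joint sign flip leaves theta unchanged
  e2 <- wald_ratio(mr_instruments(-0.5, 0.1, -0.2, 0.05))
  expect_equal(e2$theta, e$theta)
  expect_equal(e2$se, e$se)
  expect_error(wald_ratio(mr_instruments(1e-300, 1, 0, 1) |>
                            transform(beta_exp = 0)), "zero")
  # second-order SE propagates the exposure uncertainty and is larger
  expect_gt(wald_ratio(ins, second_order = TRUE)$se, e$se)
})

test_that("IVW matches its closed form and the WLS-through-origin oracle", {
  ins <- mr_instruments(c(0.3, 0.5), c(0.01, 0.01), c(0.15, 0.25), c(0.1, 0.1))
  e <- ivw(ins)
  expect_equal(e$theta, 0.5)
  expect_equal(e$se, 1 / sqrt(34))
  expect_error(ivw(ins[1, ]), "at least 2")
  # oracle: lm with intercept suppressed, weights 1/se_out^2
  set.seed(11)
  for (i in 1:25) {
    J <- sample(2:10, 1)
    ins <- mr_instruments(rnorm(J, 0, 0.3), runif(J, 0.005, 0.05),
                          rnorm(J, 0, 0.1), runif(J, 0.01, 0.2))
    fit <- lm(beta_out ~ 0 + beta_exp, data = ins, weights = 1 / ins$se_out^2)
    expect_equal(ivw(ins)$theta, unname(coef(fit)), tolerance = 1e-12)
  }
  # all-null outcome effects give exactly zero
  expect_equal(ivw(mr_instruments(c(0.2, 0.4), c(0.01, 0.01),
                                  c(0, 0), c(0.1, 0.1)))$theta, 0)
})

test_that("random-effects IVW never shrinks the SE and inflates under heterogeneity", {
  set.seed(12)
  hom <- mr_instruments(c(0.3, 0.5, 0.8), rep(0.01, 3),
                        c(0.15, 0.25, 0.40), rep(0.1, 3))
  expect_equal(ivw(hom, random_effects = TRUE)$se, ivw(hom)$se)  # Q ~ 0
  het <- mr_instruments(c(0.3, 0.5, 0.8), rep(0.01, 3),
                        c(0.5, -0.4, 0.9), rep(0.05, 3))
  expect_gt(ivw(het, random_effects = TRUE)$se, ivw(het)$se)
})

test_that("MR-Egger recovers slope and intercept of a weighted regression", {
  # collinear triples through the origin: perfect fit, slope 1/2
  ins <- mr_instruments(c(0.3, 0.5, 0.8), rep(0.02, 3),
                        c(0.15, 0.25, 0.40), rep(0.1, 3))
  eg <- mr_egger(ins)
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  # constant shift of every outcome effect moves only the intercept
  ins2 <- ins; ins2$beta_out <- ins2$beta_out + 0.1
  eg2 <- mr_egger(ins2)
  expect_equal(eg2$slope$theta, 0.5, tolerance = 1e-10)
  expect_equal(eg2$intercept, 0.1, tolerance = 1e-10)
  # orientation invariance: negating all exposure effects changes nothing
  ins3 <- ins2
  ins3$beta_exp <- -ins3$beta_exp
  ins3$beta_out <- -ins3$beta_out
  eg3 <- mr_egger(ins3)
  expect_equal(eg3$slope$theta, eg2$slope$theta)
  expect_equal(eg3$intercept, eg2$intercept)
  expect_error(mr_egger(ins[1:2, ]), "insufficient")
  # intercept p uses the t distribution with J - 2 df
  set.seed(21)
  ins4 <- mr_instruments(runif(5, 0.1, 0.5), rep(0.02, 5),
                         rnorm(5, 0.1, 0.05), runif(5, 0.05, 0.2))
  eg4 <- mr_egger(ins4)
  expect_equal(eg4$intercept_p,
               2 * pt(-abs(eg4$intercept / eg4$intercept_se), df = 3))
})

test_that("weighted median interpolates the ratio distribution at half weight", {
  # equal weights, ratios {0.2, 0.5, 0.9} -> 0.5
  ins <- mr_instruments(c(1, 1, 1), rep(0.01, 3), c(0.2, 0.5, 0.9), rep(0.1, 3))
  wm <- weighted_median(ins, n_boot = 100, seed = 1)
  expect_equal(wm$theta, 0.5)
  # identical ratios: estimate c, tiny bootstrap SE
  insc <- mr_instruments(c(0.5, 0.8, 1.2), rep(0.001, 3),
                         c(0.15, 0.24, 0.36), rep(0.001, 3))
  wmc <- weighted_median(insc, n_boot = 200, seed = 2)
  expect_equal(wmc$theta, 0.3, tolerance = 1e-9)
  expect_lt(wmc$se, 0.02)
  expect_error(weighted_median(ins[1:2, ]), ">= 3")
  # oracle equivalence on random instances, and boundedness
  set.seed(31)
  for (i in 1:40) {
    J <- sample(3:12, 1)
    ins <- mr_instruments(runif(J, 0.05, 1) * sample(c(-1, 1), J, TRUE),
                          runif(J, 0.005, 0.05),
                          rnorm(J, 0, 0.2), runif(J, 0.01, 0.2))
    th <- ins$beta_out / ins$beta_exp
    w <- (ins$se_out / abs(ins$beta_exp))^-2
    got <- weighted_median(ins, n_boot = 2, seed = i)$theta
    expect_equal(got, wmedian_oracle(th, w), tolerance = 1e-12)
    expect_gte(got, min(th))
    expect_lte(got, max(th))
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  ins <- mr_instruments(c(1, 1, 1, 1), rep(0.01, 4),
                        c(0.5, 0.5, 0.5, 5.0), rep(0.1, 4))
  wm <- weighted_mode(ins, n_boot = 50, seed = 3)
  expect_equal(wm$theta, 0.5, tolerance = 0.05)
  # brute-force grid oracle for the same bandwidth
  th <- ins$beta_out / ins$beta_exp
  w <- (ins$se_out / abs(ins$beta_exp))^-2; w <- w / sum(w)
  h <- 0.9 * min(sd(th), IQR(th) / 1.349) * length(th)^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - th) / h)), numeric(1))
  expect_equal(wm$theta, grid[which.max(dens)], tolerance = 0.02)
  # all ratios equal -> that ratio (zero-bandwidth fallback)
  insc <- mr_instruments(c(0.5, 0.8, 1.2), rep(0.01, 3),
                         c(0.25, 0.40, 0.60), rep(0.1, 3))
  expect_equal(weighted_mode(insc, n_boot = 20, seed = 4)$theta, 0.5)
  # order invariance
  set.seed(41)
  ins5 <- mr_instruments(runif(6, 0.1, 1), rep(0.02, 6),
                         rnorm(6, 0.2, 0.1), runif(6, 0.05, 0.2))
  perm <- sample(6)
  expect_equal(weighted_mode(ins5, n_boot = 2, seed = 5)$theta,
               weighted_mode(ins5[perm, ], n_boot = 2, seed = 5)$theta)
})

test_that("estimators are invariant to jointly negating any instrument", {
  set.seed(51)
  ins <- mr_instruments(runif(5, 0.1, 0.6), runif(5, 0.01, 0.03),
                        rnorm(5, 0.15, 0.1), runif(5, 0.05, 0.15))
  flipped <- ins
  k <- c(2, 4)
  flipped$beta_exp[k] <- -flipped$beta_exp[k]
  flipped$beta_out[k] <- -flipped$beta_out[k]
  expect_equal(ivw(flipped)$theta, ivw(ins)$theta)
  expect_equal(mr_egger(flipped)$slope$theta, mr_egger(ins)$slope$theta)
  expect_equal(mr_egger(flipped)$intercept, mr_egger(ins)$intercept)
  expect_equal(weighted_median(flipped, n_boot = 2, seed = 6)$theta,
               weighted_median(ins, n_boot = 2, seed = 6)$theta)
  expect_equal(weighted_mode(flipped, n_boot = 2, seed = 7)$theta,
               weighted_mode(ins, n_boot = 2, seed = 7)$theta)
})

test_that("bootstrap SEs are exactly reproducible under a fixed seed", {
  set.seed(61)
  ins <- mr_instruments(runif(4, 0.1, 0.6), runif(4, 0.01, 0.03),
                        rnorm(4, 0.15, 0.1), runif(4, 0.05, 0.15))
  expect_identical(weighted_median(ins, n_boot = 50, seed = 99)$se,
                   weighted_median(ins, n_boot = 50, seed = 99)$se)
  expect_identical(weighted_mode(ins, n_boot = 50, seed = 99)$se,
                   weighted_mode(ins, n_boot = 50, seed = 99)$se)
  # and the bootstrap does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(weighted_median(ins, n_boot = 10, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("primary dispatch uses Wald for one instrument, IVW for several", {
  ins <- mr_instruments(c(0.3, 0.5, 0.7), rep(0.02, 3),
                        c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(primary_estimate(ins[1, ])$method, "wald")
  expect_equal(primary_estimate(ins[1:2, ])$method, "ivw")
  expect_equal(primary_estimate(ins)$method, "ivw")
  expect_identical(primary_estimate(ins[1, ])$theta, wald_ratio(ins[1, ])$theta)
  expect_error(primary_estimate(ins[0, ]), "no instruments")
})

test_that("odds-scale conversion reproduces published-style OR and CI", {
  # theta 0 -> OR 1 with CI spanning 1
  e0 <- pqtlmr:::new_mr_estimate("wald", 0, 0.1, 1)
  o0 <- to_odds_scale(e0)
  expect_equal(o0$or, 1)
  expect_lt(o0$or_low, 1); expect_gt(o0$or_high, 1)
  # the FSHB-style headline, parameters back-derived from the printed
  # interval: log-scale midpoint 0.8778, se 0.2210 -> OR 2.41 (1.56, 3.71)
  e <- pqtlmr:::new_mr_estimate("ivw", 0.8778, 0.2210, 5)
  o <- to_odds_scale(e)
  expect_equal(round(o$or, 2), 2.41)
  expect_equal(round(o$or_low, 2), 1.56)
  expect_equal(round(o$or_high, 2), 3.71)
  expect_equal(to_odds_scale(pqtlmr:::new_mr_estimate("wald", -0.5, 0.1, 1))$or,
               exp(-0.5))
})
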