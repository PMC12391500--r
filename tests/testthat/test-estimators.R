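test_that("Wald ratios follow the delta method", {
  h <- toy_harmonised(bx = c(1.0, 0.5, 0.05), by = c(-1.4, 0, -0.0735),
                      by_se = c(0.5, 0.2, 0.0125))
  w <- wald_ratio(h)
  expect_equal(w$theta, c(-1.4, 0, -1.47))
  expect_equal(w$theta_se, c(0.5, 0.4, 0.25))

  # first-order SE agrees with a parametric bootstrap of the ratio
  set.seed(1)
  boot <- rnorm(2e4, -0.0735, 0.0125) / 0.05
  expect_equal(sd(boot), 0.25, tolerance = 0.03)

  # second-order form adds the exposure-noise term
  h2 <- toy_harmonised(bx = 0.05, by = -0.0735, by_se = 0.0125, bx_se = 0.01)
  expect_equal(wald_ratio(h2, second_order = TRUE)$theta_se,
               sqrt(0.0125^2 / 0.05^2 + 0.0735^2 * 0.01^2 / 0.05^4))

  expect_error(wald_ratio(toy_harmonised(bx = 0, by = 1, by_se = 1)), "rs1")
})

test_that("fixed-effects IVW pools Wald ratios by inverse variance", {
  # single SNP: the pool is the Wald ratio itself
  h1 <- toy_harmonised(bx = 0.05, by = -0.0735, by_se = 0.0125)
  r1 <- ivw_fixed(h1)
  expect_equal(r1$beta, -1.47)
  expect_equal(r1$se, 0.25)
  expect_equal(r1$or, exp(r1$beta))

  # equal weights, thetas -1 and -2 -> midpoint
  h2 <- toy_harmonised(bx = c(1, 1), by = c(-1, -2), by_se = c(0.3, 0.3))
  expect_equal(ivw_fixed(h2)$beta, -1.5)

  # CI is symmetric, exponentiated bounds keep their order
  expect_lt(r1$ci_low, r1$beta); expect_gt(r1$ci_high, r1$beta)
  expect_lt(r1$or_low, r1$or); expect_gt(r1$or_high, r1$or)

  expect_error(ivw_fixed(toy_harmonised(numeric(0), numeric(0), numeric(0))),
               "no variants")
})

test_that("IVW equals the origin-constrained WLS oracle on random instances", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    h <- toy_harmonised(bx = rnorm(n, 0.1, 0.05) + 0.2, by = rnorm(n, -0.2, 0.3),
                        by_se = runif(n, 0.05, 0.5))
    got <- ivw_fixed(h)
    ora <- wls_origin_oracle(h$bx, h$by, h$by_se)
    expect_equal(got$beta, ora$beta, tolerance = 1e-10)
    expect_equal(got$se, ora$se, tolerance = 1e-10)
    # and the generic lm solver agrees on the point estimate
    expect_equal(got$beta,
                 unname(coef(lm(by ~ 0 + bx, data = h, weights = 1 / h$by_se^2))),
                 tolerance = 1e-10)
  }
})

test_that("IVW is invariant to jointly negating any SNP and to losing precision", {
  set.seed(12)
  h <- toy_harmonised(bx = runif(8, 0.1, 0.5), by = rnorm(8, -0.5, 0.2),
                      by_se = runif(8, 0.05, 0.3))
  base <- ivw_fixed(h)
  for (j in c(1, 4, 8)) {
    hj <- h; hj$bx[j] <- -hj$bx[j]; hj$by[j] <- -hj$by[j]
    expect_equal(ivw_fixed(hj)$beta, base$beta, tolerance = 1e-12)
  }
  # removing any SNP never decreases the pooled SE
  for (j in seq_len(nrow(h))) {
    expect_gte(ivw_fixed(h[-j, ])$se, base$se)
  }
})

test_that("MR-Egger reproduces exact fits and matches the weighted-regression oracle", {
  # noiseless: by = c + b * bx recovered exactly
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.55)
  h <- toy_harmonised(bx = bx, by = 0.07 + (-1.2) * bx, by_se = rep(0.2, 5))
  e <- suppressWarnings(mr_egger(h))  # lm flags the perfect fit
  expect_equal(e$intercept, 0.07, tolerance = 1e-10)
  expect_equal(e$slope, -1.2, tolerance = 1e-10)

  # random instances against the closed-form weighted oracle
  set.seed(13)
  for (i in 1:15) {
    n <- sample(4:25, 1)
    h <- toy_harmonised(bx = runif(n, 0.05, 0.6), by = rnorm(n, -0.4, 0.3),
                        by_se = runif(n, 0.05, 0.4))
    e <- mr_egger(h)
    o <- wls_intercept_oracle(h$bx, h$by, 1 / h$by_se^2)
    expect_equal(e$slope, o$slope, tolerance = 1e-9)
    expect_equal(e$slope_se, o$slope_se, tolerance = 1e-9)
    expect_equal(e$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(e$intercept_se, o$intercept_se, tolerance = 1e-9)
    expect_equal(e$intercept_p, o$intercept_p, tolerance = 1e-9)
  }

  # orientation rule: jointly negating SNPs changes nothing
  h <- toy_harmonised(bx = runif(6, 0.1, 0.5), by = rnorm(6), by_se = runif(6, .1, .3))
  hneg <- h; hneg$bx[2] <- -hneg$bx[2]; hneg$by[2] <- -hneg$by[2]
  expect_equal(mr_egger(hneg)$slope, mr_egger(h)$slope, tolerance = 1e-12)

  expect_error(mr_egger(toy_harmonised(bx = c(1, 2), by = c(1, 2), by_se = c(1, 1))),
               "at least 3")
})

test_that("Cochran's Q decomposes into per-SNP contributions", {
  # identical ratios: no heterogeneity
  h0 <- toy_harmonised(bx = c(0.2, 0.4), by = c(-0.2, -0.4), by_se = c(0.1, 0.2))
  q0 <- cochran_q(h0)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)

  # two SNPs by hand: thetas -1 and -2, weights 4 and 1 -> pooled -1.2,
  # Q = 4*(0.2)^2 + 1*(0.8)^2 = 0.8
  h <- toy_harmonised(bx = c(1, 1), by = c(-1, -2), by_se = c(0.5, 1))
  q <- cochran_q(h)
  expect_equal(q$q, 0.8)
  expect_equal(q$df, 1L)
  expect_equal(sum(q$per_snp_q), q$q, tolerance = 1e-9)

  expect_true(is.na(cochran_q(toy_harmonised(1, 1, 1))$pval))
})

test_that("radial outlier exclusion flags exactly the planted outlier", {
  set.seed(14)
  n <- 10
  h <- toy_harmonised(bx = rep(0.3, n), by = -1.5 * 0.3 + rnorm(n, 0, 0.002),
                      by_se = rep(0.06, n))
  clean <- radial_mr(h)
  expect_length(clean$outliers, 0)
  expect_equal(clean$result$beta, ivw_fixed(h)$beta)

  # plant one SNP whose ratio sits ~10 SD away: its Q contribution must
  # exceed the Bonferroni chi-square threshold analytically (z^2 ~ 100 >> crit)
  hp <- h
  hp$by[4] <- hp$by[4] + 10 * hp$by_se[4]
  out <- radial_mr(hp)
  expect_equal(out$outliers, "rs4")
  expect_equal(out$result$n_snps, n - 1L)
  expect_equal(out$result$beta, ivw_fixed(hp[-4, ])$beta)
})

test_that("leave-one-out recomputes the pool without each SNP", {
  h2 <- toy_harmonised(bx = c(0.2, 0.5), by = c(-0.3, -0.6), by_se = c(0.1, 0.2))
  loo2 <- leave_one_out(h2)
  w <- wald_ratio(h2)
  expect_equal(loo2$beta, rev(w$theta))   # each row equals the other SNP's ratio
  expect_equal(loo2$se, rev(w$theta_se))

  set.seed(15)
  h5 <- toy_harmonised(bx = runif(5, 0.1, 0.5), by = rnorm(5, -0.4, 0.2),
                       by_se = runif(5, 0.05, 0.3))
  loo5 <- leave_one_out(h5)
  for (i in 1:5) {
    o <- wls_origin_oracle(h5$bx[-i], h5$by[-i], h5$by_se[-i])
    expect_equal(loo5$beta[i], o$beta, tolerance = 1e-10)
    expect_equal(loo5$se[i], o$se, tolerance = 1e-10)
  }

  # a SNP with essentially no weight leaves the estimate unchanged
  h6 <- rbind(h5, toy_harmonised(bx = 0.3, by = 5, by_se = 1e6, snp_id = "null"))
  loo6 <- leave_one_out(h6)
  expect_equal(loo6$beta[loo6$excluded_snp == "null"], ivw_fixed(h5)$beta,
               tolerance = 1e-6)
})

test_that("Steiger compares explained variance in the expected direction", {
  # dominance: strong exposure signal, negligible outcome signal
  h <- toy_harmonised(bx = rep(0.1, 10), bx_se = rep(0.002, 10),
                      by = rep(-0.01, 10), by_se = rep(0.05, 10))
  s <- steiger_test(h, n_exposure = 5e5, ncase = 1601, ncontrol = 830709)
  expect_true(s$direction_correct)
  expect_lt(s$pval, 1e-10)
  expect_true(s$r2_exposure <= 1 && s$r2_outcome <= 1)

  expect_error(steiger_test(h), "n_exposure")
})

test_that("odds-ratio reporting is a monotone exponentiation", {
  r0 <- cismr:::mr_result("ivw_fe", 0, 1, 5)
  expect_equal(to_or(r0)$or, 1)
  r <- cismr:::mr_result("ivw_fe", -1.4697, 0.2588, 44)
  r <- to_or(r)
  expect_equal(round(r$or, 2), 0.23)
  expect_equal(round(r$or_low, 2), 0.14)
  expect_equal(round(r$or_high, 2), 0.38)
  expect_equal(r$or, exp(r$beta), tolerance = 1e-12)
  rp <- to_or(cismr:::mr_result("ivw_fe", log(1.21), 0.065, 12))
  expect_equal(rp$or, 1.21)
})
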