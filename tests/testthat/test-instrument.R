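test_that("cis selection uses the closed +/- window on the right chromosome", {
  region <- gene_region("1", 1e6, 1.1e6, window = 3e5)
  pos <- c(7e5, 7e5 - 1, 1.4e6, 1.4e6 + 1, 1.05e6)
  tab <- toy_sumstats(paste0("rs", 1:6), beta = rep(0.1, 6), se = 0.01,
                      chrom = c(rep("1", 5), "2"), pos = c(pos, 1.05e6))
  kept <- select_cis(tab, region)
  expect_equal(kept$snp_id, c("rs1", "rs3", "rs5"))  # boundaries retained, chr2 dropped

  # brute-force interval check on a straddling panel
  set.seed(7)
  pos10 <- as.integer(runif(10, 5e5, 1.6e6))
  tab10 <- toy_sumstats(paste0("s", 1:10), beta = 0.1, se = 0.01, pos = pos10)
  expected <- tab10$snp_id[pos10 >= 7e5 & pos10 <= 1.4e6]
  expect_equal(select_cis(tab10, region)$snp_id, expected)

  expect_error(select_cis(toy_sumstats("rs1", 0.1, 0.01, chrom = "5"), region),
               "no SNPs")
})

test_that("significance filtering is strict at the threshold", {
  tab <- toy_sumstats(paste0("rs", 1:6), beta = 0.1, se = 0.01,
                      pval = c(5e-8, 4.9e-8, 1e-10, 0.05, 5.1e-8, 1e-300))
  kept <- filter_significant(tab, 5e-8)
  expect_equal(kept$snp_id, c("rs2", "rs3", "rs6"))
  loose <- filter_significant(tab, 1 - 1e-12)
  expect_equal(nrow(loose), 6L)
})

test_that("concordance keeps opposite-sign SNPs and re-orients to the raising allele", {
  il6r <- toy_sumstats(paste0("rs", 1:8),
                       beta = c(0.3, 0.3, -0.2, -0.2, 0.1, -0.1, 0.4, -0.3),
                       se = 0.01)
  crp <- toy_sumstats(paste0("rs", 1:8),
                      beta = c(-0.05, 0.05, 0.04, -0.04, -0.01, 0.02, 0.03, -0.03),
                      se = 0.005)
  out <- concordance_filter(il6r, crp)
  # sign-table enumeration: keep exactly where the two signs differ
  keep_expected <- c("rs1", "rs3", "rs5", "rs6")
  expect_equal(out$il6r$snp_id, keep_expected)
  expect_true(all(out$il6r$beta > 0))
  expect_true(all(out$crp$beta < 0))
  # rs3 was negative on the protein: alleles must have been swapped
  expect_equal(out$il6r$effect_allele[out$il6r$snp_id == "rs3"], "G")
  expect_equal(out$il6r$eaf[out$il6r$snp_id == "rs3"], 0.7)

  # unharmonised input (mismatching alleles) is fatal
  crp_bad <- crp; crp_bad$effect_allele <- "T"; crp_bad$other_allele <- "C"
  class(crp_bad) <- class(crp)
  expect_error(concordance_filter(il6r, crp_bad), "not allele-harmonised")
})

test_that("F-statistic is (beta/se)^2 with strict > 10 inclusion", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_lt(f_statistic(0.0316, 0.01), 10)  # 9.9856: excluded by strict rule
  expect_error(f_statistic(0.1, 0), "se must be > 0")
})

test_that("greedy clumping matches hand cases and rejects unknown SNPs", {
  ids <- paste0("rs", 1:2)
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, dimnames = list(ids, ids))
  tab <- toy_sumstats(ids, beta = 0.1, se = 0.01, pval = c(1e-10, 1e-8))
  expect_equal(greedy_clump(tab, ld_matrix(r), 0.1)$snp_id, "rs1")

  # independent SNPs all retained
  tab4 <- toy_sumstats(paste0("rs", 1:4), beta = 0.1, se = 0.01,
                       pval = c(1e-8, 1e-9, 1e-10, 1e-7))
  expect_equal(nrow(greedy_clump(tab4, ld_matrix(diag(4), paste0("rs", 1:4)), 0.1)), 4L)

  expect_error(greedy_clump(tab4, ld_matrix(r), 0.1), "absent from LD matrix")
})

test_that("greedy clumping equals the brute-force oracle and keeps its invariants", {
  for (seed in 1:40) {
    set.seed(seed)
    m <- 6
    ids <- paste0("rs", 1:m)
    r <- random_corr(m); dimnames(r) <- list(ids, ids)
    tab <- toy_sumstats(ids, beta = 0.1, se = 0.01,
                        pval = runif(m, 1e-12, 1e-4), pos = sample(1:1e6, m))
    thr <- sample(c(0.01, 0.1, 0.3), 1)
    got <- greedy_clump(tab, ld_matrix(r), thr)
    expect_equal(got$snp_id, brute_force_clump(ids, tab$pval, tab$pos, r, thr))
    # pairwise independence of the retained set
    if (nrow(got) > 1) {
      rr <- r[got$snp_id, got$snp_id]^2
      expect_true(all(rr[upper.tri(rr)] < thr))
    }
    # the globally most significant SNP always survives
    expect_true(tab$snp_id[which.min(tab$pval)] %in% got$snp_id)
    # tightening the threshold never increases the retained count
    expect_lte(nrow(greedy_clump(tab, ld_matrix(r), thr / 10)), nrow(got))
  }
})

make_clean_panel <- function(n = 8, seed = 3) {
  # panel built to survive every instrument filter
  set.seed(seed)
  region <- gene_region("1", 1e6, 1.1e6, window = 3e5)
  ids <- paste0("rs", 1:n)
  il6r <- toy_sumstats(ids, beta = runif(n, 0.2, 0.4), se = 0.01,
                       pos = as.integer(seq(9e5, 1.2e6, length.out = n)),
                       trait_scale = "sd_continuous")
  crp <- il6r
  crp$beta <- -runif(n, 0.02, 0.05)
  crp$se <- rep(0.004, n)
  crp$pval <- pmax(2 * pnorm(-abs(crp$beta / crp$se)), .Machine$double.xmin)
  attr(crp, "trait_scale") <- "log_continuous"
  list(il6r = il6r, crp = crp, region = region,
       ld = ld_matrix(diag(n), ids))
}

test_that("a panel passing every filter is a fixed point of instrument building", {
  p <- make_clean_panel()
  instr <- build_instrument(p$il6r, p$crp, p$region, p$ld)
  # with independent SNPs, clumping returns index SNPs in p-value order
  expect_equal(instr$snp_id, p$il6r$snp_id[order(p$il6r$pval)])
  expect_setequal(instr$snp_id, p$il6r$snp_id)
  expect_equal(instr$beta_exposure, -p$crp$beta[match(instr$snp_id, p$crp$snp_id)])
  expect_true(all(instr$beta_exposure > 0))
  expect_true(all(instr$f_stat > 10))
})

test_that("planted failures are removed stage by stage", {
  p <- make_clean_panel(n = 10)
  il6r <- p$il6r; crp <- p$crp
  il6r$pos[1] <- 2e6                          # outside the cis window
  il6r$pval[2] <- 1e-4                        # not genome-wide significant
  crp$beta[3] <- abs(crp$beta[3])             # discordant CRP direction
  il6r$beta[4] <- 0.05; il6r$se[4] <- 0.02    # F = 6.25 <= 10
  il6r$pval[4] <- 1e-9                        # but still significant
  r <- diag(10); r[5, 6] <- r[6, 5] <- 0.9    # LD pair: lower p survives
  il6r$pval[5] <- 1e-20; il6r$pval[6] <- 1e-10
  instr <- build_instrument(il6r, crp, p$region, ld_matrix(r, il6r$snp_id))
  expect_setequal(instr$snp_id, c("rs5", "rs7", "rs8", "rs9", "rs10"))
})

test_that("instrument building is invariant to input row order", {
  p <- make_clean_panel(n = 9, seed = 11)
  instr1 <- build_instrument(p$il6r, p$crp, p$region, p$ld)
  set.seed(1)
  perm <- sample(9)
  il6r2 <- p$il6r[perm, ]; class(il6r2) <- class(p$il6r)
  attr(il6r2, "trait_scale") <- "sd_continuous"
  instr2 <- build_instrument(il6r2, p$crp, p$region, p$ld)
  expect_setequal(instr1$snp_id, instr2$snp_id)
  expect_equal(instr1[order(instr1$snp_id), ], instr2[order(instr2$snp_id), ],
               ignore_attr = TRUE)
})

test_that("dual-pQTL restriction filters on the biomarker p-value", {
  p <- make_clean_panel()
  instr <- build_instrument(p$il6r, p$crp, p$region, p$ld)
  expect_equal(restrict_dual_pqtl(instr, p$crp, 5e-8)$snp_id, instr$snp_id)
  crp_weak <- p$crp; crp_weak$pval <- rep(c(1e-3, 1e-12), 4)
  class(crp_weak) <- class(p$crp)
  kept <- restrict_dual_pqtl(instr, crp_weak, 5e-8)
  expect_setequal(kept$snp_id,
                  intersect(instr$snp_id, crp_weak$snp_id[crp_weak$pval < 5e-8]))
  crp_none <- p$crp; crp_none$pval <- 1e-3
  class(crp_none) <- class(p$crp)
  expect_equal(nrow(restrict_dual_pqtl(instr, crp_none, 5e-8)), 0L)
})
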