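# Independent oracles and small builders shared across the test files.

# Origin-constrained weighted least squares by direct matrix algebra:
# beta = (x'Wx)^-1 x'Wy with known weights, var = (x'Wx)^-1.
wls_origin_oracle <- function(bx, by, by_se) {
  w <- 1 / by_se^2
  xtwx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / xtwx
  list(beta = beta, se = sqrt(1 / xtwx))
}

# Weighted regression with intercept by direct matrix algebra, residual-scaled
# covariance, t inference with n - 2 df (independent of stats::lm internals).
wls_intercept_oracle <- function(bx, by, w) {
  x <- cbind(1, bx)
  xtwx_inv <- solve(t(x) %*% (w * x))
  coefs <- unname(drop(xtwx_inv %*% t(x) %*% (w * by)))
  resid <- by - drop(x %*% coefs)
  sigma2 <- sum(w * resid^2) / (length(by) - 2)
  ses <- unname(sqrt(diag(sigma2 * xtwx_inv)))
  tval <- coefs / ses
  list(intercept = coefs[1], slope = coefs[2],
       intercept_se = ses[1], slope_se = ses[2],
       intercept_p = 2 * stats::pt(-abs(tval[1]), length(by) - 2),
       slope_p = 2 * stats::pt(-abs(tval[2]), length(by) - 2))
}

# Literal transcription of the greedy clumping procedure: repeatedly take the
# lowest-p remaining SNP (ties by position then id) as index, discard all
# remaining SNPs with r^2 >= threshold against it.
brute_force_clump <- function(snp_id, pval, pos, r, r2_threshold) {
  remaining <- seq_along(snp_id)
  kept <- integer(0)
  while (length(remaining) > 0) {
    o <- remaining[order(pval[remaining], pos[remaining], snp_id[remaining])]
    index <- o[1]
    kept <- c(kept, index)
    drop <- remaining[r[index, remaining]^2 >= r2_threshold]
    remaining <- setdiff(remaining, union(index, drop))
  }
  snp_id[kept]
}

# Random positive-definite correlation matrix for clumping tests.
random_corr <- function(m) {
  a <- matrix(stats::rnorm(m * m), m)
  stats::cov2cor(a %*% t(a) + m * diag(m))
}

# Minimal valid sumstats table from vectors, defaulting the bookkeeping cols.
toy_sumstats <- function(snp_id, beta, se, pval = NULL,
                         chrom = "1", pos = seq_along(snp_id) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, n = 1000,
                         trait_scale = "log_continuous", ...) {
  if (is.null(pval)) pval <- pmax(2 * stats::pnorm(-abs(beta / se)),
                                  .Machine$double.xmin)
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = effect_allele, other_allele = other_allele,
                      eaf = eaf, beta = beta, se = se, pval = pval, n = n),
           trait_scale = trait_scale, ...)
}

# Row-aligned harmonised input straight from exposure/outcome vectors.
toy_harmonised <- function(bx, by, by_se, bx_se = rep(1e-3, length(bx)),
                           snp_id = sprintf("rs%d", seq_along(bx))) {
  data.frame(snp_id = snp_id, bx = bx, bx_se = bx_se, by = by, by_se = by_se,
             eaf_exposure = rep(0.3, length(bx)),
             eaf_outcome = rep(0.3, length(bx)), stringsAsFactors = FALSE)
}

# Harmonised set over all simulated SNPs without instrument selection: the
# clean route for estimator sampling-property checks.
sim_harmonised <- function(sim) {
  cismr:::harmonised_set(sim$crp$snp_id, bx = -sim$crp$beta, bx_se = sim$crp$se,
                         by = sim$outcome$beta, by_se = sim$outcome$se,
                         eaf_exposure = sim$crp$eaf, eaf_outcome = sim$outcome$eaf)
}
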