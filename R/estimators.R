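#' @keywords internal
mr_result <- function(method, beta, se, n_snps) {
  z <- beta / se
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  data.frame(method = method, n_snps = as.integer(n_snps),
             beta = beta, se = se, ci_low = ci[1], ci_high = ci[2],
             pval = 2 * stats::pnorm(-abs(z)),
             or = exp(beta), or_low = exp(ci[1]), or_high = exp(ci[2]),
             stringsAsFactors = FALSE)
}

variants_of <- function(h) {
  if (inherits(h, "harmonised_set")) h$variants else as.data.frame(h)
}

#' Per-SNP Wald ratio
#'
#' The single-SNP causal estimate `theta = by / bx` with its first-order
#' delta-method standard error `by_se / |bx|`. The first-order form ignores
#' the exposure-side uncertainty, which is negligible for instruments with
#' large F; set `second_order = TRUE` to add the exposure-variance term
#' `sqrt(by_se^2 / bx^2 + by^2 * bx_se^2 / bx^4)` as a sensitivity.
#'
#' @param h a `harmonised_set` (or a data.frame with `bx`, `bx_se`, `by`,
#'   `by_se`, `snp_id`).
#' @param second_order use the second-order delta-method SE.
#' @return data.frame with `snp_id`, `theta`, `theta_se`.
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  v <- variants_of(h)
  if (any(v$bx == 0)) {
    stop("wald_ratio: exposure beta is zero for SNP(s): ",
         paste(v$snp_id[v$bx == 0], collapse = ", "), call. = FALSE)
  }
  theta <- v$by / v$bx
  theta_se <- if (second_order) {
    sqrt(v$by_se^2 / v$bx^2 + v$by^2 * v$bx_se^2 / v$bx^4)
  } else {
    v$by_se / abs(v$bx)
  }
  data.frame(snp_id = v$snp_id, theta = theta, theta_se = theta_se,
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance-weighted estimate
#'
#' Pools the per-SNP Wald ratios with weights `1 / theta_se^2 =
#' bx^2 / by_se^2`: `beta = sum(w * theta) / sum(w)`, `se = sqrt(1 / sum(w))`,
#' two-sided normal p-value. Algebraically identical to weighted least squares
#' of `by` on `bx` through the origin with weights `1 / by_se^2`.
#'
#' @inheritParams wald_ratio
#' @param method label recorded on the result row.
#' @return A one-row `MRResult` data.frame: `method`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or`, `or_low`, `or_high` (95% normal CI,
#'   odds-ratio columns exponentiated).
#' @export
ivw_fixed <- function(h, method = "ivw_fe") {
  v <- variants_of(h)
  if (nrow(v) == 0L) stop("ivw_fixed: no variants to pool", call. = FALSE)
  w <- wald_ratio(v)
  if (nrow(v) == 1L) return(mr_result(method, w$theta, w$theta_se, 1L))
  wt <- 1 / w$theta_se^2
  beta <- sum(wt * w$theta) / sum(wt)
  mr_result(method, beta, sqrt(1 / sum(wt)), nrow(v))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas with
#' a free intercept (weights `1 / by_se^2`), after orienting every SNP so its
#' exposure beta is non-negative. The intercept estimates average directional
#' pleiotropy; a non-zero intercept (p < 0.05) suggests its presence.
#' Inference uses the t distribution with `n_snps - 2` degrees of freedom,
#' with coefficient SEs from the weighted fit.
#'
#' @inheritParams wald_ratio
#' @return An `egger_result` list: `slope`, `slope_se`, `slope_p`,
#'   `intercept`, `intercept_se`, `intercept_p`, `n_snps`, and `result`
#'   (the slope as a one-row `MRResult`, method `"egger_slope"`).
#' @export
mr_egger <- function(h) {
  v <- variants_of(h)
  if (nrow(v) < 3L) {
    stop("mr_egger: need at least 3 variants for slope + intercept", call. = FALSE)
  }
  neg <- v$bx < 0
  bx <- ifelse(neg, -v$bx, v$bx)
  by <- ifelse(neg, -v$by, v$by)
  fit <- stats::lm(by ~ bx, weights = 1 / v$by_se^2)
  cf <- stats::coef(summary(fit))
  structure(list(slope = cf["bx", 1], slope_se = cf["bx", 2], slope_p = cf["bx", 4],
                 intercept = cf["(Intercept)", 1], intercept_se = cf["(Intercept)", 2],
                 intercept_p = cf["(Intercept)", 4], n_snps = nrow(v),
                 result = mr_result("egger_slope", cf["bx", 1], cf["bx", 2], nrow(v))),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger (%d SNPs): slope %.4f (SE %.4f, p %.3g); intercept %.4f (SE %.4f, p %.3g)\n",
              x$n_snps, x$slope, x$slope_se, x$slope_p,
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' Per-SNP contributions `q_j = w_j (theta_j - beta)^2` against a pooled
#' estimate, with `w_j` the IVW weights; `Q = sum(q_j)` referred to a
#' chi-square with `n_snps - 1` degrees of freedom.
#'
#' @inheritParams wald_ratio
#' @param pooled a one-row `MRResult` computed from `h` (defaults to the
#'   fixed-effects IVW estimate).
#' @return list `q`, `df`, `pval` (`NA` when df = 0), `per_snp_q` (named).
#' @export
cochran_q <- function(h, pooled = ivw_fixed(h)) {
  w <- wald_ratio(h)
  wt <- 1 / w$theta_se^2
  per <- stats::setNames(wt * (w$theta - pooled$beta)^2, w$snp_id)
  df <- length(per) - 1L
  list(q = sum(per), df = df,
       pval = if (df >= 1L) stats::pchisq(sum(per), df, lower.tail = FALSE) else NA_real_,
       per_snp_q = per)
}

#' Radial outlier exclusion
#'
#' Flags SNPs whose contribution to Cochran's Q against the current IVW
#' estimate exceeds the upper Bonferroni-corrected chi-square(1) quantile
#' (`alpha / n`), removes them, re-estimates, and iterates until no new
#' outliers appear or only two SNPs remain.
#'
#' @inheritParams wald_ratio
#' @param alpha nominal outlier level before Bonferroni correction
#'   (default 0.05).
#' @return list `outliers` (SNP ids removed, in removal order) and `result`
#'   (the post-removal IVW estimate, method `"radial_ivw"`).
#' @export
radial_mr <- function(h, alpha = 0.05) {
  v <- variants_of(h)
  if (nrow(v) < 3L) stop("radial_mr: need at least 3 variants", call. = FALSE)
  outliers <- character(0)
  repeat {
    pooled <- ivw_fixed(v, method = "radial_ivw")
    q <- cochran_q(v, pooled)
    crit <- stats::qchisq(1 - alpha / nrow(v), df = 1)
    flagged <- names(q$per_snp_q)[q$per_snp_q > crit]
    if (length(flagged) == nrow(v)) {
      stop("radial_mr: every SNP flagged as an outlier", call. = FALSE)
    }
    if (length(flagged) == 0L) break
    outliers <- c(outliers, flagged)
    v <- v[!v$snp_id %in% flagged, , drop = FALSE]
    if (nrow(v) <= 2L) break
  }
  list(outliers = outliers, result = ivw_fixed(v, method = "radial_ivw"))
}

#' Leave-one-out analysis
#'
#' Recomputes the fixed-effects IVW estimate excluding each SNP in turn.
#'
#' @inheritParams wald_ratio
#' @return data.frame with one row per excluded SNP: `excluded_snp` plus the
#'   `MRResult` columns (method `"loo_ivw"`).
#' @export
leave_one_out <- function(h) {
  v <- variants_of(h)
  if (nrow(v) < 2L) stop("leave_one_out: need at least 2 variants", call. = FALSE)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    res <- ivw_fixed(v[-i, , drop = FALSE], method = "loo_ivw")
    cbind(excluded_snp = v$snp_id[i], res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steiger directionality test
#'
#' Compares the variance the instrument explains in the exposure against the
#' variance it explains in the outcome. Exposure-side r-squared per SNP uses
#' the t-statistic transform `t^2 / (t^2 + n - 2)` with `t = bx / bx_se`;
#' outcome-side r-squared uses a linear-probability approximation to the
#' log-OR with the observed case fraction `v = ncase / (ncase + ncontrol)`:
#' `r2_j = by_j^2 * v * (1 - v) * 2 * p_j * (1 - p_j)` (allele frequency
#' `p_j` from the outcome, falling back to the exposure side). The causal
#' direction is declared exposure-to-outcome when the summed exposure
#' r-squared exceeds the summed outcome r-squared; the p-value is the
#' two-sided z-test comparing Fisher-transformed correlations.
#'
#' @inheritParams wald_ratio
#' @param n_exposure sample size of the exposure GWAS.
#' @param ncase,ncontrol outcome GWAS case and control counts.
#' @return list `r2_exposure`, `r2_outcome`, `direction_correct`, `pval`.
#' @export
steiger_test <- function(h, n_exposure, ncase, ncontrol) {
  if (missing(n_exposure) || missing(ncase) || missing(ncontrol) ||
      is.null(n_exposure) || is.null(ncase) || is.null(ncontrol)) {
    stop("steiger_test: supply n_exposure, ncase and ncontrol ",
         "(set them in the run config)", call. = FALSE)
  }
  n_outcome <- ncase + ncontrol
  stopifnot(n_exposure > 10, n_outcome > 10)
  v <- variants_of(h)
  t <- v$bx / v$bx_se
  r2_exp <- sum(t^2 / (t^2 + n_exposure - 2))
  vfrac <- ncase / n_outcome
  p <- ifelse(is.na(v$eaf_outcome), v$eaf_exposure, v$eaf_outcome)
  if (anyNA(p)) p[is.na(p)] <- 0.5  # conservative when no frequency is recorded
  r2_out <- sum(v$by^2 * vfrac * (1 - vfrac) * 2 * p * (1 - p))
  r2_exp <- min(r2_exp, 1); r2_out <- min(r2_out, 1)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(r2_exposure = r2_exp, r2_outcome = r2_out,
       direction_correct = r2_exp > r2_out,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Report a log-odds MR result on the odds-ratio scale
#'
#' Exponentiates the estimate and its confidence bounds; the monotone order
#' of the interval is preserved.
#'
#' @param result a one-row `MRResult` data.frame with `beta`, `ci_low`,
#'   `ci_high` on the log-odds scale.
#' @return The same row with `or`, `or_low`, `or_high` recomputed.
#' @export
to_or <- function(result) {
  result$or <- exp(result$beta)
  result$or_low <- exp(result$ci_low)
  result$or_high <- exp(result$ci_high)
  result
}
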