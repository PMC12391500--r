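# Run expr with a temporarily seeded RNG, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the two-sample summary-statistics simulator
#'
#' Defines the ground truth and GWAS geometry for a simulated drug-target MR
#' study: a cis instrument raising the target protein and lowering the
#' biomarker (log CRP), and a binary outcome affected causally through the
#' exposure plus optional direct (pleiotropic) SNP effects. Defaults mirror
#' the pleural-infection study geometry: 44 instrument SNPs, a protein GWAS
#' of 54,219, a biomarker GWAS of 575,000, an outcome GWAS of 1601 cases and
#' 830,709 controls, and a true causal log-OR of -1.47 per unit decrease in
#' log CRP (odds ratio 0.23).
#'
#' @param m number of SNPs.
#' @param maf_range minor-allele-frequency range, inside (0, 0.5].
#' @param ld_block_sizes block sizes for the LD matrix; must sum to `m`.
#' @param ld_rho within-block AR(1) correlation parameter, `|ld_rho| < 1`.
#' @param n_protein sample size of the protein (selection) GWAS.
#' @param n_exposure sample size of the biomarker (weighting) GWAS.
#' @param n_case,n_control outcome GWAS case/control counts.
#' @param true_effect causal log-OR on the outcome per unit decrease in log
#'   CRP.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of direct SNP-to-outcome
#'   effects (log-OR units); both 0 disables pleiotropy.
#' @param exposure_var_explained total variance in log CRP explained by the
#'   instrument, in (0, 1).
#' @param protein_scale ratio of the protein effect (SD units) to the log-CRP
#'   effect magnitude; controls selection-GWAS instrument strength.
#' @param noise_scale multiplier on the estimation noise (1 = the standard
#'   GWAS sampling error; 0 = noiseless limit). SEs are reported unscaled.
#' @param correlated_noise if `TRUE`, estimation noise is drawn with the LD
#'   correlation structure; by default noise is independent across SNPs and
#'   LD is used only by clumping.
#' @param seed integer seed; every random draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 44L,
                       maf_range = c(0.1, 0.5),
                       ld_block_sizes = rep(4L, 11L),
                       ld_rho = 0.25,
                       n_protein = 54219L,
                       n_exposure = 575000L,
                       n_case = 1601L,
                       n_control = 830709L,
                       true_effect = -1.47,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       exposure_var_explained = 0.01,
                       protein_scale = 8,
                       noise_scale = 1,
                       correlated_noise = FALSE,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory", call. = FALSE)
  stopifnot(m >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            abs(ld_rho) < 1,
            exposure_var_explained > 0, exposure_var_explained < 1,
            noise_scale >= 0)
  if (sum(ld_block_sizes) != m) {
    stop("sim_config: ld_block_sizes must sum to m", call. = FALSE)
  }
  structure(list(m = as.integer(m), maf_range = maf_range,
                 ld_block_sizes = as.integer(ld_block_sizes), ld_rho = ld_rho,
                 n_protein = n_protein, n_exposure = n_exposure,
                 n_case = n_case, n_control = n_control,
                 true_effect = true_effect,
                 pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
                 exposure_var_explained = exposure_var_explained,
                 protein_scale = protein_scale, noise_scale = noise_scale,
                 correlated_noise = correlated_noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a block LD matrix
#'
#' Block-diagonal correlation with AR(1) structure inside each block:
#' `r(i, j) = ld_rho^|i - j|` for SNPs i, j in the same block, 0 across
#' blocks. Positive definite for `|ld_rho| < 1`.
#'
#' @param cfg a [sim_config].
#' @param snp_ids optional identifiers (default `snp_1 ... snp_m`).
#' @return An [ld_matrix].
#' @export
simulate_ld <- function(cfg, snp_ids = paste0("snp_", seq_len(cfg$m))) {
  if (abs(cfg$ld_rho) >= 1) {
    stop("simulate_ld: |ld_rho| must be < 1 for a positive-definite matrix",
         call. = FALSE)
  }
  r <- matrix(0, cfg$m, cfg$m)
  offset <- 0L
  for (b in cfg$ld_block_sizes) {
    i <- offset + seq_len(b)
    r[i, i] <- cfg$ld_rho^abs(outer(seq_len(b), seq_len(b), "-"))
    offset <- offset + b
  }
  ld_matrix(r, snp_ids)
}

# Non-palindromic allele pairs cycled over the simulated SNPs.
.sim_allele_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C",
                              "A", "C", "T", "G"), ncol = 2, byrow = TRUE)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws per-SNP true effects on the exposure (one unit = one unit decrease
#' in natural-log CRP), scaled so the instrument explains
#' `exposure_var_explained` of the biomarker variance, and outcome effects
#' `true_effect * exposure_effect + pleiotropy`. Estimated betas are truth
#' plus normal noise with standard GWAS standard errors — quantitative trait:
#' `se = 1 / sqrt(2 n p (1 - p))` (unit trait SD); case-control log-OR:
#' `se = sqrt((1/ncase + 1/ncontrol) / (2 p (1 - p)))` — and Wald p-values.
#' The protein-raising allele is always the effect allele, so protein betas
#' are positive and biomarker (CRP) betas negative, as a concordant cis
#' instrument requires. Output is deterministic given the config seed.
#'
#' @param cfg a [sim_config].
#' @return list with [sumstats] tables `exposure` (protein, SD units), `crp`
#'   (natural-log biomarker), `outcome` (log odds), the `ld` matrix, the
#'   `region` ([gene_region]) the SNPs sit in, and `truth` (per-SNP true
#'   effects, pleiotropy, maf, config).
#' @export
simulate_two_sample <- function(cfg) {
  with_seed(cfg$seed, {
    m <- cfg$m
    snp_id <- sprintf("rs%05d", seq_len(m))
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    het <- 2 * maf * (1 - maf)

    # true exposure effects: bounded away from zero because the simulated SNPs
    # emulate variants that already passed pQTL selection in their discovery
    # GWAS; scaled so the set explains the target biomarker r-squared
    d_raw <- 1 + abs(stats::rnorm(m))
    d <- d_raw * sqrt(cfg$exposure_var_explained / sum(het * d_raw^2))
    protein_beta <- cfg$protein_scale * d
    pleio <- if (cfg$pleiotropy_sd > 0 || cfg$pleiotropy_mean != 0) {
      stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    } else rep(0, m)
    outcome_beta <- cfg$true_effect * d + pleio

    se_protein <- 1 / sqrt(2 * cfg$n_protein * maf * (1 - maf))
    se_crp <- 1 / sqrt(2 * cfg$n_exposure * maf * (1 - maf))
    se_out <- sqrt((1 / cfg$n_case + 1 / cfg$n_control) / het)

    ld <- simulate_ld(cfg, snp_id)
    draw <- function() {
      z <- stats::rnorm(m)
      if (cfg$correlated_noise) as.vector(chol(unclass(ld)) %*% z) else z
    }
    bhat_protein <- protein_beta + cfg$noise_scale * se_protein * draw()
    bhat_crp <- -d + cfg$noise_scale * se_crp * draw()
    bhat_out <- outcome_beta + cfg$noise_scale * se_out * draw()

    region <- gene_region("1", 1e6, 1.05e6, window = 3e5, build = "synthetic")
    pos <- as.integer(round(seq(region$start - 2.5e5, region$end + 2.5e5,
                                length.out = m)))
    pair <- .sim_allele_pairs[(seq_len(m) - 1L) %% nrow(.sim_allele_pairs) + 1L, ,
                              drop = FALSE]

    mk <- function(beta, se, label, scale, n) {
      sumstats(data.frame(snp_id = snp_id, chrom = region$chrom, pos = pos,
                          effect_allele = pair[, 1], other_allele = pair[, 2],
                          eaf = maf, beta = beta, se = se,
                          # Wald p, clamped so extreme z never underflows to an
                          # out-of-range exact zero
                          pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                                      .Machine$double.xmin), n = n),
               trait_label = label, trait_scale = scale,
               genome_build = "synthetic")
    }
    list(
      exposure = mk(bhat_protein, se_protein, "IL6R", "sd_continuous", cfg$n_protein),
      crp = mk(bhat_crp, se_crp, "CRP", "log_continuous", cfg$n_exposure),
      outcome = mk(bhat_out, se_out, "pleural_infection", "log_odds",
                   cfg$n_case + cfg$n_control),
      ld = ld,
      region = region,
      truth = list(exposure_beta = d, protein_beta = protein_beta,
                   pleiotropy = pleio, outcome_beta = outcome_beta,
                   true_effect = cfg$true_effect, maf = maf, config = cfg)
    )
  })
}

#' Paper-geometry synthetic fixture
#'
#' A complete instrument-ready dataset mirroring the study geometry — 44
#' candidate cis SNPs, 1601 cases and 830,709 controls, true causal log-OR
#' -1.47 (odds ratio 0.23) per unit decrease in log CRP, no pleiotropy —
#' together with an expected-output manifest (instrument size and IVW
#' estimate) computed from the generated data at generation time. All values
#' are synthetic; only the geometry follows the study.
#'
#' @param seed integer seed; the fixture is bit-reproducible given it.
#' @param ... overrides passed to [sim_config()].
#' @return The [simulate_two_sample()] bundle plus a `manifest` element.
#' @export
make_paper_scale_fixture <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_two_sample(cfg)
  instr <- build_instrument(sim$exposure, sim$crp, sim$region, sim$ld)
  h <- harmonise(instr, sim$outcome)
  ivw <- ivw_fixed(h)
  sim$manifest <- list(seed = cfg$seed, n_snps_candidate = cfg$m,
                       n_snps_instrument = nrow(instr),
                       true_effect = cfg$true_effect,
                       ivw_beta = ivw$beta, ivw_se = ivw$se, ivw_or = ivw$or)
  sim
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes the three canonical summary-statistics TSVs, the LD matrix TSV and
#' a JSON truth manifest into a directory.
#'
#' @param sim a [simulate_two_sample()] or [make_paper_scale_fixture()] bundle.
#' @param dir output directory (created if needed).
#' @return Named vector of the files written, invisibly.
#' @export
write_sim_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             crp = file.path(dir, "crp.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$crp, paths["crp"])
  write_sumstats(sim$outcome, paths["outcome"])
  write_ld_matrix(sim$ld, paths["ld"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(c(truth, list(region = unclass(sim$region)),
                         if (!is.null(sim$manifest)) list(manifest = sim$manifest)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
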