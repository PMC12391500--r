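pipeline_defaults <- list(
  window_bp = 3e5,
  p_threshold = 5e-8,
  r2_threshold = 0.1,
  r2_threshold_strict = 0.01,
  f_threshold = 10,
  palindrome_eaf_limit = 0.42,
  radial_alpha = 0.05
)

#' Load and validate a pipeline run configuration
#'
#' A run configuration names the four input files (`exposure`, `crp`,
#' `outcome`, `ld`), the drug-target `gene_region`
#' (`chrom`/`start`/`end`/`build`), the analysis thresholds, the sample sizes
#' needed by the Steiger test (`n_exposure`, `ncase`, `ncontrol`) and an
#' output directory. It may be a YAML file path or a list. In-memory objects
#' may be supplied instead of file paths under a `data` element (a
#' [simulate_two_sample()] bundle works as-is). Unspecified thresholds take
#' the study defaults: 300 kb window, p < 5e-8, clumping r-squared 0.1
#' (strict sensitivity 0.01), F > 10, palindrome frequency limit 0.42,
#' radial outlier alpha 0.05.
#'
#' @param config YAML file path or list.
#' @return The validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults, as.list(config))
  if (is.null(cfg$data)) {
    for (key in c("exposure", "crp", "outcome", "ld")) {
      if (is.null(cfg[[key]])) {
        stop("run config: missing input path '", key, "'", call. = FALSE)
      }
      if (!file.exists(cfg[[key]])) {
        stop("run config: ", key, " file not found: ", cfg[[key]], call. = FALSE)
      }
    }
  }
  if (is.null(cfg$gene_region) && is.null(cfg$data$region)) {
    stop("run config: gene_region {chrom, start, end} is required", call. = FALSE)
  }
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$r2_threshold > 0, cfg$r2_threshold <= 1,
            cfg$r2_threshold_strict > 0, cfg$r2_threshold_strict <= 1,
            cfg$f_threshold >= 0, cfg$radial_alpha > 0, cfg$radial_alpha < 1,
            cfg$palindrome_eaf_limit > 0, cfg$palindrome_eaf_limit < 0.5)
  cfg
}

#' Run the full cis-MR analysis battery
#'
#' Executes, in one deterministic pass: instrument construction (cis window,
#' significance filter, CRP concordance, greedy clumping at the primary
#' r-squared, F screen), harmonisation against the outcome, the primary
#' fixed-effects IVW estimate, and the sensitivity battery — stricter
#' clumping, dual-pQTL restriction, radial outlier removal, leave-one-out,
#' MR-Egger, and the Steiger directionality test.
#'
#' When `out_dir` is set, writes: `results.tsv` (one row per analysis, the
#' forest-plot input), `harmonisation_audit.tsv`, `leave_one_out.tsv`,
#' `wald_ratios.tsv` (per-SNP scatter input), a human-readable `run_log.txt`
#' and a machine-readable `run_log.json` capturing every threshold, count and
#' drop. Partial outputs are removed if any stage fails.
#'
#' @param config run configuration ([load_run_config()] input).
#' @return Invisibly, a list: `results` (analysis table), `instrument`,
#'   `harmonised`, `loo`, `wald`, `egger`, `steiger`, `radial_outliers`,
#'   `log` (the JSON sidecar content), `files` (paths written, if any).
#' @export
run_mr_pipeline <- function(config) {
  cfg <- load_run_config(config)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)

  if (!is.null(cfg$data)) {
    exposure <- cfg$data$exposure; crp <- cfg$data$crp
    outcome <- cfg$data$outcome; ld <- cfg$data$ld
    region <- cfg$data$region
  } else {
    exposure <- read_sumstats(cfg$exposure, cfg$exposure_column_map,
                              trait_scale = "sd_continuous", trait_label = "exposure_protein")
    crp <- read_sumstats(cfg$crp, cfg$crp_column_map,
                         trait_scale = "log_continuous", trait_label = "crp")
    outcome <- read_sumstats(cfg$outcome, cfg$outcome_column_map,
                             trait_scale = "log_odds", trait_label = "outcome")
    ld <- read_ld_matrix(cfg$ld)
    region <- NULL
  }
  if (!is.null(cfg$gene_region)) {
    gr <- cfg$gene_region
    region <- gene_region(gr$chrom, gr$start, gr$end,
                          window = if (!is.null(gr$window)) gr$window else cfg$window_bp,
                          build = if (!is.null(gr$build)) gr$build else NA_character_)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  instr <- run_stage("build_instrument",
    build_instrument(exposure, crp, region, ld,
                     p_threshold = cfg$p_threshold,
                     r2_threshold = cfg$r2_threshold,
                     f_threshold = cfg$f_threshold))
  h <- run_stage("harmonise", harmonise(instr, outcome, cfg$palindrome_eaf_limit))

  primary <- run_stage("ivw_primary", ivw_fixed(h, method = "ivw_fe"))

  instr_strict <- run_stage("strict_clump",
    build_instrument(exposure, crp, region, ld,
                     p_threshold = cfg$p_threshold,
                     r2_threshold = cfg$r2_threshold_strict,
                     f_threshold = cfg$f_threshold))
  h_strict <- harmonise(instr_strict, outcome, cfg$palindrome_eaf_limit)
  strict <- run_stage("ivw_strict", ivw_fixed(h_strict, method = "ivw_fe"))

  instr_dual <- run_stage("dual_pqtl",
    restrict_dual_pqtl(instr, crp, p_threshold = cfg$p_threshold))
  h_dual <- harmonise(instr_dual, outcome, cfg$palindrome_eaf_limit)
  dual <- run_stage("ivw_dual_pqtl", ivw_fixed(h_dual, method = "ivw_fe"))

  radial <- run_stage("radial_mr", radial_mr(h, alpha = cfg$radial_alpha))
  egger <- run_stage("mr_egger", mr_egger(h))
  loo <- run_stage("leave_one_out", leave_one_out(h))
  wald <- run_stage("wald_ratio", wald_ratio(h))
  steiger <- run_stage("steiger",
    steiger_test(h, n_exposure = cfg$n_exposure,
                 ncase = cfg$ncase, ncontrol = cfg$ncontrol))

  loo_lo <- loo[which.min(loo$beta), , drop = FALSE]
  loo_hi <- loo[which.max(loo$beta), , drop = FALSE]
  results <- rbind(
    cbind(analysis = "primary_ivw", primary),
    cbind(analysis = "strict_clump_ivw", strict),
    cbind(analysis = "dual_pqtl_ivw", dual),
    cbind(analysis = "radial_ivw", radial$result),
    cbind(analysis = "mr_egger_slope", egger$result),
    cbind(analysis = paste0("loo_beta_min_excl_", loo_lo$excluded_snp),
          loo_lo[, names(primary)]),
    cbind(analysis = paste0("loo_beta_max_excl_", loo_hi$excluded_snp),
          loo_hi[, names(primary)])
  )
  rownames(results) <- NULL

  log <- list(
    thresholds = cfg[names(pipeline_defaults)],
    gene_region = unclass(region),
    exposure_unit = "per unit decrease in natural-log CRP",
    counts = list(
      candidates = nrow(exposure),
      instrument_primary = nrow(instr),
      instrument_strict = nrow(instr_strict),
      instrument_dual_pqtl = nrow(instr_dual),
      harmonised_retained = nrow(h$variants),
      harmonisation = as.list(h$counts),
      radial_outliers = length(radial$outliers)
    ),
    radial_outliers = radial$outliers,
    egger = egger[c("slope", "slope_se", "slope_p",
                    "intercept", "intercept_se", "intercept_p", "n_snps")],
    steiger = steiger
  )

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(results = file.path(cfg$out_dir, "results.tsv"),
               audit = file.path(cfg$out_dir, "harmonisation_audit.tsv"),
               loo = file.path(cfg$out_dir, "leave_one_out.tsv"),
               wald = file.path(cfg$out_dir, "wald_ratios.tsv"),
               log_json = file.path(cfg$out_dir, "run_log.json"),
               log_txt = file.path(cfg$out_dir, "run_log.txt"))
    written <- files
    wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    wt(results, files["results"])
    write_harmonisation_audit(h, files["audit"])
    wt(loo, files["loo"])
    wt(wald, files["wald"])
    jsonlite::write_json(log, files["log_json"], auto_unbox = TRUE, digits = NA)
    writeLines(c(
      "cis-MR pipeline run",
      sprintf("gene region: chr%s:%s-%s (+/- %s bp, build %s)", region$chrom,
              format(region$start, scientific = FALSE),
              format(region$end, scientific = FALSE),
              format(region$window, scientific = FALSE), region$build),
      sprintf("thresholds: p<%g, clump r2>=%g (strict %g), F>%g, palindrome eaf limit %g, radial alpha %g",
              cfg$p_threshold, cfg$r2_threshold, cfg$r2_threshold_strict,
              cfg$f_threshold, cfg$palindrome_eaf_limit, cfg$radial_alpha),
      sprintf("instrument: %d SNPs (strict clump %d, dual-pQTL %d); %d harmonised",
              nrow(instr), nrow(instr_strict), nrow(instr_dual), nrow(h$variants)),
      sprintf("primary IVW: OR %.3f (95%% CI %.3f-%.3f), p %.3g, per unit decrease in log CRP",
              primary$or, primary$or_low, primary$or_high, primary$pval),
      sprintf("radial outliers removed: %s",
              if (length(radial$outliers)) paste(radial$outliers, collapse = ", ") else "none"),
      sprintf("Egger intercept: %.4f (SE %.4f, p %.3g)",
              egger$intercept, egger$intercept_se, egger$intercept_p),
      sprintf("Steiger: r2 exposure %.4g vs outcome %.4g, direction %s (p %.3g)",
              steiger$r2_exposure, steiger$r2_outcome,
              if (steiger$direction_correct) "exposure->outcome" else "indeterminate/reversed",
              steiger$pval)
    ), files["log_txt"])
  }

  ok <- TRUE
  invisible(list(results = results, instrument = instr, harmonised = h,
                 loo = loo, wald = wald, egger = egger, steiger = steiger,
                 radial_outliers = radial$outliers, log = log, files = files))
}
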