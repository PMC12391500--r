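#' Define a cis gene region
#'
#' A gene region with a flanking window, used to select cis variants. The
#' retained interval is closed: `[start - window, end + window]`. Gene
#' coordinates and build are supplied by the caller, never hardcoded.
#'
#' @param chrom chromosome of the gene.
#' @param start,end gene boundaries in base pairs (1-based, start < end).
#' @param window flank added on each side, in base pairs (default 300 kb).
#' @param build genome build label carried for provenance.
#' @return A `gene_region` list.
#' @export
gene_region <- function(chrom, start, end, window = 3e5, build = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end); window <- as.numeric(window)
  if (!(start < end)) stop("gene_region: start must be < end", call. = FALSE)
  if (window < 0) stop("gene_region: window must be >= 0", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 window = window, build = build),
            class = "gene_region")
}

#' Select cis variants around a gene
#'
#' Retains SNPs on the region's chromosome with position inside the closed
#' interval `[start - window, end + window]`.
#'
#' @param table a [sumstats] table with `chrom`/`pos` populated.
#' @param region a [gene_region].
#' @return The filtered [sumstats] table.
#' @export
select_cis <- function(table, region) {
  lo <- region$start - region$window
  hi <- region$end + region$window
  keep <- table$chrom == region$chrom & table$pos >= lo & table$pos <= hi
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf("select_cis: no SNPs within [%s, %s] on chromosome %s",
                 format(lo, scientific = FALSE), format(hi, scientific = FALSE),
                 region$chrom), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter by genome-wide significance
#'
#' Retains SNPs with `pval < p_threshold` (strict inequality, so a p-value
#' exactly at the threshold is dropped).
#'
#' @param table a [sumstats] table.
#' @param p_threshold p-value threshold in (0, 1), default 5e-8.
#' @return The filtered [sumstats] table.
#' @export
filter_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  out <- table[table$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Align table b onto a's allele orientation, SNP by SNP. Resolves swapped and
# strand-complemented allele codings; palindromic or irreconcilable SNPs are
# dropped. Returns row-aligned data.frames (a, b) restricted to resolvable SNPs.
align_tables <- function(a, b) {
  pr <- intersect_sumstats(a, b)
  a <- pr$a; b <- pr$b
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pal <- comp[a$effect_allele] == a$other_allele
  same <- b$effect_allele == a$effect_allele & b$other_allele == a$other_allele
  swap <- b$effect_allele == a$other_allele & b$other_allele == a$effect_allele
  b_ea_c <- unname(comp[b$effect_allele]); b_oa_c <- unname(comp[b$other_allele])
  same_c <- b_ea_c == a$effect_allele & b_oa_c == a$other_allele
  swap_c <- b_ea_c == a$other_allele & b_oa_c == a$effect_allele
  flip <- !pal & !same & (swap | swap_c)
  keep <- !pal & (same | swap | same_c | swap_c)
  b$beta[flip] <- -b$beta[flip]
  b$eaf[flip] <- 1 - b$eaf[flip]
  b$effect_allele <- a$effect_allele
  b$other_allele <- a$other_allele
  list(a = a[keep, , drop = FALSE], b = b[keep, , drop = FALSE])
}

#' Keep SNPs with concordant target and biomarker effects
#'
#' For a protein-raising drug-target instrument scaled on a downstream
#' biomarker, retains SNPs whose effects on the two traits have opposite
#' signs (here: raise IL-6R, lower CRP), then re-orients each SNP so the
#' protein-raising allele is the effect allele. Both inputs must already be
#' on a common effect-allele orientation per SNP; mismatched alleles are a
#' fatal error.
#'
#' @param il6r [sumstats] for the target protein GWAS.
#' @param crp [sumstats] for the downstream biomarker GWAS, allele-aligned
#'   with `il6r`.
#' @return A list of row-aligned [sumstats] tables `il6r` and `crp`, oriented
#'   so every `il6r` beta is positive and every `crp` beta negative.
#' @export
concordance_filter <- function(il6r, crp) {
  pr <- intersect_sumstats(il6r, crp)
  il6r <- pr$a; crp <- pr$b
  if (!all(crp$effect_allele == il6r$effect_allele &
           crp$other_allele == il6r$other_allele)) {
    stop("concordance_filter: inputs are not allele-harmonised; align the ",
         "biomarker table to the protein table first", call. = FALSE)
  }
  keep <- il6r$beta != 0 & crp$beta != 0 & sign(il6r$beta) != sign(crp$beta)
  il6r <- il6r[keep, , drop = FALSE]
  crp <- crp[keep, , drop = FALSE]
  # re-orient so the protein-raising allele is the effect allele
  flip <- il6r$beta < 0
  for (nm in c("il6r", "crp")) {
    tb <- get(nm)
    ea <- tb$effect_allele
    tb$effect_allele[flip] <- tb$other_allele[flip]
    tb$other_allele[flip] <- ea[flip]
    tb$beta[flip] <- -tb$beta[flip]
    tb$eaf[flip] <- 1 - tb$eaf[flip]
    rownames(tb) <- NULL
    assign(nm, tb)
  }
  list(il6r = il6r, crp = crp)
}

#' Greedy LD clumping
#'
#' Iteratively picks the remaining SNP with the smallest p-value as an index
#' SNP and removes every remaining SNP whose squared correlation with it is at
#' least `r2_threshold`; repeats until no SNPs remain. Ties on p-value are
#' broken by position, then by identifier, so output is deterministic.
#'
#' @param table a [sumstats] table.
#' @param ld an [ld_matrix] covering every SNP in `table`.
#' @param r2_threshold squared-correlation threshold; a pair at or above it is
#'   considered dependent (default 0.1).
#' @return The index SNPs as a [sumstats] table, in selection order.
#' @export
greedy_clump <- function(table, ld, r2_threshold = 0.1) {
  missing_ids <- setdiff(table$snp_id, rownames(ld))
  if (length(missing_ids) > 0L) {
    stop("greedy_clump: SNP(s) absent from LD matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  r2 <- unclass(ld[table$snp_id, table$snp_id, drop = FALSE])^2
  remaining <- seq_len(nrow(table))
  ord <- order(table$pval, table$pos, table$snp_id)
  selected <- integer(0)
  while (length(remaining) > 0L) {
    idx <- ord[ord %in% remaining][1L]
    selected <- c(selected, idx)
    remaining <- setdiff(remaining, c(idx, remaining[r2[idx, remaining] >= r2_threshold]))
  }
  out <- table[selected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F-statistic
#'
#' The single-SNP F-statistic `(beta / se)^2`; F > 10 is the conventional
#' weak-instrument cutoff.
#'
#' @param beta,se effect estimate and its standard error (`se > 0`).
#' @return The F-statistic.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("f_statistic: se must be > 0", call. = FALSE)
  (beta / se)^2
}

#' Build a CRP-weighted cis instrument
#'
#' Composes the full instrument-selection pipeline: cis-region selection on
#' the protein GWAS, genome-wide significance filter on the protein p-values,
#' allele alignment of the biomarker GWAS and the concordance filter
#' (protein-raising allele must lower the biomarker), greedy LD clumping on
#' the protein p-values, and the F > `f_threshold` screen with F computed from
#' the protein (selection) GWAS. The surviving SNPs are weighted by their
#' biomarker effect: `beta_exposure` is the (sign-flipped) CRP beta, so one
#' exposure unit is one unit *decrease* in natural-log CRP and protective
#' outcome effects appear as odds ratios below one.
#'
#' @param il6r [sumstats] of the target-protein GWAS (defines relevance).
#' @param crp [sumstats] of the biomarker GWAS (defines the weights).
#' @param region [gene_region] of the drug-target gene.
#' @param ld [ld_matrix] covering the candidate SNPs.
#' @param p_threshold significance threshold on the protein GWAS (default 5e-8).
#' @param r2_threshold clumping threshold (default 0.1).
#' @param f_threshold weak-instrument cutoff (default 10, strict `>`).
#' @return An `mr_instrument` data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `pval_exposure`, `f_stat`. All `beta_exposure` are positive (per unit
#'   decrease in log CRP for the protein-raising allele).
#' @export
build_instrument <- function(il6r, crp, region, ld,
                             p_threshold = 5e-8, r2_threshold = 0.1,
                             f_threshold = 10) {
  stage <- function(x, name) {
    if (nrow(x) == 0L) stop("build_instrument: empty instrument after stage '",
                            name, "'", call. = FALSE)
    x
  }
  cis <- stage(select_cis(il6r, region), "select_cis")
  sig <- stage(filter_significant(cis, p_threshold), "filter_significant")
  aligned <- align_tables(sig, crp)
  conc <- concordance_filter(aligned$a, aligned$b)
  stage(conc$il6r, "concordance_filter")
  clumped <- stage(greedy_clump(conc$il6r, ld, r2_threshold), "greedy_clump")
  crp_w <- conc$crp[match(clumped$snp_id, conc$crp$snp_id), , drop = FALSE]
  f <- f_statistic(clumped$beta, clumped$se)
  keep <- f > f_threshold
  clumped <- clumped[keep, , drop = FALSE]
  crp_w <- crp_w[keep, , drop = FALSE]
  if (nrow(clumped) == 0L) stop("build_instrument: empty instrument after stage 'f_filter'",
                                call. = FALSE)
  out <- data.frame(
    snp_id        = clumped$snp_id,
    chrom         = clumped$chrom,
    pos           = clumped$pos,
    effect_allele = clumped$effect_allele,
    other_allele  = clumped$other_allele,
    eaf           = clumped$eaf,
    # CRP weight: beta_crp < 0 for the protein-raising allele; flip the sign so
    # the exposure is "one unit decrease in log CRP" and betas are positive
    beta_exposure = -crp_w$beta,
    se_exposure   = crp_w$se,
    pval_exposure = crp_w$pval,
    f_stat        = f[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            crp_pval = crp_w$pval,
            exposure_unit = "per unit decrease in natural-log CRP",
            class = c("mr_instrument", "data.frame"))
}

#' Restrict an instrument to dual pQTLs
#'
#' Keeps only instrument SNPs that are themselves genome-wide significant for
#' the weighting biomarker (CRP), i.e. pQTLs for both traits.
#'
#' @param instr an `mr_instrument` from [build_instrument()].
#' @param crp [sumstats] of the biomarker GWAS containing the instrument SNPs.
#' @param p_threshold significance threshold on the biomarker p-values
#'   (default 5e-8, strict `<`).
#' @return The restricted `mr_instrument`.
#' @export
restrict_dual_pqtl <- function(instr, crp, p_threshold = 5e-8) {
  idx <- match(instr$snp_id, crp$snp_id)
  if (anyNA(idx)) {
    stop("restrict_dual_pqtl: instrument SNP(s) absent from biomarker table: ",
         paste(instr$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- instr[crp$pval[idx] < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
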