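#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a plain `data.frame` with one row per SNP and the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, plus attributes recording the trait label,
#' the scale the betas are on, and the genome build the coordinates refer to.
#' Betas are per copy of the effect allele; the scale is one of
#' `"log_continuous"` (e.g. natural-log CRP), `"sd_continuous"` (e.g. protein
#' level in SD units) or `"log_odds"` (case-control log odds ratio).
#'
#' @param df data.frame holding the canonical columns (missing `eaf`/`n` are
#'   filled with `NA`).
#' @param trait_label short name of the measured trait.
#' @param trait_scale one of `"log_continuous"`, `"sd_continuous"`, `"log_odds"`.
#' @param genome_build coordinate build the positions refer to (carried as
#'   metadata, never inferred), e.g. `"GRCh37"`.
#' @param validate drop rows violating the record invariants (default `TRUE`).
#' @return A `sumstats` data.frame. The number of rows removed during
#'   validation is stored in `attr(x, "n_dropped")`.
#' @export
sumstats <- function(df, trait_label = "trait",
                     trait_scale = c("log_continuous", "sd_continuous", "log_odds"),
                     genome_build = NA_character_, validate = TRUE) {
  trait_scale <- match.arg(trait_scale)
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats: missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_

  out <- data.frame(
    snp_id        = as.character(df$snp_id),
    chrom         = as.character(df$chrom),
    pos           = as.integer(df$pos),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele  = toupper(as.character(df$other_allele)),
    eaf           = as.numeric(df$eaf),
    beta          = as.numeric(df$beta),
    se            = as.numeric(df$se),
    pval          = as.numeric(df$pval),
    n             = as.numeric(df$n),
    stringsAsFactors = FALSE
  )

  n_dropped <- 0L
  if (validate) {
    bases <- c("A", "C", "G", "T")
    ok <- !is.na(out$snp_id) & nzchar(out$snp_id) &
      !is.na(out$beta) & is.finite(out$beta) &
      !is.na(out$se) & out$se > 0 &
      !is.na(out$pval) & out$pval > 0 & out$pval <= 1 &
      out$effect_allele %in% bases & out$other_allele %in% bases &
      out$effect_allele != out$other_allele &
      (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1))
    n_dropped <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    # duplicate snp_id: keep the lowest p-value, log the rest
    if (anyDuplicated(out$snp_id)) {
      ord <- order(out$pval, out$pos, out$snp_id)
      keep <- !duplicated(out$snp_id[ord])
      n_dup <- sum(!keep)
      out <- out[sort(ord[keep]), , drop = FALSE]
      n_dropped <- n_dropped + n_dup
    }
    rownames(out) <- NULL
  }

  structure(out,
            trait_label = trait_label,
            trait_scale = trait_scale,
            genome_build = genome_build,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s, build %s): %d SNPs, %d dropped at validation\n",
              attr(x, "trait_label"), attr(x, "trait_scale"),
              attr(x, "genome_build"), nrow(x), attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

trait_scale <- function(x) attr(x, "trait_scale")

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (tab, comma or whitespace separated, with a
#' header row) and maps its columns onto the canonical summary-statistics
#' layout. Rows violating the per-record invariants (non-positive SE, p-value
#' outside (0, 1], indel or identical alleles, frequency outside \[0, 1\]) are
#' dropped and counted; duplicated identifiers keep the smallest p-value.
#'
#' @param path file path to the delimited table.
#' @param column_map named character vector or list mapping canonical field
#'   names (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`, optionally `eaf`, `n`) to the source column names. Defaults
#'   to the identity map.
#' @inheritParams sumstats
#' @return A validated [sumstats] table.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_scale = c("log_continuous", "sd_continuous", "log_odds"),
                          trait_label = NULL, genome_build = NA_character_) {
  trait_scale <- match.arg(trait_scale)
  if (!file.exists(path)) stop("read_sumstats: file not found: ", path, call. = FALSE)
  raw <- as.data.frame(data.table::fread(path, header = TRUE, data.table = FALSE,
                                         showProgress = FALSE))
  mandatory <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  optional <- c("eaf", "n")
  if (is.null(column_map)) {
    column_map <- stats::setNames(as.list(c(mandatory, optional)), c(mandatory, optional))
  }
  column_map <- as.list(column_map)
  miss <- setdiff(mandatory, names(column_map))
  if (length(miss) > 0L) {
    stop("read_sumstats: column_map does not name mandatory field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  absent <- vapply(column_map[mandatory], function(src) !src %in% names(raw), logical(1))
  if (any(absent)) {
    stop("read_sumstats: source column(s) not found in ", path, ": ",
         paste(unlist(column_map[mandatory][absent]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in c(mandatory, optional)) {
    src <- column_map[[field]]
    if (!is.null(src) && src %in% names(raw)) df[[field]] <- raw[[src]]
  }
  out <- sumstats(df,
                  trait_label = if (is.null(trait_label)) basename(path) else trait_label,
                  trait_scale = trait_scale, genome_build = genome_build)
  if (nrow(out) == 0L) {
    stop("read_sumstats: no valid rows in ", path,
         " (", attr(out, "n_dropped"), " dropped)", call. = FALSE)
  }
  if (attr(out, "n_dropped") > 0L) {
    message("read_sumstats: dropped ", attr(out, "n_dropped"),
            " invalid/duplicate row(s) from ", basename(path))
  }
  out
}

#' Write a summary-statistics table in the canonical layout
#'
#' Writes a tab-delimited file with the fixed column order `snp_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' @param x a [sumstats] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  utils::write.table(as.data.frame(x)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect two summary-statistics tables by SNP identifier
#'
#' Returns the rows shared between two tables, keyed by `snp_id` and ordered
#' as in `a`. Counts of identifiers unique to each side are attached as
#' attributes (`n_only_a`, `n_only_b`).
#'
#' @param a,b [sumstats] tables.
#' @return A list with elements `a` and `b`: the matched rows of each table,
#'   row-aligned, in `a`'s order.
#' @export
intersect_sumstats <- function(a, b) {
  shared <- a$snp_id[a$snp_id %in% b$snp_id]
  if (length(shared) == 0L) {
    stop("intersect_sumstats: no shared SNP ids between tables; a has e.g. [",
         paste(utils::head(a$snp_id, 5), collapse = ", "), "], b has e.g. [",
         paste(utils::head(b$snp_id, 5), collapse = ", "), "]", call. = FALSE)
  }
  ia <- match(shared, a$snp_id)
  ib <- match(shared, b$snp_id)
  out <- list(a = a[ia, , drop = FALSE], b = b[ib, , drop = FALSE])
  rownames(out$a) <- rownames(out$b) <- NULL
  attr(out, "n_only_a") <- sum(!a$snp_id %in% shared)
  attr(out, "n_only_b") <- sum(!b$snp_id %in% shared)
  out
}

#' LD correlation matrices
#'
#' An `ld_matrix` is a symmetric matrix of pairwise SNP correlations (r, not
#' r-squared) with SNP identifiers as dimnames. The constructor enforces a
#' unit diagonal, `|r| <= 1`, and symmetry to 1e-12.
#'
#' @param r square numeric matrix of correlations.
#' @param snp_ids SNP identifiers in matrix order (defaults to rownames).
#' @return A validated `ld_matrix`.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(snp_ids) || length(snp_ids) != nrow(r)) {
    stop("ld_matrix: snp_ids must name every row", call. = FALSE)
  }
  if (nrow(r) != ncol(r)) stop("ld_matrix: matrix must be square", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-12) stop("ld_matrix: matrix not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-12) stop("ld_matrix: diagonal must be 1", call. = FALSE)
  if (max(abs(r)) > 1 + 1e-12) stop("ld_matrix: |r| must be <= 1", call. = FALSE)
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square numeric matrix with a SNP-identifier header row (and
#' optionally a leading identifier column). The matrix is subset and reordered
#' to `snp_ids`; numerically asymmetric input is symmetrised by averaging when
#' the largest asymmetry is at most 1e-8 and rejected otherwise.
#'
#' @param path file path.
#' @param snp_ids identifiers to retain, in the requested order; `NULL` keeps
#'   the file's own set and order.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path, snp_ids = NULL) {
  raw <- as.data.frame(data.table::fread(path, header = TRUE, data.table = FALSE,
                                         showProgress = FALSE))
  if (!is.numeric(raw[[1]])) {
    rownames(raw) <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  } else {
    rownames(raw) <- colnames(raw)
  }
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("read_ld_matrix: matrix in ", path, " is not square",
                               call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    stop("read_ld_matrix: asymmetry ", format(asym), " exceeds 1e-8 in ", path,
         call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (!is.null(snp_ids)) {
    missing_ids <- setdiff(snp_ids, colnames(m))
    if (length(missing_ids) > 0L) {
      stop("read_ld_matrix: requested SNP(s) absent from ", path, ": ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    m <- m[snp_ids, snp_ids, drop = FALSE]
  }
  ld_matrix(m)
}

#' Write an LD matrix as a delimited file with identifier header
#' @param x an [ld_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  df <- data.frame(snp_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
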