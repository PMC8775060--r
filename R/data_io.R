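# Readers, writers and harmonization for GWAS summary statistics and
# genotype panels; dosage standardization; summary-to-correlation conversion.

ss_required <- c("chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pvalue")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file with one row per variant and validates it.
#' Each record carries the variant key (chromosome, 1-based position, effect
#' allele, non-effect allele), the marginal effect size ("Beta"), its
#' standard error and p-value, and optionally the GWAS sample size. Rows
#' failing the type and range checks (non-positive standard error, p-value
#' outside (0, 1], non-finite effect, malformed alleles) are dropped with a
#' warning reporting the count.
#'
#' @param path path to a delimited text file with a header.
#' @param column_map named character vector mapping the canonical names
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pvalue` (and optionally `n_gwas`) to the column names in the file.
#'   Defaults to the identity mapping.
#' @param sep field separator.
#' @return A `data.frame` of class `"summary_stats"` with the canonical
#'   columns, typed and validated.
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_map)) {
    column_map <- stats::setNames(ss_required, ss_required)
    if ("n_gwas" %in% names(raw)) column_map <- c(column_map, n_gwas = "n_gwas")
  }
  missing_req <- setdiff(ss_required, names(column_map))
  if (length(missing_req))
    stop("column_map must name the required columns; missing: ",
         paste(missing_req, collapse = ", "))
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop(sprintf("columns not found in '%s': %s (file has: %s)", path,
                 paste(absent, collapse = ", "),
                 paste(names(raw), collapse = ", ")))
  df <- data.frame(
    chrom = as.character(raw[[column_map[["chrom"]]]]),
    pos = as.integer(raw[[column_map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    beta = as.numeric(raw[[column_map[["beta"]]]]),
    se = as.numeric(raw[[column_map[["se"]]]]),
    pvalue = as.numeric(raw[[column_map[["pvalue"]]]]),
    stringsAsFactors = FALSE
  )
  if ("n_gwas" %in% names(column_map))
    df$n_gwas <- as.integer(raw[[column_map[["n_gwas"]]]])
  validate_summary_stats(df)
}

validate_summary_stats <- function(df) {
  ok <- !is.na(df$pos) & df$pos >= 1 &
    df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1
  if ("n_gwas" %in% names(df)) ok <- ok & (is.na(df$n_gwas) | df$n_gwas >= 3)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("dropped %d summary-statistics row(s) failing validation", n_bad))
  df <- df[ok, , drop = FALSE]
  key <- paste(df$chrom, df$pos, df$effect_allele, df$other_allele, sep = ":")
  if (anyDuplicated(key)) {
    warning(sprintf("dropped %d duplicated variant record(s)", sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param stats a `summary_stats` table to serialize.
#' @export
write_summary_stats <- function(stats, path, sep = "\t") {
  utils::write.table(as.data.frame(stats), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a genotype panel
#'
#' A genotype panel holds an `n` samples x `p` variants dosage matrix with
#' values in `[0, 2]` (hard calls or imputed allele-1 dosages) together with
#' sample identifiers and per-variant records (chromosome, position, counted
#' allele `a1`, other allele `a2`). Missing calls must already be imputed;
#' the readers impute them to the per-variant mean of the observed calls.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants `data.frame` with columns `chrom`, `pos`, `a1`, `a2` and
#'   optionally `id` (defaults to `chrom:pos:a1:a2`).
#' @param sample_ids character vector of row identifiers.
#' @return An object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("'dosages' must be numeric")
  if (nrow(variants) != ncol(dosages))
    stop("variants table and dosage columns disagree in length")
  if (anyNA(dosages)) stop("dosages contain missing values; impute first")
  if (min(dosages) < 0 || max(dosages) > 2)
    stop("dosages must lie in [0, 2]")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (is.null(variants$id))
    variants$id <- paste(variants$chrom, variants$pos, variants$a1,
                         variants$a2, sep = ":")
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  af <- colMeans(x$dosages) / 2
  cat(sprintf("  counted-allele frequency range: %.3f - %.3f\n",
              min(af), max(af)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

# PLINK .bed v1.9 magic bytes and SNP-major mode flag
bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a genotype panel from PLINK bed/bim/fam or a dosage TSV
#'
#' For a PLINK fileset, `path` is the prefix (or the `.bed` path) of a
#' binary v1.9 SNP-major bed/bim/fam triple. Two-bit codes are decoded as
#' dosages of the bim's first allele (A1): `00` = 2 copies, `10` = 1,
#' `11` = 0, and `01` (missing) is imputed to the variant's mean observed
#' dosage (the imputed count per variant is recorded in the
#' `"n_imputed"` attribute). For a TSV, the file has sample ids in the
#' first column and one `chrom:pos:a1:a2` variant per remaining column.
#'
#' @param path PLINK prefix, `.bed` path, or dosage TSV path.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.tsv$", path) ||
      (file.exists(path) && !file.exists(paste0(sub("\\.bed$", "", path), ".bed"))))
    return(read_dosage_tsv(path))
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  p <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], bed_magic))
    stop("'", bed, "' is not a SNP-major PLINK v1.9 bed file (bad magic bytes)")
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) != 3 + bytes_per_variant * p)
    stop(sprintf("bed size %d inconsistent with %d samples x %d variants",
                 length(raw), n, p))
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit genotype codes of every byte, sample-fastest
  codes <- matrix(0L, nrow = 4 * bytes_per_variant, ncol = p)
  shifted <- matrix(body, nrow = bytes_per_variant, ncol = p)
  for (j in 0:3) {
    codes[seq(j + 1, by = 4, length.out = bytes_per_variant), ] <-
      shifted %% 4L
    shifted <- shifted %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  dos <- matrix(NA_real_, n, p)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  n_imputed <- integer(p)
  for (j in which(colSums(is.na(dos)) > 0)) {
    miss <- is.na(dos[, j])
    n_imputed[j] <- sum(miss)
    if (all(miss)) stop(sprintf("variant %s is 100%% missing", bim_df$id[j]))
    dos[miss, j] <- mean(dos[!miss, j])
  }
  panel <- genotype_panel(dos,
                          variants = bim_df[, c("chrom", "pos", "a1", "a2", "id")],
                          sample_ids = as.character(fam_df[[2]]))
  attr(panel, "n_imputed") <- n_imputed
  panel
}

read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  ids <- colnames(dos)
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("dosage TSV column names must be chrom:pos:a1:a2")
  variants <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    a1 = vapply(parts, `[`, "", 3),
    a2 = vapply(parts, `[`, "", 4),
    id = ids, stringsAsFactors = FALSE
  )
  n_imputed <- integer(ncol(dos))
  for (j in which(colSums(is.na(dos)) > 0)) {
    miss <- is.na(dos[, j])
    n_imputed[j] <- sum(miss)
    if (all(miss)) stop(sprintf("variant %s is 100%% missing", ids[j]))
    dos[miss, j] <- mean(dos[!miss, j])
  }
  panel <- genotype_panel(dos, variants, sample_ids)
  attr(panel, "n_imputed") <- n_imputed
  panel
}

#' Write a genotype panel to PLINK bed/bim/fam or a dosage TSV
#'
#' `format = "bed"` writes a SNP-major PLINK v1.9 triple (hard calls only;
#' non-integer dosages are rounded). `format = "tsv"` writes the dosage
#' matrix as tab-separated text with `chrom:pos:a1:a2` column names.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix (bed) or file path (tsv).
#' @param format `"bed"` or `"tsv"`.
#' @return The written path (prefix), invisibly.
#' @export
write_genotypes <- function(panel, prefix, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = panel$sample_ids,
                     panel$dosages, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, prefix, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(prefix))
  }
  dos <- round(panel$dosages)
  n <- nrow(dos); p <- ncol(dos)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, p)
  code[dos == 1] <- 2L
  code[dos == 2] <- 0L
  bytes_per_variant <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bytes_per_variant - n, p)
  code <- rbind(code, pad)
  weights <- rep(c(1L, 4L, 16L, 64L), bytes_per_variant)
  grp <- rep(seq_len(bytes_per_variant), each = 4)
  packed <- apply(code * weights, 2, function(col) tapply(col, grp, sum))
  writeBin(c(bed_magic, as.raw(as.integer(packed))), paste0(prefix, ".bed"))
  v <- panel$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

is_strand_ambiguous <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize summary statistics with a genotype panel
#'
#' Matches variants by chromosome and position and aligns effect sizes to
#' the panel's counted allele: if the stats' effect allele equals the
#' panel's A1 the effect is kept as is; if effect and other allele are
#' swapped relative to the panel the sign of the effect is flipped;
#' strand-ambiguous variants (A/T or C/G pairs) and allele-set mismatches
#' are dropped. Harmonization is idempotent: the returned table is in panel
#' orientation, so re-harmonizing changes nothing.
#'
#' @param stats a `summary_stats` table.
#' @param panel a [genotype_panel()].
#' @return A list with `stats` (the aligned `summary_stats` rows, effect
#'   alleles relabeled to panel orientation), `index` (the matching panel
#'   column indices), and `dropped` (named counts: `unmatched`, `ambiguous`,
#'   `mismatched`).
#' @export
harmonize <- function(stats, panel) {
  v <- panel$variants
  key_stats <- paste(stats$chrom, stats$pos, sep = ":")
  key_panel <- paste(v$chrom, v$pos, sep = ":")
  idx <- match(key_stats, key_panel)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  st <- stats[matched, , drop = FALSE]
  pj <- idx[matched]

  ambiguous <- is_strand_ambiguous(st$effect_allele, st$other_allele)
  same <- st$effect_allele == v$a1[pj] & st$other_allele == v$a2[pj]
  swapped <- st$effect_allele == v$a2[pj] & st$other_allele == v$a1[pj]
  keep_same <- !ambiguous & same
  keep_swap <- !ambiguous & swapped
  n_mismatch <- sum(!ambiguous & !same & !swapped)
  n_ambiguous <- sum(ambiguous)

  st$beta[keep_swap] <- -st$beta[keep_swap]
  st$effect_allele[keep_swap] <- v$a1[pj][keep_swap]
  st$other_allele[keep_swap] <- v$a2[pj][keep_swap]
  keep <- keep_same | keep_swap
  if (!any(keep))
    stop("no variant overlaps between the summary statistics and the panel")
  dropped <- c(unmatched = n_unmatched, ambiguous = n_ambiguous,
               mismatched = n_mismatch)
  if (sum(dropped) > 0)
    warning(sprintf(
      "harmonization dropped %d variant(s): %d unmatched, %d strand-ambiguous, %d allele-mismatched",
      sum(dropped), n_unmatched, n_ambiguous, n_mismatch))
  out_stats <- st[keep, , drop = FALSE]
  rownames(out_stats) <- NULL
  class(out_stats) <- c("summary_stats", "data.frame")
  list(stats = out_stats, index = pj[keep], dropped = dropped)
}

#' Standardize a dosage matrix
#'
#' Centers each column and scales it so its squared Euclidean norm is 1,
#' hence `diag(crossprod(X_std)) = 1` and, for any unit-norm vector `u`,
#' the entries of `crossprod(X_std, u)` are correlations in `[-1, 1]`.
#' Zero-variance columns cannot be standardized and are dropped with a
#' warning.
#'
#' @param X numeric matrix, samples in rows.
#' @return A list with `X_std`, `centers`, `scales` (the centered column
#'   norms) and `kept` (indices of retained columns).
#' @export
standardize_dosages <- function(X) {
  X <- as.matrix(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  scales <- sqrt(colSums(Xc^2))
  kept <- which(scales > 0)
  if (length(kept) == 0) stop("all columns are constant; nothing to standardize")
  if (length(kept) < ncol(X))
    warning(sprintf("dropped %d constant column(s)", ncol(X) - length(kept)))
  X_std <- sweep(Xc[, kept, drop = FALSE], 2, scales[kept], "/")
  list(X_std = X_std, centers = centers[kept], scales = scales[kept],
       kept = kept)
}

#' Convert a marginal GWAS effect size to a correlation
#'
#' A simple linear regression of the outcome on one standardized variant
#' relates the t-statistic \eqn{t = \beta/\mathrm{se}} to the Pearson
#' correlation by \eqn{r = t / \sqrt{n - 2 + t^2}}. This is an identity for
#' ordinary least squares, so applying it to the marginal effect and
#' standard error of each variant recovers exactly the per-variant
#' correlation with the outcome — the `r` vector the Lassosum objective
#' consumes in summary-statistics mode. The output is strictly inside
#' `(-1, 1)` for all finite inputs and odd in `beta`.
#'
#' @param beta marginal effect size(s).
#' @param se positive standard error(s).
#' @param n_gwas GWAS sample size (>= 3).
#' @return Correlation value(s) in `(-1, 1)`.
#' @export
beta_to_correlation <- function(beta, se, n_gwas) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("'se' must be positive")
  if (any(is.na(n_gwas)) || any(n_gwas < 3)) stop("'n_gwas' must be >= 3")
  t <- beta / se
  t / sqrt(n_gwas - 2 + t^2)
}
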