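make_stats_df <- function() {
  data.frame(
    chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 300L),
    effect_allele = c("A", "G", "C"),
    other_allele = c("C", "T", "T"),
    beta = c(0.3, -0.2, 0.05),
    se = c(0.1, 0.08, 0.02),
    pvalue = c(0.003, 0.01, 0.2),
    n_gwas = c(1000L, 1000L, 1000L),
    stringsAsFactors = FALSE
  )
}

test_that("summary statistics survive a write/read round trip", {
  df <- make_stats_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_summary_stats(path)
  expect_s3_class(st, "summary_stats")
  expect_equal(nrow(st), 3)
  expect_equal(st$beta, df$beta)
  expect_equal(st$pos, df$pos)

  # round trip through the package writer is the identity on typed fields
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(st, path2)
  st2 <- read_summary_stats(path2)
  expect_equal(as.data.frame(st2), as.data.frame(st))
})

test_that("invalid rows are dropped with a count and bad schemas error", {
  df <- make_stats_df()
  df$se[2] <- 0           # invalid standard error
  df$pvalue[3] <- 1.5     # invalid p-value
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(st <- read_summary_stats(path), "dropped 2")
  expect_equal(nrow(st), 1)

  # a renamed column is found through the column map ...
  df2 <- make_stats_df()
  names(df2)[names(df2) == "beta"] <- "Beta"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- c(chrom = "chrom", pos = "pos", effect_allele = "effect_allele",
            other_allele = "other_allele", beta = "Beta", se = "se",
            pvalue = "pvalue")
  expect_equal(read_summary_stats(path2, cmap)$beta, df2$Beta)
  # ... but a genuinely absent column is a schema error listing what exists
  expect_error(read_summary_stats(path2), "beta")
})

test_that("a hand-packed PLINK bed file decodes to the expected dosages", {
  prefix <- file.path(withr::local_tempdir(), "toy")
  # 4 samples x 3 variants, one byte per variant, sample 1 in the low bits;
  # codes: 00 = 2 copies of A1, 10 = 1, 11 = 0, 01 = missing
  # v1: (2,1,0,2) -> 0x38; v2: (0,0,1,1) -> 0xAF; v3: (1,NA,2,0) -> 0xC6
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0xaf, 0xc6)),
           paste0(prefix, ".bed"))
  writeLines(c("1\t1:100:A:C\t0\t100\tA\tC",
               "1\t1:200:G:T\t0\t200\tG\tT",
               "2\t2:300:C:T\t0\t300\tC\tT"), paste0(prefix, ".bim"))
  writeLines(sprintf("F%d\tS%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(prefix, ".fam"))

  panel <- read_genotypes(prefix)
  expected <- cbind(c(2, 1, 0, 2), c(0, 0, 1, 1), c(1, 1, 2, 0))
  expect_equal(unname(panel$dosages), expected)
  expect_equal(attr(panel, "n_imputed"), c(0L, 0L, 1L))  # mean of (1,2,0) = 1
  expect_equal(panel$sample_ids, sprintf("S%d", 1:4))
  expect_equal(panel$variants$pos, c(100L, 200L, 300L))

  # a wrong magic number is rejected
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x38)), paste0(prefix, "bad.bed"))
  file.copy(paste0(prefix, ".bim"), paste0(prefix, "bad.bim"))
  file.copy(paste0(prefix, ".fam"), paste0(prefix, "bad.fam"))
  expect_error(read_genotypes(paste0(prefix, "bad")), "magic")
})

test_that("bed and TSV encodings of one panel read back identically", {
  cfg <- simulation_config(n = 25, n_ref = 5, p = 12, seed = 50)
  panel <- simulate_genotypes(cfg)$panel
  dir <- withr::local_tempdir()
  write_genotypes(panel, file.path(dir, "x"), format = "bed")
  write_genotypes(panel, file.path(dir, "x.tsv"), format = "tsv")
  from_bed <- read_genotypes(file.path(dir, "x"))
  from_tsv <- read_genotypes(file.path(dir, "x.tsv"))
  expect_equal(from_bed$dosages, from_tsv$dosages)
  expect_equal(from_bed$variants$id, from_tsv$variants$id)
  expect_equal(unname(from_bed$dosages), unname(panel$dosages))
})

test_that("harmonization aligns, flips, drops and is idempotent", {
  panel <- genotype_panel(
    matrix(c(0, 1, 2, 1,  2, 2, 0, 1,  1, 0, 1, 2,  0, 1, 1, 0), 4, 4),
    variants = data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                          a1 = c("A", "G", "A", "C"),
                          a2 = c("C", "T", "T", "G"))
  )
  stats <- data.frame(
    chrom = "1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    effect_allele = c("A", "T", "A", "C", "G"),
    other_allele = c("C", "G", "T", "G", "A"),
    beta = c(0.5, 0.3, 0.2, 0.1, 0.7),
    se = rep(0.1, 5), pvalue = rep(0.01, 5), n_gwas = rep(500L, 5),
    stringsAsFactors = FALSE
  )
  class(stats) <- c("summary_stats", "data.frame")
  expect_warning(h <- harmonize(stats, panel), "dropped 3")
  # pos 100: same orientation, kept as is; pos 200: swapped, sign flipped;
  # pos 300 (A/T) and 400 (C/G) ambiguous; pos 500 unmatched
  expect_equal(h$index, c(1L, 2L))
  expect_equal(h$stats$beta, c(0.5, -0.3))
  expect_equal(h$dropped,
               c(unmatched = 1L, ambiguous = 2L, mismatched = 0L))

  # idempotence: re-harmonizing the aligned table changes nothing
  h2 <- harmonize(h$stats, panel)
  expect_equal(h2$stats, h$stats)
  expect_equal(h2$index, h$index)

  # an allele-set mismatch is dropped too
  stats_bad <- stats[1, ]
  stats_bad$effect_allele <- "G"; stats_bad$other_allele <- "T"
  class(stats_bad) <- c("summary_stats", "data.frame")
  expect_error(harmonize(stats_bad, panel), "no variant overlaps")
})

test_that("standardization hits the stated normalization exactly", {
  x <- c(0, 1, 2, 1)
  std <- standardize_dosages(matrix(x, 4, 1))
  expect_equal(drop(std$X_std), c(-1, 0, 1, 0) / sqrt(2))
  expect_equal(sum(std$X_std^2), 1)
  expect_equal(std$centers, 1)
  expect_equal(std$scales, sqrt(2))

  set.seed(51)
  X <- matrix(rnorm(60), 20, 3)
  std <- standardize_dosages(X)
  expect_lt(max(abs(colMeans(std$X_std))), 1e-12)
  expect_equal(unname(colSums(std$X_std^2)), rep(1, 3))
  # idempotence
  again <- standardize_dosages(std$X_std)
  expect_equal(again$X_std, std$X_std, tolerance = 1e-12)

  Xc <- cbind(X, 5)  # constant column dropped with a warning
  expect_warning(stdc <- standardize_dosages(Xc), "constant")
  expect_equal(stdc$kept, 1:3)
  expect_error(standardize_dosages(matrix(1, 5, 2)), "constant")
})

test_that("beta-to-correlation conversion is the t-statistic identity", {
  expect_equal(beta_to_correlation(0, 0.1, 100), 0)
  expect_equal(beta_to_correlation(0.2, 0.1, 6), 2 / sqrt(8))
  set.seed(52)
  b <- rnorm(100); se <- runif(100, 0.01, 1); n <- sample(3:50, 100, TRUE)
  r <- beta_to_correlation(b, se, n)
  expect_true(all(abs(r) < 1))
  expect_equal(beta_to_correlation(-b, se, n), -r)  # odd in beta

  # defining identity: recovers the empirical Pearson correlation from a
  # fitted simple regression
  set.seed(53)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  sm <- summary(lm(y ~ x))$coefficients
  expect_equal(beta_to_correlation(sm[2, 1], sm[2, 2], 40), cor(x, y),
               tolerance = 1e-6)
  expect_error(beta_to_correlation(1, 0, 10), "positive")
  expect_error(beta_to_correlation(1, 1, 2), "n_gwas")
})
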