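test_that("hard calls take the argmax probability, ties toward the smaller genotype", {
  expect_identical(hard_call(c(0.1, 0.2, 0.7), type = "probs"), 2L)
  expect_identical(hard_call(c(0.4, 0.4, 0.2), type = "probs"), 0L)
  probs <- rbind(c(0.9, 0.05, 0.05), c(0.2, 0.5, 0.3), c(0.3, 0.3, 0.4))
  expect_identical(hard_call(probs), c(0L, 1L, 2L))
  expect_error(hard_call(matrix(NA_real_, 2, 3)), "missing")

  # dosages: nearest integer, half-way down
  expect_identical(hard_call(c(0.1, 1.6, 2.0, 0.5, 1.5)),
                   c(0L, 2L, 2L, 0L, 1L))
  expect_identical(hard_call(NA_real_, type = "dosage"), NA_integer_)
})

test_that("genotype block recomputes CAF and validates its inputs", {
  dos <- cbind(c(0, 1, 2, NA), c(0.5, 0.5, 1.5, 1.5))
  gb <- genotype_block(c("v1", "v2"), c("1", "1"), c(100L, 200L),
                       c("A", "C"), c("G", "T"), dos, paste0("S", 1:4))
  expect_equal(gb$caf, c(mean(c(0, 1, 2)) / 2, 0.5), tolerance = 1e-12)
  expect_error(genotype_block("v", "1", 1L, "A", "G",
                              matrix(3, 2, 1), c("S1", "S2")), "\\[0, 2\\]")
  expect_error(genotype_block("v", "1", 1L, "A", "G",
                              matrix(1, 2, 1), c("S1", "S1")), "duplicate")
})

test_that("TSV genotype matrices round-trip through read_genotype_matrix", {
  dos <- cbind(c(0, 1, 2, 1), c(0.1, 1.0, 1.9, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_geno_tsv(path, dos, info = c(0.99, 0.85))
  gb <- read_genotype_matrix(path, "tsv")
  expect_equal(gb$dosages, dos, ignore_attr = TRUE)
  expect_equal(gb$info, c(0.99, 0.85))
  expect_equal(gb$caf, colMeans(dos) / 2, tolerance = 1e-12)
  expect_equal(gb$sample_ids, paste0("S", 1:4))
  expect_equal(gb$pos, c(1000L, 2000L))
})

test_that("VCF parsing prefers DS, falls back to GT, and flags missing calls", {
  skip_if_not_installed("VariantAnnotation")
  samples <- c("S1", "S2", "S3")
  body <- c(
    # DS present: dosage copied
    "1\t100\trs1\tA\tG\t.\tPASS\tINFO=0.97\tGT:DS\t0/0:0.1\t0/1:1.0\t1/1:1.9",
    # GT only: coded-allele count
    "1\t200\trs2\tC\tT\t.\tPASS\tINFO=0.95\tGT:DS\t0/0:.\t0/1:.\t1/1:.",
    # missing genotype excluded from the CAF denominator
    "1\t300\trs3\tG\tA\t.\tPASS\tINFO=0.99\tGT:DS\t./.:.\t0/1:.\t1/1:.")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, body, samples)
  gb <- read_genotype_matrix(path, "vcf")
  expect_equal(gb$dosages[, 1], c(0.1, 1.0, 1.9))
  expect_equal(gb$dosages[, 2], c(0, 1, 2))
  expect_true(is.na(gb$dosages[1, 3]))
  expect_equal(gb$caf[3], mean(c(1, 2)) / 2)
  expect_equal(gb$info, c(0.97, 0.95, 0.99))
  expect_equal(gb$noncoded_allele, c("A", "C", "G"))
  expect_equal(gb$coded_allele, c("G", "T", "A"))
  expect_equal(gb$pos, c(100L, 200L, 300L))
})

test_that("variant filters use strict boundaries and are idempotent", {
  n <- 200
  dos <- withr::with_seed(7, cbind(
    rbinom(n, 2, 0.005),   # caf ~ 0.005: fails MAF
    rbinom(n, 2, 0.05),    # passes both
    rbinom(n, 2, 0.30),    # fails info
    rbinom(n, 2, 0.40)))   # boundary cases handled below
  # force exact boundary CAF = 0.01 on the last variant: 4 alleles in 200
  dos[, 4] <- c(rep(1, 4), rep(0, n - 4))
  gb <- genotype_block(paste0("v", 1:4), "2", 1:4 * 10L, rep("A", 4),
                       rep("G", 4), dos, paste0("S", seq_len(n)),
                       info = c(0.95, 0.95, 0.90, 0.95))
  kept <- apply_variant_filters(gb, maf_min = 0.01, info_min = 0.9)
  expect_equal(kept$variant_ids, "v2")       # v3 info == 0.9 is excluded
  expect_equal(kept$caf, colMeans(dos[, 2, drop = FALSE]) / 2,
               tolerance = 1e-12)
  # idempotence
  again <- apply_variant_filters(kept, maf_min = 0.01, info_min = 0.9)
  expect_identical(again$variant_ids, kept$variant_ids)
  expect_identical(again$dosages, kept$dosages)
  # variants without info pass the info filter
  gb2 <- genotype_block("v", "1", 1L, "A", "G",
                        matrix(rbinom(n, 2, 0.3), ncol = 1),
                        paste0("S", seq_len(n)))
  expect_equal(length(apply_variant_filters(gb2)$variant_ids), 1L)
})

test_that("blood-pressure preparation applies the medication adjustment then log-PP", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   sbp_1 = c(120, 118, 140), sbp_2 = c(120, 122, NA),
                   dbp_1 = c(80, 78, 90), dbp_2 = c(80, 82, NA),
                   medication = c(TRUE, FALSE, TRUE),
                   bmi = c(25, 27, 30))
  tab <- phenotype_table(df)
  sbp <- prepare_bp_traits(tab, "SBP")
  dbp <- prepare_bp_traits(tab, "DBP")
  pp <- prepare_bp_traits(tab, "PP")
  # medicated: +15 (SBP) and +10 (DBP) mm Hg; unmedicated untouched
  expect_equal(sbp$values, c(135, 120, 155))
  expect_equal(dbp$values, c(90, 80, 100))
  # PP = adjusted SBP - adjusted DBP, natural log
  expect_equal(pp$values, log(c(45, 40, 55)))
  expect_true(pp$transform_log)
  expect_false(sbp$transform_log)
  # degenerate PP errors
  df$dbp_1 <- df$dbp_2 <- c(150, 78, 90)
  expect_error(prepare_bp_traits(phenotype_table(df), "PP"),
               "non-positive")
})

test_that("sample filters drop missingness first, then 5-SD outliers in one pass", {
  n <- 101
  trait_vals <- c(rnorm_vals <- withr::with_seed(5, rnorm(n - 1, 140, 15)),
                  NA)
  df <- data.frame(sample_id = paste0("S", seq_len(n)),
                   sex = rep(0:1, length.out = n),
                   bmi = withr::with_seed(6, rnorm(n, 27, 4)))
  df$bmi[3] <- NA
  tab <- phenotype_table(df)
  tv <- trait_vector(trait_vals, "generic")

  # oracle: complete cases, then one-pass z-screen on trait and BMI
  keep1 <- !is.na(trait_vals) & !is.na(df$bmi)
  z_t <- abs(scale(trait_vals[keep1]))
  z_b <- abs(scale(df$bmi[keep1]))
  oracle <- which(keep1)[z_t < 5 & z_b < 5]
  expect_identical(apply_sample_filters(tab, tv), oracle)

  # boundary: plant a value exactly 5 SD out (of the filtered mean/SD)
  vals <- trait_vals
  keep <- keep1
  m <- mean(vals[keep]); s <- sd(vals[keep])
  # iterate once: appending x changes mean/SD, so solve numerically
  f <- function(x) {
    v <- c(vals[keep], x)
    (x - mean(v)) / sd(v) - 5
  }
  x5 <- uniroot(f, c(m + 4 * s, m + 40 * s))$root
  df2 <- rbind(df, data.frame(sample_id = "S999", sex = 0, bmi = 27))
  tv2 <- trait_vector(c(vals, x5), "generic")
  idx <- apply_sample_filters(phenotype_table(df2), tv2)
  expect_false(nrow(df2) %in% idx)            # z = 5 exactly: excluded
  tv3 <- trait_vector(c(vals, x5 * 0.999), "generic")
  idx3 <- apply_sample_filters(phenotype_table(df2), tv3)
  expect_true(nrow(df2) %in% idx3)            # just under 5 SD: retained
})

test_that("scan results write a fixed header and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- vqtlscan:::empty_scan_records()
  write_scan_results(empty, path)
  expect_length(readLines(path), 1L)
  expect_equal(strsplit(readLines(path), "\t")[[1]],
               vqtlscan:::scan_record_columns)

  row <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
                    NCA = "A", CA = "G", CAF = 0.31234567, n = 1000L,
                    beta_main = -0.4084, se_main = 0.0417,
                    p_main = 1.1e-22, r2_main = 2.43e-4,
                    tau1 = 340.2, tau2 = 0.51, tau3 = 1.02,
                    lrt_het = 30.55, p_het = 2.75e-8, r2_het = 8.5e-5,
                    method = "vc", converged = TRUE, n_iter = 6L)
  write_scan_results(row, path)
  expect_length(readLines(path), 2L)
  back <- read_scan_results(path)
  expect_equal(back$beta_main, row$beta_main, tolerance = 1e-12)
  expect_equal(back$p_het, row$p_het, tolerance = 1e-12)
  expect_equal(back$method, "vc")
  expect_error(write_scan_results(row[, -1], path), "missing columns")
})
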