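# Shared fixture builders. Everything is generated in code at test time;
# no binary data ships with the package.

# residuals with genotype-dependent variance v(g) = tau1 + 2 tau2 g + tau3 g^2
make_het_resid <- function(n, tau = c(1, 0, 0.5), maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    g <- rbinom(n, 2, maf)
    v <- tau[1] + 2 * tau[2] * g + tau[3] * g^2
    residual_set(rnorm(n, 0, sqrt(v)), g)
  })
}

# the saturated worked example: squared residuals {1,3}/{2,6}/{4,12} by genotype
saturated_example <- function() {
  residual_set(sqrt(c(1, 3, 2, 6, 4, 12)), c(0, 0, 1, 1, 2, 2))
}

# genotype TSV fixture (variants x samples)
write_geno_tsv <- function(path, dosages, ids = NULL, info = NULL,
                           chrom = "1") {
  m <- ncol(dosages)
  n <- nrow(dosages)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  tab <- data.frame(id = paste0("rs", seq_len(m)),
                    chrom = rep(chrom, m),
                    pos = 1000L * seq_len(m),
                    NCA = rep("A", m), CA = rep("G", m))
  if (!is.null(info)) tab$info <- info
  geno <- as.data.frame(t(dosages))
  names(geno) <- ids
  utils::write.table(cbind(tab, geno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# minimal plain-text VCF fixture
write_vcf_fixture <- function(path, body, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# phenotype data frame with two SBP/DBP measurements and covariates
make_pheno_df <- function(n, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      sample_id = paste0("S", seq_len(n)),
      sbp_1 = rnorm(n, 138, 18), sbp_2 = rnorm(n, 138, 18),
      dbp_1 = rnorm(n, 82, 10), dbp_2 = rnorm(n, 82, 10),
      medication = rbinom(n, 1, 0.2) == 1,
      sex = rbinom(n, 1, 0.46),
      age = runif(n, 40, 69),
      bmi = rnorm(n, 27, 4.8),
      pc1 = rnorm(n), pc2 = rnorm(n))
  })
}

# small generic-trait scan fixture: `m` null variants plus one vQTL
make_scan_fixture <- function(n = 4000, seed = 11, sigma2 = 1) {
  withr::with_seed(seed, {
    g_null1 <- rbinom(n, 2, 0.25)
    g_null2 <- rbinom(n, 2, 0.40)
    g_vqtl <- rbinom(n, 2, 0.30)
    x1 <- rnorm(n)
    b <- rnorm(n, -0.3, sqrt(sigma2))
    y <- 2 + 0.5 * x1 + 0.2 * g_null1 + b * g_vqtl + rnorm(n)
    dos <- cbind(g_null1, g_vqtl, g_null2)
    dimnames(dos) <- NULL
    list(dosages = dos, vqtl_index = 2L,
         pheno = data.frame(sample_id = paste0("S", seq_len(n)),
                            trait = y, x1 = x1))
  })
}
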