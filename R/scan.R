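#' Scan configuration
#'
#' @param method Heteroscedasticity test(s): `"lmm"`, `"vc"`, `"ols"`,
#'   `"chi2"`, `"levene"` or `"all"`. The variance-component model is the
#'   default primary analysis (same power as the mixed model at a fraction
#'   of the cost).
#' @param maf_min,info_min Variant filters (exclusive bounds), see
#'   [apply_variant_filters].
#' @param alpha_gw Genome-wide significance level (strict `p < alpha_gw`).
#' @param trait Trait name: `"SBP"`, `"DBP"`, `"PP"` (prepared via
#'   [prepare_bp_traits]) or the name of a column in the phenotype table.
#' @param covariates Covariate column names (default: the phenotype
#'   table's covariate set).
#' @param out Optional output TSV path (written via [write_scan_results]).
#' @param threads Number of worker processes for the per-variant loop
#'   (results are emitted in input order regardless).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(method = "vc", maf_min = 0.01, info_min = 0.9,
                        alpha_gw = 5e-8, trait = "SBP", covariates = NULL,
                        out = NULL, threads = 1L) {
  method <- match.arg(method,
                      c("vc", "lmm", "ols", "chi2", "levene", "all"))
  stopifnot(alpha_gw > 0, alpha_gw < 1, threads >= 1L)
  structure(list(method = method, maf_min = maf_min, info_min = info_min,
                 alpha_gw = alpha_gw, trait = trait,
                 covariates = covariates, out = out,
                 threads = as.integer(threads)),
            class = "scan_config")
}

scan_methods <- function(method) {
  if (method == "all") c("lmm", "vc", "ols", "chi2", "levene") else method
}

# dispatch one heteroscedasticity test on prepared inputs
run_het_test <- function(method, rs, y = NULL, X = NULL, start = NULL) {
  switch(method,
         ols = fit_ols_squared(rs),
         chi2 = fit_chisq_regression(rs, start = start),
         vc = fit_variance_component(rs, start = start),
         lmm = fit_lmm(y, X, rs$genotype, start = start)$het,
         levene = levene_bf(rs),
         stop("unknown method: ", method))
}

#' Genome-wide vQTL scan
#'
#' Driver for the per-variant analysis: aligns samples between genotype and
#' phenotype data, prepares the trait, applies sample and variant filters,
#' and for each passing variant fits the mean model (covariates + additive
#' genotype), extracts residuals and runs the requested heteroscedasticity
#' test(s). Monomorphic or otherwise degenerate variants are skipped with a
#' logged reason rather than aborting the scan. The scan is deterministic:
#' re-running with the same inputs and configuration reproduces the records
#' bit for bit.
#'
#' @param geno A [genotype_block].
#' @param pheno A [phenotype_table].
#' @param config A [scan_config].
#' @return A data frame of scan records with the columns written by
#'   [write_scan_results] (one row per variant per method); skipped
#'   variants and reasons are available in `attr(, "skipped")`.
#' @export
run_scan <- function(geno, pheno, config = scan_config()) {
  stopifnot(inherits(geno, "genotype_block"),
            inherits(pheno, "phenotype_table"),
            inherits(config, "scan_config"))
  common <- intersect(geno$sample_ids, pheno$sample_ids)
  if (!length(common)) stop("no overlapping samples")
  covariates <- config$covariates
  if (is.null(covariates)) covariates <- pheno$covariates
  # trait preparation
  if (config$trait %in% c("SBP", "DBP", "PP")) {
    tv <- prepare_bp_traits(pheno, config$trait)
  } else {
    if (!config$trait %in% names(pheno$data))
      stop("trait column not found: ", config$trait)
    tv <- trait_vector(pheno$data[[config$trait]], "generic",
                       sample_ids = pheno$sample_ids)
  }
  ptab <- phenotype_table(pheno$data, covariates = covariates)
  keep_rows <- apply_sample_filters(ptab, tv)
  kept_ids <- pheno$sample_ids[keep_rows]
  use_ids <- intersect(geno$sample_ids, kept_ids)   # genotype order
  prow <- keep_rows[match(use_ids, kept_ids)]
  grow <- match(use_ids, geno$sample_ids)
  y_all <- tv$values[prow]
  X_all <- cbind(intercept = 1,
                 as.matrix(pheno$data[prow, covariates, drop = FALSE]))
  storage.mode(X_all) <- "double"

  gb <- apply_variant_filters(geno, config$maf_min, config$info_min)
  if (!length(gb$variant_ids)) stop("no variants pass the filters")
  methods <- scan_methods(config$method)

  one_variant <- function(j) {
    g <- gb$dosages[grow, j]
    cc <- !is.na(g)
    g <- g[cc]
    if (length(g) < length(methods) + 5L || stats::sd(g) == 0)
      return(list(skip = sprintf("%s: monomorphic or too few samples",
                                 gb$variant_ids[j])))
    y <- y_all[cc]
    X <- X_all[cc, , drop = FALSE]
    mm <- tryCatch(fit_mean_model(y, X, g), error = function(e)
      conditionMessage(e))
    if (is.character(mm))
      return(list(skip = paste0(gb$variant_ids[j], ": ", mm)))
    if (mm$main$degenerate)
      return(list(skip = sprintf("%s: degenerate zero-residual fit",
                                 gb$variant_ids[j])))
    rs <- mm$resid
    start <- tryCatch(fit_ols_squared(rs)$tau, error = function(e) NULL)
    if (is.null(start))
      return(list(skip = sprintf("%s: fewer than 3 genotype values",
                                 gb$variant_ids[j])))
    rows <- lapply(methods, function(m) {
      ht <- tryCatch(run_het_test(m, rs, y = y, X = X, start = start),
                     error = function(e) NULL)
      if (is.null(ht)) return(NULL)
      tau <- if (is.null(ht$tau)) c(NA_real_, NA_real_, NA_real_)
             else as_tau3(ht$tau)
      data.frame(variant_id = gb$variant_ids[j], chrom = gb$chrom[j],
                 pos = gb$pos[j], NCA = gb$noncoded_allele[j],
                 CA = gb$coded_allele[j],
                 CAF = mean(g) / 2, n = length(g),
                 beta_main = mm$main$beta_g, se_main = mm$main$se,
                 p_main = mm$main$p_main, r2_main = mm$main$r2_main,
                 tau1 = tau[1L], tau2 = tau[2L], tau3 = tau[3L],
                 lrt_het = ht$lrt, p_het = ht$p_het, r2_het = ht$r2_het,
                 method = m, converged = isTRUE(ht$converged),
                 n_iter = ht$n_iter,
                 stringsAsFactors = FALSE)
    })
    list(rows = do.call(rbind, rows))
  }

  jidx <- seq_along(gb$variant_ids)
  res <- if (config$threads > 1L &&
             requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(jidx, one_variant, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(jidx, one_variant)
  }
  skipped <- unlist(lapply(res, function(r) r$skip))
  for (s in skipped) message("skipping variant ", s)
  records <- do.call(rbind, lapply(res, function(r) r$rows))
  if (is.null(records))
    records <- empty_scan_records()
  rownames(records) <- NULL
  attr(records, "skipped") <- skipped
  attr(records, "alpha_gw") <- config$alpha_gw
  if (!is.null(config$out)) write_scan_results(records, config$out)
  records
}

scan_record_columns <- c("variant_id", "chrom", "pos", "NCA", "CA", "CAF",
                         "n", "beta_main", "se_main", "p_main", "r2_main",
                         "tau1", "tau2", "tau3", "lrt_het", "p_het",
                         "r2_het", "method", "converged", "n_iter")

empty_scan_records <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(scan_record_columns)),
    scan_record_columns))
  df
}

#' Write scan records to TSV
#'
#' Tab-separated output with one row per variant per method and the fixed
#' column set `variant_id, chrom, pos, NCA, CA, CAF, n, beta_main, se_main,
#' p_main, r2_main, tau1, tau2, tau3, lrt_het, p_het, r2_het, method,
#' converged, n_iter`.
#'
#' @param rows Data frame of scan records (as returned by [run_scan]).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_scan_results <- function(rows, path) {
  rows <- as.data.frame(rows)
  missing_cols <- setdiff(scan_record_columns, names(rows))
  if (length(missing_cols))
    stop("scan records missing columns: ",
         paste(missing_cols, collapse = ", "))
  utils::write.table(rows[, scan_record_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read scan records back from TSV
#'
#' @param path Path written by [write_scan_results].
#' @return Data frame of scan records.
#' @export
read_scan_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Quantile-quantile coordinates for p-values
#'
#' Sorted observed p-values on a negative log10 scale against their
#' expected uniform-order-statistic quantiles `-log10((i - 0.5) / m)`.
#'
#' @param pvals P-values in `(0, 1]`.
#' @return Data frame with columns `expected` and `observed` (both
#'   `-log10`), ordered by increasing significance.
#' @export
qq_points <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  expected <- (seq_len(m) - 0.5) / m
  data.frame(expected = -log10(expected),
             observed = -log10(sort(pvals)))
}
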