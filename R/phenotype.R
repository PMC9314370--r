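#' Phenotype and covariate table
#'
#' Row-aligned phenotype container: sample IDs, raw blood-pressure
#' measurements (any columns whose names start with `sbp` or `dbp` are
#' treated as repeated measurements of SBP/DBP, in mm Hg), an
#' antihypertensive-medication flag, and covariates (typically sex, age,
#' age squared, BMI and principal components).
#'
#' @param df Data frame with a `sample_id` column.
#' @param covariates Character vector naming the covariate columns. If
#'   `NULL`, every column that is not `sample_id`, a trait measurement
#'   (`sbp*`, `dbp*`, or a declared generic trait) or `medication` is
#'   treated as a covariate.
#' @param medication_col Name of the logical/0-1 medication flag column
#'   (optional; absent means unmedicated).
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(df, covariates = NULL,
                            medication_col = "medication") {
  df <- as.data.frame(df)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs")
  sbp_cols <- grep("^sbp", names(df), ignore.case = TRUE, value = TRUE)
  dbp_cols <- grep("^dbp", names(df), ignore.case = TRUE, value = TRUE)
  med <- if (medication_col %in% names(df)) as.logical(df[[medication_col]])
         else rep(FALSE, nrow(df))
  if (is.null(covariates))
    covariates <- setdiff(names(df),
                          c("sample_id", sbp_cols, dbp_cols, medication_col))
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate columns not found: ", paste(missing_cov, collapse = ", "))
  structure(list(data = df,
                 sample_ids = as.character(df$sample_id),
                 sbp_cols = sbp_cols, dbp_cols = dbp_cols,
                 medication = med, covariates = covariates),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples; SBP cols: %s; DBP cols: %s\n",
              nrow(x$data),
              if (length(x$sbp_cols)) paste(x$sbp_cols, collapse = ",") else "-",
              if (length(x$dbp_cols)) paste(x$dbp_cols, collapse = ",") else "-"))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Read a phenotype/covariate TSV
#'
#' Tab-separated file with a header containing `sample_id`; see
#' [phenotype_table] for the column conventions.
#'
#' @inheritParams phenotype_table
#' @param path Path to the TSV file.
#' @return A [phenotype_table].
#' @export
read_phenotype_table <- function(path, covariates = NULL,
                                 medication_col = "medication") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  phenotype_table(tab, covariates = covariates,
                  medication_col = medication_col)
}

#' Prepared trait vector
#'
#' @param values Numeric trait values.
#' @param trait_name One of `"SBP"`, `"DBP"`, `"PP"`, `"generic"`.
#' @param transform_log Was a log transform applied?
#' @param sample_ids Optional sample IDs aligned to `values`.
#' @return An object of class `trait_vector`.
#' @export
trait_vector <- function(values, trait_name = "generic",
                         transform_log = FALSE, sample_ids = NULL) {
  trait_name <- match.arg(trait_name, c("SBP", "DBP", "PP", "generic"))
  structure(list(values = as.numeric(values), trait_name = trait_name,
                 transform_log = isTRUE(transform_log),
                 n = length(values), sample_ids = sample_ids),
            class = "trait_vector")
}

trait_values <- function(y) {
  if (inherits(y, "trait_vector")) y$values else as.numeric(y)
}

#' Prepare blood-pressure traits
#'
#' SBP and DBP are averaged over the available repeated measurements, then
#' adjusted for antihypertensive medication use by adding 15 mm Hg (SBP) or
#' 10 mm Hg (DBP) for medicated samples. Pulse pressure (PP) is the
#' difference of the adjusted SBP and DBP, transformed by the natural
#' logarithm (PP is right-skewed; the medication adjustment is applied
#' before the subtraction, a net +5 mm Hg).
#'
#' @param table A [phenotype_table].
#' @param trait `"SBP"`, `"DBP"` or `"PP"`.
#' @return A [trait_vector] aligned to the table rows (missing measurements
#'   stay `NA` and are removed later by [apply_sample_filters]).
#' @export
prepare_bp_traits <- function(table, trait = c("SBP", "DBP", "PP")) {
  stopifnot(inherits(table, "phenotype_table"))
  trait <- match.arg(trait)
  med <- table$medication
  mean_cols <- function(cols, label) {
    if (!length(cols)) stop("no ", label, " measurement columns present")
    m <- as.matrix(table$data[, cols, drop = FALSE])
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  if (trait %in% c("SBP", "PP"))
    sbp <- mean_cols(table$sbp_cols, "SBP") + 15 * med
  if (trait %in% c("DBP", "PP"))
    dbp <- mean_cols(table$dbp_cols, "DBP") + 10 * med
  if (trait == "SBP")
    return(trait_vector(sbp, "SBP", FALSE, table$sample_ids))
  if (trait == "DBP")
    return(trait_vector(dbp, "DBP", FALSE, table$sample_ids))
  pp <- sbp - dbp
  if (any(pp <= 0, na.rm = TRUE))
    stop("non-positive pulse pressure before log transform")
  trait_vector(log(pp), "PP", TRUE, table$sample_ids)
}

#' Sample filters: missingness and 5-SD outliers
#'
#' Drops samples with any missing trait or covariate value, then, in a
#' single pass over the remaining samples, drops those whose trait value or
#' BMI lies 5 or more sample standard deviations from the sample mean (the
#' mean and SD are computed once on the missingness-filtered samples, not
#' iteratively).
#'
#' @param table A [phenotype_table].
#' @param traits A [trait_vector] or list of them, aligned to the table.
#' @param sd_limit Outlier threshold in SD units (inclusive; default 5).
#' @return Integer vector of retained row indices into the table.
#' @export
apply_sample_filters <- function(table, traits, sd_limit = 5) {
  stopifnot(inherits(table, "phenotype_table"))
  if (inherits(traits, "trait_vector")) traits <- list(traits)
  n <- nrow(table$data)
  tmat <- vapply(traits, function(t) {
    stopifnot(inherits(t, "trait_vector"))
    if (t$n != n) stop("trait not aligned to the phenotype table")
    t$values
  }, numeric(n))
  if (is.null(dim(tmat))) tmat <- matrix(tmat, nrow = n)
  cov <- as.matrix(table$data[, table$covariates, drop = FALSE])
  keep <- stats::complete.cases(tmat) & stats::complete.cases(cov)
  if (!any(keep)) stop("all samples removed by missingness filter")
  # outlier screen: each prepared trait plus BMI when present
  screen <- tmat[keep, , drop = FALSE]
  bmi_col <- grep("^bmi$", table$covariates, ignore.case = TRUE, value = TRUE)
  if (length(bmi_col))
    screen <- cbind(screen, cov[keep, bmi_col[1L]])
  ok <- rep(TRUE, sum(keep))
  for (j in seq_len(ncol(screen))) {
    x <- screen[, j]
    s <- stats::sd(x)
    if (s > 0) ok <- ok & (abs(x - mean(x)) < sd_limit * s)
  }
  idx <- which(keep)[ok]
  if (!length(idx)) stop("all samples removed by outlier filter")
  idx
}
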