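#' Genotype block container
#'
#' Per-variant dosages with metadata for a set of samples. Dosages are
#' expected coded-allele counts in `[0, 2]` (missing allowed); the coded
#' allele frequency (CAF) is always recomputed from the non-missing dosages.
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param chrom Chromosome per variant.
#' @param pos 1-based position per variant (as in VCF).
#' @param noncoded_allele,coded_allele Allele strings; the coded allele is
#'   the one counted by the dosage.
#' @param dosages Numeric matrix, samples x variants, entries in `[0, 2]`
#'   or `NA`.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param hard_calls Optional integer matrix in `{0, 1, 2}`, samples x
#'   variants.
#' @param info Optional imputation information score per variant, in
#'   `[0, 1]` (taken from input metadata, never recomputed).
#' @return An object of class `genotype_block`.
#' @export
genotype_block <- function(variant_ids, chrom, pos, noncoded_allele,
                           coded_allele, dosages, sample_ids,
                           hard_calls = NULL, info = NULL) {
  dosages <- as.matrix(dosages)
  m <- length(variant_ids)
  n <- length(sample_ids)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (length(noncoded_allele) == 1L) noncoded_allele <- rep(noncoded_allele, m)
  if (length(coded_allele) == 1L) coded_allele <- rep(coded_allele, m)
  stopifnot(ncol(dosages) == m, nrow(dosages) == n,
            length(chrom) == m, length(pos) == m,
            length(noncoded_allele) == m, length(coded_allele) == m)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stop("dosages must lie in [0, 2] (or be NA)")
  if (is.null(info)) info <- rep(NA_real_, m)
  caf <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(variant_ids = as.character(variant_ids),
                 chrom = as.character(chrom),
                 pos = as.integer(pos),
                 noncoded_allele = as.character(noncoded_allele),
                 coded_allele = as.character(coded_allele),
                 dosages = dosages,
                 hard_calls = hard_calls,
                 caf = unname(caf),
                 info = as.numeric(info),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  cat(sprintf("genotype_block: %d variants x %d samples\n",
              length(x$variant_ids), length(x$sample_ids)))
  cat(sprintf("  CAF range: %.4g - %.4g; info %s\n",
              min(x$caf), max(x$caf),
              if (all(is.na(x$info))) "absent" else "present"))
  invisible(x)
}

#' @export
`[.genotype_block` <- function(x, i) {
  genotype_block(x$variant_ids[i], x$chrom[i], x$pos[i],
                 x$noncoded_allele[i], x$coded_allele[i],
                 x$dosages[, i, drop = FALSE], x$sample_ids,
                 hard_calls = if (!is.null(x$hard_calls))
                   x$hard_calls[, i, drop = FALSE],
                 info = x$info[i])
}

#' Read a genotype matrix from VCF or TSV
#'
#' For VCF (4.x, plain text or compressed; parsed by the Bioconductor
#' `VariantAnnotation` package), the per-sample dosage is the `DS` FORMAT
#' field when present, otherwise the coded-allele count derived from `GT`;
#' missing genotypes (`./.`) become `NA` and are excluded from the CAF
#' denominator. Only biallelic records are supported; the coded allele is
#' the ALT allele. An imputation info score is looked up among the INFO
#' keys `INFO`, `R2`, `DR2`, `INFO_SCORE` if present.
#'
#' For TSV, the file is variants x samples: a header row whose first five
#' columns are `id`, `chrom`, `pos`, `NCA`, `CA` (optionally followed by an
#' `info` column), then one column per sample ID holding dosages.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` or `"tsv"`.
#' @return A [genotype_block].
#' @export
read_genotype_matrix <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") read_genotype_tsv(path) else read_genotype_vcf(path)
}

read_genotype_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  need <- c("id", "chrom", "pos", "NCA", "CA")
  if (!identical(names(tab)[1:5], need))
    stop("TSV genotype matrix must start with columns: ",
         paste(need, collapse = ", "))
  first_sample <- 6L
  info <- NULL
  if (ncol(tab) >= 6L && names(tab)[6L] == "info") {
    info <- as.numeric(tab[[6L]])
    first_sample <- 7L
  }
  if (ncol(tab) < first_sample) stop("no sample columns in TSV genotype file")
  sample_ids <- names(tab)[first_sample:ncol(tab)]
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  dos <- t(as.matrix(tab[, first_sample:ncol(tab), drop = FALSE]))
  storage.mode(dos) <- "double"
  dimnames(dos) <- NULL
  genotype_block(tab$id, tab$chrom, tab$pos, tab$NCA, tab$CA, dos,
                 sample_ids, info = info)
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L))
    stop("multiallelic VCF records are not supported; split them first")
  gen <- VariantAnnotation::geno(vcf)
  dos <- NULL
  if ("DS" %in% names(gen)) {
    dos <- t(gen$DS)               # readVcf: variants x samples
    storage.mode(dos) <- "double"
  }
  if ("GT" %in% names(gen)) {
    gt <- t(gen$GT)
    from_gt <- matrix(gt_to_dosage(gt), nrow = nrow(gt))
    if (is.null(dos)) {
      dos <- from_gt
    } else if (anyNA(dos)) {       # records without DS fall back to GT
      miss <- is.na(dos)
      dos[miss] <- from_gt[miss]
    }
  }
  if (is.null(dos)) stop("no parsable genotype field (need DS or GT)")
  dimnames(dos) <- NULL
  sample_ids <- colnames(vcf)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  info_df <- VariantAnnotation::info(vcf)
  key <- intersect(c("INFO", "R2", "DR2", "INFO_SCORE"), names(info_df))
  info <- if (length(key)) as.numeric(info_df[[key[1L]]]) else NULL
  genotype_block(names(rr),
                 as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr),
                 as.character(VariantAnnotation::ref(vcf)),
                 as.character(unlist(alt)),
                 dos, sample_ids, info = info)
}

# "0/1", "0|1", "./." -> coded-allele count or NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  out <- (a1 == "1") + (a2 == "1")
  out[a1 == "." | a2 == "."] <- NA_real_
  as.numeric(out)
}

#' Hard-call genotypes from dosages or genotype probabilities
#'
#' With genotype probabilities (a matrix with columns for genotypes 0, 1,
#' 2), returns the genotype with the largest probability; ties are broken
#' toward the smaller genotype so calls are deterministic. With dosages,
#' returns the nearest integer (half-way dosages also go to the smaller
#' genotype).
#'
#' @param x Numeric dosage vector, or an `n x 3` matrix of genotype
#'   probabilities (a bare length-3 vector of values in `[0, 1]` summing to
#'   1 is also treated as one sample's probabilities under `type = "auto"`).
#' @param type `"auto"`, `"dosage"` or `"probs"`.
#' @return Integer vector of hard calls in `{0, 1, 2}` (`NA` preserved).
#' @examples
#' hard_call(c(0.1, 0.2, 0.7), type = "probs")  # 2
#' hard_call(1.6)                               # 2
#' @export
hard_call <- function(x, type = c("auto", "dosage", "probs")) {
  type <- match.arg(type)
  if (type == "auto") {
    type <- if (is.matrix(x)) "probs"
    else if (length(x) == 3L && all(!is.na(x)) && all(x >= 0 & x <= 1) &&
             abs(sum(x) - 1) < 1e-6) "probs"
    else "dosage"
  }
  if (type == "probs") {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    if (ncol(x) != 3L) stop("genotype probabilities need 3 columns")
    out <- rep(NA_integer_, nrow(x))
    ok <- stats::complete.cases(x)
    if (!any(ok)) stop("all probabilities missing")
    out[ok] <- max.col(x[ok, , drop = FALSE], ties.method = "first") - 1L
    out
  } else {
    if (any(x < -1e-9 | x > 2 + 1e-9, na.rm = TRUE))
      stop("dosages must lie in [0, 2]")
    as.integer(ceiling(x - 0.5))
  }
}

#' Variant filters on allele frequency and imputation quality
#'
#' Keeps variants with minor allele frequency strictly above `maf_min` and
#' info score strictly above `info_min` (the boundaries are excluded).
#' Variants without an info score pass the info filter; set
#' `info_min = 0` to disable it entirely.
#'
#' @param block A [genotype_block].
#' @param maf_min Minimum (exclusive) minor allele frequency.
#' @param info_min Minimum (exclusive) info score.
#' @return The filtered [genotype_block] (possibly with zero variants).
#' @export
apply_variant_filters <- function(block, maf_min = 0.01, info_min = 0.9) {
  stopifnot(inherits(block, "genotype_block"))
  maf <- pmin(block$caf, 1 - block$caf)
  keep <- maf > maf_min & (is.na(block$info) | block$info > info_min)
  block[which(keep)]
}
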