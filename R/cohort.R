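#' Case-control cohort container
#'
#' Bundles an annotated variant table, an allele-dosage matrix (variants x
#' individuals, entries 0/1/2 or `NA` for missing genotypes) and a
#' dichotomous phenotype. Per-variant allele counts are derived from column
#' sums split by phenotype; missing genotypes are excluded from both the
#' allele count and the chromosome count of their cohort.
#'
#' @param variants annotation data frame (one row per variant; must include
#'   a `gene` column to be scoreable by gene-level tests).
#' @param genotypes integer matrix, `nrow(variants)` rows; column names are
#'   sample ids.
#' @param phenotype character/factor of `"case"` / `"control"` per
#'   individual (length `ncol(genotypes)`).
#' @return object of class `cc_cohort`.
#' @export
case_control_cohort <- function(variants, genotypes, phenotype) {
  genotypes <- as.matrix(genotypes)
  phenotype <- as.character(phenotype)
  if (nrow(variants) != nrow(genotypes))
    stop("variants and genotypes disagree on the number of variants",
         call. = FALSE)
  if (length(phenotype) != ncol(genotypes))
    stop("phenotype length must equal the number of individuals",
         call. = FALSE)
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype values must be 'case' or 'control'", call. = FALSE)
  if (any(!is.na(genotypes) & !(genotypes %in% 0:2)))
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  structure(list(variants = variants, genotypes = genotypes,
                 phenotype = phenotype),
            class = "cc_cohort")
}

#' @exportS3Method base::print
print.cc_cohort <- function(x, ...) {
  cat(sprintf("case-control cohort: %d variant(s) x %d individuals (%d cases, %d controls)\n",
              nrow(x$variants), ncol(x$genotypes),
              sum(x$phenotype == "case"), sum(x$phenotype == "control")))
  invisible(x)
}

#' Per-variant allele counts split by phenotype
#'
#' @param cohort a `cc_cohort`.
#' @param rows optional row indices restricting to a subset of variants.
#' @return data frame with `x_case`, `n_case`, `x_bg`, `n_bg` per variant;
#'   chromosome counts are `2 *` the number of non-missing genotypes in the
#'   cohort.
#' @export
allele_counts <- function(cohort, rows = NULL) {
  g <- cohort$genotypes
  if (!is.null(rows)) g <- g[rows, , drop = FALSE]
  case <- cohort$phenotype == "case"
  gc <- g[, case, drop = FALSE]
  gb <- g[, !case, drop = FALSE]
  data.frame(
    x_case = rowSums(gc, na.rm = TRUE),
    n_case = 2L * rowSums(!is.na(gc)),
    x_bg = rowSums(gb, na.rm = TRUE),
    n_bg = 2L * rowSums(!is.na(gb)))
}

#' Read a case-control cohort from VCF + phenotype table
#'
#' Genotypes are read with \pkg{vcfR} and converted to allele dosages
#' (biallelic records; multi-allelic records are skipped with a message).
#' The phenotype file is tab-separated with columns `sample` and `status`
#' (`case`/`control`); samples present in the VCF but absent from the
#' phenotype file are dropped.
#'
#' @param vcf_path VCF 4.x file (plain or bgzipped).
#' @param phenotype_path tab-separated sample/status table.
#' @param annotation optional annotation data frame (from
#'   [annotate_variants()] or [read_annotation()]) to use as the variant
#'   table; matched to VCF records by `chrom`, `pos`, `ref`, `alt`.
#' @return a [case_control_cohort()].
#' @export
read_cohort_vcf <- function(vcf_path, phenotype_path, annotation = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep))
    message(sum(!keep), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dosage <- apply(gt, 2, function(col) {
    alleles <- strsplit(gsub("\\|", "/", col), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, 0L)
  })
  dosage <- matrix(as.integer(dosage), nrow = nrow(fix),
                   dimnames = list(NULL, colnames(gt)))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "|")
    idx <- match(key(variants), key(annotation))
    if (anyNA(idx))
      stop("annotation table lacks ", sum(is.na(idx)), " VCF record(s)",
           call. = FALSE)
    variants <- annotation[idx, , drop = FALSE]
    rownames(variants) <- NULL
  }
  phen <- read_phenotypes(phenotype_path)
  common <- intersect(colnames(dosage), phen$sample)
  if (length(common) == 0)
    stop("no VCF samples found in the phenotype table", call. = FALSE)
  dosage <- dosage[, common, drop = FALSE]
  status <- phen$status[match(common, phen$sample)]
  case_control_cohort(variants, dosage, status)
}

#' @rdname read_cohort_vcf
#' @export
read_phenotypes <- function(phenotype_path) {
  phen <- utils::read.table(phenotype_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "status") %in% names(phen)))
    stop("phenotype file needs columns 'sample' and 'status'", call. = FALSE)
  phen$status <- tolower(phen$status)
  if (!all(phen$status %in% c("case", "control")))
    stop("phenotype status must be 'case' or 'control'", call. = FALSE)
  phen
}

#' Write a cohort's genotypes as VCF plus phenotype table
#'
#' Intended for exporting simulated cohorts so any VCF-consuming tool can
#' read them. Writes an uncompressed minimal VCF 4.2 with GT fields, a
#' phenotype table, and the annotation table.
#'
#' @param cohort a `cc_cohort`.
#' @param prefix output path prefix; writes `<prefix>.vcf`,
#'   `<prefix>.phenotypes.tsv`, `<prefix>.annotation.tsv`.
#' @export
write_cohort_vcf <- function(cohort, prefix) {
  v <- cohort$variants
  n_ind <- ncol(cohort$genotypes)
  samples <- colnames(cohort$genotypes)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n_ind))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cohort$genotypes + 1L],
                   nrow = nrow(v))
  gt_str[is.na(gt_str)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  id <- if (is.null(v$id)) rep(".", nrow(v)) else ifelse(is.na(v$id), ".", v$id)
  body <- paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), paste0(prefix, ".vcf"))
  utils::write.table(
    data.frame(sample = samples, status = cohort$phenotype),
    paste0(prefix, ".phenotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_annotation(v, paste0(prefix, ".annotation.tsv"))
  invisible(prefix)
}
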