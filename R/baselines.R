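#' Weighted-sum statistic (WSS) rank test
#'
#' Madsen-Browning groupwise test. Each variant is weighted by the inverse
#' binomial standard deviation of its allele frequency as estimated from
#' the unaffected (background) individuals with a +1 pseudo-allele:
#' `q_i = (x_bg_i + 1) / (2 n_controls + 2)`,
#' `w_i = sqrt(n q_i (1 - q_i))` with `n` the total number of genotyped
#' individuals. Each individual's genetic score is `sum_i dosage_i / w_i`;
#' the statistic is the sum of case midranks of these scores, and the
#' p-value is the one-sided `(k + 1)/(N + 1)` permutation estimate
#' (`mode = "normal"` instead standardizes the observed rank sum against
#' permutation moments and uses the upper normal tail, the published
#' device for deep-tail significance).
#'
#' @param cohort a `cc_cohort`.
#' @param gene gene id.
#' @param n_perm number of label permutations.
#' @param seed optional RNG seed.
#' @param mode `"permutation"`, `"normal"`, or `"exhaustive"` (exact
#'   enumeration over all label assignments; small cohorts only).
#' @return list of class `baseline_result`: `gene_id`, `statistic`
#'   (weighted rank sum), `p_value`, `method = "wss"`.
#' @export
wss_test <- function(cohort, gene, n_perm = 999, seed = NULL,
                     mode = c("permutation", "normal", "exhaustive")) {
  mode <- match.arg(mode)
  rows <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene)
  if (length(rows) < 1) stop("gene ", gene, " has no variants", call. = FALSE)
  case <- cohort$phenotype == "case"
  if (!any(case) || !any(!case))
    stop("need at least one case and one control", call. = FALSE)
  geno <- cohort$genotypes[rows, , drop = FALSE]
  geno[is.na(geno)] <- 0L
  counts <- allele_counts(cohort, rows)
  n_controls <- sum(!case)
  q <- (counts$x_bg + 1) / (2 * n_controls + 2)
  w <- sqrt(ncol(geno) * q * (1 - q))
  gscore <- colSums(geno / w)
  r <- rank(gscore)                      # midranks for ties
  stat <- sum(r[case])
  if (!is.null(seed)) set.seed(seed)
  n_cases <- sum(case)
  p <- if (mode == "exhaustive") {
    if (choose(length(r), n_cases) > 1e5)
      stop("exhaustive mode infeasible for this cohort size", call. = FALSE)
    combos <- utils::combn(length(r), n_cases)
    perm <- apply(combos, 2, function(i) sum(r[i]))
    mean(perm >= stat - 1e-12)
  } else {
    perm <- vapply(seq_len(n_perm),
                   function(b) sum(r[sample.int(length(r), n_cases)]), 0)
    if (mode == "permutation") {
      (sum(perm >= stat - 1e-12) + 1) / (n_perm + 1)
    } else {
      s <- stats::sd(perm)
      if (s == 0) 1 else stats::pnorm((stat - mean(perm)) / s,
                                      lower.tail = FALSE)
    }
  }
  structure(list(gene_id = gene, statistic = stat, p_value = p,
                 method = "wss"),
            class = "baseline_result")
}

#' Carrier burden (CAST-style) test
#'
#' Collapses a gene to a carrier indicator -- at least one allele at a
#' variant with background MAF below `maf_threshold` -- and tests the 2x2
#' carrier-by-phenotype table with the two-sided Fisher exact test. The
#' reported statistic is the carrier odds ratio with 0.5 continuity
#' correction on zero cells.
#'
#' @inheritParams wss_test
#' @param maf_threshold rare-variant threshold in `(0, 1)` on background
#'   MAF.
#' @return `baseline_result` with `method = "burden"`.
#' @export
burden_test <- function(cohort, gene, maf_threshold = 0.01) {
  if (maf_threshold <= 0 || maf_threshold >= 1)
    stop("maf_threshold must lie in (0, 1)", call. = FALSE)
  rows <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene)
  if (length(rows) < 1) stop("gene ", gene, " has no variants", call. = FALSE)
  case <- cohort$phenotype == "case"
  counts <- allele_counts(cohort, rows)
  bg_maf <- ifelse(counts$n_bg > 0, counts$x_bg / counts$n_bg, 0)
  rare <- bg_maf < maf_threshold
  geno <- cohort$genotypes[rows[rare], , drop = FALSE]
  geno[is.na(geno)] <- 0L
  carrier <- if (nrow(geno) > 0) colSums(geno) > 0 else
    rep(FALSE, ncol(cohort$genotypes))
  a <- sum(carrier & case); b <- sum(!carrier & case)
  c_ <- sum(carrier & !case); d <- sum(!carrier & !case)
  tab <- matrix(c(a, c_, b, d), 2)
  p <- if (sum(carrier) == 0) 1 else stats::fisher.test(tab)$p.value
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  structure(list(gene_id = gene, statistic = or, p_value = p,
                 method = "burden"),
            class = "baseline_result")
}

#' @exportS3Method base::print
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s test, gene %s: statistic %.4g, p = %.4g\n",
              x$method, x$gene_id, x$statistic, x$p_value))
  invisible(x)
}
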