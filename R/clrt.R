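#' Binomial composite likelihood-ratio term for one variant
#'
#' Log likelihood ratio contrasting two binomial models of the observed
#' allele counts: the null holds the allele frequency equal in cases and
#' background (pooled maximum-likelihood estimate), the alternative lets
#' the two frequencies differ (per-cohort MLEs). Binomial coefficients
#' cancel; `0 * log 0` is taken as 0. The alternative nests the null, so
#' the returned value is always `>= 0`, with equality exactly when the two
#' sample frequencies coincide.
#'
#' @param x_case,x_bg alternate-allele counts in cases / background.
#' @param n_case,n_bg chromosome counts (`> 0`).
#' @return numeric vector, `ln L_alt - ln L_null` (natural log), `>= 0`.
#' @export
variant_log_lr <- function(x_case, n_case, x_bg, n_bg) {
  if (any(n_case <= 0) || any(n_bg <= 0))
    stop("chromosome counts must be positive in both cohorts", call. = FALSE)
  if (any(x_case < 0 | x_case > n_case) || any(x_bg < 0 | x_bg > n_bg))
    stop("allele counts must satisfy 0 <= x <= n", call. = FALSE)
  p_case <- x_case / n_case
  p_bg <- x_bg / n_bg
  p_0 <- (x_case + x_bg) / (n_case + n_bg)
  ll <- xlogy(x_case, p_case) + xlogy(n_case - x_case, 1 - p_case) +
    xlogy(x_bg, p_bg) + xlogy(n_bg - x_bg, 1 - p_bg) -
    xlogy(x_case, p_0) - xlogy(n_case - x_case, 1 - p_0) -
    xlogy(x_bg, p_0) - xlogy(n_bg - x_bg, 1 - p_0)
  pmax(ll, 0)  # guard against negative rounding noise
}

# x * log(y) with the 0 * log 0 = 0 convention; vector/matrix safe.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

#' Severity of annotated variants under a trained matrix
#'
#' Amino-acid-changing variants (missense, stop-gain, stop-loss) receive
#' the conservation-interpolated [severity_ratio()]; coding indels receive
#' their category's [indel_severity()]; synonymous and noncoding variants
#' receive severity 1 (frequency-only scoring). Missing conservation is
#' scored as 0 (unconserved).
#'
#' @param variants annotation data frame rows.
#' @param casm trained `casm` matrix.
#' @return numeric vector of severity ratios (`> 0`).
#' @export
variant_severity <- function(variants, casm) {
  sev <- rep(1, nrow(variants))
  cons <- variants$conservation
  cons[is.na(cons)] <- 0
  is_aas <- variants$consequence %in% c("missense", "stop_gain", "stop_loss")
  if (any(is_aas))
    sev[is_aas] <- severity_ratio(casm, variants$ref_aa[is_aas],
                                  variants$alt_aa[is_aas], cons[is_aas])
  is_indel <- variants$consequence %in%
    c("inframe_ins", "inframe_del", "frameshift_ins", "frameshift_del")
  if (any(is_indel))
    sev[is_indel] <- indel_severity(casm,
                                    variants$indel_kind[is_indel],
                                    variants$indel_length[is_indel],
                                    variants$frame_disrupting[is_indel])
  sev
}

#' Severity-updated contribution of one variant to the gene score
#'
#' The frequency log-likelihood-ratio of [variant_log_lr()] is updated by
#' the log severity ratio and clamped: a variant contributes
#' `max(0, logLR + ln severity)` when it is case-enriched and 0 otherwise
#' (the test targets risk-increasing alleles; background-enriched or
#' equally frequent variants never subtract signal).
#'
#' @param av annotated variant rows carrying allele counts `x_case`,
#'   `n_case`, `x_bg`, `n_bg` (see [allele_counts()]).
#' @param casm trained `casm` matrix.
#' @return non-negative numeric vector of per-variant contributions.
#' @export
variant_contribution <- function(av, casm) {
  sev <- variant_severity(av, casm)
  llr <- variant_log_lr(av$x_case, av$n_case, av$x_bg, av$n_bg)
  enriched <- av$x_case / av$n_case > av$x_bg / av$n_bg
  ifelse(enriched, pmax(0, llr + log(sev)), 0)
}

#' Collapse rare variants in a gene into pseudo-variants
#'
#' Variants whose background minor-allele frequency falls below
#' `maf_threshold` (or whose background allele count is at most
#' `count_threshold`) are merged into per-category groups -- one group for
#' rare SNVs and one for rare indels, so overlapping indels always share a
#' group. A pseudo-variant's allele counts are sums over its members; its
#' severity is the case-allele-count-weighted mean of member severities
#' (plain mean when no case alleles are observed). Variants at or above
#' the threshold are kept as-is, so a gene with no rare variants is
#' returned unchanged.
#'
#' @param cohort a `cc_cohort`.
#' @param gene gene id (matched against `cohort$variants$gene`).
#' @param casm trained `casm` matrix (needed for member severities).
#' @param maf_threshold background-MAF collapsing threshold in `(0, 1)`.
#' @param count_threshold background allele-count alternative trigger.
#' @param collapse set `FALSE` to skip grouping (every variant scored
#'   individually).
#' @return list with `table` (one row per (pseudo-)variant: label, counts,
#'   severity, number of members) and `genotypes` (pseudo-variant dosage
#'   matrix, member rows summed; missing genotypes treated as 0 within
#'   groups).
#' @export
collapse_rare <- function(cohort, gene, casm, maf_threshold = 0.01,
                          count_threshold = 1, collapse = TRUE) {
  if (collapse && (maf_threshold <= 0 || maf_threshold >= 1))
    stop("maf_threshold must lie in (0, 1)", call. = FALSE)
  rows <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene)
  v <- cohort$variants[rows, , drop = FALSE]
  counts <- allele_counts(cohort, rows)
  geno <- cohort$genotypes[rows, , drop = FALSE]
  geno[is.na(geno)] <- 0L
  if (nrow(v) == 0)
    return(list(table = data.frame(label = character(0), x_case = numeric(0),
                                   n_case = numeric(0), x_bg = numeric(0),
                                   n_bg = numeric(0), severity = numeric(0),
                                   n_members = integer(0)),
                genotypes = geno))
  sev <- variant_severity(v, casm)
  label <- paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)

  bg_maf <- ifelse(counts$n_bg > 0, counts$x_bg / counts$n_bg, 0)
  rare <- collapse & (bg_maf < maf_threshold | counts$x_bg <= count_threshold)
  is_indel <- v$consequence %in%
    c("inframe_ins", "inframe_del", "frameshift_ins", "frameshift_del")
  group <- ifelse(rare, ifelse(is_indel, "indel_group", "snv_group"),
                  label)

  out_tab <- list()
  out_geno <- list()
  for (gkey in unique(group)) {
    m <- which(group == gkey)
    if (length(m) == 1) {
      out_tab[[gkey]] <- data.frame(
        label = label[m], x_case = counts$x_case[m],
        n_case = counts$n_case[m], x_bg = counts$x_bg[m],
        n_bg = counts$n_bg[m], severity = sev[m], n_members = 1L,
        stringsAsFactors = FALSE)
      out_geno[[gkey]] <- geno[m, , drop = FALSE]
    } else {
      w <- counts$x_case[m]
      gsev <- if (sum(w) > 0) sum(sev[m] * w) / sum(w) else mean(sev[m])
      n_case <- round(mean(counts$n_case[m]))
      n_bg <- round(mean(counts$n_bg[m]))
      out_tab[[gkey]] <- data.frame(
        label = sprintf("%s(%d)", gkey, length(m)),
        x_case = min(sum(counts$x_case[m]), n_case),
        n_case = n_case,
        x_bg = min(sum(counts$x_bg[m]), n_bg),
        n_bg = n_bg,
        severity = gsev, n_members = length(m), stringsAsFactors = FALSE)
      out_geno[[gkey]] <- matrix(colSums(geno[m, , drop = FALSE]), nrow = 1)
    }
  }
  tab <- do.call(rbind, out_tab)
  rownames(tab) <- NULL
  list(table = tab,
       genotypes = do.call(rbind, out_geno))
}

#' Severity-weighted composite likelihood-ratio gene score
#'
#' After rare-variant collapsing, every (pseudo-)variant contributes
#' `max(0, logLR + ln severity)` if case-enriched (see
#' [variant_contribution()]); the gene score is twice the summed
#' contributions. The optional inheritance constraint zeroes the score
#' when no case individual carries the required number of scoring allele
#' copies in the gene (`>= 2` for `"recessive"`, `>= 1` for
#' `"dominant"`).
#'
#' @inheritParams collapse_rare
#' @param inheritance `"none"`, `"dominant"` or `"recessive"`.
#' @return object of class `gene_score_result`: `gene_id`, `score`,
#'   `p_value` (`NA` until [significance()] is run), and the per-variant
#'   contribution table.
#' @export
gene_score <- function(cohort, gene, casm,
                       inheritance = c("none", "dominant", "recessive"),
                       maf_threshold = 0.01, count_threshold = 1,
                       collapse = TRUE) {
  inheritance <- match.arg(inheritance)
  cl <- collapse_rare(cohort, gene, casm, maf_threshold, count_threshold,
                      collapse)
  tab <- cl$table
  if (nrow(tab) == 0) {
    return(structure(list(gene_id = gene, score = 0, p_value = 1,
                          n_variants = 0L, contributions = tab,
                          inheritance = inheritance),
                     class = "gene_score_result"))
  }
  llr <- variant_log_lr(tab$x_case, tab$n_case, tab$x_bg, tab$n_bg)
  enriched <- tab$x_case / tab$n_case > tab$x_bg / tab$n_bg
  contrib <- ifelse(enriched, pmax(0, llr + log(tab$severity)), 0)
  freq_contrib <- ifelse(enriched, llr, 0)
  tab$log_lr <- llr
  tab$log_severity <- log(tab$severity)
  tab$contribution <- contrib
  score <- 2 * sum(contrib)
  if (inheritance %in% c("dominant", "recessive") && score > 0) {
    need <- if (inheritance == "recessive") 2L else 1L
    scoring <- which(contrib > 0)
    case_cols <- cohort$phenotype == "case"
    load_per_case <- colSums(cl$genotypes[scoring, case_cols, drop = FALSE])
    if (!any(load_per_case >= need)) score <- 0
  }
  structure(list(gene_id = gene, score = score, p_value = NA_real_,
                 n_variants = nrow(tab), contributions = tab,
                 freq_statistic = 2 * sum(freq_contrib),
                 inheritance = inheritance),
            class = "gene_score_result")
}

#' @exportS3Method base::print
print.gene_score_result <- function(x, ...) {
  cat(sprintf("gene %s: score %.3f over %d (pseudo-)variant(s)",
              x$gene_id, x$score, x$n_variants))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Significance of a gene score
#'
#' Three modes are offered. `"permutation"` shuffles case/control labels,
#' recomputes the full severity-weighted score and returns the
#' `(k + 1) / (N + 1)` estimate, where `k` counts permuted scores at least
#' as large as the observed one. `"exhaustive"` enumerates every label
#' assignment (feasible for small cohorts) and returns the exact
#' proportion. `"asymptotic"` evaluates the frequency-only clamped
#' statistic against its large-sample null: because each of the `k`
#' evaluated (pseudo-)variants contributes a zero-clamped one-sided LR
#' component, the null is the chi-bar-square mixture
#' \deqn{\sum_{j=0}^{k} \binom{k}{j} 2^{-k} \chi^2_j,}
#' not a plain chi-square with `k` degrees of freedom; at `k = 1` this is
#' half the upper chi-square(1) tail. The asymptotic mode ignores the
#' severity update (which has no chi-square calibration) and is intended
#' for deep-tail thresholds -- such as a genome-wide level of
#' `2.4e-6` -- where permutation is infeasible; the two modes agree within
#' Monte-Carlo error at moderate significance levels.
#'
#' @inheritParams gene_score
#' @param mode `"permutation"`, `"asymptotic"` or `"exhaustive"`.
#' @param n_perm number of label permutations (`>= 1`).
#' @param seed optional RNG seed for the permutation draw.
#' @return p-value in `(0, 1]`.
#' @export
significance <- function(cohort, gene, casm,
                         mode = c("permutation", "asymptotic", "exhaustive"),
                         n_perm = 999, seed = NULL,
                         inheritance = c("none", "dominant", "recessive"),
                         maf_threshold = 0.01, count_threshold = 1,
                         collapse = TRUE) {
  mode <- match.arg(mode)
  inheritance <- match.arg(inheritance)
  gs <- gene_score(cohort, gene, casm, inheritance, maf_threshold,
                   count_threshold, collapse)
  if (gs$n_variants == 0L) return(1)

  if (mode == "asymptotic") {
    if (gs$score == 0) return(1)
    return(chibar_sf(gs$freq_statistic, gs$n_variants))
  }

  n_ind <- ncol(cohort$genotypes)
  n_cases <- sum(cohort$phenotype == "case")
  if (mode == "permutation") {
    if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    assign <- matrix(0L, n_ind, n_perm)
    for (b in seq_len(n_perm))
      assign[sample.int(n_ind, n_cases), b] <- 1L
    perm <- permuted_scores(cohort, gene, casm, assign, maf_threshold,
                            count_threshold, collapse, inheritance)
    return((sum(perm >= gs$score - 1e-12) + 1) / (n_perm + 1))
  }

  # exhaustive enumeration over all case-label assignments
  n_assign <- choose(n_ind, n_cases)
  if (n_assign > 1e5)
    stop("exhaustive mode infeasible: ", n_assign, " label assignments",
         call. = FALSE)
  combos <- utils::combn(n_ind, n_cases)
  assign <- matrix(0L, n_ind, ncol(combos))
  for (b in seq_len(ncol(combos))) assign[combos[, b], b] <- 1L
  perm <- permuted_scores(cohort, gene, casm, assign, maf_threshold,
                          count_threshold, collapse, inheritance)
  mean(perm >= gs$score - 1e-12)
}

# Severity-weighted gene scores under case-label reassignments, with the
# full scoring path (rare-group membership, group severity weights, clamp)
# recomputed for every relabeling. `assign` is an individuals x B 0/1
# matrix of case labels; all B scores are computed in one vectorized pass.
permuted_scores <- function(cohort, gene, casm, assign,
                            maf_threshold = 0.01, count_threshold = 1,
                            collapse = TRUE, inheritance = "none") {
  if (inheritance %in% c("dominant", "recessive")) {
    # constraint needs per-relabeling carrier genotypes: plain loop
    return(vapply(seq_len(ncol(assign)), function(b) {
      relabeled <- cohort
      relabeled$phenotype <- ifelse(assign[, b] == 1L, "case", "control")
      gene_score(relabeled, gene, casm, inheritance, maf_threshold,
                 count_threshold, collapse)$score
    }, 0))
  }
  rows <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene)
  v <- cohort$variants[rows, , drop = FALSE]
  geno <- cohort$genotypes[rows, , drop = FALSE]
  geno[is.na(geno)] <- 0L
  k <- nrow(v)
  B <- ncol(assign)
  if (k == 0) return(numeric(B))
  sev <- variant_severity(v, casm)
  is_indel <- v$consequence %in%
    c("inframe_ins", "inframe_del", "frameshift_ins", "frameshift_del")

  x_tot <- rowSums(geno)
  xc <- geno %*% assign                       # k x B case allele counts
  n_case <- 2 * colSums(assign)
  n_bg <- 2 * (nrow(assign) - colSums(assign))
  xb <- x_tot - xc
  nc <- matrix(n_case, k, B, byrow = TRUE)
  nb <- matrix(n_bg, k, B, byrow = TRUE)

  clamped_llr <- function(xc, nc, xb, nb, log_sev) {
    pc <- xc / nc; pb <- xb / nb
    p0 <- (xc + xb) / (nc + nb)
    llr <- xlogy(xc, pc) + xlogy(nc - xc, 1 - pc) +
      xlogy(xb, pb) + xlogy(nb - xb, 1 - pb) -
      xlogy(xc, p0) - xlogy(nc - xc, 1 - p0) -
      xlogy(xb, p0) - xlogy(nb - xb, 1 - p0)
    pmax(pmax(llr, 0) + log_sev, 0) * (pc > pb)
  }

  rare <- if (collapse) {
    (xb / nb < maf_threshold) | (xb <= count_threshold)
  } else matrix(FALSE, k, B)

  # ungrouped part: variants at or above the threshold score individually
  contrib_ind <- clamped_llr(xc, nc, xb, nb,
                             matrix(log(sev), k, B)) * !rare
  scores <- colSums(contrib_ind)

  # grouped part: one pseudo-variant per category per relabeling
  for (cat_rows in list(which(!is_indel), which(is_indel))) {
    if (length(cat_rows) == 0) next
    R <- rare[cat_rows, , drop = FALSE]
    n_mem <- colSums(R)
    if (all(n_mem == 0)) next
    xc_c <- xc[cat_rows, , drop = FALSE]
    xb_c <- xb[cat_rows, , drop = FALSE]
    XC <- pmin(colSums(xc_c * R), n_case)
    XB <- pmin(colSums(xb_c * R), n_bg)
    cw <- colSums(xc_c * R)
    wsev <- colSums(sev[cat_rows] * xc_c * R)
    msev <- colSums(sev[cat_rows] * R) / pmax(n_mem, 1)
    gsev <- ifelse(cw > 0, wsev / pmax(cw, 1), msev)
    gsev[n_mem == 0] <- 1
    gc <- clamped_llr(XC, n_case, XB, n_bg, log(gsev))
    gc[n_mem == 0] <- 0
    scores <- scores + gc
  }
  2 * scores
}

# Upper tail of the chi-bar-square mixture sum_j C(k,j) 2^-k chisq_j.
chibar_sf <- function(stat, k) {
  if (stat <= 1e-12) return(1)
  w <- stats::dbinom(seq_len(k), k, 0.5)
  sum(w * stats::pchisq(stat, df = seq_len(k), lower.tail = FALSE))
}

#' Score and rank all genes in a cohort
#'
#' Runs [gene_score()] and [significance()] for every gene, then ranks by
#' ascending p-value with ties broken by descending score and then gene
#' id. Rank bins follow the genome-wide search convention: 1-10, 11-100,
#' 101-1000, >1000.
#'
#' @inheritParams significance
#' @param genes gene ids to score; defaults to all genes in the cohort.
#' @return data frame with `gene`, `score`, `p_value`, `n_variants`,
#'   `rank`, `bin`, ordered by rank.
#' @export
rank_genome <- function(cohort, casm, genes = NULL,
                        mode = c("asymptotic", "permutation"),
                        n_perm = 999, seed = NULL,
                        inheritance = c("none", "dominant", "recessive"),
                        maf_threshold = 0.01, count_threshold = 1) {
  mode <- match.arg(mode)
  inheritance <- match.arg(inheritance)
  if (is.null(genes))
    genes <- sort(unique(stats::na.omit(cohort$variants$gene)))
  if (length(genes) < 1) stop("no genes to rank", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(genes, function(g) {
    gs <- gene_score(cohort, g, casm, inheritance, maf_threshold,
                     count_threshold)
    p <- significance(cohort, g, casm, mode = mode, n_perm = n_perm,
                      inheritance = inheritance,
                      maf_threshold = maf_threshold,
                      count_threshold = count_threshold)
    data.frame(gene = g, score = gs$score, p_value = p,
               n_variants = gs$n_variants, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ord <- order(out$p_value, -out$score, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$bin <- rank_bin(out$rank)
  rownames(out) <- NULL
  out
}

rank_bin <- function(rank) {
  cut(rank, breaks = c(0, 10, 100, 1000, Inf),
      labels = c("1-10", "11-100", "101-1000", ">1000"))
}
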