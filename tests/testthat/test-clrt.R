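test_that("the binomial log-LR matches a dbinom oracle and is non-negative", {
  expect_equal(variant_log_lr(5, 200, 5, 200), 0)
  expect_equal(variant_log_lr(0, 100, 0, 100), 0)
  expect_equal(variant_log_lr(5, 200, 0, 200),
               oracle_log_lr(5, 200, 0, 200))
  # random grid: always >= 0, equal to the oracle, zero iff equal freqs
  set.seed(21)
  for (i in 1:200) {
    nc <- sample(10:400, 1); nb <- sample(10:400, 1)
    xc <- sample(0:nc, 1); xb <- sample(0:nb, 1)
    v <- variant_log_lr(xc, nc, xb, nb)
    expect_gte(v, 0)
    expect_equal(v, max(0, oracle_log_lr(xc, nc, xb, nb)), tolerance = 1e-9)
    if (abs(xc / nc - xb / nb) < 1e-12) expect_equal(v, 0)
    if (v == 0) expect_equal(xc / nc, xb / nb)
  }
  expect_error(variant_log_lr(0, 0, 1, 10), "positive")
  expect_error(variant_log_lr(5, 4, 0, 10), "0 <= x <= n")
})

test_that("variant contributions apply the severity update and one-sided clamp", {
  cm <- test_casm()
  base <- ann_row("g", consequence = "synonymous")
  # equally frequent, severity 1: zero contribution
  av <- cbind(base, x_case = 5, n_case = 200, x_bg = 5, n_bg = 200)
  expect_equal(variant_contribution(av, cm), 0)
  # case-enriched with severity 1 (synonymous): contribution = log-LR
  av <- cbind(base, x_case = 8, n_case = 200, x_bg = 1, n_bg = 200)
  expect_equal(variant_contribution(av, cm),
               variant_log_lr(8, 200, 1, 200))
  # background-enriched with huge severity: clamped to zero
  nonsense <- ann_row("g", consequence = "stop_gain", ref_aa = "L",
                      alt_aa = "*", conservation = 1)
  av <- cbind(nonsense, x_case = 0, n_case = 200, x_bg = 10, n_bg = 200)
  expect_gt(severity_ratio(cm, "L", "*", 1), 1)
  expect_equal(variant_contribution(av, cm), 0)
  # case-enriched missense: log severity is added before clamping
  av <- cbind(nonsense, x_case = 6, n_case = 200, x_bg = 1, n_bg = 200)
  expect_equal(variant_contribution(av, cm),
               variant_log_lr(6, 200, 1, 200) +
                 log(severity_ratio(cm, "L", "*", 1)))
})

test_that("rare variants collapse into per-category pseudo-variants", {
  cm <- test_casm()
  variants <- rbind(
    ann_row("g", "missense", "V", "A", 0.9, pos = 1L),
    ann_row("g", "missense", "L", "P", 0.8, pos = 2L),
    ann_row("g", "frameshift_del", indel_kind = "deletion",
            indel_length = 2L, frame_disrupting = TRUE, pos = 3L,
            ref = "ACT", alt = "A"),
    ann_row("g", "inframe_del", indel_kind = "deletion",
            indel_length = 3L, frame_disrupting = FALSE, pos = 4L,
            ref = "ACTG", alt = "A"),
    ann_row("g", "missense", "G", "R", 0.5, pos = 5L))
  # 4 cases, 4 controls; variants 1-4 rare (bg count 0), variant 5 common
  geno <- rbind(
    c(1, 0, 0, 0, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0, 0, 0, 0),
    c(0, 0, 1, 0, 0, 0, 0, 0),
    c(1, 0, 1, 0, 0, 0, 0, 0),
    c(2, 2, 1, 1, 2, 2, 1, 1))
  cohort <- toy_cohort(geno, 4, variants)
  cl <- collapse_rare(cohort, "g", cm, maf_threshold = 0.2)
  expect_equal(nrow(cl$table), 3)  # snv group, indel group, common variant
  snv <- cl$table[grep("snv_group", cl$table$label), ]
  ind <- cl$table[grep("indel_group", cl$table$label), ]
  expect_equal(snv$x_case, 2)      # two singleton case alleles summed
  expect_equal(snv$x_bg, 0)
  expect_equal(snv$n_members, 2L)
  expect_equal(ind$x_case, 3)      # dosages 1 + (1+1)
  sev <- variant_severity(variants, cm)
  # group severity: case-allele-count-weighted mean of member severities
  expect_equal(snv$severity, (sev[1] * 1 + sev[2] * 1) / 2)
  expect_equal(ind$severity, (sev[3] * 1 + sev[4] * 2) / 3)
  # grouped genotype row is the member dosage sum
  expect_equal(unname(cl$genotypes[grep("snv_group", cl$table$label), ]),
               unname(colSums(geno[1:2, ])))
  # the stated weighted-mean example: severities 4 and 1 with case counts
  # 3 and 1 give 3.25 under the same rule
  expect_equal((4 * 3 + 1 * 1) / (3 + 1), 3.25)
  # nothing below the threshold: cohort unchanged
  cl2 <- collapse_rare(cohort, "g", cm, maf_threshold = 0.2,
                       count_threshold = -1, collapse = FALSE)
  expect_equal(nrow(cl2$table), 5)
  expect_equal(cl2$table$x_case, c(1, 1, 1, 2, 6))
})

test_that("gene scores equal an independent straight-line oracle", {
  cm <- test_casm()
  # degenerate gene: no variants
  empty <- toy_cohort(matrix(0, 1, 8), 4, ann_row("other"))
  gs <- gene_score(empty, "g", cm)
  expect_equal(gs$score, 0)
  # single variant: score is twice its contribution
  v1 <- cbind(ann_row("g", "missense", "V", "M", 0.7),
              x_case = 3, n_case = 8, x_bg = 0, n_bg = 8)
  single <- toy_cohort(rbind(c(1, 1, 1, 0, 0, 0, 0, 0)), 4,
                       v1[, annotation_columns()])
  gs <- gene_score(single, "g", cm)
  expect_equal(gs$score, 2 * variant_contribution(v1, cm))
  # multi-variant fixtures, with and without collapsing
  set.seed(42)
  for (rep in 1:8) {
    k <- sample(2:5, 1)
    variants <- do.call(rbind, lapply(seq_len(k), function(i) {
      pick <- sample(3, 1)
      if (pick == 1) ann_row("g", "missense",
                             sample(setdiff(aas_alphabet(), "*"), 1),
                             sample(setdiff(aas_alphabet(), "*"), 1),
                             runif(1), pos = i)
      else if (pick == 2) ann_row("g", "frameshift_ins",
                                  indel_kind = "insertion",
                                  indel_length = sample(c(1, 2, 4), 1),
                                  frame_disrupting = TRUE, pos = i,
                                  ref = "A", alt = "AT")
      else ann_row("g", "synonymous", pos = i)
    }))
    bad <- variants$ref_aa == variants$alt_aa & !is.na(variants$ref_aa)
    variants$alt_aa[bad] <- "*"
    variants$consequence[bad] <- "stop_gain"
    geno <- matrix(sample(0:2, k * 12, TRUE, prob = c(0.7, 0.2, 0.1)),
                   nrow = k)
    cohort <- toy_cohort(geno, 6, variants)
    for (collapse in c(TRUE, FALSE)) {
      gs <- gene_score(cohort, "g", cm, maf_threshold = 0.3,
                       collapse = collapse)
      expect_equal(gs$score,
                   oracle_gene_score(cohort, "g", cm, maf_threshold = 0.3,
                                     collapse = collapse),
                   tolerance = 1e-9)
    }
  }
})

test_that("gene scores are invariant to variant order and monotone in case count", {
  cm <- test_casm()
  set.seed(11)
  k <- 5
  variants <- do.call(rbind, lapply(1:k, function(i)
    ann_row("g", "missense", "V", "A", 0.8, pos = i)))
  geno <- matrix(sample(0:2, k * 16, TRUE, prob = c(0.8, 0.15, 0.05)), k)
  cohort <- toy_cohort(geno, 8, variants)
  s0 <- gene_score(cohort, "g", cm)$score
  perm <- sample(k)
  cohort2 <- toy_cohort(geno[perm, ], 8, variants[perm, ])
  expect_equal(gene_score(cohort2, "g", cm)$score, s0)
  # raising a case dosage never lowers the score
  for (i in 1:10) {
    g2 <- geno
    slot <- which(g2[, 1:8] < 2)[1]
    g2[, 1:8][slot] <- g2[, 1:8][slot] + 1L
    s2 <- gene_score(toy_cohort(g2, 8, variants), "g", cm)$score
    expect_gte(s2 + 1e-9, s0)
    geno <- g2
    s0 <- s2
  }
})

test_that("inheritance-model constraints gate the score on case genotypes", {
  cm <- test_casm()
  variants <- rbind(ann_row("g", "missense", "V", "A", 0.9, pos = 1L),
                    ann_row("g", "missense", "L", "P", 0.9, pos = 2L))
  # each case carries one allele at a different site: fine for dominant,
  # zeroed under the recessive requirement (no case has two copies)
  geno_het <- rbind(c(1, 0, 0, 0, 0, 0),
                    c(0, 1, 0, 0, 0, 0))
  het <- toy_cohort(geno_het, 2, variants)
  expect_gt(gene_score(het, "g", cm, inheritance = "dominant")$score, 0)
  expect_equal(gene_score(het, "g", cm, inheritance = "recessive")$score, 0)
  # compound heterozygote case: two scoring copies in one individual
  geno_ch <- rbind(c(1, 0, 0, 0, 0, 0),
                   c(1, 0, 0, 0, 0, 0))
  ch <- toy_cohort(geno_ch, 2, variants)
  expect_gt(gene_score(ch, "g", cm, inheritance = "recessive")$score, 0)
})

test_that("exhaustive permutation p equals full enumeration on 4+4 cohorts", {
  cm <- test_casm()
  set.seed(33)
  for (rep in 1:4) {
    k <- sample(2:4, 1)
    variants <- do.call(rbind, lapply(seq_len(k), function(i)
      ann_row("g", "missense", "M", "T", runif(1), pos = i)))
    geno <- matrix(sample(0:2, k * 8, TRUE, prob = c(0.6, 0.3, 0.1)), k)
    cohort <- toy_cohort(geno, 4, variants)
    p_impl <- significance(cohort, "g", cm, mode = "exhaustive",
                           maf_threshold = 0.3)
    p_oracle <- oracle_exhaustive_p(cohort, "g", cm, maf_threshold = 0.3)
    expect_equal(p_impl, p_oracle)
    # all 70 assignments enter the enumeration
    expect_true(p_impl >= 1 / choose(8, 4))
  }
})

test_that("permutation p follows the (k+1)/(N+1) convention", {
  cm <- test_casm()
  # 20 cases carry a private allele each, 20 controls carry nothing: the
  # observed labeling is effectively the unique maximum, so p = 1/(N+1)
  k <- 6
  geno <- matrix(0L, k, 40)
  for (i in seq_len(k)) geno[i, sample(1:20, 3)] <- 1L
  variants <- do.call(rbind, lapply(seq_len(k), function(i)
    ann_row("g", "missense", "R", "W", 0.95, pos = i)))
  cohort <- toy_cohort(geno, 20, variants)
  p <- significance(cohort, "g", cm, mode = "permutation", n_perm = 99,
                    seed = 5)
  expect_equal(p, 1 / 100)
  # identical genotype columns: every permutation ties, p = 1
  geno_null <- matrix(1L, 2, 8)
  null_cohort <- toy_cohort(geno_null, 4,
                            rbind(ann_row("g", "missense", "V", "A", 0.5,
                                          pos = 1L),
                                  ann_row("g", "missense", "V", "A", 0.5,
                                          pos = 2L)))
  expect_equal(significance(null_cohort, "g", cm, mode = "permutation",
                            n_perm = 49, seed = 1), 1)
  expect_error(significance(cohort, "g", cm, mode = "permutation",
                            n_perm = 0), "n_perm")
})

test_that("null permutation p-values are stochastically valid", {
  cm <- test_casm()
  set.seed(77)
  pvals <- replicate(120, {
    geno <- matrix(sample(0:2, 2 * 8, TRUE, prob = c(0.5, 0.3, 0.2)), 2)
    cohort <- toy_cohort(geno, 4,
                         rbind(ann_row("g", "missense", "A", "T", 0.6,
                                       pos = 1L),
                               ann_row("g", "missense", "A", "T", 0.6,
                                       pos = 2L)))
    significance(cohort, "g", cm, mode = "exhaustive", maf_threshold = 0.3)
  })
  for (alpha in c(0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + 3 * se)
  }
})

test_that("asymptotic and permutation p agree at moderate levels", {
  cm <- test_casm()
  set.seed(55)
  # a moderately case-enriched gene in a 60+60 cohort
  k <- 4
  geno <- matrix(rbinom(k * 120, 2, 0.04), k)
  geno[, 1:25] <- geno[, 1:25] + rbinom(k * 25, 1, 0.12)
  geno <- pmin(geno, 2)
  variants <- do.call(rbind, lapply(seq_len(k), function(i)
    ann_row("g", "synonymous", pos = i)))  # severity 1: calibrated regime
  cohort <- toy_cohort(geno, 60, variants)
  p_perm <- significance(cohort, "g", cm, mode = "permutation",
                         n_perm = 1999, seed = 8)
  p_asym <- significance(cohort, "g", cm, mode = "asymptotic")
  mc_se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(p_perm - p_asym), max(5 * mc_se, 0.02))
})

test_that("genome ranking sorts by p, then score, then gene id", {
  cm <- test_casm()
  sev_hi <- ann_row("gA", "stop_gain", "L", "*", 1, pos = 1L)
  sev_lo <- ann_row("gB", "synonymous", pos = 2L)
  none <- ann_row("gC", "missense", "V", "A", 0.1, pos = 3L)
  variants <- rbind(sev_hi, sev_lo, none)
  # gA and gB have identical case-enriched counts (same frequency-only
  # asymptotic p); gA carries the high-severity allele, so its score wins
  geno <- rbind(c(1, 1, 0, 0, 0, 0, 0, 0),
                c(1, 1, 0, 0, 0, 0, 0, 0),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  cohort <- toy_cohort(geno, 4, variants)
  res <- rank_genome(cohort, cm, mode = "asymptotic")
  expect_equal(res$gene, c("gA", "gB", "gC"))
  expect_equal(res$rank, 1:3)
  expect_equal(res$p_value[1], res$p_value[2])
  expect_gt(res$score[1], res$score[2])
  expect_equal(as.character(res$bin), rep("1-10", 3))
  # single gene ranks first
  solo <- toy_cohort(matrix(c(1, 0, 0, 0), 1), 2, ann_row("only"))
  expect_equal(rank_genome(solo, cm)$rank, 1L)
})
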