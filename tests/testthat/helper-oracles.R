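# Independent straight-line oracle implementations used to cross-check the
# package's vectorized code paths. These deliberately take the dumbest
# possible route (explicit loops, dbinom-based likelihoods) and share no
# code with the implementation.

# Binomial log-LR via dbinom at the MLEs (coefficients cancel in the ratio).
oracle_log_lr <- function(x_case, n_case, x_bg, n_bg) {
  p_case <- x_case / n_case
  p_bg <- x_bg / n_bg
  p_pool <- (x_case + x_bg) / (n_case + n_bg)
  dbinom(x_case, n_case, p_case, log = TRUE) +
    dbinom(x_bg, n_bg, p_bg, log = TRUE) -
    dbinom(x_case, n_case, p_pool, log = TRUE) -
    dbinom(x_bg, n_bg, p_pool, log = TRUE)
}

# Double-loop CASM endpoint estimation straight from the definitions.
oracle_train_endpoints <- function(training) {
  v <- training[training$class == "aas", , drop = FALSE]
  C <- nrow(v)
  out <- list()
  for (i in seq_len(C)) {
    key <- paste0(v$ref_aa[i], ">", v$alt_aa[i])
    if (is.null(out[[key]])) out[[key]] <- c(e1 = 0, e0 = 0)
    out[[key]]["e1"] <- out[[key]]["e1"] + v$conservation[i] / C
    out[[key]]["e0"] <- out[[key]]["e0"] + (1 - v$conservation[i]) / C
  }
  out
}

# Full severity lookup for one annotated-variant row, by the book.
oracle_severity <- function(row, casm) {
  if (row$consequence %in% c("missense", "stop_gain", "stop_loss")) {
    x <- row$conservation
    if (is.na(x)) x <- 0
    i <- which(casm$aas$ref_aa == row$ref_aa & casm$aas$alt_aa == row$alt_aa)
    r1 <- (casm$aas$a1[i] + casm$meta$eps_a) / (casm$aas$h1[i] + casm$meta$eps_h)
    r0 <- (casm$aas$a0[i] + casm$meta$eps_a) / (casm$aas$h0[i] + casm$meta$eps_h)
    return(x * r1 + (1 - x) * r0)
  }
  if (row$consequence %in% c("inframe_ins", "inframe_del",
                             "frameshift_ins", "frameshift_del")) {
    len <- row$indel_length
    cls <- if (len <= 3) as.character(len) else if (len <= 9) "4-9" else "10+"
    fr <- if (row$frame_disrupting) "frameshift" else "inframe"
    key <- paste(row$indel_kind, cls, fr, sep = ":")
    i <- which(casm$indel$category == key)
    return((casm$indel$a[i] + casm$meta$eps_a_indel) /
             (casm$indel$h[i] + casm$meta$eps_h_indel))
  }
  1
}

# Straight-line severity-weighted gene score: per-variant counts from
# explicit loops over individuals, optional collapsing by the stated rule.
oracle_gene_score <- function(cohort, gene, casm, maf_threshold = 0.01,
                              count_threshold = 1, collapse = TRUE,
                              phenotype = cohort$phenotype) {
  rows <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene)
  if (length(rows) == 0) return(0)
  v <- cohort$variants[rows, , drop = FALSE]
  n <- length(rows)
  xc <- xb <- nc <- nb <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(cohort$genotypes))) {
      d <- cohort$genotypes[rows[i], j]
      if (is.na(d)) next
      if (phenotype[j] == "case") {
        xc[i] <- xc[i] + d; nc[i] <- nc[i] + 2
      } else {
        xb[i] <- xb[i] + d; nb[i] <- nb[i] + 2
      }
    }
  }
  sev <- vapply(seq_len(n), function(i) oracle_severity(v[i, ], casm), 0)
  is_indel <- v$consequence %in% c("inframe_ins", "inframe_del",
                                   "frameshift_ins", "frameshift_del")
  rare <- collapse & (xb / nb < maf_threshold | xb <= count_threshold)
  group <- ifelse(rare, ifelse(is_indel, "I", "S"), paste0("v", seq_len(n)))
  total <- 0
  for (gk in unique(group)) {
    m <- which(group == gk)
    X_c <- min(sum(xc[m]), round(mean(nc[m])))
    X_b <- min(sum(xb[m]), round(mean(nb[m])))
    N_c <- round(mean(nc[m])); N_b <- round(mean(nb[m]))
    s <- if (length(m) == 1) sev[m]
         else if (sum(xc[m]) > 0) sum(sev[m] * xc[m]) / sum(xc[m])
         else mean(sev[m])
    if (X_c / N_c > X_b / N_b) {
      contrib <- max(0, oracle_log_lr(X_c, N_c, X_b, N_b) + log(s))
      total <- total + contrib
    }
  }
  2 * total
}

# Exact permutation p-value by enumerating every case-label assignment.
oracle_exhaustive_p <- function(cohort, gene, casm, ...) {
  n_ind <- ncol(cohort$genotypes)
  n_cases <- sum(cohort$phenotype == "case")
  obs <- oracle_gene_score(cohort, gene, casm, ...)
  combos <- combn(n_ind, n_cases)
  perm <- apply(combos, 2, function(idx) {
    ph <- rep("control", n_ind)
    ph[idx] <- "case"
    oracle_gene_score(cohort, gene, casm, ..., phenotype = ph)
  })
  mean(perm >= obs - 1e-12)
}

# Pairwise-comparison AUC: P(score_damaging > score_benign) + 0.5 ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "damaging"]
  neg <- scores[labels == "benign"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
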