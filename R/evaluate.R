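#' Receiver operating characteristic of a variant classifier
#'
#' Computes the stepwise ROC over all score thresholds, the area under the
#' curve via the Mann-Whitney rank formulation (midranks for ties), the
#' true-positive rate at a false-positive rate of 0.05 (linear
#' interpolation between adjacent thresholds), and the accuracy at that
#' operating point on the benchmark set's own class balance.
#'
#' @param scores numeric classifier scores (higher = more damaging).
#' @param labels `"damaging"` / `"benign"` (or logical, `TRUE` =
#'   damaging), one per score; both classes must be present.
#' @return list of class `roc_result`: `fpr`, `tpr`, `thresholds`, `auc`,
#'   `tpr_at_fpr05`, `accuracy_at_fpr05`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "damaging", "benign")
  if (!all(labels %in% c("damaging", "benign")))
    stop("labels must be 'damaging' or 'benign'", call. = FALSE)
  pos <- labels == "damaging"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, 0)

  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  tpr05 <- interp_at(fpr, tpr, 0.05)
  acc05 <- (tpr05 * n_pos + (1 - 0.05) * n_neg) / (n_pos + n_neg)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 tpr_at_fpr05 = tpr05, accuracy_at_fpr05 = acc05),
            class = "roc_result")
}

# Linear interpolation of y at x = x0 along a monotone stepwise curve.
interp_at <- function(x, y, x0) {
  if (x0 <= min(x)) return(y[which.min(x)])
  if (x0 >= max(x)) return(max(y[x >= x0][1], y[which.max(x)]))
  lo <- max(which(x <= x0))
  hi <- min(which(x >= x0))
  if (x[hi] == x[lo]) return(max(y[x == x[lo]]))
  y[lo] + (y[hi] - y[lo]) * (x0 - x[lo]) / (x[hi] - x[lo])
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f, TPR %.3f / accuracy %.3f at FPR 0.05\n",
              x$auc, x$tpr_at_fpr05, x$accuracy_at_fpr05))
  invisible(x)
}

#' Statistical power over a grid of simulation conditions
#'
#' For every grid row and method, simulates `n_replicates` cohorts (fresh
#' simulation per replicate by default; `mode = "bootstrap"` instead
#' resamples cases and controls with replacement from one simulated
#' cohort, the protocol used with fixed real datasets) and reports the
#' fraction of replicates significant at `alpha`, with its Monte-Carlo
#' standard error `sqrt(power (1 - power) / n_replicates)`.
#'
#' @param grid data frame; columns override [simulation_config()] fields
#'   (`total_par`, `nd`, `n_noncausal`, `inheritance`, `n_cases`,
#'   `n_controls`).
#' @param casm trained severity matrix (trained from a default synthetic
#'   training set when omitted).
#' @param methods any of `"clrt"`, `"wss"`, `"burden"`.
#' @param alpha significance level; defaults to the genome-wide level
#'   `2.4e-6`.
#' @param n_replicates replicates per grid point.
#' @param p_mode p-value mode for the CLRT (asymptotic recommended at
#'   deep-tail `alpha`).
#' @param n_perm permutations for permutation-based p-values.
#' @param inheritance inheritance-model option passed to the CLRT scorer
#'   (the simulation model itself comes from the grid).
#' @param mode `"fresh"` or `"bootstrap"`.
#' @param seed master seed; per-replicate seeds are drawn from it and
#'   recorded.
#' @param base_config named list of [simulation_config()] arguments used
#'   for fields the grid does not override.
#' @return data frame of power-curve points (one row per grid row x
#'   method) with `power`, `se`, `n_replicates`, `alpha` and the grid
#'   fields.
#' @export
power_sweep <- function(grid, casm = NULL, methods = "clrt",
                        alpha = 2.4e-6, n_replicates = 100,
                        p_mode = c("asymptotic", "permutation"),
                        n_perm = 999,
                        inheritance = "none",
                        mode = c("fresh", "bootstrap"), seed = 1,
                        base_config = list()) {
  p_mode <- match.arg(p_mode)
  mode <- match.arg(mode)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.null(casm)) {
    ts <- generate_training_sets(seed = seed)
    casm <- train_casm(ts$disease, ts$neutral)
  }
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * n_replicates),
                      nrow(grid), n_replicates)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    args <- base_config
    for (col in names(grid)) args[[col]] <- grid[[col]][i]
    boot_parent <- NULL
    if (mode == "bootstrap") {
      args$seed <- rep_seeds[i, 1]
      boot_parent <- simulate_case_control(do.call(simulation_config, args))
    }
    pvals <- matrix(NA_real_, n_replicates, length(methods),
                    dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      if (mode == "fresh") {
        args$seed <- rep_seeds[i, r]
        cohort <- simulate_case_control(do.call(simulation_config, args))
      } else {
        cohort <- bootstrap_cohort(boot_parent, seed = rep_seeds[i, r])
      }
      for (m in methods) {
        pvals[r, m] <- switch(m,
          clrt = significance(cohort, "GENE1", casm, mode = p_mode,
                              n_perm = n_perm, inheritance = inheritance),
          wss = wss_test(cohort, "GENE1", n_perm = n_perm,
                         mode = "normal")$p_value,
          burden = burden_test(cohort, "GENE1")$p_value,
          stop("unknown method '", m, "'", call. = FALSE))
      }
    }
    for (m in methods) {
      pw <- mean(pvals[, m] <= alpha)
      row <- as.data.frame(grid[i, , drop = FALSE])
      row$method <- m
      row$power <- pw
      row$se <- sqrt(pw * (1 - pw) / n_replicates)
      row$n_replicates <- n_replicates
      row$alpha <- alpha
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Resample cases and controls with replacement, preserving group sizes.
bootstrap_cohort <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  case <- which(cohort$phenotype == "case")
  ctrl <- which(cohort$phenotype == "control")
  idx <- c(sample(case, length(case), replace = TRUE),
           sample(ctrl, length(ctrl), replace = TRUE))
  out <- cohort
  out$genotypes <- cohort$genotypes[, idx, drop = FALSE]
  colnames(out$genotypes) <- sprintf("S%05d", seq_along(idx))
  out$phenotype <- cohort$phenotype[idx]
  out
}

#' Smallest sample size reaching a power target
#'
#' Walks an ascending grid of equal case/control sample sizes, estimating
#' power at each, and returns the smallest size whose power reaches
#' `target` (or `Inf` when none does).
#'
#' @inheritParams power_sweep
#' @param sizes ascending vector of candidate sample sizes (cases =
#'   controls).
#' @param target power target (default 0.8).
#' @param config_args named list of [simulation_config()] arguments
#'   (everything but the sample sizes).
#' @return list with `n` (smallest adequate size or `Inf`) and the power
#'   table for the sizes visited.
#' @export
sample_size_for_power <- function(sizes, config_args, casm = NULL,
                                  target = 0.8, alpha = 2.4e-6,
                                  n_replicates = 100, seed = 1,
                                  p_mode = "asymptotic") {
  visited <- list()
  for (n in sizes) {
    grid <- data.frame(n_cases = n, n_controls = n)
    pt <- power_sweep(grid, casm = casm, alpha = alpha,
                      n_replicates = n_replicates, p_mode = p_mode,
                      seed = seed + n, base_config = config_args)
    visited[[length(visited) + 1]] <- pt
    if (pt$power >= target)
      return(list(n = n, table = do.call(rbind, visited)))
  }
  list(n = Inf, table = do.call(rbind, visited))
}

#' False-positive rate under stratified null scenarios
#'
#' For each scenario (a stratification setting), simulates null
#' case-control cohorts from a two-subpopulation model and reports the
#' fraction of genes significant at `alpha` -- the empirical
#' false-positive rate. Balanced mixing should stay at `alpha`; strong
#' case/control imbalance inflates it.
#'
#' @param scenarios named list; each element a list with `fst`,
#'   `case_mix`, `control_mix`.
#' @param n_genes number of independent null genes per scenario.
#' @param alpha significance level.
#' @param config_args [simulation_config()] arguments shared across
#'   scenarios (site counts, sample sizes, MAF law).
#' @inheritParams power_sweep
#' @return data frame with `scenario`, `fpr`, `se`, `n_genes`, `alpha`.
#' @export
fpr_sweep <- function(scenarios, casm = NULL, n_genes = 200, alpha = 0.05,
                      p_mode = c("asymptotic", "permutation"),
                      n_perm = 199, seed = 1,
                      config_args = list(total_par = 0, nd = 10,
                                         n_noncausal = 10,
                                         n_cases = 200, n_controls = 200,
                                         maf_distribution = list(
                                           name = "loguniform",
                                           min = 0.005, max = 0.2))) {
  p_mode <- match.arg(p_mode)
  if (is.null(casm)) {
    ts <- generate_training_sets(seed = seed)
    casm <- train_casm(ts$disease, ts$neutral)
  }
  set.seed(seed)
  gene_seeds <- matrix(sample.int(.Machine$integer.max,
                                  length(scenarios) * n_genes),
                       length(scenarios), n_genes)
  out <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    hits <- 0L
    for (g in seq_len(n_genes)) {
      args <- config_args
      args$stratification <- sc
      args$seed <- gene_seeds[s, g]
      cohort <- simulate_stratified(do.call(simulation_config, args))
      p <- significance(cohort, "GENE1", casm, mode = p_mode,
                        n_perm = n_perm)
      if (p <= alpha) hits <- hits + 1L
    }
    fpr <- hits / n_genes
    out[[s]] <- data.frame(scenario = names(scenarios)[s], fpr = fpr,
                           se = sqrt(fpr * (1 - fpr) / n_genes),
                           n_genes = n_genes, alpha = alpha,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank-bin summary for genome-wide disease-gene searches
#'
#' Summarizes the genome-wide ranks of target genes over replicated
#' searches into the standard bins 1-10, 11-100, 101-1000, >1000, with
#' binomial standard errors. Proportions sum to 1.
#'
#' @param ranks integer vector of target-gene ranks (one per replicate).
#' @return data frame with `bin`, `count`, `proportion`, `se`.
#' @export
rank_bins <- function(ranks) {
  if (any(ranks < 1)) stop("ranks must be >= 1", call. = FALSE)
  b <- rank_bin(ranks)
  n <- length(ranks)
  cnt <- as.integer(table(b))
  prop <- cnt / n
  data.frame(bin = levels(b), count = cnt, proportion = prop,
             se = sqrt(prop * (1 - prop) / n), stringsAsFactors = FALSE)
}
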