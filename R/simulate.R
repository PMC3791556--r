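#' Simulation configuration
#'
#' Study conditions for the population-attributable-risk (PAR) case-control
#' simulator. The total PAR is apportioned equally across the `nd` causal
#' sites (`PAR_i = total_par / nd`); each causal site draws a population
#' MAF from `maf_distribution`, converts its PAR share into a relative risk
#' via the risk-genotype frequency, and contributes multiplicatively to
#' disease risk. Noncausal sites are sampled identically in both cohorts.
#'
#' The default MAF spectrum is log-uniform on `[1e-5, 2e-4]` (mean MAF
#' about 6e-5): deleterious risk alleles held rare by purifying selection,
#' the regime rare-variant aggregative tests are designed for. The
#' spectrum is configurable (`name` one of `"loguniform"`, `"uniform"`,
#' `"beta"`, `"fixed"`) and power results are sensitive to it.
#'
#' @param total_par total population attributable risk in `[0, 1)`.
#' @param nd number of causal sites (allelic-heterogeneity knob).
#' @param n_noncausal number of noncausal sites in the same gene.
#' @param inheritance `"dominant"` or `"recessive"` risk-genotype model.
#' @param n_cases,n_controls cohort sizes (individuals).
#' @param maf_distribution list naming the MAF law and its parameters.
#' @param prevalence disease prevalence `f0`; the simulator uses the
#'   rare-disease approximation (control genotype frequencies equal
#'   population frequencies), which is accurate for small `f0`.
#' @param stratification optional list (`fst`, `case_mix`, `control_mix`)
#'   for [simulate_stratified()].
#' @param seed RNG seed (mandatory; recorded in the output).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(total_par = 0.05, nd = 50, n_noncausal = 50,
                              inheritance = c("dominant", "recessive"),
                              n_cases = 1000, n_controls = 1000,
                              maf_distribution = list(name = "loguniform",
                                                      min = 1e-5,
                                                      max = 2e-4),
                              prevalence = 0.01, stratification = NULL,
                              seed = 1) {
  inheritance <- match.arg(inheritance)
  if (total_par < 0 || total_par >= 1)
    stop("total_par must lie in [0, 1)", call. = FALSE)
  if (nd < 1) stop("nd must be >= 1", call. = FALSE)
  if (!is.null(stratification)) {
    for (mx in c("case_mix", "control_mix")) {
      if (abs(sum(stratification[[mx]]) - 1) > 1e-8)
        stop(mx, " must sum to 1", call. = FALSE)
    }
  }
  structure(list(total_par = total_par, nd = nd, n_noncausal = n_noncausal,
                 inheritance = inheritance, n_cases = n_cases,
                 n_controls = n_controls,
                 maf_distribution = maf_distribution,
                 prevalence = prevalence, stratification = stratification,
                 seed = seed),
            class = "sim_config")
}

draw_maf <- function(n, dist) {
  out <- switch(dist$name,
    loguniform = exp(stats::runif(n, log(dist$min), log(dist$max))),
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    fixed = rep_len(dist$value, n),
    stop("unknown maf_distribution '", dist$name, "'", call. = FALSE))
  if (any(out <= 0 | out >= 1))
    stop("MAF draws must lie in (0, 1)", call. = FALSE)
  out
}

#' Relative risk implied by a per-site PAR share
#'
#' Inverts the population-attributable-risk identity
#' `PAR = g (RR - 1) / (1 + g (RR - 1))` for the relative risk, where `g`
#' is the population frequency of the risk genotype (`1 - (1-p)^2` under a
#' dominant model, `p^2` under a recessive one).
#'
#' @param par_i per-site PAR share in `[0, 1)`.
#' @param g risk-genotype frequency in `(0, 1]`.
#' @return relative risk `>= 1`.
#' @export
par_to_relative_risk <- function(par_i, g) {
  if (any(par_i < 0 | par_i >= 1))
    stop("per-site PAR must lie in [0, 1)", call. = FALSE)
  if (any(g <= 0 | g > 1))
    stop("risk-genotype frequency must lie in (0, 1] (infeasible site)",
         call. = FALSE)
  1 + par_i / (g * (1 - par_i))
}

#' Closed-form risk-genotype frequency among cases
#'
#' Under the PAR model the frequency of the risk genotype among cases is
#' `PAR_i + g (1 - PAR_i)`: Bayes inversion of the multiplicative risk
#' model, using `1 + g (RR - 1) = 1 / (1 - PAR_i)`.
#'
#' @inheritParams par_to_relative_risk
#' @export
risk_genotype_case_freq <- function(par_i, g) par_i + g * (1 - par_i)

# Per-site genotype distribution among cases (cols: dosage 0, 1, 2).
case_genotype_probs <- function(p, rr, par_i, inheritance) {
  hw0 <- (1 - p)^2; hw1 <- 2 * p * (1 - p); hw2 <- p^2
  if (inheritance == "dominant") {
    cbind(hw0 * (1 - par_i), hw1 * rr * (1 - par_i), hw2 * rr * (1 - par_i))
  } else {
    cbind(hw0 * (1 - par_i), hw1 * (1 - par_i), hw2 * rr * (1 - par_i))
  }
}

sample_genotypes <- function(n_ind, probs) {
  vapply(seq_len(nrow(probs)),
         function(i) sample(0:2, n_ind, replace = TRUE, prob = probs[i, ]),
         integer(n_ind))
}

#' Simulate a PAR-apportioned case-control cohort
#'
#' For each causal site: draw the MAF, form the risk-genotype frequency
#' (`1-(1-p)^2` dominant, `p^2` recessive), solve the relative risk from
#' the PAR share, and sample case genotypes from the Bayes-inverted
#' genotype distribution (`P(G|case) \propto P(case|G) P(G)`; sites
#' independent under the multiplicative risk model, no linkage
#' disequilibrium). Controls use Hardy-Weinberg population frequencies
#' (rare-disease approximation). Noncausal sites are Hardy-Weinberg in
#' both cohorts. Causal sites are annotated as high-conservation missense
#' or nonsense changes; noncausal sites as low-conservation benign-profile
#' substitutions.
#'
#' @param config a [simulation_config()].
#' @return a `sim_cohort` (also a `cc_cohort`): annotated variant table,
#'   genotypes, phenotype, plus `$truth` (per-site causal flag, MAF,
#'   relative risk) and `$config`.
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nd <- config$nd; nn <- config$n_noncausal
  par_i <- config$total_par / nd
  p <- draw_maf(nd, config$maf_distribution)
  pn <- if (nn > 0) draw_maf(nn, config$maf_distribution) else numeric(0)
  g <- if (config$inheritance == "dominant") 1 - (1 - p)^2 else p^2
  rr <- par_to_relative_risk(par_i, g)
  probs_case <- case_genotype_probs(p, rr, par_i, config$inheritance)
  probs_pop <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  probs_pop_n <- cbind((1 - pn)^2, 2 * pn * (1 - pn), pn^2)

  gc_causal <- t(sample_genotypes(config$n_cases, probs_case))
  gb_causal <- t(sample_genotypes(config$n_controls, probs_pop))
  geno <- rbind(cbind(gc_causal, gb_causal))
  if (nn > 0) {
    gc_non <- t(sample_genotypes(config$n_cases, probs_pop_n))
    gb_non <- t(sample_genotypes(config$n_controls, probs_pop_n))
    geno <- rbind(geno, cbind(gc_non, gb_non))
  }
  colnames(geno) <- sprintf("S%05d", seq_len(ncol(geno)))
  phenotype <- rep(c("case", "control"),
                   c(config$n_cases, config$n_controls))

  k <- nd + nn
  causal <- c(rep(TRUE, nd), rep(FALSE, nn))
  variants <- simulated_site_annotation(k, causal, gene = "GENE1")
  cohort <- case_control_cohort(variants, geno, phenotype)
  cohort$truth <- data.frame(site = seq_len(k), causal = causal,
                             maf = c(p, pn),
                             relative_risk = c(rr, rep(1, nn)))
  cohort$config <- config
  class(cohort) <- c("sim_cohort", class(cohort))
  cohort
}

# Annotation rows for simulated sites: causal sites look like damaging
# coding changes (high conservation, radical/nonsense substitutions),
# noncausal sites like benign ones.
simulated_site_annotation <- function(k, causal, gene, chrom = "1",
                                      pos0 = 0L) {
  profile <- ifelse(causal, "damaging", "benign")
  aas <- sample_aas(k, profile)
  cons <- ifelse(causal, stats::rbeta(k, 8, 2), stats::rbeta(k, 2, 8))
  data.frame(chrom = chrom, pos = pos0 + seq_len(k) * 3L,
             id = sprintf("%s_v%d", gene, seq_len(k)),
             ref = "A", alt = "G", gene = gene,
             consequence = ifelse(aas$alt_aa == "*", "stop_gain", "missense"),
             ref_aa = aas$ref_aa, alt_aa = aas$alt_aa,
             indel_kind = NA_character_, indel_length = NA_integer_,
             frame_disrupting = NA, conservation = round(cons, 4),
             stringsAsFactors = FALSE)
}

# Draw AAS types under a damaging or benign substitution profile.
sample_aas <- function(n, profile) {
  types <- aas_types()
  rg <- aa_property_group(types$ref_aa)
  ag <- aa_property_group(types$alt_aa)
  w_damaging <- ifelse(ag == "stop", 10,
                       ifelse(rg == "stop", 0.5, ifelse(rg != ag, 3, 1)))
  w_benign <- ifelse(ag == "stop" | rg == "stop", 0.05,
                     ifelse(rg != ag, 0.5, 1))
  idx <- vapply(profile, function(pr) {
    w <- switch(pr, damaging = w_damaging, benign = w_benign,
                uniform = rep(1, nrow(types)))
    sample.int(nrow(types), 1, prob = w)
  }, 0L)
  types[idx, c("ref_aa", "alt_aa"), drop = FALSE]
}

#' Simulate a stratified-population null cohort
#'
#' Two subpopulations differentiated at level `fst` around shared
#' ancestral MAFs (Balding-Nichols beta model); no causal sites. Cases and
#' controls draw their individuals from the subpopulations at the
#' configured mixing ratios, so unbalanced mixes (e.g. 7:3 in cases vs 3:7
#' in controls) create spurious case-control frequency differences while
#' balanced mixes do not. Genotypes are Hardy-Weinberg within
#' subpopulation.
#'
#' @param config a [simulation_config()] whose `stratification` element is
#'   a list with `fst` and mixing proportions `case_mix`, `control_mix`
#'   (each length 2, summing to 1).
#' @return a `sim_cohort` with per-individual subpopulation labels in
#'   `$subpop` and per-site subpopulation frequencies in `$truth`.
#' @export
simulate_stratified <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$stratification
  if (is.null(st)) stop("config$stratification is required", call. = FALSE)
  set.seed(config$seed)
  k <- config$nd + config$n_noncausal
  p_anc <- draw_maf(k, config$maf_distribution)
  fst <- st$fst
  subfreq <- function(p) {
    if (fst == 0) return(cbind(p, p))
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    cbind(stats::rbeta(k, a, b), stats::rbeta(k, a, b))
  }
  ps <- subfreq(p_anc)
  ps <- pmin(pmax(ps, 1e-8), 1 - 1e-8)

  mix_counts <- function(n, mix) {
    n1 <- round(n * mix[1])
    c(n1, n - n1)
  }
  nc <- mix_counts(config$n_cases, st$case_mix)
  nb <- mix_counts(config$n_controls, st$control_mix)
  subpop <- c(rep(1:2, nc), rep(1:2, nb))
  phenotype <- rep(c("case", "control"),
                   c(config$n_cases, config$n_controls))
  geno <- vapply(seq_along(subpop), function(j)
    stats::rbinom(k, 2, ps[, subpop[j]]), integer(k))
  geno <- matrix(geno, nrow = k)
  colnames(geno) <- sprintf("S%05d", seq_len(ncol(geno)))

  variants <- simulated_site_annotation(k, rep(FALSE, k), gene = "GENE1")
  cohort <- case_control_cohort(variants, geno, phenotype)
  cohort$truth <- data.frame(site = seq_len(k), causal = FALSE,
                             maf = p_anc, p_sub1 = ps[, 1], p_sub2 = ps[, 2])
  cohort$subpop <- subpop
  cohort$config <- config
  class(cohort) <- c("sim_cohort", class(cohort))
  cohort
}

#' Spike known causal alleles into healthy background genomes
#'
#' Builds a synthetic multi-gene background panel (a stand-in for a
#' reference set of healthy personal genomes): `n_genes` genes, each with
#' a Poisson number of segregating coding sites whose MAFs follow
#' `background_maf` (spanning rare through common variation, including
#' common nonsynonymous SNVs). One to a few case genomes are then drawn
#' from the same population and given published-style causal alleles in
#' the target gene: under the dominant scenario one distinct allele per
#' case genome; under the recessive scenario two distinct alleles per
#' case. Causal alleles are absent from the background and carry
#' high-severity annotations (nonsense or radical missense at
#' conservation `causal_conservation`).
#'
#' @param n_genes number of background genes.
#' @param n_background number of background (control) genomes.
#' @param n_cases number of case genomes (1-3 in the benchmark protocol).
#' @param inheritance `"dominant"` or `"recessive"`.
#' @param sites_per_gene Poisson mean number of segregating sites per gene.
#' @param background_maf MAF law for background sites.
#' @param causal_conservation conservation score given to spiked alleles.
#' @param target_gene index of the gene receiving the spiked alleles.
#' @param target_capacity maximum number of distinct causal alleles the
#'   target gene can host; exceeding it is an error (gene too short).
#' @param seed RNG seed.
#' @return a `sim_cohort`; `$truth$target` names the spiked gene.
#' @export
spike_in_mendelian <- function(n_genes = 2000, n_background = 200,
                               n_cases = 1,
                               inheritance = c("dominant", "recessive"),
                               sites_per_gene = 6,
                               background_maf = list(name = "loguniform",
                                                     min = 1e-4, max = 0.2),
                               causal_conservation = 0.98,
                               target_gene = 1, target_capacity = 1000,
                               seed = 1) {
  inheritance <- match.arg(inheritance)
  set.seed(seed)
  alleles_per_case <- if (inheritance == "dominant") 1L else 2L
  n_spike <- n_cases * alleles_per_case
  if (n_spike > target_capacity)
    stop("target gene too short to host ", n_spike, " distinct causal alleles",
         call. = FALSE)

  n_sites <- pmax(1L, stats::rpois(n_genes, sites_per_gene))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  gene_of_site <- rep(gene_ids, n_sites)
  k <- length(gene_of_site)
  p <- draw_maf(k, background_maf)
  n_ind <- n_background + n_cases
  geno <- matrix(stats::rbinom(k * n_ind, 2, rep(p, n_ind)), nrow = k)

  causal_flag <- rep(FALSE, k)
  variants <- simulated_site_annotation(k, causal_flag, gene = "BG")
  variants$gene <- gene_of_site
  variants$id <- sprintf("%s_v%d", gene_of_site,
                         unlist(lapply(n_sites, seq_len)))
  # benign-profile background; consequence mix of missense and synonymous
  syn <- stats::runif(k) < 0.4
  variants$consequence[syn] <- "synonymous"
  variants$ref_aa[syn] <- NA; variants$alt_aa[syn] <- NA

  target <- gene_ids[target_gene]
  spike_ann <- simulated_site_annotation(n_spike, rep(TRUE, n_spike),
                                         gene = target, pos0 = 10L * k)
  spike_ann$conservation <- causal_conservation
  spike_ann$id <- sprintf("%s_spike%d", target, seq_len(n_spike))
  spike_geno <- matrix(0L, n_spike, n_ind)
  for (j in seq_len(n_cases)) {
    rows <- ((j - 1) * alleles_per_case + 1):(j * alleles_per_case)
    spike_geno[rows, j] <- 1L
  }
  variants <- rbind(variants, spike_ann)
  geno <- rbind(geno, spike_geno)
  colnames(geno) <- sprintf("S%05d", seq_len(n_ind))
  phenotype <- rep(c("case", "control"), c(n_cases, n_background))
  cohort <- case_control_cohort(variants, geno, phenotype)
  cohort$truth <- list(target = target, n_cases = n_cases,
                       inheritance = inheritance,
                       spiked = spike_ann$id)
  cohort$config <- list(seed = seed, n_genes = n_genes,
                        n_background = n_background)
  class(cohort) <- c("sim_cohort", class(cohort))
  cohort
}

#' Generate synthetic disease / neutral training sets
#'
#' Synthetic stand-ins for a curated disease-mutation database and a
#' common-variant neutral set. Disease variants draw conservation from a
#' high-mean beta law and substitution types from a damaging-enriched
#' profile (nonsense and cross-property-group missense changes
#' over-represented); neutral variants draw low-mean conservation and a
#' benign profile. A fraction of each set is indels, frameshift-enriched
#' on the disease side. With `profile = "uniform"` for both sets and
#' identical conservation laws the two sets are exchangeable and all
#' trained severities are ~1.
#'
#' @param n_disease,n_neutral set sizes (`>= 1`).
#' @param disease_conservation,neutral_conservation beta shape pairs for
#'   the conservation mixtures.
#' @param disease_profile,neutral_profile `"damaging"`, `"benign"` or
#'   `"uniform"` substitution-type profiles.
#' @param enrichment optional named vector of multiplicative weights on
#'   specific AAS types (names like `"V>A"`) applied to the disease draw.
#' @param indel_fraction fraction of each set that is indels.
#' @param seed RNG seed.
#' @return list with elements `disease` and `neutral` (training-variant
#'   data frames for [train_casm()]).
#' @export
generate_training_sets <- function(n_disease = 2000, n_neutral = 2000,
                                   disease_conservation = c(8, 2),
                                   neutral_conservation = c(2, 8),
                                   disease_profile = "damaging",
                                   neutral_profile = "benign",
                                   enrichment = NULL,
                                   indel_fraction = 0.1, seed = 1) {
  if (n_disease < 1 || n_neutral < 1)
    stop("training set sizes must be >= 1", call. = FALSE)
  for (sh in list(disease_conservation, neutral_conservation)) {
    if (length(sh) != 2 || any(sh <= 0))
      stop("conservation mixture parameters must be two positive beta shapes",
           call. = FALSE)
  }
  set.seed(seed)
  one_set <- function(n, shapes, profile, enrich, fs_weight) {
    n_indel <- round(n * indel_fraction)
    n_aas <- n - n_indel
    types <- aas_types()
    rg <- aa_property_group(types$ref_aa)
    ag <- aa_property_group(types$alt_aa)
    w <- switch(profile,
      damaging = ifelse(ag == "stop", 10,
                        ifelse(rg == "stop", 0.5,
                               ifelse(rg != ag, 3, 1))),
      benign = ifelse(ag == "stop" | rg == "stop", 0.05,
                      ifelse(rg != ag, 0.5, 1)),
      uniform = rep(1, nrow(types)),
      stop("unknown profile '", profile, "'", call. = FALSE))
    if (!is.null(enrich)) {
      i <- match(names(enrich), types$type)
      if (anyNA(i)) stop("unknown AAS type in enrichment: ",
                         paste(names(enrich)[is.na(i)], collapse = ", "),
                         call. = FALSE)
      w[i] <- w[i] * enrich
    }
    idx <- sample.int(nrow(types), n_aas, replace = TRUE, prob = w)
    aas <- data.frame(class = "aas",
                      ref_aa = types$ref_aa[idx], alt_aa = types$alt_aa[idx],
                      indel_kind = NA_character_, indel_length = NA_integer_,
                      conservation = round(stats::rbeta(n_aas, shapes[1],
                                                        shapes[2]), 4),
                      stringsAsFactors = FALSE)
    if (n_indel == 0) return(aas)
    len <- sample(1:12, n_indel, replace = TRUE,
                  prob = ifelse(1:12 %% 3 == 0, 1, fs_weight))
    ind <- data.frame(class = "indel",
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      indel_kind = sample(c("insertion", "deletion"),
                                          n_indel, replace = TRUE),
                      indel_length = len,
                      conservation = NA_real_, stringsAsFactors = FALSE)
    rbind(aas, ind)
  }
  list(disease = one_set(n_disease, disease_conservation, disease_profile,
                         enrichment, fs_weight = 4),
       neutral = one_set(n_neutral, neutral_conservation, neutral_profile,
                         NULL, fs_weight = 0.25))
}

#' Read / write training-variant tables
#'
#' Tab-separated with columns `class`, `ref_aa`, `alt_aa`, `indel_kind`,
#' `indel_length`, `conservation`.
#'
#' @param tv training-variant data frame.
#' @param path file path.
#' @export
write_training_tsv <- function(tv, path) {
  utils::write.table(tv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_tsv
#' @export
read_training_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
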