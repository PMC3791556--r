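# Fixture builders: all test data is constructed in code.

# Toy plus-strand gene: 10 bp of upstream sequence, then CDS ATG GTG TAA
# (M V stop) at genomic positions 11..19, then 10 bp downstream.
toy_reference <- function() {
  c(chr1 = paste0("AAAAAAAAAA", "ATGGTGTAA", "CCCCCCCCCC"))
}

toy_gene_plus <- function() {
  gene_model("toyP", "chr1", "+", data.frame(start = 11, end = 19),
             reference = toy_reference())
}

# Mirror gene on the minus strand encoding the same CDS: the genomic
# segment at 11..19 is the reverse complement of ATGGTGTAA.
toy_reference_minus <- function() {
  c(chr1 = paste0("AAAAAAAAAA", "TTACACCAT", "CCCCCCCCCC"))
}

toy_gene_minus <- function() {
  gene_model("toyM", "chr1", "-", data.frame(start = 11, end = 19),
             reference = toy_reference_minus())
}

# A longer two-exon gene used for indel and enumeration tests:
# CDS = ATG GTT CCA TGG GAT TAA (M V P W D stop), split across two exons
# with a 5-bp intron. Exon1 = positions 6..14 (9 nt), intron 15..19,
# exon2 = positions 20..28 (9 nt).
twoexon_reference <- function() {
  c(chr2 = paste0("GGGGG", "ATGGTTCCA", "TTTTT", "TGGGATTAA", "GGGGG"))
}

twoexon_gene <- function() {
  gene_model("twoexon", "chr2", "+",
             data.frame(start = c(6, 20), end = c(14, 28)),
             reference = twoexon_reference())
}

# Small trained severity matrix shared across tests (deterministic).
test_casm <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      ts <- generate_training_sets(n_disease = 1500, n_neutral = 1500,
                                   seed = 2024)
      cached <<- train_casm(ts$disease, ts$neutral)
    }
    cached
  }
})

complement_base_t <- function(x) chartr("ACGT", "TGCA", x)

# Annotation rows for hand-built cohorts.
ann_row <- function(gene, consequence = "synonymous", ref_aa = NA,
                    alt_aa = NA, conservation = NA, indel_kind = NA,
                    indel_length = NA, frame_disrupting = NA, pos = 1L,
                    chrom = "1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, id = NA_character_, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             ref_aa = ref_aa, alt_aa = alt_aa, indel_kind = indel_kind,
             indel_length = indel_length,
             frame_disrupting = frame_disrupting,
             conservation = conservation, stringsAsFactors = FALSE)
}

# Hand-built cohort from a dosage matrix (variants x individuals).
toy_cohort <- function(geno, n_cases, variants) {
  geno <- matrix(as.integer(geno), nrow = nrow(variants))
  colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
  phen <- rep(c("case", "control"), c(n_cases, ncol(geno) - n_cases))
  case_control_cohort(variants, geno, phen)
}
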