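#' Protein-coding gene model
#'
#' A minimal transcript-level gene model: a chromosome, a strand and an
#' ordered set of CDS intervals, plus the coding-strand CDS sequence
#' (supplied directly or extracted from a reference). Coordinates are
#' 1-based inclusive at this boundary (VCF/GFF3 convention); all interval
#' arithmetic inside the package converts as needed.
#'
#' Validation warns (and keeps the model) when the concatenated CDS length
#' is not divisible by 3, does not begin with a start codon, or contains an
#' internal stop; these are common artifacts of partial gene models and
#' should not abort an annotation run.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals data frame or 2-column matrix of `start`, `end`
#'   (1-based inclusive genomic coordinates); stored sorted in ascending
#'   genomic order, which is transcription order for `+` and its mirror
#'   for `-`.
#' @param reference named character vector or `Biostrings::DNAStringSet`
#'   holding the chromosome sequence (used to derive `cds_sequence`).
#' @param cds_sequence coding-strand CDS nucleotide string; derived from
#'   `reference` when omitted.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_intervals,
                       reference = NULL, cds_sequence = NULL,
                       transcript_id = gene_id) {
  stopifnot(strand %in% c("+", "-"))
  iv <- as.data.frame(cds_intervals)
  names(iv)[1:2] <- c("start", "end")
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  if (any(iv$end < iv$start))
    stop("CDS interval with end < start in gene ", gene_id, call. = FALSE)
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
    stop("overlapping CDS intervals in gene ", gene_id, call. = FALSE)

  if (is.null(cds_sequence)) {
    if (is.null(reference))
      stop("either cds_sequence or reference must be given", call. = FALSE)
    chrom_seq <- extract_chrom_seq(reference, chrom)
    pieces <- substring(chrom_seq, iv$start, iv$end)
    cds_sequence <- paste(pieces, collapse = "")
    if (strand == "-") cds_sequence <- revcomp(cds_sequence)
  }
  cds_sequence <- toupper(cds_sequence)
  len <- nchar(cds_sequence)
  if (len != sum(iv$end - iv$start + 1))
    stop("cds_sequence length does not match CDS intervals for gene ",
         gene_id, call. = FALSE)
  if (len %% 3 != 0)
    warning("CDS length of gene ", gene_id, " (", len,
            ") is not divisible by 3; keeping model", call. = FALSE)
  if (len >= 3) {
    aa <- translate_cds(cds_sequence)
    if (substr(cds_sequence, 1, 3) != "ATG")
      warning("CDS of gene ", gene_id, " does not begin with ATG",
              call. = FALSE)
    internal <- substr(aa, 1, max(0, nchar(aa) - 1))
    if (grepl("*", internal, fixed = TRUE))
      warning("CDS of gene ", gene_id, " contains an internal stop codon",
              call. = FALSE)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 cds_intervals = iv, cds_sequence = cds_sequence),
            class = "gene_model")
}

extract_chrom_seq <- function(reference, chrom) {
  if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    i <- match(chrom, nm)
    if (is.na(i)) stop("chromosome ", chrom, " not found in reference",
                       call. = FALSE)
    return(as.character(reference[[i]]))
  }
  if (!chrom %in% names(reference))
    stop("chromosome ", chrom, " not found in reference", call. = FALSE)
  toupper(reference[[chrom]])
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

translate_cds <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Map a genomic position to a 1-based CDS coordinate on the coding strand,
# or NA when the position falls outside every CDS interval.
genomic_to_cds <- function(model, pos) {
  iv <- model$cds_intervals
  widths <- iv$end - iv$start + 1
  before <- c(0, cumsum(widths))[-(nrow(iv) + 1)]
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (length(hit) == 0) return(NA_integer_)
  fwd <- before[hit] + (pos - iv$start[hit] + 1)
  if (model$strand == "+") as.integer(fwd)
  else as.integer(sum(widths) - fwd + 1)
}

cds_overlap_length <- function(model, start, end) {
  iv <- model$cds_intervals
  sum(pmax(0, pmin(iv$end, end) - pmax(iv$start, start) + 1))
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s, strand %s): %d CDS interval(s), CDS %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$cds_intervals),
              nchar(x$cds_sequence)))
  invisible(x)
}

#' Read gene models from GFF3 + FASTA
#'
#' Imports CDS features from a GFF3 file, groups them by transcript, picks
#' the longest-CDS transcript per gene (so each variant receives a single
#' deterministic annotation), and extracts coding sequences from the FASTA
#' reference.
#'
#' @param gff3_path GFF3 file with `CDS` features carrying `Parent`
#'   attributes (transcript features with `Parent` gene attributes are used
#'   to resolve gene ids when present).
#' @param fasta_path reference FASTA.
#' @return named list of [gene_model()] objects (one per gene).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path)
  df <- as.data.frame(gr)
  reference <- Biostrings::readDNAStringSet(fasta_path)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("no CDS features in ", gff3_path, call. = FALSE)
  first_chr <- function(x) if (length(x) == 0) NA_character_ else as.character(x[[1]])
  cds$tx <- vapply(seq_len(nrow(cds)), function(i) {
    p <- cds$Parent[[i]]
    if (length(p) > 0) as.character(p[1])
    else if (!is.null(cds$ID)) as.character(cds$ID[i]) else NA_character_
  }, "")
  # transcript -> gene map from mRNA/transcript features
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- if (nrow(tx_rows) > 0) {
    stats::setNames(
      vapply(seq_len(nrow(tx_rows)), function(i) {
        p <- tx_rows$Parent[[i]]
        if (length(p) > 0) as.character(p[1]) else as.character(tx_rows$ID[i])
      }, ""),
      as.character(tx_rows$ID))
  } else character(0)

  models <- list()
  for (tx in unique(cds$tx)) {
    rows <- cds[cds$tx == tx, , drop = FALSE]
    gene <- if (tx %in% names(tx2gene)) tx2gene[[tx]] else tx
    len <- sum(rows$end - rows$start + 1)
    if (!is.null(models[[gene]]) && models[[gene]]$len >= len) next
    models[[gene]] <- list(
      gene = gene, tx = tx, len = len,
      chrom = as.character(rows$seqnames[1]),
      strand = as.character(rows$strand[1]),
      iv = data.frame(start = rows$start, end = rows$end))
  }
  out <- lapply(models, function(m)
    gene_model(m$gene, m$chrom, m$strand, m$iv, reference = reference,
               transcript_id = m$tx))
  names(out) <- vapply(out, function(g) g$gene_id, "")
  out
}
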