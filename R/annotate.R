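#' Annotate a single-nucleotide variant against a gene model
#'
#' Maps the variant position into the coding sequence (strand-aware),
#' substitutes the alternate base into the affected codon, and translates
#' both codons with the standard genetic code. Stop codons are represented
#' by `*`, so stop-gain and stop-loss changes carry an AAS type just like
#' missense changes. Positions outside every CDS interval are annotated as
#' `noncoding`; a mismatch between the VCF reference allele and the gene
#' model's sequence is an error.
#'
#' @param v a variant: list or one-row data frame with `chrom`, `pos`
#'   (1-based), `ref`, `alt` (single bases for SNVs) and optionally `id`.
#' @param model a [gene_model()].
#' @return one-row annotation data frame (see [annotation_columns()]).
#' @export
annotate_snv <- function(v, model) {
  v <- as_variant(v)
  if (nchar(v$ref) != 1 || nchar(v$alt) != 1)
    stop("annotate_snv() expects a single-nucleotide substitution",
         call. = FALSE)
  av <- empty_annotation(v, model$gene_id)
  if (v$chrom != model$chrom) {
    av$gene <- NA_character_
    return(av)
  }
  cds_pos <- genomic_to_cds(model, v$pos)
  if (is.na(cds_pos)) return(av)  # noncoding, not an error

  coding_ref <- if (model$strand == "+") v$ref else complement_base(v$ref)
  coding_alt <- if (model$strand == "+") v$alt else complement_base(v$alt)
  have <- substr(model$cds_sequence, cds_pos, cds_pos)
  if (have != toupper(coding_ref))
    stop(sprintf(
      "reference mismatch at %s:%d: VCF ref '%s' vs gene model '%s' (%s)",
      v$chrom, v$pos, v$ref,
      if (model$strand == "+") have else complement_base(have),
      model$gene_id), call. = FALSE)

  codon_i <- (cds_pos - 1) %/% 3
  within <- (cds_pos - 1) %% 3 + 1
  codon_start <- codon_i * 3 + 1
  ref_codon <- substr(model$cds_sequence, codon_start, codon_start + 2)
  if (nchar(ref_codon) < 3) return(av)  # trailing partial codon: keep noncoding
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- toupper(coding_alt)
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) return(av)

  if (ref_aa == alt_aa) {
    av$consequence <- "synonymous"
  } else {
    av$consequence <- if (alt_aa == "*") "stop_gain"
                      else if (ref_aa == "*") "stop_loss"
                      else "missense"
    av$ref_aa <- ref_aa
    av$alt_aa <- alt_aa
  }
  av
}

#' Annotate an insertion or deletion against a gene model
#'
#' Uses the VCF left-anchored convention: for a deletion the removed bases
#' occupy `pos + 1 .. pos + L`; an insertion lands immediately after `pos`.
#' Only the CDS-overlapping portion of the event counts as the affected
#' length; an indel that straddles a CDS boundary is truncated to the
#' overlap and flagged with a message. The event disrupts the reading frame
#' iff the affected length is not a multiple of 3.
#'
#' @inheritParams annotate_snv
#' @return one-row annotation data frame.
#' @export
annotate_indel <- function(v, model) {
  v <- as_variant(v)
  lr <- nchar(v$ref); la <- nchar(v$alt)
  if (lr == la)
    stop("annotate_indel() expects an insertion or deletion", call. = FALSE)
  av <- empty_annotation(v, model$gene_id)
  if (v$chrom != model$chrom) {
    av$gene <- NA_character_
    return(av)
  }
  if (la > lr) {                                  # insertion
    len <- la - lr
    inside <- !is.na(genomic_to_cds(model, v$pos))
    if (!inside) return(av)
    affected <- len
  } else {                                        # deletion
    len <- lr - la
    affected <- cds_overlap_length(model, v$pos + 1, v$pos + len)
    if (affected == 0) return(av)
    if (affected < len)
      message(sprintf(
        "indel at %s:%d spans a CDS boundary; scoring the %d of %d deleted bases inside the CDS",
        v$chrom, v$pos, affected, len))
  }
  kind <- if (la > lr) "insertion" else "deletion"
  frame <- (affected %% 3L) != 0L
  av$consequence <- paste0(if (frame) "frameshift_" else "inframe_",
                           if (kind == "insertion") "ins" else "del")
  av$indel_kind <- kind
  av$indel_length <- as.integer(affected)
  av$frame_disrupting <- frame
  av
}

#' @rdname annotate_snv
#' @export
annotate_variant <- function(v, model) {
  v <- as_variant(v)
  if (nchar(v$ref) == 1 && nchar(v$alt) == 1) annotate_snv(v, model)
  else annotate_indel(v, model)
}

as_variant <- function(v) {
  v <- as.list(v)
  if (is.null(v$id)) v$id <- NA_character_
  stopifnot(!is.null(v$chrom), !is.null(v$pos), !is.null(v$ref),
            !is.null(v$alt))
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  if (identical(v$ref, v$alt)) stop("ref and alt must differ", call. = FALSE)
  v
}

#' Canonical annotation-table columns
#' @return character vector of column names used by annotation tables.
#' @export
annotation_columns <- function() {
  c("chrom", "pos", "id", "ref", "alt", "gene", "consequence",
    "ref_aa", "alt_aa", "indel_kind", "indel_length", "frame_disrupting",
    "conservation")
}

empty_annotation <- function(v, gene) {
  data.frame(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
             alt = v$alt, gene = gene, consequence = "noncoding",
             ref_aa = NA_character_, alt_aa = NA_character_,
             indel_kind = NA_character_, indel_length = NA_integer_,
             frame_disrupting = NA, conservation = NA_real_,
             stringsAsFactors = FALSE)
}

#' Attach per-site conservation scores to annotated variants
#'
#' The conservation score of an SNV is the score at its reference position;
#' for a deletion it is the arithmetic mean over the deleted reference
#' positions, and for an insertion the score at the anchor position.
#' Positions absent from the track follow the missing-score policy:
#' `"zero"` (default; treat as unconserved, so every variant stays
#' scoreable), `"na"`, or `"error"`.
#'
#' @param av annotation data frame (one or more rows).
#' @param scores a conservation track from [read_conservation()] or
#'   [conservation_track()].
#' @param missing missing-score policy.
#' @return `av` with the `conservation` column filled (always in `[0, 1]`
#'   under the `"zero"` policy).
#' @export
attach_conservation <- function(av, scores,
                                missing = c("zero", "na", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(scores, "conservation_track"))
  n_missing <- 0L
  av$conservation <- vapply(seq_len(nrow(av)), function(i) {
    lr <- nchar(av$ref[i]); la <- nchar(av$alt[i])
    pos <- if (lr > la) (av$pos[i] + 1):(av$pos[i] + (lr - la))
           else av$pos[i]
    key <- paste0(av$chrom[i], ":", pos)
    s <- unname(scores$score[key])
    if (anyNA(s)) {
      n_missing <<- n_missing + sum(is.na(s))
      if (missing == "error")
        stop("no conservation score at ", paste(key[is.na(s)], collapse = ", "),
             call. = FALSE)
      if (missing == "na") return(NA_real_)
      s[is.na(s)] <- 0
    }
    mean(s)
  }, 0)
  if (n_missing > 0 && missing == "zero")
    message(n_missing,
            " position(s) absent from the conservation track; scored as 0")
  av
}

#' Build / read a conservation score track
#'
#' `read_conservation()` accepts either a 3-column tab-separated table
#' (`chrom`, `pos`, `score`; 1-based positions) or 4-column bedGraph
#' (`chrom`, `start`, `end`, `score`; 0-based half-open, expanded to
#' per-position scores). Scores must lie in `[0, 1]`.
#'
#' @param path file path.
#' @param df data frame with columns `chrom`, `pos`, `score`.
#' @return an object of class `conservation_track`.
#' @export
read_conservation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (is.character(tab[1, 2])) {  # header line present
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, comment.char = "#")
  }
  if (ncol(tab) == 4) {           # bedGraph: expand half-open intervals
    rows <- lapply(seq_len(nrow(tab)), function(i)
      data.frame(chrom = tab[i, 1], pos = (tab[i, 2] + 1):tab[i, 3],
                 score = tab[i, 4], stringsAsFactors = FALSE))
    tab <- do.call(rbind, rows)
  } else if (ncol(tab) == 3) {
    names(tab) <- c("chrom", "pos", "score")
  } else {
    stop("conservation file must have 3 (chrom, pos, score) or 4 (bedGraph) columns",
         call. = FALSE)
  }
  conservation_track(tab)
}

#' @rdname read_conservation
#' @export
conservation_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(df)))
  if (any(df$score < 0 | df$score > 1))
    stop("conservation scores must lie in [0, 1]", call. = FALSE)
  structure(list(score = stats::setNames(as.numeric(df$score),
                                         paste0(df$chrom, ":", df$pos))),
            class = "conservation_track")
}

#' Annotate a variant table against a set of gene models
#'
#' For each variant, the containing gene (by CDS footprint span, same
#' chromosome) is located; variants inside no gene are annotated
#' `noncoding` with `gene = NA`. A conservation track may be attached in
#' the same call.
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optional `id`.
#' @param models named list of [gene_model()]s (e.g. from
#'   [read_gene_models()]).
#' @param conservation optional `conservation_track`.
#' @param missing missing-score policy passed to [attach_conservation()].
#' @return annotation data frame, one row per input variant.
#' @export
annotate_variants <- function(variants, models, conservation = NULL,
                              missing = "zero") {
  spans <- data.frame(
    gene = vapply(models, function(m) m$gene_id, ""),
    chrom = vapply(models, function(m) m$chrom, ""),
    start = vapply(models, function(m) min(m$cds_intervals$start), 0),
    end = vapply(models, function(m) max(m$cds_intervals$end), 0),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    hit <- which(spans$chrom == v$chrom & spans$start <= v$pos &
                   spans$end >= v$pos)
    if (length(hit) == 0) {
      av <- empty_annotation(as_variant(v), NA_character_)
    } else {
      av <- annotate_variant(v, models[[hit[1]]])
    }
    av
  })
  av <- do.call(rbind, rows)
  if (!is.null(conservation))
    av <- attach_conservation(av, conservation, missing = missing)
  av
}

#' Read / write annotation tables
#'
#' Plain tab-separated files with the columns of [annotation_columns()].
#'
#' @param av annotation data frame.
#' @param path file path.
#' @export
write_annotation <- function(av, path) {
  utils::write.table(av[, intersect(annotation_columns(), names(av))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
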