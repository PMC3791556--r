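#' Train a conservation-controlled amino-acid substitution severity matrix
#'
#' Estimates, for every ordered amino-acid substitution (AAS) type `i`, the
#' endpoint likelihoods of being disease-causing (`a_i1`, `a_i0`) and of
#' being nondamaging (`h_i1`, `h_i0`) at per-site conservation scores of 1
#' and 0 respectively. Each training variant `j` of type `i` carries a
#' conservation score `P_ij` in `[0, 1]` (a PhastCons-style probability that
#' the site is under negative selection) and contributes `P_ij` mass to the
#' conserved endpoint and `1 - P_ij` to the unconserved endpoint:
#'
#' \deqn{a_{i1} = \sum_j P_{ij} / C_D, \qquad a_{i0} = \sum_j (1-P_{ij}) / C_D}
#'
#' over the disease set (total size `C_D`), and analogously `h_i1`, `h_i0`
#' over the neutral set (size `C_N`). Insertion/deletion variants are
#' handled as categories (kind x length class x frame status) whose
#' disease/neutral proportions play the role of `a`/`h` directly, with no
#' conservation interpolation.
#'
#' The stored endpoints are the raw (pre-pseudocount) proportions; a
#' Laplace-style pseudocount `eps = 1/(C + m)` (with `C` the training-set
#' size and `m` the number of types of the relevant class) is added when
#' ratios are formed, so zero cells yield finite log-severities.
#'
#' @param disease,neutral training-variant data frames as produced by
#'   [generate_training_sets()] or [read_training_tsv()]: columns `class`
#'   (`"aas"` or `"indel"`), `ref_aa`, `alt_aa` (AAS rows),
#'   `indel_kind` (`"insertion"`/`"deletion"`), `indel_length` (positive
#'   integer), and `conservation` in `[0, 1]` (AAS rows; ignored for
#'   indels).
#' @return an object of class `casm`: endpoint tables for all 420 AAS types
#'   and the indel category grid, plus training metadata.
#' @seealso [severity_ratio()], [indel_severity()], [save_casm()]
#' @export
train_casm <- function(disease, neutral) {
  for (nm in c("disease", "neutral")) {
    df <- get(nm)
    if (!is.data.frame(df) || nrow(df) == 0)
      stop("the ", nm, " training set must be a non-empty data frame",
           call. = FALSE)
  }
  d <- normalize_training(disease, "disease")
  n <- normalize_training(neutral, "neutral")

  types <- aas_types()
  tally_aas <- function(tv) {
    v <- tv[tv$class == "aas", , drop = FALSE]
    if (nrow(v) > 0) check_aas_symbols(c(v$ref_aa, v$alt_aa))
    key <- aas_key(v$ref_aa, v$alt_aa)
    c_tot <- nrow(v)
    s1 <- vapply(types$type, function(t) sum(v$conservation[key == t]), 0)
    s0 <- vapply(types$type, function(t) sum(1 - v$conservation[key == t]), 0)
    list(e1 = if (c_tot > 0) s1 / c_tot else s1,
         e0 = if (c_tot > 0) s0 / c_tot else s0,
         n = c_tot)
  }
  da <- tally_aas(d)
  na <- tally_aas(n)

  aas <- data.frame(types,
                    a0 = unname(da$e0), a1 = unname(da$e1),
                    h0 = unname(na$e0), h1 = unname(na$e1),
                    stringsAsFactors = FALSE)

  cats <- indel_category_grid()
  tally_indel <- function(tv) {
    v <- tv[tv$class == "indel", , drop = FALSE]
    c_tot <- nrow(v)
    key <- indel_category_key(v$indel_kind, v$indel_length)
    cnt <- vapply(cats$category, function(k) sum(key == k), 0L)
    list(p = if (c_tot > 0) cnt / c_tot else as.numeric(cnt), n = c_tot)
  }
  di <- tally_indel(d)
  ni <- tally_indel(n)
  indel <- data.frame(cats, a = unname(di$p), h = unname(ni$p),
                      stringsAsFactors = FALSE)

  m_aas <- nrow(types)
  m_indel <- nrow(cats)
  structure(list(
    aas = aas,
    indel = indel,
    meta = list(
      C_D = da$n, C_N = na$n,
      C_D_indel = di$n, C_N_indel = ni$n,
      m_aas = m_aas, m_indel = m_indel,
      eps_a = 1 / (da$n + m_aas), eps_h = 1 / (na$n + m_aas),
      eps_a_indel = 1 / (di$n + m_indel), eps_h_indel = 1 / (ni$n + m_indel),
      alphabet = paste(aas_alphabet(), collapse = ""),
      length_classes = paste(indel_length_classes(), collapse = ","),
      version = as.character(utils::packageVersion("aggvar"))
    )
  ), class = "casm")
}

# Coerce a user training table to the canonical column layout and validate.
normalize_training <- function(tv, label) {
  if (!"class" %in% names(tv)) {
    tv$class <- ifelse(!is.na(tv$ref_aa) & nzchar(tv$ref_aa), "aas", "indel")
  }
  if (!all(tv$class %in% c("aas", "indel")))
    stop("training set '", label, "': class must be 'aas' or 'indel'",
         call. = FALSE)
  for (col in c("ref_aa", "alt_aa", "indel_kind", "indel_length",
                "conservation")) {
    if (!col %in% names(tv)) tv[[col]] <- NA
  }
  cons <- tv$conservation[tv$class == "aas"]
  if (anyNA(cons) || any(cons < 0 | cons > 1))
    stop("training set '", label,
         "': conservation must lie in [0, 1] for every AAS variant",
         call. = FALSE)
  tv
}

#' Interpolated severity ratio of an amino-acid substitution
#'
#' Returns the conservation-interpolated likelihood ratio that a variant of
#' the given AAS type is disease-causing rather than nondamaging:
#' \deqn{a_{ix}/h_{ix} = x \frac{a_{i1}}{h_{i1}} + (1-x) \frac{a_{i0}}{h_{i0}}}
#' where `x` is the variant's conservation score. The two endpoint ratios
#' are formed after adding the matrix's pseudocounts, so the result is
#' always finite and strictly positive; its natural log is the
#' conservation-aware classifier score for the substitution.
#'
#' @param casm a `casm` object from [train_casm()] or [load_casm()].
#' @param ref_aa,alt_aa one-letter amino-acid symbols (stop = `*`);
#'   vectorized.
#' @param conservation conservation score(s) in `[0, 1]`.
#' @return positive numeric vector of severity ratios.
#' @export
severity_ratio <- function(casm, ref_aa, alt_aa, conservation) {
  stopifnot(inherits(casm, "casm"))
  check_aas_symbols(c(ref_aa, alt_aa))
  if (any(ref_aa == alt_aa))
    stop("ref_aa and alt_aa must differ", call. = FALSE)
  if (anyNA(conservation) || any(conservation < 0 | conservation > 1))
    stop("conservation must lie in [0, 1]", call. = FALSE)
  key <- aas_key(ref_aa, alt_aa)
  idx <- match(key, casm$aas$type)
  if (anyNA(idx))
    stop("AAS type(s) unknown to the matrix: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  ea <- casm$meta$eps_a
  eh <- casm$meta$eps_h
  r1 <- (casm$aas$a1[idx] + ea) / (casm$aas$h1[idx] + eh)
  r0 <- (casm$aas$a0[idx] + ea) / (casm$aas$h0[idx] + eh)
  conservation * r1 + (1 - conservation) * r0
}

#' Severity ratio of an indel category
#'
#' Indels are binned by kind (insertion/deletion), affected coding length
#' (classes 1, 2, 3, 4-9, >= 10) and frame status; the severity of a
#' category is the pseudocounted ratio of its disease-set and neutral-set
#' proportions, `(a_c + eps) / (h_c + eps)`. Conservation is not
#' interpolated for indels. A category absent from both training sets has
#' severity `eps/eps = 1` (uninformative).
#'
#' @inheritParams severity_ratio
#' @param kind `"insertion"` or `"deletion"`; vectorized.
#' @param length affected nucleotide length (>= 1) within the coding
#'   sequence.
#' @param frame_disrupting logical; defaults to `length %% 3 != 0`.
#' @return positive numeric vector of severity ratios.
#' @export
indel_severity <- function(casm, kind, length,
                           frame_disrupting = (length %% 3L) != 0L) {
  stopifnot(inherits(casm, "casm"))
  key <- indel_category_key(kind, length, frame_disrupting)
  idx <- match(key, casm$indel$category)
  if (anyNA(idx))
    stop("indel category unknown to the matrix: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  ea <- casm$meta$eps_a_indel
  eh <- casm$meta$eps_h_indel
  (casm$indel$a[idx] + ea) / (casm$indel$h[idx] + eh)
}

indel_length_classes <- function() c("1", "2", "3", "4-9", "10+")

indel_length_class <- function(length) {
  if (any(length < 1)) stop("indel length must be >= 1", call. = FALSE)
  ifelse(length <= 3, as.character(length),
         ifelse(length <= 9, "4-9", "10+"))
}

indel_category_grid <- function() {
  grid <- expand.grid(
    frame_disrupting = c(FALSE, TRUE),
    length_class = indel_length_classes(),
    kind = c("insertion", "deletion"),
    stringsAsFactors = FALSE
  )[, c("kind", "length_class", "frame_disrupting")]
  grid$category <- paste(grid$kind, grid$length_class,
                         ifelse(grid$frame_disrupting, "frameshift",
                                "inframe"),
                         sep = ":")
  rownames(grid) <- NULL
  grid
}

indel_category_key <- function(kind, length, frame_disrupting = NULL) {
  if (length(kind) == 0) return(character(0))
  if (!all(kind %in% c("insertion", "deletion")))
    stop("indel kind must be 'insertion' or 'deletion'", call. = FALSE)
  if (is.null(frame_disrupting)) frame_disrupting <- (length %% 3L) != 0L
  paste(kind, indel_length_class(length),
        ifelse(frame_disrupting, "frameshift", "inframe"), sep = ":")
}

#' Serialize / deserialize a severity matrix
#'
#' The on-disk format is a plain tab-separated table with `#key<TAB>value`
#' metadata header lines (training-set sizes, alphabet, length-class bins,
#' package version) followed by one row per AAS type or indel category.
#' The round trip is lossless.
#'
#' @param casm a `casm` object.
#' @param path file path.
#' @return `load_casm()` returns the reconstructed `casm` object.
#' @export
save_casm <- function(casm, path) {
  stopifnot(inherits(casm, "casm"))
  meta <- casm$meta
  hdr <- vapply(names(meta), function(k) paste0("#", k, "\t", meta[[k]]), "")
  aas <- data.frame(class = "aas", key = casm$aas$type,
                    ref_aa = casm$aas$ref_aa, alt_aa = casm$aas$alt_aa,
                    kind = NA, length_class = NA, frame_disrupting = NA,
                    a0 = casm$aas$a0, a1 = casm$aas$a1,
                    h0 = casm$aas$h0, h1 = casm$aas$h1,
                    stringsAsFactors = FALSE)
  ind <- data.frame(class = "indel", key = casm$indel$category,
                    ref_aa = NA, alt_aa = NA,
                    kind = casm$indel$kind,
                    length_class = casm$indel$length_class,
                    frame_disrupting = casm$indel$frame_disrupting,
                    a0 = casm$indel$a, a1 = NA,
                    h0 = casm$indel$h, h1 = NA,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(rbind(aas, ind), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_casm
#' @export
load_casm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed metadata at line ", i, " of ", path, call. = FALSE)
    meta[[kv[1]]] <- kv[2]
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  tab <- tryCatch(
    utils::read.table(text = lines[body_start:length(lines)], sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE,
                      na.strings = "NA"),
    error = function(e) stop("failed to parse ", path, " at or after line ",
                             body_start, ": ", conditionMessage(e),
                             call. = FALSE))
  need <- c("class", "key", "ref_aa", "alt_aa", "kind", "length_class",
            "frame_disrupting", "a0", "a1", "h0", "h1")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("severity-matrix file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  aas <- tab[tab$class == "aas", , drop = FALSE]
  ind <- tab[tab$class == "indel", , drop = FALSE]
  num <- function(x) as.numeric(x)
  for (k in c("C_D", "C_N", "C_D_indel", "C_N_indel", "m_aas", "m_indel",
              "eps_a", "eps_h", "eps_a_indel", "eps_h_indel")) {
    if (is.null(meta[[k]]))
      stop("severity-matrix file ", path, " is missing metadata '", k, "'",
           call. = FALSE)
    meta[[k]] <- num(meta[[k]])
  }
  structure(list(
    aas = data.frame(ref_aa = aas$ref_aa, alt_aa = aas$alt_aa,
                     type = aas$key, a0 = num(aas$a0), a1 = num(aas$a1),
                     h0 = num(aas$h0), h1 = num(aas$h1),
                     stringsAsFactors = FALSE),
    indel = data.frame(kind = ind$kind, length_class = ind$length_class,
                       frame_disrupting = as.logical(ind$frame_disrupting),
                       category = ind$key, a = num(ind$a0), h = num(ind$h0),
                       stringsAsFactors = FALSE),
    meta = meta
  ), class = "casm")
}

#' @exportS3Method base::print
print.casm <- function(x, ...) {
  cat("Conservation-controlled AAS severity matrix\n")
  cat(sprintf("  AAS types: %d (trained on %d disease / %d neutral variants)\n",
              nrow(x$aas), x$meta$C_D, x$meta$C_N))
  cat(sprintf("  indel categories: %d (%d disease / %d neutral variants)\n",
              nrow(x$indel), x$meta$C_D_indel, x$meta$C_N_indel))
  invisible(x)
}
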