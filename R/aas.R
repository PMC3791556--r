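#' Amino-acid alphabet and substitution types
#'
#' The severity matrix is indexed by ordered amino-acid substitution (AAS)
#' types over a 21-symbol alphabet: the 20 standard amino acids plus the
#' stop symbol `*`, so that nonsense (stop-gain) and stop-loss changes are
#' first-class AAS types.
#'
#' @return `aas_alphabet()` returns the 21 one-letter symbols;
#'   `aas_types()` returns all 420 ordered `ref_aa -> alt_aa` pairs
#'   (`ref != alt`) as a data frame with columns `ref_aa`, `alt_aa`, `type`.
#' @export
aas_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "*")
}

#' @rdname aas_alphabet
#' @export
aas_types <- function() {
  ab <- aas_alphabet()
  grid <- expand.grid(alt_aa = ab, ref_aa = ab,
                      stringsAsFactors = FALSE)[, c("ref_aa", "alt_aa")]
  grid <- grid[grid$ref_aa != grid$alt_aa, , drop = FALSE]
  grid$type <- paste0(grid$ref_aa, ">", grid$alt_aa)
  rownames(grid) <- NULL
  grid
}

# Coarse physicochemical grouping used only by the synthetic training-set
# generator to decide which substitutions count as "radical".
aa_property_group <- function(aa) {
  groups <- c(
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
    W = "hydrophobic", C = "hydrophobic",
    S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    G = "special", P = "special", `*` = "stop"
  )
  unname(groups[aa])
}

aas_key <- function(ref_aa, alt_aa) paste0(ref_aa, ">", alt_aa)

check_aas_symbols <- function(aa) {
  bad <- setdiff(unique(aa), aas_alphabet())
  if (length(bad) > 0)
    stop("unknown amino-acid symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
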