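#' Elemental formula of a (bio)molecule
#'
#' A minimal CHNOS+charge container used for protein chemistry.  Formulas
#' combine additively, element by element, so the formula of a peptide is the
#' sum of its residue formulas plus (optionally) one terminal water.
#'
#' @param c,h,n,o,s Non-negative atom counts (carbon, hydrogen, nitrogen,
#'   oxygen, sulfur).
#' @param z Net charge; the neutral-species convention (`z = 0`) is used for
#'   all proteins.
#' @return An object of class `elemental_formula`: a named list with fields
#'   `c`, `h`, `n`, `o`, `s`, `z`.
#' @examples
#' glycine <- elemental_formula(c = 2, h = 5, n = 1, o = 2)
#' zc(glycine)
#' @export
elemental_formula <- function(c = 0, h = 0, n = 0, o = 0, s = 0, z = 0) {
  counts <- c(c = c, h = h, n = n, o = o, s = s)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("atom counts must be finite and non-negative", call. = FALSE)
  structure(list(c = c, h = h, n = n, o = o, s = s, z = z),
            class = "elemental_formula")
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  elemental_formula(e1$c + e2$c, e1$h + e2$h, e1$n + e2$n,
                    e1$o + e2$o, e1$s + e2$s, e1$z + e2$z)
}

#' @export
format.elemental_formula <- function(x, ...) {
  el <- c(C = x$c, H = x$h, N = x$n, O = x$o, S = x$s)
  el <- el[el > 0]
  body <- paste0(names(el), ifelse(el == 1, "", el), collapse = "")
  if (x$z != 0) body <- paste0(body, " (", sprintf("%+d", x$z), ")")
  body
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

# Residue composition table (free amino acid minus one water), cached.
# Rows ordered as in the shipped resource; one row per one-letter code.
residue_table <- function() {
  if (is.null(.ventredox$residues)) {
    path <- system.file("extdata", "aa_residue_formulas.tsv",
                        package = "ventredox", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$code
    .ventredox$residues <- tab
  }
  .ventredox$residues
}

# 20 x 5 numeric matrix of residue atom counts, rownames = one-letter codes
residue_matrix <- function() {
  tab <- residue_table()
  as.matrix(tab[, c("c", "h", "n", "o", "s")])
}

#' Elemental formula of an amino-acid residue
#'
#' Returns the formula of the residue as incorporated in a peptide chain,
#' i.e. the free amino acid minus one water, with zero net charge.
#'
#' @param aa One-letter amino-acid code (case-insensitive).  Only the 20
#'   standard residues are supported; ambiguity codes and the rare residues
#'   selenocysteine (`U`) and pyrrolysine (`O`) signal an error of class
#'   `ventredox_unknown_residue` so that callers can choose a skip-or-fail
#'   policy.
#' @return An [elemental_formula].
#' @examples
#' residue_formula("G")  # C2H3NO
#' @export
residue_formula <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L)
  code <- toupper(aa)
  tab <- residue_table()
  if (!code %in% rownames(tab)) {
    cond <- structure(
      class = c("ventredox_unknown_residue", "error", "condition"),
      list(message = sprintf("unknown amino-acid code '%s'", aa),
           call = sys.call(-1)))
    stop(cond)
  }
  row <- tab[code, ]
  elemental_formula(row$c, row$h, row$n, row$o, row$s, z = 0)
}

# Split a sequence string into single characters (uppercased), with a
# trailing stop codon '*' stripped silently (common gene-caller dialect).
split_residues <- function(sequence) {
  sequence <- toupper(sequence)
  sequence <- sub("\\*+$", "", sequence)
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

#' Elemental formula of a protein sequence
#'
#' Sums residue formulas over the chain and, by convention, adds one water
#' for the free termini.  A trailing `*` (stop codon) is stripped silently.
#'
#' @param sequence Character string of one-letter residue codes.
#' @param terminal_water Add one H2O for the chain termini (default `TRUE`,
#'   the convention used for protein Z_C; the effect is negligible for
#'   chains much longer than ~10 residues).
#' @param on_nonstandard Policy for residues outside the 20 standard codes:
#'   `"drop"` removes them with a warning, `"fail"` signals an error.
#' @return An [elemental_formula] with zero net charge.
#' @examples
#' protein_formula("G")    # free glycine, C2H5NO2
#' protein_formula("GG")   # C4H8N2O3
#' @export
protein_formula <- function(sequence, terminal_water = TRUE,
                            on_nonstandard = c("drop", "fail")) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- split_residues(sequence)
  if (length(chars) == 0L)
    stop("empty protein sequence", call. = FALSE)
  mat <- residue_matrix()
  known <- chars %in% rownames(mat)
  if (any(!known)) {
    if (on_nonstandard == "fail")
      stop(sprintf("non-standard residue(s): %s",
                   paste(unique(chars[!known]), collapse = ", ")),
           call. = FALSE)
    warning(sprintf("dropping %d non-standard residue(s): %s",
                    sum(!known), paste(unique(chars[!known]), collapse = ", ")),
            call. = FALSE)
    chars <- chars[known]
  }
  if (length(chars) == 0L)
    stop("no standard residues left in sequence", call. = FALSE)
  counts <- table(factor(chars, levels = rownames(mat)))
  atoms <- as.numeric(counts) %*% mat
  f <- elemental_formula(atoms[1L], atoms[2L], atoms[3L], atoms[4L], atoms[5L])
  if (terminal_water) f <- f + elemental_formula(h = 2, o = 1)
  f
}

#' Average carbon oxidation state
#'
#' The mean nominal oxidation state of the carbon atoms of a molecule,
#' computed from its elemental formula as
#' \deqn{Z_C = (z - h + 3n + 2o + 2s) / c}
#' using the nominal states H = +1, N = -3, O = -2, S = -2 and net charge
#' `z`.  Lower values indicate chemically more reduced material; for
#' proteins Z_C is used as a proxy for the redox conditions under which a
#' community's proteome evolved.
#'
#' @param f An [elemental_formula] (or anything with numeric fields
#'   `c`, `h`, `n`, `o`, `s`, `z`).
#' @return Z_C as a single numeric value, in `[-4, 4]` for any chemically
#'   valid formula.
#' @examples
#' zc(protein_formula("G"))  # +1, glycine
#' zc(protein_formula("A"))  #  0, alanine
#' @export
zc <- function(f) {
  if (is.null(f$c) || f$c < 1)
    stop("Z_C is undefined for formulas without carbon", call. = FALSE)
  z <- if (is.null(f$z)) 0 else f$z
  (z - f$h + 3 * f$n + 2 * f$o + 2 * f$s) / f$c
}

# Vectorized proteome chemistry --------------------------------------------

# Per-protein atom counts, carbon-normalized Z_C and residue bookkeeping for
# a character vector of sequences.  Uses Biostrings letter counting; faster
# than per-protein formula objects and exact.
#
# Returns a data.frame with columns: length (standard residues kept),
# n_nonstandard, c, h, n, o, s (including terminal water if requested), zc.
proteome_chemistry <- function(sequences, terminal_water = TRUE) {
  sequences <- toupper(sequences)
  sequences <- sub("\\*+$", "", sequences)
  mat <- residue_matrix()
  aas <- Biostrings::AAStringSet(sequences)
  counts <- Biostrings::letterFrequency(aas, letters = rownames(mat))
  total_len <- Biostrings::width(aas)
  kept <- rowSums(counts)
  atoms <- counts %*% mat
  if (terminal_water) {
    atoms[, "h"] <- atoms[, "h"] + 2
    atoms[, "o"] <- atoms[, "o"] + 1
  }
  zc_vec <- ifelse(atoms[, "c"] >= 1,
                   (-atoms[, "h"] + 3 * atoms[, "n"] + 2 * atoms[, "o"] +
                      2 * atoms[, "s"]) / atoms[, "c"],
                   NA_real_)
  data.frame(length = kept,
             n_nonstandard = total_len - kept,
             c = atoms[, "c"], h = atoms[, "h"], n = atoms[, "n"],
             o = atoms[, "o"], s = atoms[, "s"], zc = zc_vec,
             row.names = NULL)
}

#' Z_C of the 20 standard residues
#'
#' @return Named numeric vector of residue (in-chain) Z_C values, ordered as
#'   in the shipped composition table.  Glycine attains the maximum (+1) and
#'   leucine/isoleucine the minimum (-1).
#' @export
residue_zc <- function() {
  mat <- residue_matrix()
  vals <- (-mat[, "h"] + 3 * mat[, "n"] + 2 * mat[, "o"] + 2 * mat[, "s"]) /
    mat[, "c"]
  setNames(as.numeric(vals), rownames(mat))
}
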