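# The 20 standard amino acids, in the conventional Ala..Val (three-letter
# alphabetical) order used for all matrix rows in this package.
AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA_ONE) <- AA_THREE

#' The standard amino-acid alphabet
#'
#' Returns the 20 standard amino acids as a tibble with the one-letter and
#' three-letter codes in matrix row order (Ala ... Val). All peptide and
#' matrix operations in the package are restricted to this alphabet;
#' ambiguity codes (X, B, Z), selenocysteine (U) and gaps are rejected on
#' input because the models define values only for the 20 standard residues.
#'
#' @return A tibble with columns `one` and `three`.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  tibble(one = unname(AA_ONE), three = AA_THREE)
}

#' Convert between one-letter and three-letter residue codes
#'
#' @param x Character vector of residue codes (all one-letter or all
#'   three-letter).
#' @return For `aa_to_one()`, a one-letter vector; for `aa_to_three()`, a
#'   three-letter vector. Unknown codes raise an error.
#' @export
#' @examples
#' aa_to_one(c("Glu", "Pro"))
#' aa_to_three(c("E", "P"))
aa_to_one <- function(x) {
  out <- ifelse(x %in% AA_ONE, x, AA_ONE[match(x, AA_THREE)])
  if (anyNA(out)) {
    abort(sprintf("unknown amino-acid code(s): %s",
                  paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' @rdname aa_to_one
#' @export
aa_to_three <- function(x) {
  out <- ifelse(x %in% AA_THREE, x, AA_THREE[match(x, AA_ONE)])
  if (anyNA(out)) {
    abort(sprintf("unknown amino-acid code(s): %s",
                  paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

# Indices (1..20) of the residues of an uppercase sequence string; NA for
# non-standard characters.
aa_index <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], AA_ONE)
}
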