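#' Round half away from zero
#'
#' Decimal rounding where ties go up (`0.15` to one decimal is `0.2`), matching
#' the convention used throughout the package's printed percentages and means.
#' Base [round()] rounds half to even and would print `0.1` there.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.15, 17.6667, 85.9497), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: standard genetic code lookup (codon -> amino acid, "*" = stop)
codon_table <- function() Biostrings::GENETIC_CODE

# internal: translate one codon, ambiguity -> "X"
translate_codon <- function(codon) {
  tab <- codon_table()
  aa <- unname(tab[codon])
  aa[is.na(aa)] <- "X"
  aa
}

# internal: complement / reverse complement on plain character strings
revcomp <- function(seq) {
  chartr("ACGTUacgtu", "TGCAATGCAA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

is_unambiguous <- function(base) base %in% c("A", "C", "G", "T")

transition_of <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[[base]]
}
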