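#' Global pairwise alignment of two genomes
#'
#' Optimal global alignment with affine gap penalties, computed by a banded
#' three-state (Gotoh) dynamic program restricted to diagonals
#' `|j - i| <= band_width`. Within the band the result equals the full
#' dynamic program; the default 600-nt band is far wider than the indel
#' spread of congeneric flavivirus genomes at >= 84% identity. A gap of
#' length k scores `gap_open + (k - 1) * gap_extend`. Traceback ties are
#' broken diagonal > up > left, so results are deterministic.
#'
#' @param ref,qry Reference and query: a one-row genome tibble (columns `id`,
#'   `sequence`) or a plain (optionally named) character string.
#' @param match,mismatch Per-column scores (defaults +1 / -1).
#' @param gap_open Score of the first base of a gap (default -4).
#' @param gap_extend Score of each further gap base (default -1).
#' @param band_width Band half-width in nt; must be at least the length
#'   difference of the two sequences (default 600).
#' @return A `pairwise_aln` object: list with `ref_id`, `qry_id`,
#'   `aligned_ref`, `aligned_qry`, `score`, `ref_coord_map` and
#'   `qry_coord_map` (per-column 1-based positions, `NA` in gap columns), and
#'   `params`.
#' @examples
#' aln <- global_align(c(ref = "ACGTACGT"), c(qry = "ACGAACGT"))
#' glance(aln)
#' @export
global_align <- function(ref, qry, match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1, band_width = 600) {
  r <- as_seq_entry(ref, "ref")
  q <- as_seq_entry(qry, "qry")
  if (nchar(r$sequence) == 0L || nchar(q$sequence) == 0L) {
    stop("sequences must be nonempty")
  }
  dlen <- abs(nchar(r$sequence) - nchar(q$sequence))
  if (band_width < dlen) {
    stop(sprintf(paste0("band_width (%d) is narrower than the length ",
                        "difference (%d); widen band_width"),
                 as.integer(band_width), dlen))
  }
  res <- .banded_align_cpp(r$sequence, q$sequence, match, mismatch,
                           gap_open, gap_extend, as.integer(band_width))
  new_pairwise_aln(r$id, q$id, res$aligned_ref, res$aligned_qry, res$score,
                   params = list(match = match, mismatch = mismatch,
                                 gap_open = gap_open, gap_extend = gap_extend,
                                 band_width = band_width))
}

as_seq_entry <- function(x, fallback_id) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    if (nrow(x) != 1L) stop("expected exactly one genome row")
    list(id = x$id[[1L]], sequence = x$sequence[[1L]])
  } else if (is.character(x) && length(x) == 1L) {
    id <- names(x)
    list(id = if (is.null(id) || !nzchar(id)) fallback_id else id,
         sequence = toupper(unname(x)))
  } else {
    stop("sequence input must be a one-row genome tibble or a character string")
  }
}

new_pairwise_aln <- function(ref_id, qry_id, aligned_ref, aligned_qry, score,
                             params = list()) {
  stopifnot(nchar(aligned_ref) == nchar(aligned_qry))
  rc <- strsplit(aligned_ref, "")[[1L]]
  qc <- strsplit(aligned_qry, "")[[1L]]
  if (any(rc == "-" & qc == "-")) stop("column with gap in both sequences")
  ref_map <- ifelse(rc == "-", NA_integer_, cumsum(rc != "-"))
  qry_map <- ifelse(qc == "-", NA_integer_, cumsum(qc != "-"))
  structure(list(ref_id = ref_id, qry_id = qry_id,
                 aligned_ref = aligned_ref, aligned_qry = aligned_qry,
                 score = score,
                 ref_coord_map = as.integer(ref_map),
                 qry_coord_map = as.integer(qry_map),
                 params = params),
            class = "pairwise_aln")
}

#' @export
print.pairwise_aln <- function(x, ...) {
  cat(sprintf("<pairwise_aln> %s vs %s: %d columns, score %.1f, identity %.1f%%\n",
              x$ref_id, x$qry_id, nchar(x$aligned_ref), x$score, identity_pct(x)))
  invisible(x)
}

#' Per-column tidy view of an alignment
#'
#' @param x A `pairwise_aln`.
#' @param ... Unused.
#' @return A tibble with one row per alignment column: `column`, `ref_pos`,
#'   `qry_pos`, `ref_base`, `qry_base`, `match`.
#' @exportS3Method generics::tidy
#' @export
tidy.pairwise_aln <- function(x, ...) {
  rc <- strsplit(x$aligned_ref, "")[[1L]]
  qc <- strsplit(x$aligned_qry, "")[[1L]]
  tibble::tibble(
    column = seq_along(rc),
    ref_pos = x$ref_coord_map,
    qry_pos = x$qry_coord_map,
    ref_base = rc,
    qry_base = qc,
    match = rc == qc & rc != "-"
  )
}

#' One-row summary of an alignment
#'
#' @param x A `pairwise_aln`.
#' @param ... Unused.
#' @return A one-row tibble with ids, column count, score, mismatch and gap
#'   column counts, and overall percent identity.
#' @exportS3Method generics::glance
#' @export
glance.pairwise_aln <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    ref_id = x$ref_id, qry_id = x$qry_id,
    columns = nrow(td),
    score = x$score,
    n_match = sum(td$match),
    n_mismatch = sum(!td$match & td$ref_base != "-" & td$qry_base != "-"),
    n_gap_cols = sum(td$ref_base == "-" | td$qry_base == "-"),
    identity = identity_pct(x)
  )
}

#' Percent identity of an alignment over an optional reference interval
#'
#' blastn-style identity on the shared span: the denominator counts every
#' column whose reference position lies in the interval plus internal gap
#' columns between them, excludes terminal overhangs (leading/trailing
#' columns where either sequence has not started/has ended), and excludes
#' columns containing IUPAC ambiguity codes. The numerator counts identical
#' unambiguous base columns. Rounded half-up to one decimal.
#'
#' @param aln A `pairwise_aln`.
#' @param ref_interval Optional `c(start, end)` 1-based inclusive reference
#'   coordinates; default the whole reference span.
#' @return Percentage (one decimal).
#' @export
identity_pct <- function(aln, ref_interval = NULL) {
  rc <- strsplit(aln$aligned_ref, "")[[1L]]
  qc <- strsplit(aln$aligned_qry, "")[[1L]]
  n <- length(rc)
  # terminal overhangs: columns before the first / after the last column in
  # which both sequences have a base
  both <- which(rc != "-" & qc != "-")
  if (length(both) == 0L) stop("alignment has no shared columns")
  core <- seq(min(both), max(both))
  refpos <- aln$ref_coord_map
  # anchor: last reference position emitted at or before this column
  anchor <- cummax(ifelse(is.na(refpos), 0L, refpos))
  if (is.null(ref_interval)) {
    keep <- core
  } else {
    s <- ref_interval[[1L]]; e <- ref_interval[[2L]]
    if (e < s) stop("empty interval")
    in_iv <- (!is.na(refpos) & refpos >= s & refpos <= e) |
      (is.na(refpos) & anchor >= s & anchor < e)
    keep <- intersect(core, which(in_iv))
  }
  ambig <- (rc != "-" & !(rc %in% c("A", "C", "G", "T"))) |
    (qc != "-" & !(qc %in% c("A", "C", "G", "T")))
  keep <- setdiff(keep, which(ambig))
  if (length(keep) == 0L) stop("empty interval: no comparable columns")
  matched <- sum(rc[keep] == qc[keep] & rc[keep] != "-")
  round_half_up(100 * matched / length(keep), 1)
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard genetic code (translation table 1). A terminal stop codon is
#' dropped; an internal stop is rendered `*` with a warning; any codon
#' containing a non-ACGT character translates to `X`.
#'
#' @param seq In-frame nucleotide string, length divisible by 3.
#' @return Amino acid string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- translate_codon(codons)
  aa[!grepl("^[ACGT]{3}$", codons)] <- "X"
  if (length(aa) > 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) warning("internal stop codon(s) rendered as '*'")
  paste(aa, collapse = "")
}

#' Export a pairwise alignment as aligned FASTA
#'
#' @param aln A `pairwise_aln`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(c(aln$aligned_ref, aln$aligned_qry))
  names(set) <- c(aln$ref_id, aln$qry_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
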