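#' Find forward-strand open reading frames
#'
#' Three-frame forward scan for `ATG ... stop` ORFs, the appropriate model
#' for a flavivirus genome with a single long polyprotein ORF; the reverse
#' strand is ignored. Coordinates are 1-based inclusive and include the stop
#' codon. Nested ORFs (inner ATGs sharing a stop) are all reported.
#'
#' @param genome One-row genome tibble or character sequence.
#' @param min_length Minimum ORF length in nt including the stop (default 300).
#' @return A tibble with columns `start`, `end`, `strand`, `length`, sorted by
#'   decreasing length.
#' @examples
#' find_orfs("AAATGTAAAA", min_length = 6)
#' @export
find_orfs <- function(genome, min_length = 300) {
  seq <- as_seq_entry(genome, "g")$sequence
  n <- nchar(seq)
  codonize <- function(from) {
    if (n - from + 1L < 3L) return(character(0))
    last <- from + ((n - from + 1L) %/% 3L) * 3L - 1L
    substring(seq, seq(from, last - 2L, 3L), seq(from + 2L, last, 3L))
  }
  out <- list()
  for (frame in 0:2) {
    codons <- codonize(frame + 1L)
    if (length(codons) == 0L) next
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (s in starts) {
      stp <- stops[stops >= s]
      if (length(stp) == 0L) next
      stp <- stp[[1L]]
      start_nt <- frame + 1L + (s - 1L) * 3L
      end_nt <- frame + 1L + stp * 3L - 1L
      len <- end_nt - start_nt + 1L
      if (len >= min_length) {
        out[[length(out) + 1L]] <- c(start_nt, end_nt, len)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1L], end = m[, 2L], strand = "+",
                 length = m[, 3L]) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$start)
}

#' Delineate untranslated regions around an ORF
#'
#' Everything upstream of the ORF is the 5' UTR; everything downstream is the
#' 3' UTR. Either may be empty.
#'
#' @param genome One-row genome tibble or character sequence.
#' @param orf List or one-row data frame with `start` and `end` (1-based,
#'   inclusive, including the stop codon).
#' @return A tibble with one row per UTR: `region`, `start`, `end`, `length`
#'   (empty UTRs have length 0 and `NA` coordinates).
#' @export
delineate_utrs <- function(genome, orf) {
  n <- nchar(as_seq_entry(genome, "g")$sequence)
  s <- orf$start[[1L]]; e <- orf$end[[1L]]
  if (s < 1L || e > n || s > e) stop("ORF outside genome")
  tibble::tibble(
    region = c("5UTR", "3UTR"),
    start = c(if (s > 1L) 1L else NA_integer_,
              if (e < n) e + 1L else NA_integer_),
    end = c(if (s > 1L) s - 1L else NA_integer_,
            if (e < n) n else NA_integer_),
    length = c(s - 1L, n - e)
  )
}

#' Transfer a reference region partition onto a query genome
#'
#' Maps each region's reference start/end through the alignment coordinate
#' map into query coordinates. A boundary falling in a query gap snaps inward
#' (start snaps right, end snaps left) so a region is never inflated with
#' unaligned bases. A region whose reference span is entirely deleted from
#' the query is flagged `missing`, never silently dropped.
#'
#' @param table A `region_tbl` in reference coordinates.
#' @param aln A `pairwise_aln` whose `ref_id` matches
#'   `attr(table, "reference_id")` (checked when both are non-`NA`).
#' @return A tibble like `table` with query-coordinate `start`/`end`, plus a
#'   logical `missing` column.
#' @export
transfer_regions <- function(table, aln) {
  ref_id <- attr(table, "reference_id")
  if (!is.na(ref_id) && !is.null(aln$ref_id) && ref_id != aln$ref_id) {
    stop(sprintf("region table refers to '%s' but alignment reference is '%s'",
                 ref_id, aln$ref_id))
  }
  refpos <- aln$ref_coord_map
  qrypos <- aln$qry_coord_map
  # query position aligned to each reference position (NA where query gapped)
  ref_len <- max(refpos, na.rm = TRUE)
  q_at_ref <- rep(NA_integer_, ref_len)
  ok <- !is.na(refpos)
  q_at_ref[refpos[ok]] <- qrypos[ok]
  map_boundary <- function(pos, lim, snap) {
    cand <- if (snap == "right") pos:lim else pos:1L
    hit <- which(!is.na(q_at_ref[cand]))
    if (length(hit) == 0L) NA_integer_ else q_at_ref[cand[hit[[1L]]]]
  }
  res <- purrr::pmap_dfr(table[, c("region", "start", "end", "kind")],
    function(region, start, end, kind) {
      if (start > ref_len || end > ref_len) stop("region outside alignment span")
      qs <- map_boundary(start, end, "right")
      qe <- map_boundary(end, start, "left")
      missing <- is.na(qs) || is.na(qe) || qs > qe
      tibble::tibble(region = region,
                     start = if (missing) NA_integer_ else qs,
                     end = if (missing) NA_integer_ else qe,
                     kind = kind, missing = missing)
    })
  res$length <- res$end - res$start + 1L
  attr(res, "reference_id") <- aln$qry_id
  res
}
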