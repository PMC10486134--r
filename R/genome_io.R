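#' Read genomes from a FASTA file
#'
#' Reads a (multi-)FASTA file into a tibble of genomes. Sequences are
#' uppercased and RNA `U` is normalized to `T` at ingest, so the whole package
#' works over a single DNA alphabet; the frameshift-site functions convert
#' back to RNA for display only. CRLF line endings and trailing blank lines
#' are tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id` (first token of
#'   the header), `description` (remainder of the header), `sequence`
#'   (uppercase DNA string) and `length` (nucleotide count).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x demo", "acgu"), tf)
#' read_fasta(tf)
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("no records: record with empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "U", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  allowed <- "ACGTNRYSWKMBDHV"
  for (k in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", allowed), seqs[[k]])
    if (bad > 0) {
      stop(sprintf("illegal character '%s' at position %d in record '%s'",
                   substr(seqs[[k]], bad, bad), bad, ids[[k]]))
    }
  }
  tibble::tibble(id = ids, description = unname(desc),
                 sequence = unname(seqs), length = nchar(unname(seqs)))
}

#' Write genomes to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then re-reading reproduces the input
#' sequences byte for byte.
#'
#' @param genomes Genome tibble (columns `id`, `sequence`, optionally
#'   `description`).
#' @param path Output path.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 60) {
  stopifnot(is.data.frame(genomes))
  if (nrow(genomes) == 0L) stop("no genomes to write")
  set <- Biostrings::BStringSet(genomes$sequence)
  desc <- if ("description" %in% names(genomes)) genomes$description else ""
  names(set) <- ifelse(nzchar(desc), paste(genomes$id, desc), genomes$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a genome region partition table
#'
#' Reads the TSV describing the mature-peptide/UTR partition of a flavivirus
#' genome in 1-based inclusive reference coordinates (columns `region`,
#' `start`, `end`, `kind` with `kind` one of `utr` or `mat_peptide`).
#' Mature-peptide regions must be non-overlapping and contiguous; the
#' polyprotein ORF span is the union of the mat-peptide regions. Regions may
#' split codons (the 69-nt 2K peptide does); codon phase is always taken from
#' the single ORF, not per region.
#'
#' @param path Path to the TSV file.
#' @param reference_id Optional id of the genome the coordinates refer to.
#' @return A `region_tbl`: a tibble with columns `region`, `start`, `end`,
#'   `kind`, `length`, sorted by `start`, carrying attributes `reference_id`,
#'   `orf_start`, `orf_end`.
#' @examples
#' path <- system.file("extdata", "qbv_regions.tsv", package = "flavicomp")
#' read_region_table(path)
#' @export
read_region_table <- function(path, reference_id = NA_character_) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    kind = readr::col_character()
  ), progress = FALSE)
  as_region_tbl(df, reference_id = reference_id)
}

#' Build a region table from a data frame
#'
#' Validates the partition invariants (see [read_region_table()]) and attaches
#' the ORF span derived from the mat-peptide regions.
#'
#' @param df Data frame with columns `region`, `start`, `end`, `kind`.
#' @param reference_id Optional genome id the coordinates refer to.
#' @return A `region_tbl` tibble.
#' @export
as_region_tbl <- function(df, reference_id = NA_character_) {
  req <- c("region", "start", "end", "kind")
  if (!all(req %in% names(df))) {
    stop("region table needs columns: ", paste(req, collapse = ", "))
  }
  df <- tibble::as_tibble(df[req])
  if (any(!df$kind %in% c("utr", "mat_peptide"))) {
    stop("kind must be 'utr' or 'mat_peptide'")
  }
  if (any(df$start < 1L) || any(df$end < df$start)) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  df <- dplyr::arrange(df, .data$start)
  mp <- df[df$kind == "mat_peptide", ]
  if (nrow(mp) > 0L) {
    if (nrow(mp) > 1L) {
      gaps <- mp$start[-1L] - mp$end[-nrow(mp)] - 1L
      if (any(gaps < 0L)) {
        i <- which(gaps < 0L)[1L]
        stop(sprintf("overlapping mat_peptide regions: %s (..%d) and %s (%d..)",
                     mp$region[i], mp$end[i], mp$region[i + 1L], mp$start[i + 1L]))
      }
      if (any(gaps > 0L)) {
        i <- which(gaps > 0L)[1L]
        stop(sprintf("gap between mat_peptide regions %s and %s (positions %d..%d)",
                     mp$region[i], mp$region[i + 1L], mp$end[i] + 1L,
                     mp$start[i + 1L] - 1L))
      }
    }
    orf_start <- min(mp$start)
    orf_end <- max(mp$end)
  } else {
    orf_start <- NA_integer_
    orf_end <- NA_integer_
  }
  df$length <- df$end - df$start + 1L
  structure(df,
            reference_id = reference_id,
            orf_start = orf_start, orf_end = orf_end,
            class = c("region_tbl", class(df)))
}

#' @export
print.region_tbl <- function(x, ...) {
  cat(sprintf("# Region partition (reference: %s; ORF %s..%s)\n",
              attr(x, "reference_id"),
              format(attr(x, "orf_start")), format(attr(x, "orf_end"))))
  NextMethod()
}

#' Write a region table to TSV
#'
#' @param table A `region_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path) {
  readr::write_tsv(table[, c("region", "start", "end", "kind")], path,
                   progress = FALSE)
  invisible(path)
}

#' ORF span of a region table
#'
#' @param table A `region_tbl`.
#' @return Integer vector `c(orf_start, orf_end)` (1-based inclusive).
#' @export
orf_span <- function(table) {
  c(attr(table, "orf_start"), attr(table, "orf_end"))
}
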