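#' Call single-nucleotide variants from a pairwise alignment
#'
#' One record per alignment column where reference and query both carry an
#' unambiguous base (A/C/G/T) and the bases differ. Gap columns never yield
#' SNVs (indels are out of scope) and columns containing IUPAC ambiguity
#' codes are excluded rather than guessed at. Effects are unset; see
#' [classify_snvs()].
#'
#' @param aln A `pairwise_aln`.
#' @return A tibble with columns `genome` (query id), `ref_pos`, `qry_pos`,
#'   `ref_base`, `alt_base`, sorted by `ref_pos`.
#' @export
call_snvs <- function(aln) {
  td <- tidy(aln)
  td |>
    dplyr::filter(
      .data$ref_base %in% c("A", "C", "G", "T"),
      .data$qry_base %in% c("A", "C", "G", "T"),
      .data$ref_base != .data$qry_base
    ) |>
    dplyr::transmute(genome = aln$qry_id,
                     ref_pos = .data$ref_pos, qry_pos = .data$qry_pos,
                     ref_base = .data$ref_base, alt_base = .data$qry_base) |>
    dplyr::arrange(.data$ref_pos)
}

#' Classify SNVs as synonymous / nonsynonymous / noncoding
#'
#' Each SNV is evaluated independently against the reference reading frame:
#' the reference codon containing the position is substituted at that one
#' position (co-occurring substitutions in the same codon are ignored for the
#' call, ANNOVAR-style) and translated with the standard code. Codon phase
#' comes from the single polyprotein ORF
#' (`codon_index = ceiling((ref_pos - orf_start + 1) / 3)`), so regions that
#' split codons (the 69-nt 2K peptide) still classify in the global frame.
#' Positions outside the ORF are `noncoding`. Codons hit by more than one SNV
#' of the same query are flagged `multihit`.
#'
#' @param snvs SNV tibble from [call_snvs()] (may combine several query
#'   genomes via the `genome` column).
#' @param ref One-row genome tibble or character string: the reference.
#' @param table A `region_tbl` in reference coordinates.
#' @return The input tibble with added columns `region`, `codon_index`,
#'   `codon_pos`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`,
#'   `multihit`.
#' @export
classify_snvs <- function(snvs, ref, table) {
  refseq <- as_seq_entry(ref, "ref")$sequence
  n <- nchar(refseq)
  if (nrow(snvs) > 0L && any(snvs$ref_pos < 1L | snvs$ref_pos > n)) {
    stop("SNV position outside reference genome")
  }
  orf <- orf_span(table)
  os <- orf[[1L]]; oe <- orf[[2L]]
  region_of <- function(pos) {
    i <- which(table$start <= pos & table$end >= pos)
    if (length(i) >= 1L) return(table$region[[i[[1L]]]])
    if (!is.na(os) && pos < os) "5UTR" else "3UTR"
  }
  out <- snvs
  out$region <- vapply(snvs$ref_pos, region_of, character(1))
  coding <- !is.na(os) & snvs$ref_pos >= os & snvs$ref_pos <= oe
  ci <- ifelse(coding, ((snvs$ref_pos - os) %/% 3L) + 1L, NA_integer_)
  cp <- ifelse(coding, ((snvs$ref_pos - os) %% 3L) + 1L, NA_integer_)
  cstart <- os + (ci - 1L) * 3L
  ref_codon <- ifelse(coding, substring(refseq, cstart, cstart + 2L), NA)
  alt_codon <- ref_codon
  for (k in which(coding)) {
    substr(alt_codon[k], cp[k], cp[k]) <- snvs$alt_base[k]
  }
  ref_aa <- ifelse(coding, translate_codon(ref_codon), NA)
  alt_aa <- ifelse(coding, translate_codon(alt_codon), NA)
  out$codon_index <- as.integer(ci)
  out$codon_pos <- as.integer(cp)
  out$ref_codon <- ref_codon
  out$alt_codon <- alt_codon
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$effect <- dplyr::case_when(
    !coding ~ "noncoding",
    ref_aa == alt_aa ~ "synonymous",
    TRUE ~ "nonsynonymous"
  )
  out |>
    dplyr::group_by(.data$genome, .data$codon_index) |>
    dplyr::mutate(multihit = !is.na(.data$codon_index) & dplyr::n() > 1L) |>
    dplyr::ungroup()
}

#' Per-region SNV summary table
#'
#' The region-by-isolate counting behind a per-mature-peptide SNV table: per
#' region, the number of SNVs and of nonsynonymous SNVs for each query
#' genome, their cross-query means (rounded half-up to one decimal), and a
#' totals row summing the coding (mat-peptide) regions. Noncoding SNVs are
#' counted under their UTR rows and excluded from the totals row.
#'
#' @param snvs Classified SNV tibble (see [classify_snvs()]) with a `genome`
#'   column; genomes with zero SNVs must still appear if their columns are
#'   wanted (pass `genomes` to force the column set).
#' @param table A `region_tbl`.
#' @param genomes Optional character vector fixing the query column order.
#' @return A tibble with columns `region`, `start`, `end`, `kind`, one
#'   `snv_<id>` and `nonsyn_<id>` column per query, `mean_snv`,
#'   `mean_nonsyn`; last row `Total`.
#' @export
summarize_regions <- function(snvs, table, genomes = NULL) {
  if (is.null(genomes)) genomes <- unique(snvs$genome)
  utr_rows <- tibble::tibble(
    region = setdiff(unique(snvs$region[snvs$effect == "noncoding"]),
                     table$region),
    start = NA_integer_, end = NA_integer_, kind = "utr"
  )
  skel <- dplyr::bind_rows(
    tibble::as_tibble(table)[, c("region", "start", "end", "kind")],
    utr_rows
  )
  counts <- tidyr::expand_grid(region = skel$region, genome = genomes) |>
    dplyr::left_join(
      snvs |>
        dplyr::group_by(.data$region, .data$genome) |>
        dplyr::summarise(
          snv = dplyr::n(),
          nonsyn = sum(.data$effect == "nonsynonymous"),
          .groups = "drop"
        ),
      by = c("region", "genome")
    ) |>
    dplyr::mutate(snv = dplyr::coalesce(.data$snv, 0L),
                  nonsyn = dplyr::coalesce(.data$nonsyn, 0L))
  wide <- counts |>
    tidyr::pivot_wider(names_from = "genome",
                       values_from = c("snv", "nonsyn"),
                       names_sep = "_")
  res <- dplyr::left_join(skel, wide, by = "region") |>
    dplyr::mutate(
      mean_snv = round_half_up(rowMeans(dplyr::pick(dplyr::starts_with("snv_"))), 1),
      mean_nonsyn = round_half_up(rowMeans(dplyr::pick(dplyr::starts_with("nonsyn_"))), 1)
    )
  coding <- res$kind == "mat_peptide"
  total <- res[coding, ] |>
    dplyr::summarise(
      region = "Total", start = NA_integer_, end = NA_integer_,
      kind = "total",
      dplyr::across(dplyr::starts_with("snv_"), sum),
      dplyr::across(dplyr::starts_with("nonsyn_"), sum)
    ) |>
    dplyr::mutate(
      mean_snv = round_half_up(rowMeans(dplyr::pick(dplyr::starts_with("snv_"))), 1),
      mean_nonsyn = round_half_up(rowMeans(dplyr::pick(dplyr::starts_with("nonsyn_"))), 1)
    )
  out <- dplyr::bind_rows(res, total)
  class(out) <- c("region_snv_summary", class(out))
  out
}

#' Substitution spectrum
#'
#' Counts of the 12 ordered substitution types (A>C ... T>G) among SNVs
#' passing the filters, with proportions as percentages of the filtered total
#' (half-up, one decimal; `NA` when the filtered set is empty).
#'
#' @param snvs Classified SNV tibble.
#' @param regions Optional character vector of region names to keep.
#' @param effects Optional character vector of effect classes to keep.
#' @return A `substitution_spectrum` tibble with 12 rows: `ref_base`,
#'   `alt_base`, `type`, `count`, `proportion`.
#' @export
snv_spectrum <- function(snvs, regions = NULL, effects = NULL) {
  if (!is.null(regions)) snvs <- dplyr::filter(snvs, .data$region %in% regions)
  if (!is.null(effects)) snvs <- dplyr::filter(snvs, .data$effect %in% effects)
  bases <- c("A", "C", "G", "T")
  types <- tidyr::expand_grid(ref_base = bases, alt_base = bases) |>
    dplyr::filter(.data$ref_base != .data$alt_base)
  tot <- nrow(snvs)
  out <- types |>
    dplyr::left_join(
      dplyr::count(snvs, .data$ref_base, .data$alt_base, name = "count"),
      by = c("ref_base", "alt_base")
    ) |>
    dplyr::mutate(
      type = paste0(.data$ref_base, ">", .data$alt_base),
      count = dplyr::coalesce(.data$count, 0L),
      proportion = if (tot > 0L) round_half_up(100 * .data$count / tot, 1)
                   else NA_real_
    ) |>
    dplyr::select("type", "ref_base", "alt_base", "count", "proportion")
  class(out) <- c("substitution_spectrum", class(out))
  out
}

#' Write classified SNVs to a VCF 4.2 file
#'
#' One data line per SNV; `CHROM` is the reference id, `POS`/`REF`/`ALT` the
#' single-base substitution, and `INFO` carries the annotation
#' (`REGION`, `EFFECT`, codon context, `MULTIHIT` flag) so [read_vcf()]
#' round-trips the records exactly. An empty SNV set yields a valid
#' header-only VCF.
#'
#' @param snvs Classified SNV tibble for a single query genome.
#' @param ref One-row genome tibble (reference; used for `CHROM` and the
#'   contig header line).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, ref, path) {
  r <- as_seq_entry(ref, "ref")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", r$id, nchar(r$sequence)),
    "##INFO=<ID=GENOME,Number=1,Type=String,Description=\"Query genome id\">",
    "##INFO=<ID=QPOS,Number=1,Type=Integer,Description=\"Query coordinate\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genome region\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"synonymous, nonsynonymous or noncoding\">",
    "##INFO=<ID=CODON_INDEX,Number=1,Type=Integer,Description=\"Codon number within ORF\">",
    "##INFO=<ID=CODON_POS,Number=1,Type=Integer,Description=\"Position within codon (1-3)\">",
    "##INFO=<ID=CODON,Number=1,Type=String,Description=\"ref_codon>alt_codon\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"ref_aa>alt_aa\">",
    "##INFO=<ID=MULTIHIT,Number=0,Type=Flag,Description=\"Codon hit by more than one SNV\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  lines <- character(0)
  if (nrow(snvs) > 0L) {
    info <- purrr::pmap_chr(snvs, function(genome, ref_pos, qry_pos, ref_base,
                                           alt_base, region, codon_index,
                                           codon_pos, ref_codon, alt_codon,
                                           ref_aa, alt_aa, effect, multihit,
                                           ...) {
      parts <- c(sprintf("GENOME=%s", genome),
                 sprintf("QPOS=%d", qry_pos),
                 sprintf("REGION=%s", region),
                 sprintf("EFFECT=%s", effect))
      if (!is.na(codon_index)) {
        parts <- c(parts,
                   sprintf("CODON_INDEX=%d", codon_index),
                   sprintf("CODON_POS=%d", codon_pos),
                   sprintf("CODON=%s>%s", ref_codon, alt_codon),
                   sprintf("AA=%s>%s", ref_aa, alt_aa))
      }
      if (isTRUE(multihit)) parts <- c(parts, "MULTIHIT")
      paste(parts, collapse = ";")
    })
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                     r$id, snvs$ref_pos, snvs$ref_base, snvs$alt_base, info)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path Path to the VCF file.
#' @return A classified SNV tibble with the same columns [classify_snvs()]
#'   produces.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  cols <- c("genome", "ref_pos", "qry_pos", "ref_base", "alt_base", "region",
            "codon_index", "codon_pos", "ref_codon", "alt_codon",
            "ref_aa", "alt_aa", "effect", "multihit")
  if (length(body) == 0L) {
    out <- tibble::tibble(genome = character(), ref_pos = integer(),
                          qry_pos = integer(), ref_base = character(),
                          alt_base = character(), region = character(),
                          codon_index = integer(), codon_pos = integer(),
                          ref_codon = character(), alt_codon = character(),
                          ref_aa = character(), alt_aa = character(),
                          effect = character(), multihit = logical())
    return(out[cols])
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(sprintf("(?<=^|;)%s=[^;]*", key), info,
                                  perl = TRUE))
    if (length(m) == 0L) NA_character_ else sub("^[^=]*=", "", m)
  }
  purrr::map_dfr(f, function(x) {
    info <- x[[8L]]
    codon <- info_get(info, "CODON")
    aa <- info_get(info, "AA")
    ci <- info_get(info, "CODON_INDEX")
    tibble::tibble(
      genome = info_get(info, "GENOME"),
      ref_pos = as.integer(x[[2L]]),
      qry_pos = as.integer(info_get(info, "QPOS")),
      ref_base = x[[4L]],
      alt_base = x[[5L]],
      region = info_get(info, "REGION"),
      codon_index = as.integer(ci),
      codon_pos = as.integer(info_get(info, "CODON_POS")),
      ref_codon = if (is.na(codon)) NA_character_ else sub(">.*$", "", codon),
      alt_codon = if (is.na(codon)) NA_character_ else sub("^.*>", "", codon),
      ref_aa = if (is.na(aa)) NA_character_ else sub(">.*$", "", aa),
      alt_aa = if (is.na(aa)) NA_character_ else sub("^.*>", "", aa),
      effect = info_get(info, "EFFECT"),
      multihit = grepl("(^|;)MULTIHIT($|;)", info)
    )
  })[, cols]
}
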