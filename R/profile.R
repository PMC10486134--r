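#' Per-region similarity of query genomes to the reference
#'
#' Percent identity ([identity_pct()]) of each alignment over each region
#' interval of the partition, with the cross-query mean (half-up, one
#' decimal) — the data behind a per-region similarity track.
#'
#' @param alns A list of `pairwise_aln` objects sharing the same reference.
#' @param table A `region_tbl` in reference coordinates.
#' @return A tibble with `region`, `start`, `end`, `kind`, one identity
#'   column per query genome, and `mean_identity`.
#' @export
region_similarity <- function(alns, table) {
  if (inherits(alns, "pairwise_aln")) alns <- list(alns)
  ids <- vapply(alns, function(a) a$qry_id, character(1))
  vals <- purrr::map(alns, function(a) {
    vapply(seq_len(nrow(table)), function(i) {
      identity_pct(a, c(table$start[[i]], table$end[[i]]))
    }, numeric(1))
  })
  out <- tibble::as_tibble(table)[, c("region", "start", "end", "kind")]
  for (k in seq_along(ids)) out[[ids[[k]]]] <- vals[[k]]
  m <- as.matrix(out[, ids, drop = FALSE])
  out$mean_identity <- round_half_up(rowMeans(m), 1)
  class(out) <- c("similarity_track", class(out))
  out
}

#' Sliding-window identity track
#'
#' Tiles the reference span with windows and computes percent identity per
#' window — the data behind a circular similarity plot. The final window may
#' be shorter than `window` and is flagged `partial`.
#'
#' @param aln A `pairwise_aln`.
#' @param window Window size in nt (default 500).
#' @param step Step size in nt; `window >= step >= 1` (default `window`).
#' @return A tibble with `ref_start`, `ref_end`, `identity`, `partial`.
#' @export
window_identity <- function(aln, window = 500, step = window) {
  if (step < 1 || window < step) stop("need window >= step >= 1")
  ref_len <- max(aln$ref_coord_map, na.rm = TRUE)
  starts <- seq(1L, max(1L, ref_len), by = as.integer(step))
  starts <- starts[starts <= ref_len]
  out <- purrr::map_dfr(starts, function(s) {
    e <- min(s + window - 1L, ref_len)
    tibble::tibble(ref_start = s, ref_end = e,
                   identity = identity_pct(aln, c(s, e)),
                   partial = (e - s + 1L) < window)
  })
  # drop trailing duplicated partial windows fully covered by the previous one
  out <- out[!duplicated(out$ref_end) | !out$partial, ]
  class(out) <- c("identity_track", class(out))
  out
}

#' All-pairs identity matrix over coding regions
#'
#' Pairwise percent identity between genomes, computed over the aligned
#' coding sequences (`mode = "nt_cds"`) or their aligned polyprotein
#' translations (`mode = "aa"`). Each genome's CDS is located as its longest
#' forward-strand ORF; genomes without an ORF of at least `min_orf` nt are
#' excluded with a warning. The same gap and ambiguity conventions as
#' [identity_pct()] apply, so the matrix is symmetric with a 100 diagonal.
#'
#' @param genomes Genome tibble (one row per genome).
#' @param mode `"nt_cds"` or `"aa"`.
#' @param min_orf Minimum ORF length in nt (default 300).
#' @param ... Alignment parameters passed to [global_align()].
#' @return A symmetric numeric matrix of percentages with genome ids as
#'   dimnames.
#' @export
identity_matrix <- function(genomes, mode = c("nt_cds", "aa"), min_orf = 300,
                            ...) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 2L)
  seqs <- list()
  for (i in seq_len(nrow(genomes))) {
    orfs <- find_orfs(genomes[i, ], min_length = min_orf)
    if (nrow(orfs) == 0L) {
      warning(sprintf("genome '%s' has no ORF >= %d nt; excluded",
                      genomes$id[[i]], min_orf))
      next
    }
    cds <- substring(genomes$sequence[[i]], orfs$start[[1L]], orfs$end[[1L]])
    seqs[[genomes$id[[i]]]] <- if (mode == "aa") translate_cds(cds) else cds
  }
  ids <- names(seqs)
  if (length(ids) < 2L) stop("need at least 2 genomes with a located ORF")
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- stats::setNames(seqs[[i]], ids[[i]])
      b <- stats::setNames(seqs[[j]], ids[[j]])
      bw <- max(600, abs(nchar(seqs[[i]]) - nchar(seqs[[j]])))
      aln <- global_align(a, b, band_width = bw, ...)
      v <- identity_pct(aln)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Export similarity tracks to BED and TSV
#'
#' Writes the window track as BED (coordinates converted to the format's
#' native 0-based half-open convention) and the region summary as TSV
#' (1-based inclusive, as in the data model).
#'
#' @param region_track Output of [region_similarity()] (or `NULL` to skip).
#' @param window_track Output of [window_identity()] (or `NULL` to skip).
#' @param path_prefix Output path prefix; files `<prefix>_regions.tsv` and
#'   `<prefix>_windows.bed` are written.
#' @param chrom Chromosome/genome id for the BED lines (default "ref").
#' @return Character vector of paths written, invisibly.
#' @export
export_tracks <- function(region_track = NULL, window_track = NULL,
                          path_prefix, chrom = "ref") {
  written <- character(0)
  if (!is.null(region_track)) {
    p <- paste0(path_prefix, "_regions.tsv")
    readr::write_tsv(tibble::as_tibble(region_track), p, progress = FALSE)
    written <- c(written, p)
  }
  if (!is.null(window_track)) {
    p <- paste0(path_prefix, "_windows.bed")
    bed <- tibble::tibble(
      chrom = chrom,
      start = as.integer(window_track$ref_start) - 1L,  # 0-based half-open
      end = as.integer(window_track$ref_end),
      name = sprintf("window_%d", seq_len(nrow(window_track))),
      score = window_track$identity
    )
    readr::write_tsv(bed, p, col_names = FALSE, progress = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' @describeIn region_similarity Bar plot of per-region mean identity.
#' @param object A `similarity_track`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.similarity_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$mean_identity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mean nucleotide identity (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn window_identity Line plot of the sliding-window identity.
#' @param object An `identity_track`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.identity_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$ref_start + .data$ref_end) / 2,
                                   y = .data$identity)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Reference position (nt)", y = "Identity (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn snv_spectrum Bar plot of the 12 substitution types.
#' @param object A `substitution_spectrum`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.substitution_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$count)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "Substitution", y = "Count") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise identity matrix
#'
#' @param m Symmetric percentage matrix from [identity_matrix()].
#' @return A ggplot object.
#' @export
plot_identity_heatmap <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = ~c("row", "col", "identity"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$identity)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal()
}
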