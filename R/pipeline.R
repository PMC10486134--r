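# End-to-end workflow functions tying the stages together: compare isolates
# to a reference, build a bootstrapped NJ tree, screen for -1 frameshift
# sites, emit a synthetic dataset. Each is deterministic for fixed inputs
# and seeds and writes a fixed file set.

#' Compare query genomes to a reference
#'
#' The full reference-anchored comparison: align each query to the
#' reference, call and classify SNVs, summarize per region, compute
#' substitution spectra and similarity tracks, and (optionally) write the
#' result files (one VCF per query, a region summary TSV, a spectrum TSV,
#' a per-region similarity TSV and a window BED).
#'
#' @param reference One-row genome tibble.
#' @param queries Genome tibble (>= 1 row).
#' @param table A `region_tbl` in reference coordinates.
#' @param outdir Output directory (created); `NULL` to skip writing.
#' @param window Sliding-window size in nt for the identity track (500).
#' @param ... Alignment parameters passed to [global_align()].
#' @return A list: `alignments` (named list of `pairwise_aln`), `snvs`
#'   (classified tibble over all queries), `summary` (region summary),
#'   `spectrum`, `similarity` (per-region), `windows` (named list of window
#'   tracks), `files` (paths written, if any).
#' @export
run_compare <- function(reference, queries, table, outdir = NULL,
                        window = 500, ...) {
  stopifnot(is.data.frame(queries), nrow(queries) >= 1L)
  alns <- list()
  snvs <- list()
  for (i in seq_len(nrow(queries))) {
    aln <- global_align(reference, queries[i, ], ...)
    alns[[queries$id[[i]]]] <- aln
    snvs[[i]] <- classify_snvs(call_snvs(aln), reference, table)
  }
  snvs <- dplyr::bind_rows(snvs)
  summary <- summarize_regions(snvs, table, genomes = queries$id)
  spect <- snv_spectrum(snvs)
  sim <- region_similarity(alns, table)
  wins <- purrr::map(alns, window_identity, window = window)
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (idq in names(alns)) {
      p <- file.path(outdir, paste0(idq, ".vcf"))
      write_vcf(dplyr::filter(snvs, .data$genome == idq), reference, p)
      files <- c(files, p)
    }
    p <- file.path(outdir, "region_summary.tsv")
    readr::write_tsv(tibble::as_tibble(summary), p, progress = FALSE)
    files <- c(files, p)
    p <- file.path(outdir, "spectrum.tsv")
    readr::write_tsv(tibble::as_tibble(spect), p, progress = FALSE)
    files <- c(files, p)
    tr <- export_tracks(sim, wins[[1L]], file.path(outdir, "similarity"),
                        chrom = reference$id[[1L]])
    files <- c(files, tr)
  }
  list(alignments = alns, snvs = snvs, summary = summary, spectrum = spect,
       similarity = sim, windows = wins, files = files)
}

#' Build a bootstrapped neighbor-joining tree from genomes
#'
#' Builds a reference-anchored pseudo-MSA ([stack_alignments()]; skipped if
#' the sequences are already aligned, i.e. equal length and `aligned =
#' TRUE`), computes TN93 or p distances with pairwise deletion, infers the
#' NJ tree and attaches bootstrap supports.
#'
#' @param genomes Genome tibble (>= 3 rows).
#' @param model `"tn93"` or `"p"`.
#' @param gamma_shape Optional gamma shape for TN93 (e.g. 1).
#' @param n_boot Bootstrap replicates; 0 for no supports.
#' @param seed Integer seed for the bootstrap.
#' @param aligned Set TRUE when `genomes$sequence` are already aligned.
#' @param out Optional Newick output path.
#' @return A list: `tree` (`ape::phylo`, node labels = supports when
#'   bootstrapped), `distances` (matrix), `bootstrap` (full [nj_bootstrap()]
#'   result or `NULL`), `file`.
#' @export
run_tree <- function(genomes, model = "tn93", gamma_shape = NULL,
                     n_boot = 1000, seed = 42, aligned = FALSE, out = NULL) {
  stopifnot(nrow(genomes) >= 3L)
  msa <- if (aligned) {
    stopifnot(length(unique(nchar(genomes$sequence))) == 1L)
    stats::setNames(genomes$sequence, genomes$id)
  } else {
    stack_alignments(genomes)
  }
  d <- distance_matrix(msa, model = model, gamma_shape = gamma_shape)
  bs <- NULL
  if (n_boot > 0) {
    bs <- nj_bootstrap(msa, n_reps = n_boot, seed = seed, model = model,
                       gamma_shape = gamma_shape)
    tree <- bs$tree
  } else {
    tree <- neighbor_joining(d)
  }
  file <- NULL
  if (!is.null(out)) {
    write_newick(tree, out)
    file <- out
  }
  list(tree = tree, distances = d, bootstrap = bs, file = file)
}

#' Screen genomes for -1 frameshift sites
#'
#' Runs [detect_prf()] on every genome and optionally writes a combined
#' site report.
#'
#' @param genomes Genome tibble.
#' @param table Optional `region_tbl` for region annotation.
#' @param window Downstream fold window in nt (default 150).
#' @param out Optional output TSV path.
#' @param ... Passed to [detect_prf()].
#' @return A tibble of sites over all genomes (extra column `genome`).
#' @export
run_prf <- function(genomes, table = NULL, window = 150, out = NULL, ...) {
  res <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    sites <- detect_prf(genomes[i, ], table = table, window = window, ...)
    if (nrow(sites) > 0L) sites$genome <- genomes$id[[i]]
    else sites$genome <- character(0)
    sites
  })
  if (!is.null(out)) {
    cols <- c("genome", "pattern", "start", "region", "stem_loop_found",
              "stem_length", "loop_length", "truncated")
    readr::write_tsv(res[intersect(cols, names(res))], out, progress = FALSE)
  }
  res
}

#' Emit a synthetic study dataset to disk
#'
#' Generates the default synthetic study ([simulate_study()]) and writes
#' reference and isolate FASTA, the region TSV, and a JSON truth manifest.
#'
#' @param outdir Output directory.
#' @param seed Integer seed (default 42, logged in the manifest).
#' @return The [simulate_study()] list, with `files` added.
#' @export
run_simulate <- function(outdir, seed = 42) {
  sim <- simulate_study(seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f_ref <- file.path(outdir, "reference.fasta")
  f_iso <- file.path(outdir, "isolates.fasta")
  f_reg <- file.path(outdir, "regions.tsv")
  f_man <- file.path(outdir, "manifest.json")
  write_fasta(sim$reference, f_ref)
  write_fasta(sim$isolates, f_iso)
  write_region_table(sim$table, f_reg)
  manifest <- list(
    seed = seed,
    reference_id = sim$reference$id,
    reference_length = sim$reference$length,
    isolates = sim$isolates$id,
    planted_snvs = sim$truth
  )
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  sim$files <- c(f_ref, f_iso, f_reg, f_man)
  sim
}
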