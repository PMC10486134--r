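# -1 programmed ribosomal frameshift detection: slippery heptamer scan,
# downstream window folding by base-pair maximization, stem-loop geometry
# verification.

#' Canonical slippery heptamer patterns
#'
#' The five heptanucleotide motifs reported at insect-specific flavivirus
#' -1 frameshift sites, in RNA alphabet.
#'
#' @return Character vector of 7-mers.
#' @export
slippery_patterns <- function() {
  c("GGAUUUC", "GGAUUUU", "GUUUUUU", "UUUUUUU", "UUUUUUC")
}

#' Scan a genome for slippery heptamers
#'
#' Exact occurrences (T and U equivalent) of each pattern, overlapping
#' matches included, reported with the 1-based coordinate of the heptamer's
#' first base and sorted by start.
#'
#' @param genome One-row genome tibble or character sequence.
#' @param patterns Heptamer patterns, RNA alphabet (default
#'   [slippery_patterns()]).
#' @param search_interval Optional `c(start, end)` restricting the scan
#'   (1-based inclusive; a match must start within the interval).
#' @return A tibble with columns `pattern`, `start`.
#' @export
scan_slippery <- function(genome, patterns = slippery_patterns(),
                          search_interval = NULL) {
  if (length(patterns) == 0L) stop("patterns must be nonempty")
  if (any(nchar(patterns) != 7L)) stop("patterns must be 7 nt")
  if (any(grepl("[^ACGU]", patterns))) {
    stop("pattern with non-RNA character (alphabet ACGU)")
  }
  seq <- as_seq_entry(genome, "g")$sequence         # DNA alphabet internally
  dna_patterns <- chartr("U", "T", patterns)
  hits <- purrr::map2_dfr(patterns, dna_patterns, function(p, dp) {
    m <- gregexpr(sprintf("(?=%s)", dp), seq, perl = TRUE)[[1L]]
    if (m[[1L]] == -1L) return(NULL)
    tibble::tibble(pattern = p, start = as.integer(m))
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(pattern = character(), start = integer()))
  }
  if (!is.null(search_interval)) {
    hits <- dplyr::filter(hits, .data$start >= search_interval[[1L]],
                          .data$start <= search_interval[[2L]])
  }
  dplyr::arrange(hits, .data$start)
}

#' Fold an RNA window by base-pair maximization
#'
#' Maximum-cardinality nested pairing under Watson-Crick plus (optionally)
#' GU wobble rules with hairpin loops of at least `min_loop` unpaired bases,
#' computed by Nussinov-style dynamic programming with a deterministic
#' traceback (a base pairs with its smallest optimal partner). This asks the
#' structural question ("is there a stem-loop?") without a thermodynamic
#' model; an external MFE folder can be substituted upstream if desired.
#'
#' @param window RNA (or DNA) string.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param allow_gu Allow GU wobble pairs (default TRUE).
#' @return A `fold_result`: list with `sequence` (RNA), `pairing` (tibble
#'   `i`, `j` of 1-based pairs), `pair_count`, `structure` (dot-bracket).
#' @examples
#' fold_rna("GGGGAAAACCCC")$structure  # "((((....))))"
#' @export
fold_rna <- function(window, min_loop = 3, allow_gu = TRUE) {
  rna <- chartr("T", "U", toupper(window))
  n <- nchar(rna)
  partner <- if (n >= min_loop + 2) {
    .nussinov_cpp(rna, as.integer(min_loop), isTRUE(allow_gu))
  } else {
    integer(n)
  }
  paired_i <- which(partner > 0 & seq_len(n) < partner)
  db <- rep(".", n)
  db[paired_i] <- "("
  db[partner[paired_i]] <- ")"
  structure(list(
    sequence = rna,
    pairing = tibble::tibble(i = paired_i, j = partner[paired_i]),
    pair_count = length(paired_i),
    structure = paste(db, collapse = "")
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("%d base pairs\n", x$pair_count))
  invisible(x)
}

#' Check a folded window for a hairpin stem-loop
#'
#' Looks for a terminal hairpin: an innermost pair closing an entirely
#' unpaired loop of `loop_range` nt, extended outward through stacked pairs
#' (bulges of at most 1 nt allowed between stacks) into a helix of at least
#' `min_stem` pairs whose 5' end lies within the first `search_prefix` nt of
#' the window. When several hairpins qualify, the one with the longest stem
#' (then the most 5') is reported.
#'
#' @param fr A `fold_result`.
#' @param min_stem Minimum helix length in base pairs (default 4).
#' @param loop_range Allowed terminal loop sizes, `c(min, max)` (default
#'   `c(3, 10)`).
#' @param search_prefix Helix 5' end must start within this many nt of the
#'   window start (default 60).
#' @return A one-row tibble: `found`, `stem_length`, `loop_length`, `apex`
#'   (5' position of the innermost pair) and `helix_start` (5' position of
#'   the outermost helix pair); positions are `NA` when not found.
#' @export
stem_loop_check <- function(fr, min_stem = 4, loop_range = c(3, 10),
                            search_prefix = 60) {
  pairs <- fr$pairing
  none <- tibble::tibble(found = FALSE, stem_length = NA_integer_,
                         loop_length = NA_integer_, apex = NA_integer_,
                         helix_start = NA_integer_)
  if (nrow(pairs) == 0L) return(none)
  n <- nchar(fr$sequence)
  paired <- rep(FALSE, n)
  paired[pairs$i] <- TRUE
  paired[pairs$j] <- TRUE
  partner <- rep(0L, n)
  partner[pairs$i] <- pairs$j
  partner[pairs$j] <- pairs$i
  candidates <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[[k]]; j <- pairs$j[[k]]
    loop <- j - i - 1L
    if (loop < loop_range[[1L]] || loop > loop_range[[2L]]) next
    if (loop > 0L && any(paired[(i + 1L):(j - 1L)])) next  # not terminal
    # extend outward through stacked pairs, allowing <= 1-nt bulges
    stem <- 1L
    ci <- i; cj <- j
    repeat {
      nxt <- NULL
      for (bi in 0:1) {
        for (bj in 0:1) {
          pi <- ci - 1L - bi; pj <- cj + 1L + bj
          if (pi >= 1L && pj <= n && partner[pi] == pj) {
            # intervening bulge bases must be unpaired
            okb <- TRUE
            if (bi == 1L && paired[ci - 1L]) okb <- FALSE
            if (bj == 1L && paired[cj + 1L]) okb <- FALSE
            if (okb) { nxt <- c(pi, pj); break }
          }
        }
        if (!is.null(nxt)) break
      }
      if (is.null(nxt)) break
      ci <- nxt[[1L]]; cj <- nxt[[2L]]
      stem <- stem + 1L
    }
    if (stem >= min_stem && ci <= search_prefix) {
      candidates[[length(candidates) + 1L]] <-
        tibble::tibble(found = TRUE, stem_length = stem,
                       loop_length = loop, apex = i, helix_start = ci)
    }
  }
  if (length(candidates) == 0L) return(none)
  dplyr::bind_rows(candidates) |>
    dplyr::arrange(dplyr::desc(.data$stem_length), .data$apex) |>
    dplyr::slice(1L)
}

#' Detect candidate -1 frameshift sites in a genome
#'
#' Scans for slippery heptamers, folds the 150 nt immediately 3' of each
#' heptamer's last base, and verifies hairpin stem-loop geometry. All matches
#' are reported; `stem_loop_found` marks the verified ones. Matches whose
#' downstream window is truncated by the genome end are flagged.
#'
#' @param genome One-row genome tibble or character sequence.
#' @param table Optional `region_tbl` used to annotate each site with the
#'   region containing its start.
#' @param patterns Heptamer patterns (default [slippery_patterns()]).
#' @param window Downstream window length in nt (default 150).
#' @param min_stem,loop_range,search_prefix Passed to [stem_loop_check()].
#' @param search_interval Optional scan restriction, as [scan_slippery()].
#' @return A tibble with one row per match: `pattern`, `start`, `region`,
#'   `window_start`, `window_len`, `truncated`, `structure`,
#'   `stem_loop_found`, `stem_length`, `loop_length`, `downstream_seq`.
#' @export
detect_prf <- function(genome, table = NULL, patterns = slippery_patterns(),
                       window = 150, min_stem = 4, loop_range = c(3, 10),
                       search_prefix = 60, search_interval = NULL) {
  entry <- as_seq_entry(genome, "g")
  seq <- entry$sequence
  n <- nchar(seq)
  hits <- scan_slippery(entry$sequence, patterns, search_interval)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(pattern = character(), start = integer(),
                          region = character(), window_start = integer(),
                          window_len = integer(), truncated = logical(),
                          structure = character(), stem_loop_found = logical(),
                          stem_length = integer(), loop_length = integer(),
                          downstream_seq = character()))
  }
  region_of <- function(pos) {
    if (is.null(table)) return(NA_character_)
    i <- which(table$start <= pos & table$end >= pos)
    if (length(i) >= 1L) table$region[[i[[1L]]]] else NA_character_
  }
  purrr::pmap_dfr(hits, function(pattern, start) {
    ws <- start + 7L
    we <- min(n, ws + window - 1L)
    wlen <- max(0L, we - ws + 1L)
    down <- if (wlen > 0L) substring(seq, ws, we) else ""
    fr <- fold_rna(down)
    sl <- stem_loop_check(fr, min_stem = min_stem, loop_range = loop_range,
                          search_prefix = search_prefix)
    if (!sl$found && wlen >= 2L * min_stem + loop_range[[1L]]) {
      # A stimulatory stem-loop is a local element: the whole-window maximum
      # pairing can absorb a real hairpin into long-range pairs, so when the
      # global structure shows none, refold short subwindows across the
      # search prefix and accept a hairpin whose helix starts inside it.
      for (s in seq(1L, min(search_prefix, wlen - 2L * min_stem), by = 5L)) {
        sub <- substring(down, s, min(wlen, s + 39L))
        chk <- stem_loop_check(fold_rna(sub), min_stem = min_stem,
                               loop_range = loop_range,
                               search_prefix = nchar(sub))
        if (chk$found && (s - 1L + chk$helix_start) <= search_prefix) {
          chk$apex <- chk$apex + s - 1L
          chk$helix_start <- chk$helix_start + s - 1L
          sl <- chk
          break
        }
      }
    }
    tibble::tibble(
      pattern = pattern, start = start, region = region_of(start),
      window_start = ws, window_len = wlen, truncated = wlen < window,
      structure = fr$structure,
      stem_loop_found = sl$found,
      stem_length = sl$stem_length, loop_length = sl$loop_length,
      downstream_seq = chartr("T", "U", down)
    )
  })
}

#' Write a -1 frameshift site report
#'
#' TSV of the site table plus a plain-text dot-bracket dump per site.
#'
#' @param sites Output of [detect_prf()].
#' @param path_prefix Output prefix; writes `<prefix>_sites.tsv` and
#'   `<prefix>_structures.txt`.
#' @return Paths written, invisibly.
#' @export
write_prf_report <- function(sites, path_prefix) {
  tsv <- paste0(path_prefix, "_sites.tsv")
  readr::write_tsv(
    sites[, c("pattern", "start", "region", "stem_loop_found",
              "stem_length", "loop_length", "truncated")],
    tsv, progress = FALSE
  )
  txt <- paste0(path_prefix, "_structures.txt")
  blocks <- purrr::pmap_chr(sites, function(pattern, start, downstream_seq,
                                            structure, ...) {
    sprintf("> %s @ %d\n%s\n%s", pattern, start, downstream_seq, structure)
  })
  writeLines(blocks, txt)
  invisible(c(tsv, txt))
}
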