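# Synthetic flavivirus-like genomes with fully known ground truth: reference
# generation, SNV planting with verified effects, slippery-site/hairpin
# planting, and sequence evolution along a tree. Every operation takes an
# explicit seed and replays byte-identically.

DNA_BASES <- c("A", "C", "G", "T")

# internal: random DNA of given length and GC content
random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# internal: rewrite any ATG occurrence (used to keep UTRs ORF-silent)
scrub_atg <- function(seq) {
  repeat {
    m <- regexpr("ATG", seq, fixed = TRUE)
    if (m < 0) return(seq)
    substr(seq, m + 2L, m + 2L) <- "C"
  }
}

#' Default mature-peptide partition lengths for a synthetic genome
#'
#' The canonical 11-region flavivirus polyprotein partition used by the
#' generator, sized like the Quang Binh virus reference partition but made
#' self-consistent with a 10,080-nt CDS (the NS5 region absorbs the stop
#' codon).
#'
#' @return Named integer vector of region lengths summing to 10,080.
#' @export
default_region_lengths <- function() {
  c("AC+C" = 408L, "PrM+M" = 426L, "E" = 1281L, "NS1" = 1179L,
    "NS2A" = 606L, "NS2B" = 438L, "NS3" = 1764L, "NS4A" = 465L,
    "2K" = 69L, "NS4B" = 774L, "NS5" = 2670L)
}

#' Generate a synthetic flavivirus-like reference genome
#'
#' A random genome with a 5' UTR, one long ORF (start `ATG`, terminal stop,
#' no internal stop in frame) partitioned into contiguous mature-peptide
#' regions, and a 3' UTR. Defaults emulate a Quang Binh virus-like genome:
#' 98-nt 5' UTR, 10,080-nt CDS, 653-nt 3' UTR, total 10,831 nt. UTRs are
#' generated free of `ATG` so the planted ORF is unambiguous.
#'
#' @param utr5_len,cds_len,utr3_len Segment lengths in nt (`cds_len`
#'   divisible by 3).
#' @param region_lengths Named vector of mat-peptide lengths summing to
#'   `cds_len` (default [default_region_lengths()], rescaled NS5 if
#'   `cds_len` differs).
#' @param gc GC content of the random sequence (default 0.5).
#' @param seed Integer seed (mandatory).
#' @param id Genome id (default "synthetic_ref").
#' @return A list with `genome` (one-row genome tibble) and `table`
#'   (a `region_tbl` including the UTR rows).
#' @export
generate_reference <- function(utr5_len = 98, cds_len = 10080,
                               utr3_len = 653, region_lengths = NULL,
                               gc = 0.5, seed, id = "synthetic_ref") {
  stopifnot(cds_len %% 3 == 0, cds_len >= 9)
  if (is.null(region_lengths)) {
    region_lengths <- default_region_lengths()
    if (sum(region_lengths) != cds_len) {
      # keep the canonical shape for non-default sizes: scale proportionally,
      # then absorb the rounding remainder in the last region
      sc <- cds_len / sum(region_lengths)
      region_lengths <- pmax(3L, as.integer(round(region_lengths * sc)))
      region_lengths[length(region_lengths)] <-
        region_lengths[length(region_lengths)] +
        (cds_len - sum(region_lengths))
    }
  }
  if (sum(region_lengths) != cds_len) {
    stop("region lengths must sum to cds_len")
  }
  with_local_seed(seed, {
    utr5 <- if (utr5_len > 0) scrub_atg(random_dna(utr5_len, gc)) else ""
    utr3 <- if (utr3_len > 0) scrub_atg(random_dna(utr3_len, gc)) else ""
    n_codons <- cds_len / 3L
    stops <- c("TAA", "TAG", "TGA")
    body <- character(n_codons - 2L)
    for (k in seq_along(body)) {
      repeat {
        cd <- random_dna(3L, gc)
        if (!cd %in% stops) break
      }
      body[k] <- cd
    }
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    seqn <- paste0(utr5, cds, utr3)
  })
  orf_start <- utr5_len + 1L
  ends <- orf_start - 1L + cumsum(region_lengths)
  starts <- c(orf_start, utils::head(ends, -1L) + 1L)
  rows <- tibble::tibble(region = names(region_lengths),
                         start = as.integer(starts), end = as.integer(ends),
                         kind = "mat_peptide")
  if (utr5_len > 0) {
    rows <- dplyr::bind_rows(
      tibble::tibble(region = "5UTR", start = 1L, end = as.integer(utr5_len),
                     kind = "utr"), rows)
  }
  if (utr3_len > 0) {
    gl <- utr5_len + cds_len + utr3_len
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(region = "3UTR", start = as.integer(utr5_len + cds_len + 1L),
                     end = as.integer(gl), kind = "utr"))
  }
  genome <- tibble::tibble(id = id, description = "synthetic reference",
                           sequence = seqn, length = nchar(seqn))
  list(genome = genome, table = as_region_tbl(rows, reference_id = id))
}

# internal: draw an alternative base with transition bias
draw_alt <- function(ref_base, ts_tv_bias) {
  ts <- transition_of(ref_base)
  tv <- setdiff(DNA_BASES, c(ref_base, ts))
  sample(c(ts, tv), 1L,
         prob = c(ts_tv_bias, 1, 1) / (ts_tv_bias + 2))
}

#' Plant SNVs with known effects into a reference genome
#'
#' Produces a mutant genome differing from the reference at exactly the
#' requested number of positions per region, with each substitution's
#' synonymous/nonsynonymous/noncoding effect verified by codon translation
#' before emission (site-wise rejection sampling, <= 1000 retries per SNV).
#' Alternative bases are drawn with a transition bias. By default at most
#' one SNV lands in any codon, keeping per-SNV truth unambiguous;
#' `allow_multihit` lifts that for testing multi-hit annotation.
#'
#' @param reference One-row genome tibble (the reference).
#' @param table A `region_tbl` for the reference.
#' @param spec Data frame with columns `region`, `n_syn`, `n_nonsyn`
#'   (and optionally `n_noncoding` for UTR rows).
#' @param ts_tv_bias Transition/transversion draw bias (default 2.0).
#' @param seed Integer seed (mandatory).
#' @param id Mutant genome id.
#' @param allow_multihit Allow two SNVs in one codon (default FALSE).
#' @return A list with `genome` (mutant, one-row tibble) and `truth`
#'   (classified-SNV-style tibble of planted substitutions).
#' @export
plant_snvs <- function(reference, table, spec, ts_tv_bias = 2.0, seed,
                       id = "synthetic_isolate", allow_multihit = FALSE) {
  refseq <- reference$sequence[[1L]]
  orf <- orf_span(table)
  os <- orf[[1L]]; oe <- orf[[2L]]
  effect_of <- function(pos, alt) {
    if (is.na(os) || pos < os || pos > oe) return("noncoding")
    ci <- (pos - os) %/% 3L + 1L
    cp <- (pos - os) %% 3L + 1L
    cstart <- os + (ci - 1L) * 3L
    ref_codon <- substring(refseq, cstart, cstart + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, cp, cp) <- alt
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    if (ref_aa == alt_aa) return("synonymous")
    # keep the planted ORF intact: no nonsense mutations, no start-codon loss
    if (alt_aa == "*" || ref_aa == "*" || ci == 1L) return("rejected")
    "nonsynonymous"
  }
  used_pos <- integer(0)
  used_codon <- integer(0)
  records <- list()
  with_local_seed(seed, {
    for (r in seq_len(nrow(spec))) {
      reg <- spec$region[[r]]
      ti <- which(table$region == reg)
      if (length(ti) != 1L) stop("unknown region in spec: ", reg)
      lo <- table$start[[ti]]; hi <- table$end[[ti]]
      wanted <- c(
        synonymous = if ("n_syn" %in% names(spec)) spec$n_syn[[r]] else 0L,
        nonsynonymous = if ("n_nonsyn" %in% names(spec)) spec$n_nonsyn[[r]] else 0L,
        noncoding = if ("n_noncoding" %in% names(spec)) spec$n_noncoding[[r]] else 0L
      )
      wanted[is.na(wanted)] <- 0L
      for (eff in names(wanted)) {
        for (k in seq_len(wanted[[eff]])) {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            pos <- sample(lo:hi, 1L)
            if (pos %in% used_pos) next
            if (!allow_multihit && !is.na(os) && pos >= os && pos <= oe) {
              ci <- (pos - os) %/% 3L + 1L
              if (ci %in% used_codon) next
            }
            rb <- substring(refseq, pos, pos)
            alt <- draw_alt(rb, ts_tv_bias)
            if (effect_of(pos, alt) != eff) next
            used_pos <- c(used_pos, pos)
            if (!is.na(os) && pos >= os && pos <= oe) {
              used_codon <- c(used_codon, (pos - os) %/% 3L + 1L)
            }
            records[[length(records) + 1L]] <-
              tibble::tibble(genome = id, ref_pos = pos, ref_base = rb,
                             alt_base = alt, region = reg, effect = eff)
            placed <- TRUE
            break
          }
          if (!placed) {
            stop(sprintf("could not place a %s SNV in region %s", eff, reg))
          }
        }
      }
    }
  })
  truth <- if (length(records) > 0L) {
    dplyr::arrange(dplyr::bind_rows(records), .data$ref_pos)
  } else {
    tibble::tibble(genome = character(), ref_pos = integer(),
                   ref_base = character(), alt_base = character(),
                   region = character(), effect = character())
  }
  mut <- strsplit(refseq, "")[[1L]]
  mut[truth$ref_pos] <- truth$alt_base
  genome <- tibble::tibble(id = id, description = "synthetic isolate",
                           sequence = paste(mut, collapse = ""),
                           length = nchar(refseq))
  list(genome = genome, truth = truth)
}

#' Plant a slippery heptamer and downstream hairpin
#'
#' Writes the heptamer at the given position and, `offset` nt after its last
#' base, a designed hairpin: a GC-rich stem of `stem` pairs closed by an
#' `loop`-nt A-loop, isolated by non-pairing `AA` spacers so the planted
#' geometry is what the folder recovers. Any other occurrence of the five
#' slippery patterns (pre-existing or accidentally created) is scrubbed by a
#' single-base edit, so detection on the result finds exactly the planted
#' site.
#'
#' @param genome One-row genome tibble.
#' @param position 1-based coordinate for the heptamer's first base.
#' @param pattern Heptamer (RNA alphabet, default `GGAUUUC`).
#' @param hairpin List with `stem` (pairs, default 8), `loop` (nt, default
#'   5), `offset` (nt between heptamer end and hairpin, default 10).
#' @param seed Integer seed (stem arm composition).
#' @return A list with `genome` (modified tibble) and `truth` (one-row tibble
#'   `pattern`, `start`, `stem`, `loop`, `offset`).
#' @export
plant_prf_site <- function(genome, position, pattern = "GGAUUUC",
                           hairpin = list(stem = 8, loop = 5, offset = 10),
                           seed = 1) {
  seqv <- strsplit(genome$sequence[[1L]], "")[[1L]]
  n <- length(seqv)
  stem <- hairpin$stem; loop <- hairpin$loop; offset <- hairpin$offset
  hp_len <- 2L * stem + loop + 4L   # incl. AA spacers each side
  if (position + 6L + offset + hp_len > n) {
    stop("site plus downstream window exceeds genome")
  }
  dna_pat <- chartr("U", "T", pattern)
  seqv[position:(position + 6L)] <- strsplit(dna_pat, "")[[1L]]
  with_local_seed(seed, {
    arm <- sample(c("G", "C"), stem, replace = TRUE)
  })
  arm_rc <- rev(chartr("GC", "CG", arm))
  hp <- c("A", "A", arm, rep("A", loop), arm_rc, "A", "A")
  hp_start <- position + 7L + offset - 2L  # spacers start 2 nt early
  hp_start <- max(hp_start, position + 7L)
  seqv[hp_start:(hp_start + length(hp) - 1L)] <- hp
  out <- paste(seqv, collapse = "")
  out <- scrub_slippery(out, keep = position)
  g <- genome
  g$sequence <- out
  g$length <- nchar(out)
  list(genome = g,
       truth = tibble::tibble(pattern = pattern, start = position,
                              stem = stem, loop = loop, offset = offset))
}

#' Remove slippery-pattern occurrences from a sequence
#'
#' Rewrites one base inside every occurrence of the five slippery heptamers
#' (except any starting at a `keep` coordinate) until the sequence is free of
#' them. Used to construct pattern-free negative controls and to isolate
#' planted sites.
#'
#' @param seq Character sequence (DNA alphabet).
#' @param keep Integer vector of match start positions to preserve.
#' @return The edited sequence.
#' @export
scrub_slippery <- function(seq, keep = integer(0)) {
  repeat {
    hits <- scan_slippery(seq)
    hits <- hits[!(hits$start %in% keep), ]
    # also protect matches overlapping kept sites (editing them would edit
    # shared bases); they disappear when their private bases change
    if (nrow(hits) == 0L) return(seq)
    pos <- hits$start[[1L]]
    protected <- any(abs(hits$start[[1L]] - keep) < 7L)
    if (protected) {
      # overlapping a kept site: edit the base outside the kept heptamer
      span <- pos:(pos + 6L)
      kept_span <- unlist(lapply(keep, function(k) k:(k + 6L)))
      free <- setdiff(span, kept_span)
      if (length(free) == 0L) stop("cannot scrub pattern overlapping kept site")
      edit_at <- free[[1L]]
    } else {
      edit_at <- pos + 3L
    }
    old <- substring(seq, edit_at, edit_at)
    substr(seq, edit_at, edit_at) <- if (old == "C") "G" else "C"
  }
}

#' Evolve sequences along a phylogeny
#'
#' Simulates site-independent nucleotide evolution along a tree with branch
#' lengths in substitutions/site, under Jukes-Cantor or a TN93
#' parameterization (transition probabilities from the eigendecomposition of
#' the normalized rate matrix). The root carries the reference sequence.
#'
#' @param reference One-row genome tibble (root sequence).
#' @param tree An `ape::phylo` tree (or Newick string) with branch lengths.
#' @param model `"JC"` (default) or `"TN93"`.
#' @param tn93_params For `model = "TN93"`: list with `alpha1` (A<->G rate),
#'   `alpha2` (C<->T), `beta` (transversion), `freqs` (named A/C/G/T vector).
#' @param seed Integer seed (mandatory).
#' @return A list with `genomes` (tibble of leaf sequences, ids = tip
#'   labels) and `tree` (the input tree).
#' @export
evolve_on_tree <- function(reference, tree, model = c("JC", "TN93"),
                           tn93_params = NULL, seed) {
  model <- match.arg(model)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  P_of <- function(d) {
    if (model == "JC") {
      pc <- 3 / 4 * (1 - exp(-4 * d / 3))
      m <- matrix(pc / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
      diag(m) <- 1 - pc
      m
    } else {
      p <- tn93_params
      if (is.null(p)) {
        p <- list(alpha1 = 2, alpha2 = 2, beta = 1,
                  freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
      }
      f <- p$freqs[DNA_BASES]
      Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
      rate <- function(a, b) {
        if ((a == "A" && b == "G") || (a == "G" && b == "A")) p$alpha1
        else if ((a == "C" && b == "T") || (a == "T" && b == "C")) p$alpha2
        else p$beta
      }
      for (a in DNA_BASES) for (b in DNA_BASES) {
        if (a != b) Q[a, b] <- rate(a, b) * f[[b]]
      }
      diag(Q) <- -rowSums(Q)
      mu <- -sum(f * diag(Q))
      Q <- Q / mu
      e <- eigen(Q)
      V <- e$vectors
      Vi <- solve(V)
      Re(V %*% diag(exp(e$values * d)) %*% Vi)
    }
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(reference$sequence[[1L]], "")[[1L]]
  edges <- stats::reorder(tree, "cladewise")
  with_local_seed(seed, {
    for (k in seq_len(nrow(edges$edge))) {
      par <- edges$edge[k, 1L]; child <- edges$edge[k, 2L]
      d <- edges$edge.length[[k]]
      x <- seqs[[par]]
      if (d > 0) {
        P <- P_of(d)
        for (b in DNA_BASES) {
          idx <- which(x == b)
          if (length(idx) > 0L) {
            pr <- pmax(P[b, ], 0)
            x[idx] <- sample(DNA_BASES, length(idx), replace = TRUE,
                             prob = pr / sum(pr))
          }
        }
      }
      seqs[[child]] <- x
    }
  })
  genomes <- tibble::tibble(
    id = tree$tip.label,
    description = "evolved on tree",
    sequence = vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                      character(1))
  )
  genomes$length <- nchar(genomes$sequence)
  list(genomes = genomes, tree = tree)
}

#' Packaged Quang Binh virus region partition fixture
#'
#' The published 11-region mature-peptide partition of the QBV reference
#' genome (VN180, NC_012671), verbatim in 1-based reference coordinates.
#'
#' @return A `region_tbl`.
#' @export
qbv_region_fixture <- function() {
  read_region_table(
    system.file("extdata", "qbv_regions.tsv", package = "flavicomp"),
    reference_id = "NC_012671"
  )
}

#' Packaged per-region SNV count fixture
#'
#' Published per-region SNV and nonsynonymous-SNV counts of the three
#' Guizhou QBV isolates against the VN180 reference.
#'
#' @return A tibble with columns `region`, `snv_<isolate>`,
#'   `nonsyn_<isolate>` for the three isolates.
#' @export
qbv_snv_count_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "qbv_snv_counts.tsv", package = "flavicomp"),
    col_types = readr::cols(region = readr::col_character(),
                            .default = readr::col_integer()),
    progress = FALSE
  )
}

#' Simulate a full reference-plus-isolates study
#'
#' The generator's study conditions: a QBV-like reference genome
#' (98/10,080/653 nt segments) and one mutant isolate per column of the
#' packaged SNV count fixture, each planted with exactly the published
#' per-region synonymous/nonsynonymous counts. This gives every downstream
#' stage a dataset whose true per-region counts are the published ones.
#'
#' @param seed Integer seed (mandatory).
#' @param counts Count table (default [qbv_snv_count_fixture()]); columns
#'   `region`, `snv_<id>`, `nonsyn_<id>`.
#' @param ts_tv_bias Transition bias for planted substitutions (default 2).
#' @return A list with `reference`, `table`, `isolates` (genome tibble),
#'   `truth` (planted SNV tibble over all isolates), `spec` (per-isolate
#'   plant specs).
#' @export
simulate_study <- function(seed, counts = qbv_snv_count_fixture(),
                           ts_tv_bias = 2.0) {
  ref <- generate_reference(seed = seed)
  ids <- sub("^snv_", "", grep("^snv_", names(counts), value = TRUE))
  isolates <- list()
  truths <- list()
  specs <- list()
  for (k in seq_along(ids)) {
    idc <- ids[[k]]
    spec <- tibble::tibble(
      region = counts$region,
      n_syn = counts[[paste0("snv_", idc)]] - counts[[paste0("nonsyn_", idc)]],
      n_nonsyn = counts[[paste0("nonsyn_", idc)]]
    )
    pl <- plant_snvs(ref$genome, ref$table, spec, ts_tv_bias = ts_tv_bias,
                     seed = seed + k, id = idc)
    isolates[[k]] <- pl$genome
    truths[[k]] <- pl$truth
    specs[[k]] <- spec
  }
  list(reference = ref$genome, table = ref$table,
       isolates = dplyr::bind_rows(isolates),
       truth = dplyr::bind_rows(truths),
       spec = stats::setNames(specs, ids))
}
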