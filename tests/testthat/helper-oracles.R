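# Independent oracles used across the suite. These deliberately do not share
# code with the package: the full-matrix aligner is a plain three-matrix
# Gotoh DP in R, the folding oracle is an exhaustive recursion over nested
# structures, and the topology oracle scores every unrooted topology by
# least squares.

# full (unbanded) global affine-gap DP; returns the optimal score
nw_full_score <- function(a, b, match = 1, mismatch = -1,
                          gap_open = -4, gap_extend = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an alignment under the same affine convention
score_alignment <- function(ar, aq, match = 1, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  rc <- strsplit(ar, "")[[1]]
  qc <- strsplit(aq, "")[[1]]
  sc <- 0
  in_gap_r <- FALSE; in_gap_q <- FALSE
  for (k in seq_along(rc)) {
    if (rc[k] == "-") {
      sc <- sc + if (in_gap_r) gap_extend else gap_open
      in_gap_r <- TRUE; in_gap_q <- FALSE
    } else if (qc[k] == "-") {
      sc <- sc + if (in_gap_q) gap_extend else gap_open
      in_gap_q <- TRUE; in_gap_r <- FALSE
    } else {
      sc <- sc + if (rc[k] == qc[k]) match else mismatch
      in_gap_r <- FALSE; in_gap_q <- FALSE
    }
  }
  sc
}

# exhaustive search over all nested structures (no memoization): the maximum
# number of pairs under WC+GU rules with a minimum hairpin loop
max_pairs_exhaustive <- function(rna, min_loop = 3, allow_gu = TRUE) {
  v <- strsplit(chartr("T", "U", toupper(rna)), "")[[1]]
  pairable <- function(p, q) {
    a <- v[p]; b <- v[q]
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (allow_gu && ((a == "G" && b == "U") || (a == "U" && b == "G")))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairable(i, k)) {
        cand <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(v) < min_loop + 2) 0L else rec(1L, length(v))
}

# mutate a sequence to a given substitution divergence (returns the string)
mutate_seq <- function(seq, n_subs) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_subs)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# least-squares fit of a distance matrix on a fixed topology: SSE
ls_sse <- function(tree, d) {
  labs <- rownames(d)
  n <- length(labs)
  pairs <- t(combn(n, 2))
  tipidx <- match(labs, tree$tip.label)
  nE <- nrow(tree$edge)
  A <- matrix(0, nrow(pairs), nE)
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- tipidx[pairs[r, 1]]; b <- tipidx[pairs[r, 2]]
    path <- ape::nodepath(tree, a, b)
    for (s in seq_len(length(path) - 1)) {
      e <- which((tree$edge[, 1] == path[s] & tree$edge[, 2] == path[s + 1]) |
                 (tree$edge[, 2] == path[s] & tree$edge[, 1] == path[s + 1]))
      A[r, e] <- 1
    }
    y[r] <- d[pairs[r, 1], pairs[r, 2]]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# exhaustive unrooted topology search: the topology minimizing LS error
best_topology_exhaustive <- function(d) {
  labs <- rownames(d)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  sse <- vapply(trees, ls_sse, numeric(1), d = d)
  trees[[which.min(sse)]]
}

# random unrooted tree with branch lengths; returns list(tree, dist)
random_additive_instance <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = stats::cophenetic(tr))
}

# small region table for hand-built classification tests
toy_region_table <- function(cds_start, cds_end, genome_len,
                             name = "CDS", ref_id = "ref") {
  rows <- tibble::tibble(region = name, start = cds_start, end = cds_end,
                         kind = "mat_peptide")
  if (cds_start > 1) {
    rows <- dplyr::bind_rows(
      tibble::tibble(region = "5UTR", start = 1L, end = cds_start - 1L,
                     kind = "utr"), rows)
  }
  if (cds_end < genome_len) {
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(region = "3UTR", start = cds_end + 1L,
                     end = genome_len, kind = "utr"))
  }
  as_region_tbl(rows, reference_id = ref_id)
}
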