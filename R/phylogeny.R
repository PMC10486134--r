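# Distance-based phylogenetics: p / TN93 distances with pairwise deletion,
# Saitou-Nei neighbor-joining with deterministic tie-breaks, column bootstrap.

# internal: split two aligned strings into comparable-column base pairs
comparable_columns <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1L]]
  y <- strsplit(toupper(b), "")[[1L]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  list(x = x[ok], y = y[ok])
}

#' Proportion of differing sites (p-distance)
#'
#' Mismatches divided by comparable columns; columns with a gap or ambiguity
#' code in either sequence are excluded pairwise.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @return Substitutions per site.
#' @export
p_distance <- function(a, b) {
  cc <- comparable_columns(a, b)
  if (length(cc$x) == 0L) stop("no comparable columns")
  sum(cc$x != cc$y) / length(cc$x)
}

#' Tamura-Nei (1993) distance
#'
#' Closed-form TN93 distance from the two transition proportions (purine
#' `P1` = A<->G, pyrimidine `P2` = C<->T), the transversion proportion `Q`,
#' and empirical base frequencies pooled over both sequences. With
#' `gamma_shape` the standard gamma-rates variant replaces each `-k log(w)`
#' term by `k * a * (w^(-1/a) - 1)`. Saturated pairs (a log argument <= 0)
#' return `Inf` with a warning. Gap/ambiguity columns are excluded pairwise.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @param gamma_shape Optional gamma shape parameter `a` (e.g. 1).
#' @return Substitutions per site (possibly `Inf` when saturated).
#' @export
tn93_distance <- function(a, b, gamma_shape = NULL) {
  cc <- comparable_columns(a, b)
  n <- length(cc$x)
  if (n == 0L) stop("no comparable columns")
  pooled <- c(cc$x, cc$y)
  g <- vapply(c("A", "C", "G", "T"), function(b0) mean(pooled == b0), numeric(1))
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- cc$x != cc$y
  is_ts1 <- diff & (cc$x %in% c("A", "G")) & (cc$y %in% c("A", "G"))
  is_ts2 <- diff & (cc$x %in% c("C", "T")) & (cc$y %in% c("C", "T"))
  P1 <- mean(is_ts1); P2 <- mean(is_ts2); Q <- mean(diff & !is_ts1 & !is_ts2)
  if (P1 + P2 + Q == 0) return(0)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warning("TN93 distance saturated; returning Inf")
    return(Inf)
  }
  term <- function(k, w) {
    if (is.null(gamma_shape)) -k * log(w)
    else k * gamma_shape * (w^(-1 / gamma_shape) - 1)
  }
  term(k1, w1) + term(k2, w2) + term(k3, w3)
}

#' Pairwise distance matrix from aligned sequences
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param model `"tn93"` (default) or `"p"`.
#' @param gamma_shape Optional gamma shape for TN93.
#' @return Symmetric numeric matrix (substitutions/site) with sequence names
#'   as dimnames.
#' @export
distance_matrix <- function(msa, model = c("tn93", "p"), gamma_shape = NULL) {
  model <- match.arg(model)
  stopifnot(!is.null(names(msa)), length(msa) >= 2L)
  n <- length(msa)
  m <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (model == "p") p_distance(msa[[i]], msa[[j]])
           else tn93_distance(msa[[i]], msa[[j]], gamma_shape)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair minimizing
#' the Q-criterion `(n-2) d(i,j) - r(i) - r(j)`; branch lengths from the
#' usual formulas; new distances by the reduction formula. Ties are broken by
#' the lexicographically lowest pair of current cluster indices, so the
#' result is deterministic. Negative branch-length estimates are clamped to
#' zero (count in attribute `negative_clamped`).
#'
#' @param d Symmetric numeric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  frag <- labels           # newick fragment per active cluster
  D <- d
  clamped <- 0L
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # lexicographically lowest (i, j), i < j, among ties
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (Q[i, j] <= qmin + 1e-12) { best <- c(i, j); break }
      }
      if (!is.null(best)) break
    }
    i <- best[[1L]]; j <- best[[2L]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; lj <- min(lj - li, D[i, j]); li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- min(li - lj, D[i, j]); lj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[[i]], li, frag[[j]], lj)
    others <- setdiff(seq_len(n), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    newd <- pmax(newd, 0)
    D2 <- rbind(cbind(D[others, others, drop = FALSE], newd),
                c(newd, 0))
    frag <- c(frag[others], newfrag)
    rownames(D2) <- colnames(D2) <- seq_len(nrow(D2))
    D <- D2
  }
  # resolve the final three clusters around the central node
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  clamped <- clamped + sum(c(v1, v2, v3) < 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[[1L]], v[[1L]], frag[[2L]], v[[2L]], frag[[3L]], v[[3L]])
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition
#' (counted with `ape::prop.clades`). Replicates in which all resampled
#' sequences are identical carry no signal and are skipped (reported in
#' `n_skipped`); supports are percentages of the replicates actually used.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory; the resampling is the only source of
#'   randomness).
#' @param model,gamma_shape Distance model, as [distance_matrix()].
#' @return A list: `tree` (the original-data NJ tree with `node.label` set to
#'   the supports), `supports` (numeric per internal node), `n_used`,
#'   `n_skipped`.
#' @export
nj_bootstrap <- function(msa, n_reps = 1000, seed, model = "tn93",
                         gamma_shape = NULL) {
  stopifnot(n_reps >= 1)
  tree <- neighbor_joining(distance_matrix(msa, model, gamma_shape))
  L <- nchar(msa[[1L]])
  chars <- lapply(msa, function(s) strsplit(s, "")[[1L]])
  boot_trees <- list()
  n_skipped <- 0L
  with_local_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      res <- vapply(chars, function(v) paste(v[idx], collapse = ""), character(1))
      if (length(unique(res)) == 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      bt <- tryCatch(
        neighbor_joining(distance_matrix(res, model, gamma_shape)),
        error = function(e) NULL
      )
      if (!is.null(bt)) boot_trees[[length(boot_trees) + 1L]] <- bt
      else n_skipped <- n_skipped + 1L
    }
  })
  n_used <- n_reps - n_skipped
  if (n_used == 0L) stop("all bootstrap replicates degenerate")
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round_half_up(100 * counts / n_used, 1)
  tree$node.label <- as.character(supports)
  list(tree = tree, supports = supports, n_used = n_used,
       n_skipped = n_skipped)
}

# internal: run code with a temporary RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(code))
}

#' Write a tree in Newick format
#'
#' Branch lengths and (when present) internal-node support labels are
#' serialized; `ape::read.tree` round-trips topology and lengths.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Stack reference-anchored pairwise alignments into a pseudo-MSA
#'
#' Aligns every other genome to the chosen reference and records, for each
#' reference position, the base each query aligns there (`-` where the query
#' is gapped; insertions relative to the reference are dropped). The result
#' is a set of equal-length sequences in reference coordinates, suitable for
#' [distance_matrix()] with pairwise deletion. This sidesteps progressive
#' multiple alignment; at the within-species divergences the pipeline
#' targets, the reference-anchored columns match an MSA over the shared span.
#'
#' @param genomes Genome tibble (>= 2 rows).
#' @param ref_id Id of the reference genome (default: first row).
#' @param ... Parameters passed to [global_align()].
#' @return Named character vector of equal-length sequences.
#' @export
stack_alignments <- function(genomes, ref_id = genomes$id[[1L]], ...) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 2L)
  ref <- genomes[genomes$id == ref_id, ]
  if (nrow(ref) != 1L) stop("ref_id not found (or not unique) in genomes")
  ref_len <- nchar(ref$sequence[[1L]])
  out <- stats::setNames(ref$sequence[[1L]], ref_id)
  for (i in which(genomes$id != ref_id)) {
    aln <- global_align(ref, genomes[i, ], ...)
    td <- tidy(aln)
    row <- rep("-", ref_len)
    keep <- !is.na(td$ref_pos)
    row[td$ref_pos[keep]] <- td$qry_base[keep]
    out[[genomes$id[[i]]]] <- paste(row, collapse = "")
  }
  out
}
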