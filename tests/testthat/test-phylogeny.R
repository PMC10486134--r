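test_that("p-distance uses pairwise deletion of gap/ambiguous columns", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance(strrep("A", 100), paste0(strrep("A", 90),
                                                   strrep("C", 10))), 0.1)
  # gap column excluded from the denominator
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3)
  expect_error(p_distance("---", "AAA"), "no comparable")
})

test_that("TN93 is zero for identical pairs and dominates the p-distance", {
  s <- random_dna_str(500)
  expect_equal(tn93_distance(s, s), 0)
  set.seed(123)
  for (k in 1:50) {
    a <- random_dna_str(400)
    b <- mutate_seq(a, sample(10:60, 1))
    expect_gte(tn93_distance(a, b), p_distance(a, b) - 1e-12)
  }
})

test_that("TN93 agrees with an independent implementation of the same formulas", {
  set.seed(7)
  ref <- generate_reference(seed = 3, utr5_len = 20, cds_len = 900,
                            utr3_len = 30,
                            region_lengths = c(R1 = 450L, R2 = 450L))
  ev <- evolve_on_tree(ref$genome,
                       "((A:0.05,B:0.08):0.02,(C:0.06,D:0.04):0.03);",
                       seed = 9)
  msa <- stats::setNames(ev$genomes$sequence, ev$genomes$id)
  bin <- ape::as.DNAbin(do.call(rbind, lapply(msa, function(s)
    strsplit(s, "")[[1]])))
  mine <- distance_matrix(msa, "tn93")
  oracle <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                    pairwise.deletion = TRUE))
  expect_lt(max(abs(mine - oracle[rownames(mine), colnames(mine)])), 1e-3)
  mine_g <- distance_matrix(msa, "tn93", gamma_shape = 1)
  oracle_g <- as.matrix(ape::dist.dna(bin, model = "TN93", gamma = 1,
                                      pairwise.deletion = TRUE))
  expect_lt(max(abs(mine_g - oracle_g[rownames(mine_g), colnames(mine_g)])),
            1e-3)
})

test_that("TN93 flags saturated pairs", {
  a <- strrep("A", 60)
  b <- strrep("G", 60)
  expect_warning(d <- tn93_distance(a, b), "saturated")
  expect_equal(d, Inf)
})

test_that("three taxa resolve with closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[c("a", "b", "c")],
               c(a = 1, b = 2, c = 3))
})

test_that("NJ recovers additive four-taxon trees found by exhaustive search", {
  set.seed(17)
  for (k in 1:5) {
    inst <- random_additive_instance(4)
    nj <- neighbor_joining(inst$d)
    oracle <- best_topology_exhaustive(inst$d)
    expect_equal(phangorn::RF.dist(nj, oracle), 0)
    expect_equal(phangorn::RF.dist(nj, inst$tree), 0)
  }
})

test_that("NJ rejects non-symmetric input and needs three taxa", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), "3 taxa")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "symmetric")
})

test_that("NJ agrees with an established implementation on random matrices", {
  set.seed(29)
  for (n in c(5, 8)) {
    inst <- random_additive_instance(n)
    noisy <- inst$d + matrix(stats::runif(n * n, 0, 0.01), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- neighbor_joining(noisy)
    ref <- ape::nj(as.dist(noisy))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("bootstrap finds near-certain support for a planted split", {
  set.seed(31)
  base <- random_dna_str(400)
  cladeAB <- mutate_seq(base, 25)
  cladeCD <- mutate_seq(base, 25)
  msa <- c(A = mutate_seq(cladeAB, 2), B = mutate_seq(cladeAB, 2),
           C = mutate_seq(cladeCD, 2), D = mutate_seq(cladeCD, 2))
  bs <- nj_bootstrap(msa, n_reps = 100, seed = 5)
  # the single internal edge separates AB from CD
  expect_gte(min(bs$supports[-1]), 95)
  # determinism under a fixed seed
  bs2 <- nj_bootstrap(msa, n_reps = 100, seed = 5)
  expect_identical(bs$supports, bs2$supports)
  # n_reps = 1: supports are all-or-nothing
  bs1 <- nj_bootstrap(msa, n_reps = 1, seed = 8)
  expect_true(all(bs1$supports %in% c(0, 100)))
})

test_that("bootstrap supports are equivariant under taxon reordering", {
  set.seed(37)
  base <- random_dna_str(300)
  msa <- c(A = mutate_seq(base, 30), B = mutate_seq(base, 5),
           C = mutate_seq(base, 18), D = mutate_seq(base, 12))
  b1 <- nj_bootstrap(msa, n_reps = 50, seed = 3)
  b2 <- nj_bootstrap(msa[c("C", "A", "D", "B")], n_reps = 50, seed = 3)
  s1 <- sort(unname(b1$supports[-1]))
  s2 <- sort(unname(b2$supports[-1]))
  expect_equal(s1, s2, tolerance = 10)
})

test_that("Newick output round-trips topology, lengths and supports", {
  d <- cophenetic(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);"))
  tr <- neighbor_joining(d)
  tr$node.label <- c("", "98")
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- ape::read.tree(tf)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_true("98" %in% back$node.label)
})

test_that("stacked pairwise alignments equal the true MSA without indels", {
  ref <- generate_reference(seed = 41, utr5_len = 10, cds_len = 300,
                            utr3_len = 10, region_lengths = c(R1 = 300L))
  genomes <- ref$genome
  set.seed(43)
  for (k in 1:2) {
    g <- ref$genome
    g$id <- paste0("iso", k)
    g$sequence <- mutate_seq(g$sequence, 15)
    genomes <- dplyr::bind_rows(genomes, g)
  }
  msa <- stack_alignments(genomes)
  expect_equal(unname(nchar(msa)), rep(320L, 3))
  expect_equal(unname(msa[c("iso1", "iso2")]),
               genomes$sequence[2:3])
})
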