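test_that("the default reference has the emulated genome architecture", {
  ref <- generate_reference(seed = 1)
  expect_equal(ref$genome$length, 10831L)
  expect_equal(orf_span(ref$table), c(99L, 10178L))
  expect_equal(sum(ref$table$length[ref$table$kind == "mat_peptide"]), 10080L)
  # ORF structure: starts ATG, ends in a stop, no internal stop in frame
  cds <- substring(ref$genome$sequence, 99, 10178)
  expect_equal(substring(cds, 1, 3), "ATG")
  aa <- translate_cds(cds)
  expect_equal(nchar(aa), 3359L)
  expect_false(grepl("\\*", aa))
})

test_that("generation is deterministic in the seed", {
  a <- generate_reference(seed = 7)
  b <- generate_reference(seed = 7)
  c <- generate_reference(seed = 8)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("planted SNVs hit the requested counts with verified effects", {
  ref <- generate_reference(seed = 12, utr5_len = 30, cds_len = 1200,
                            utr3_len = 40,
                            region_lengths = c(R1 = 600L, R2 = 600L))
  spec <- tibble::tibble(region = c("R1", "R2"), n_syn = c(10L, 6L),
                         n_nonsyn = c(4L, 8L))
  pl <- plant_snvs(ref$genome, ref$table, spec, seed = 13, id = "iso")
  expect_equal(nrow(pl$truth), 28L)
  # mutant differs from the reference at exactly the planted positions
  rv <- strsplit(ref$genome$sequence, "")[[1]]
  mv <- strsplit(pl$genome$sequence, "")[[1]]
  expect_equal(which(rv != mv), pl$truth$ref_pos)
  # the truth effects agree with the package's classifier
  cl <- classify_snvs(
    dplyr::mutate(pl$truth[, c("genome", "ref_pos", "ref_base", "alt_base")],
                  qry_pos = .data$ref_pos),
    ref$genome, ref$table)
  expect_equal(cl$effect, pl$truth$effect)
  # every nonsynonymous SNV changes the polyprotein at exactly one residue
  orf <- orf_span(ref$table)
  aa_ref <- strsplit(translate_cds(substring(ref$genome$sequence, orf[1],
                                             orf[2])), "")[[1]]
  aa_mut <- strsplit(translate_cds(substring(pl$genome$sequence, orf[1],
                                             orf[2])), "")[[1]]
  expect_equal(sum(aa_ref != aa_mut), sum(pl$truth$effect == "nonsynonymous"))
})

test_that("an all-zero spec returns the reference unchanged", {
  ref <- generate_reference(seed = 14, utr5_len = 10, cds_len = 300,
                            utr3_len = 10, region_lengths = c(R1 = 300L))
  pl <- plant_snvs(ref$genome, ref$table,
                   tibble::tibble(region = "R1", n_syn = 0L, n_nonsyn = 0L),
                   seed = 15)
  expect_identical(pl$genome$sequence, ref$genome$sequence)
  expect_equal(nrow(pl$truth), 0L)
})

test_that("infeasible specs fail naming the region", {
  ref <- generate_reference(seed = 16, utr5_len = 10, cds_len = 300,
                            utr3_len = 10, region_lengths = c(R1 = 300L))
  expect_error(
    plant_snvs(ref$genome, ref$table,
               tibble::tibble(region = "R1", n_syn = 200L, n_nonsyn = 0L),
               seed = 17),
    "R1")
})

test_that("the study simulation plants the published per-region counts", {
  sim <- simulate_study(seed = 3)
  expect_equal(nrow(sim$isolates), 3L)
  counts <- qbv_snv_count_fixture()
  planted <- sim$truth |>
    dplyr::filter(.data$genome == "GZ21m081") |>
    dplyr::count(.data$region)
  for (r in counts$region) {
    expect_equal(planted$n[planted$region == r],
                 counts$snv_GZ21m081[counts$region == r])
  }
})

test_that("evolution along a zero-length tree copies the root sequence", {
  ref <- generate_reference(seed = 22, utr5_len = 10, cds_len = 300,
                            utr3_len = 10, region_lengths = c(R1 = 300L))
  ev <- evolve_on_tree(ref$genome, "(A:0,B:0);", seed = 23)
  expect_equal(unique(ev$genomes$sequence), ref$genome$sequence)
  expect_error(evolve_on_tree(ref$genome, "(A:-0.1,B:0.1);", seed = 1),
               "negative")
})

test_that("pairwise divergence under JC matches the closed form", {
  ref <- generate_reference(seed = 24)  # 10,080-nt CDS genome
  ev <- evolve_on_tree(ref$genome, "(A:0.05,B:0.05);", seed = 25)
  p_obs <- p_distance(ev$genomes$sequence[[1]], ev$genomes$sequence[[2]])
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))   # 0.0945 at distance 0.1
  n <- ref$genome$length
  mc_sd <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * mc_sd)
})

test_that("NJ on TN93 distances recovers the generating eight-leaf topology", {
  set.seed(26)
  ref <- generate_reference(seed = 26, utr5_len = 20, cds_len = 2400,
                            utr3_len = 30, region_lengths = c(R1 = 2400L))
  tr <- ape::unroot(ape::rtree(8))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.08)
  ev <- evolve_on_tree(ref$genome, tr, seed = 27)
  msa <- stats::setNames(ev$genomes$sequence, ev$genomes$id)
  nj <- neighbor_joining(distance_matrix(msa, "tn93"))
  expect_equal(phangorn::RF.dist(nj, tr), 0)
})

test_that("TN93 distance is monotone in simulated divergence time", {
  ref <- generate_reference(seed = 28, utr5_len = 10, cds_len = 3000,
                            utr3_len = 10, region_lengths = c(R1 = 3000L))
  times <- seq(0.01, 0.4, length.out = 10)
  dists <- vapply(seq_along(times), function(i) {
    ev <- evolve_on_tree(ref$genome,
                         sprintf("(A:%f,B:0);", times[i]), seed = 300 + i)
    tn93_distance(ev$genomes$sequence[[1]], ev$genomes$sequence[[2]])
  }, numeric(1))
  expect_equal(stats::cor(times, dists, method = "spearman"), 1)
})

test_that("slippery-site planting is deterministic and collision-free", {
  ref <- generate_reference(seed = 29, utr5_len = 20, cds_len = 900,
                            utr3_len = 250, region_lengths = c(R1 = 900L))
  g <- ref$genome
  g$sequence <- scrub_slippery(g$sequence)
  a <- plant_prf_site(g, 500, seed = 4)
  b <- plant_prf_site(g, 500, seed = 4)
  expect_identical(a$genome$sequence, b$genome$sequence)
  hits <- scan_slippery(a$genome$sequence)
  expect_equal(hits$start, 500L)
})
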