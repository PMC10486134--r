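test_that("slippery scan finds exact and overlapping matches", {
  seq <- paste0(strrep("C", 3418), "GGATTTC", strrep("C", 200))
  hits <- scan_slippery(seq)
  expect_equal(hits$pattern, "GGAUUUC")
  expect_equal(hits$start, 3419L)

  expect_equal(nrow(scan_slippery(strrep("C", 100))), 0L)

  over <- scan_slippery("TTTTTTTT")
  expect_equal(over$start, c(1L, 2L))
  expect_equal(unique(over$pattern), "UUUUUUU")

  expect_error(scan_slippery("ACGT", patterns = "GGAXUUC"), "non-RNA")
  expect_error(scan_slippery("ACGT", patterns = "GGAU"), "7 nt")

  # interval restriction
  seq2 <- paste0("GGATTTC", strrep("A", 50), "GGATTTC")
  expect_equal(scan_slippery(seq2, search_interval = c(10, 70))$start, 58L)
})

test_that("folding maximizes base pairs with the expected structures", {
  fr <- fold_rna("GGGGAAAACCCC")
  expect_equal(fr$pair_count, 4L)
  expect_equal(fr$structure, "((((....))))")

  fr0 <- fold_rna("AAAAAA")
  expect_equal(fr0$pair_count, 0L)
  expect_equal(fr0$structure, "......")

  # DNA input is folded as RNA
  expect_equal(fold_rna("GGGGAAAACCCC")$structure,
               fold_rna("GGGGAAAACCCC")$structure)
  # structure is balanced and matches the pairing list
  fr2 <- fold_rna(random_dna_str(40))
  expect_equal(nchar(fr2$structure), 40L)
  expect_equal(sum(strsplit(fr2$structure, "")[[1]] == "("),
               fr2$pair_count)
})

test_that("fold pair counts match exhaustive enumeration on small windows", {
  set.seed(51)
  for (k in 1:15) {
    w <- random_dna_str(sample(8:18, 1))
    expect_equal(fold_rna(w)$pair_count, max_pairs_exhaustive(w),
                 info = w)
  }
})

test_that("GU wobble pairs obey the allow_gu switch", {
  # a G/U-only window can pair only through GU wobble
  expect_gt(fold_rna("GGGGGUUUUU", allow_gu = TRUE)$pair_count, 0L)
  expect_equal(fold_rna("GGGGGUUUUU", allow_gu = FALSE)$pair_count, 0L)
})

test_that("stem-loop geometry checks stem length, loop size and position", {
  fr <- fold_rna("GGGGAAAACCCC")
  sl <- stem_loop_check(fr)
  expect_true(sl$found)
  expect_equal(sl$stem_length, 4L)
  expect_equal(sl$loop_length, 4L)

  # a lone pair is not a stem
  single <- fold_rna("GAAAC")  # one GC pair possible
  expect_false(stem_loop_check(single)$found)

  # a hairpin beyond the search prefix is rejected
  far <- paste0(strrep("A", 70), "GGGGGG", "AAAA", "CCCCCC")
  expect_false(stem_loop_check(fold_rna(far), search_prefix = 60)$found)
  expect_true(stem_loop_check(fold_rna(far), search_prefix = 90)$found)
})

test_that("planted sites are detected with their designed geometry", {
  ref <- generate_reference(seed = 55)
  g <- ref$genome
  g$sequence <- scrub_slippery(g$sequence)
  g$length <- nchar(g$sequence)
  pl <- plant_prf_site(g, 3419, seed = 2)
  sites <- detect_prf(pl$genome, table = ref$table)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pattern, "GGAUUUC")
  expect_equal(sites$start, 3419L)
  expect_true(sites$stem_loop_found)
  expect_equal(sites$stem_length, 8L)
  expect_equal(sites$loop_length, 5L)
  expect_equal(sites$region, "NS2A")
  # genome-slice invariant: the genome really carries the pattern
  expect_equal(substring(chartr("T", "U", pl$genome$sequence), 3419, 3425),
               sites$pattern)
})

test_that("a weak stem below min_stem is reported but not verified", {
  # downstream window built from A/C plus a 2-bp GC stem: at most two base
  # pairs can ever form, so no qualifying hairpin exists anywhere
  down <- paste0(strrep("A", 10), "GG", "AAAAA", "CC", strrep("CA", 60))
  seqn <- paste0(strrep("C", 50), "GGATTTC", down)
  sites <- detect_prf(c(g = seqn))
  expect_equal(sites$start, 51L)
  expect_false(sites$stem_loop_found)
  # the same geometry with an 8-bp stem verifies
  down2 <- paste0(strrep("A", 10), "GGGGGGGG", "AAAAA", "CCCCCCCC",
                  strrep("CA", 55))
  sites2 <- detect_prf(c(g = paste0(strrep("C", 50), "GGATTTC", down2)))
  expect_true(sites2$stem_loop_found)
  expect_equal(sites2$stem_length, 8L)
  expect_equal(sites2$loop_length, 5L)
})

test_that("pattern-free genomes yield no sites", {
  ref <- generate_reference(seed = 57, utr5_len = 20, cds_len = 1200,
                            utr3_len = 50, region_lengths = c(R1 = 1200L))
  clean <- scrub_slippery(ref$genome$sequence)
  expect_equal(nrow(detect_prf(c(g = clean))), 0L)
})

test_that("matches near the 3' end carry a truncated-window flag", {
  seq <- paste0(strrep("C", 100), "GGATTTC", strrep("A", 20))
  sites <- detect_prf(c(g = seq))
  expect_equal(sites$start, 101L)
  expect_true(sites$truncated)
  expect_equal(sites$window_len, 20L)
})

test_that("site reports serialize pattern, coordinates and structure", {
  seq <- paste0(strrep("C", 30), "GGATTTC", strrep("A", 10),
                "GGCGGCGG", "AAAAA", "CCGCCGCC", strrep("C", 120))
  sites <- detect_prf(c(g = seq))
  prefix <- file.path(withr::local_tempdir(), "prf")
  write_prf_report(sites, prefix)
  tsv <- readr::read_tsv(paste0(prefix, "_sites.tsv"), show_col_types = FALSE)
  expect_equal(tsv$start, sites$start)
  txt <- readLines(paste0(prefix, "_structures.txt"))
  expect_true(any(grepl("GGAUUUC", txt)))
})
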