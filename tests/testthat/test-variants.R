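test_that("call_snvs reports exactly the differing unambiguous columns", {
  aln <- global_align(c(r = "ACGT"), c(q = "ACGT"))
  expect_equal(nrow(call_snvs(aln)), 0L)

  aln2 <- global_align(c(r = "ACGT"), c(q = "ACAT"))
  snv <- call_snvs(aln2)
  expect_equal(snv$ref_pos, 3L)
  expect_equal(snv$ref_base, "G")
  expect_equal(snv$alt_base, "A")

  # ambiguity and gap columns yield no SNVs
  aln3 <- flavicomp:::new_pairwise_aln("r", "q", "ACNGTT", "AC-GAT", 0)
  snv3 <- call_snvs(aln3)
  expect_equal(snv3$ref_pos, 5L)
})

test_that("classification follows the genetic code against the reference codon", {
  # genome: 2-nt leader, CDS ATG AAA GAT TAA, 2-nt trailer
  refseq <- paste0("TT", "ATGAAAGATTAA", "GG")
  tbl <- toy_region_table(3L, 14L, 16L)
  ref <- c(ref = refseq)
  snvs <- tibble::tibble(
    genome = "q", ref_pos = c(8L, 9L, 1L),
    qry_pos = c(8L, 9L, 1L),
    ref_base = c("A", "G", "T"), alt_base = c("G", "A", "C")
  )
  cl <- classify_snvs(snvs, ref, tbl)
  # AAA -> AAG at codon pos 3: Lys -> Lys, synonymous
  expect_equal(cl$effect[cl$ref_pos == 8], "synonymous")
  expect_equal(cl$ref_codon[cl$ref_pos == 8], "AAA")
  expect_equal(cl$alt_codon[cl$ref_pos == 8], "AAG")
  # GAT -> AAT at codon pos 1: Asp -> Asn, nonsynonymous
  expect_equal(cl$effect[cl$ref_pos == 9], "nonsynonymous")
  expect_equal(cl$ref_aa[cl$ref_pos == 9], "D")
  expect_equal(cl$alt_aa[cl$ref_pos == 9], "N")
  # leader position is noncoding
  expect_equal(cl$effect[cl$ref_pos == 1], "noncoding")
  expect_equal(cl$region[cl$ref_pos == 1], "5UTR")
})

test_that("two SNVs in one codon are each evaluated against the reference codon", {
  refseq <- paste0("ATG", "GAT", "TAA")
  tbl <- toy_region_table(1L, 9L, 9L)
  snvs <- tibble::tibble(
    genome = "q", ref_pos = c(4L, 6L), qry_pos = c(4L, 6L),
    ref_base = c("G", "T"), alt_base = c("A", "C")
  )
  cl <- classify_snvs(snvs, c(ref = refseq), tbl)
  # GAT->AAT (D->N, nonsyn); GAT->GAC (D->D, syn) -- independent calls
  expect_equal(cl$effect, c("nonsynonymous", "synonymous"))
  expect_true(all(cl$multihit))
  expect_equal(unique(cl$codon_index), 2L)
})

test_that("classification agrees with exhaustive codon-substitution enumeration", {
  code <- Biostrings::GENETIC_CODE
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  codons <- names(code)[sample(length(code), 30)]
  refseq <- paste0("AA", paste(codons, collapse = ""), "CC")
  tbl <- toy_region_table(3L, 2L + 3L * length(codons), nchar(refseq))
  for (ci in seq_along(codons)) {
    for (cp in 1:3) {
      pos <- 2L + (ci - 1L) * 3L + cp
      rb <- substr(codons[ci], cp, cp)
      for (alt in setdiff(bases, rb)) {
        cl <- classify_snvs(
          tibble::tibble(genome = "q", ref_pos = pos, qry_pos = pos,
                         ref_base = rb, alt_base = alt),
          c(ref = refseq), tbl
        )
        mutated <- codons[ci]
        substr(mutated, cp, cp) <- alt
        expected <- if (code[[codons[ci]]] == code[[mutated]]) {
          "synonymous"
        } else {
          "nonsynonymous"
        }
        expect_equal(cl$effect, expected,
                     info = sprintf("%s pos %d -> %s", codons[ci], cp, alt))
      }
    }
  }
})

test_that("region summary counts planted SNVs and builds the totals row", {
  ref <- generate_reference(seed = 61, utr5_len = 20, cds_len = 600,
                            utr3_len = 30,
                            region_lengths = c(R1 = 300L, R2 = 300L))
  spec <- tibble::tibble(region = c("R1", "R2"), n_syn = c(5L, 2L),
                         n_nonsyn = c(3L, 4L))
  mut <- plant_snvs(ref$genome, ref$table, spec, seed = 62, id = "iso1")
  aln <- global_align(ref$genome, mut$genome)
  cl <- classify_snvs(call_snvs(aln), ref$genome, ref$table)
  sm <- summarize_regions(cl, ref$table)
  expect_equal(sm$snv_iso1[sm$region == "R1"], 8L)
  expect_equal(sm$nonsyn_iso1[sm$region == "R1"], 3L)
  expect_equal(sm$snv_iso1[sm$region == "R2"], 6L)
  expect_equal(sm$nonsyn_iso1[sm$region == "R2"], 4L)
  expect_equal(sm$snv_iso1[sm$region == "Total"], 14L)
  # conservation: region counts (incl. UTRs) sum to the number of calls
  expect_equal(sum(sm$snv_iso1[sm$region != "Total"]), nrow(cl))
})

test_that("noncoding SNVs are counted under UTR rows, outside the totals", {
  ref <- generate_reference(seed = 63, utr5_len = 50, cds_len = 300,
                            utr3_len = 50, region_lengths = c(R1 = 300L))
  spec <- tibble::tibble(region = c("R1", "5UTR", "3UTR"),
                         n_syn = c(2L, 0L, 0L), n_nonsyn = c(1L, 0L, 0L),
                         n_noncoding = c(0L, 4L, 2L))
  mut <- plant_snvs(ref$genome, ref$table, spec, seed = 64, id = "q")
  aln <- global_align(ref$genome, mut$genome)
  cl <- classify_snvs(call_snvs(aln), ref$genome, ref$table)
  sm <- summarize_regions(cl, ref$table)
  expect_equal(sm$snv_q[sm$region == "5UTR"], 4L)
  expect_equal(sm$snv_q[sm$region == "3UTR"], 2L)
  expect_equal(sm$snv_q[sm$region == "Total"], 3L)
  expect_equal(sum(cl$effect == "noncoding"), 6L)
})

test_that("substitution spectrum proportions match hand arithmetic", {
  snvs <- tibble::tibble(
    genome = "q",
    ref_base = c(rep("A", 6), rep("G", 4), rep("C", 7)),
    alt_base = c(rep("G", 6), rep("A", 4), rep("T", 7)),
    region = "NS3", effect = "nonsynonymous"
  )
  sp <- snv_spectrum(snvs)
  expect_equal(sp$count[sp$type == "A>G"], 6L)
  expect_equal(sp$proportion[sp$type == "A>G"], 35.3)  # 6/17
  sp13 <- snv_spectrum(snvs[1:13, ])
  expect_equal(sp13$proportion[sp13$type == "G>A"], 30.8)  # 4/13
  # empty input: zero counts, undefined proportions
  sp0 <- snv_spectrum(snvs[0, ])
  expect_equal(sum(sp0$count), 0L)
  expect_true(all(is.na(sp0$proportion)))
  # filters
  spf <- snv_spectrum(snvs, regions = "NS3", effects = "nonsynonymous")
  expect_equal(sum(spf$count), 17L)
})

test_that("VCF output round-trips classified records", {
  ref <- generate_reference(seed = 71, utr5_len = 30, cds_len = 1200,
                            utr3_len = 40,
                            region_lengths = c(R1 = 600L, R2 = 600L))
  spec <- tibble::tibble(region = c("R1", "R2"), n_syn = c(30L, 20L),
                         n_nonsyn = c(25L, 25L))
  mut <- plant_snvs(ref$genome, ref$table, spec, seed = 72, id = "q")
  aln <- global_align(ref$genome, mut$genome)
  cl <- classify_snvs(call_snvs(aln), ref$genome, ref$table)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cl, ref$genome, tf)
  back <- read_vcf(tf)
  expect_equal(back, cl[names(back)])

  # a mainstream VCF parser reads the same positions and alleles
  v <- vcfR::read.vcfR(tf, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), cl$ref_pos)
  expect_equal(unname(v@fix[, "ALT"]), cl$alt_base)

  # header-only VCF for an empty record set
  write_vcf(cl[0, ], ref$genome, tf)
  expect_equal(nrow(read_vcf(tf)), 0L)
  expect_true(any(startsWith(readLines(tf), "##fileformat=VCFv4.2")))
})
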