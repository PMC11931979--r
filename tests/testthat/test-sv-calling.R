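test_that("amplicon tallying counts reads and unique UMIs per pair and decodes sites", {
  bc1 <- ac_barcode(201); bc2 <- ac_barcode(202)
  core <- function(site) paste0(
    "TGAGC", bc1, shufflekit:::SITE_SUFFIX_CS2[[site]],
    shufflekit:::SITE_CORES[[site]],
    "AAAGC", bc2, shufflekit:::SITE_SUFFIX_CS1[[site]])
  umis <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  reads <- data.table::data.table(
    seq = paste0(rep(umis, c(5, 3, 2)), core("attL")))
  tal <- tally_amplicons(reads)
  expect_identical(nrow(tal), 1L)
  expect_identical(tal$read_count, 10L)
  expect_identical(tal$umi_count, 3L)
  expect_identical(tal$site, "attL")
  expect_identical(tal$barcode1, bc1)

  # unparseable reads are excluded and tallied in QC
  reads_bad <- rbind(reads, data.table::data.table(seq = strrep("T", 90)))
  tal2 <- tally_amplicons(reads_bad)
  expect_identical(attr(tal2, "qc")$unparseable_reads, 1L)

  # reverse-orientation reads are re-oriented to the intrinsic frame
  rev_reads <- data.table::data.table(
    seq = paste0("TTTTTTTT", revcomp(core("attP"))))
  tal3 <- tally_amplicons(rev_reads)
  expect_identical(tal3$barcode1, bc1)
  expect_identical(tal3$site, "attP")
  expect_identical(tal3$orientation, "rev")
})

test_that("four-primer collapse requires both amplicon orientations", {
  tb <- data.table::data.table(
    barcode1 = rep(ac_barcode(210), 3), barcode2 = rep(ac_barcode(211), 3),
    site = "attL", orientation = c("fwd", "rev", "fwd"),
    replicate = c(1L, 1L, 2L), read_count = c(5L, 7L, 4L),
    umi_count = c(2L, 3L, 2L))
  out <- collapse_four_primer(tb)
  expect_identical(out[replicate == 1]$read_count, 12L)    # 5 + 7 summed
  expect_identical(out[replicate == 1]$umi_count, 5L)
  expect_identical(nrow(out[replicate == 2]), 0L)          # one orientation

  one_ori <- tb[orientation == "fwd"]
  expect_error(collapse_four_primer(one_ori), "both")
})

test_that("normalization is CPM within replicate, then replicate-averaged", {
  tb <- data.table::data.table(
    barcode1 = c("b1", "b2", "b1", "b2"), barcode2 = c("c1", "c2", "c1", "c2"),
    site = "loxPsym", replicate = c(1L, 1L, 2L, 2L),
    read_count = c(30L, 70L, 60L, 140L), umi_count = c(3L, 7L, 6L, 14L))
  out <- normalize_and_average(tb)
  # depth halves between replicates but CPM is invariant
  expect_equal(out[barcode1 == "b1"]$norm_reads, 0.3 * 1e6)
  expect_equal(out[barcode1 == "b2"]$norm_reads, 0.7 * 1e6)

  # duplicating a replicate leaves the average unchanged
  tb3 <- rbind(tb, data.table::copy(tb[replicate == 2])[, replicate := 3L])
  out3 <- normalize_and_average(tb3)
  expect_equal(out3$norm_reads, out$norm_reads)

  # single replicate: normalization only
  out1 <- normalize_and_average(tb[replicate == 1])
  expect_equal(out1[barcode1 == "b1"]$norm_reads, 0.3 * 1e6)
})

test_that("novel pair detection enforces parental membership and the UMI floor", {
  pm <- toy_parental_map()
  mk <- function(b1, b2, umis) data.table::data.table(
    barcode1 = b1, barcode2 = b2, site = "loxPsym", umi_count = umis,
    read_count = umis * 5L)
  # (X.bc1, Y.bc2) at 3 UMIs: candidate
  tb <- mk(pm$barcode1[1], pm$barcode2[2], 3L)
  out <- call_novel_pairs(tb, pm)
  expect_identical(nrow(out), 1L)
  expect_identical(out$parent1, 1L)
  expect_identical(out$parent2, 2L)

  # 1 UMI: rejected; parental combination: rejected; unknown barcode: rejected
  expect_identical(nrow(call_novel_pairs(mk(pm$barcode1[1], pm$barcode2[2], 1L),
                                         pm)), 0L)
  expect_identical(nrow(call_novel_pairs(mk(pm$barcode1[1], pm$barcode2[1], 9L),
                                         pm)), 0L)
  expect_identical(nrow(call_novel_pairs(mk(pm$barcode1[1], ac_barcode(999), 9L),
                                         pm)), 0L)

  # reciprocal pairs share a group id
  tb2 <- rbind(mk(pm$barcode1[1], pm$barcode2[2], 3L),
               mk(pm$barcode1[2], pm$barcode2[1], 4L))
  out2 <- call_novel_pairs(tb2, pm)
  expect_identical(out2$reciprocal_group[1], out2$reciprocal_group[2])
})

test_that("classification follows the orientation rules and is parent-symmetric", {
  pm <- toy_parental_map()
  # same chromosome, same orientation: deletion with the coordinate distance
  sv <- classify_sv(list(barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[2]),
                    pm)
  expect_identical(sv$class, "deletion")
  expect_identical(sv$size, 2500000L)
  # reciprocal combination classifies identically
  sv_r <- classify_sv(list(barcode1 = pm$barcode1[2],
                           barcode2 = pm$barcode2[1]), pm)
  expect_identical(sv_r$class, "deletion")
  expect_identical(sv_r$size, sv$size)

  # opposite orientation: inversion; different chromosomes: translocation
  expect_identical(classify_sv(list(barcode1 = pm$barcode1[1],
                                    barcode2 = pm$barcode2[3]), pm)$class,
                   "inversion")
  expect_identical(classify_sv(list(barcode1 = pm$barcode1[1],
                                    barcode2 = pm$barcode2[4]), pm)$class,
                   "translocation")
})

test_that("deletion products split into scar and ecDNA by barcode composition", {
  pm <- toy_parental_map()        # rows 1, 2 are top-strand X (1 Mb), Y (3.5 Mb)
  scar_pair <- list(barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[2])
  ecdna_pair <- list(barcode1 = pm$barcode1[2], barcode2 = pm$barcode2[1])
  expect_identical(label_deletion_products(scar_pair, pm), "scar")
  expect_identical(label_deletion_products(ecdna_pair, pm), "ecdna")

  # bottom-strand pair: the opposite assignment
  pmb <- data.table::copy(pm)[, strand := "bottom_CS1"]
  expect_identical(label_deletion_products(scar_pair, pmb), "ecdna")
  expect_identical(label_deletion_products(ecdna_pair, pmb), "scar")

  expect_error(label_deletion_products(
    list(barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[4]), pm),
    "deletions only")
})

test_that("translocations subclassify by centromere retention per barcode", {
  cen <- c(chrA = 5e6, chrB = 5e6)
  mkpm <- function(posA, strandA, posB, strandB) data.table::data.table(
    chrom = c("chrA", "chrB"), pos = c(posA, posB),
    strand = c(strandA, strandB),
    barcode1 = ac_barcodes(2, 300), barcode2 = ac_barcodes(2, 305),
    allele = "BL6")
  pair_of <- function(pm) list(barcode1 = pm$barcode1[1],
                               barcode2 = pm$barcode2[2])

  # top X at 8 Mb keeps the left (centromeric) fragment with barcode1;
  # top Y at 2 Mb keeps the right (centromeric) fragment with barcode2
  pm <- mkpm(8e6, "top_CS2", 2e6, "top_CS2")
  expect_identical(classify_translocation(pair_of(pm), pm, cen), "dicentric")
  # both distal
  pm2 <- mkpm(2e6, "top_CS2", 8e6, "top_CS2")
  expect_identical(classify_translocation(pair_of(pm2), pm2, cen), "acentric")
  # mixed: balanced
  pm3 <- mkpm(8e6, "top_CS2", 8e6, "top_CS2")
  expect_identical(classify_translocation(pair_of(pm3), pm3, cen), "balanced")
  # flipping one insertion's strand flips its retained side
  pm4 <- mkpm(8e6, "bottom_CS1", 2e6, "top_CS2")
  expect_identical(classify_translocation(pair_of(pm4), pm4, cen), "balanced")

  expect_error(classify_translocation(
    list(barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[1]), pm, cen),
    "translocations only")
})

test_that("arm-spanning flags cis events whose parents flank the centromere", {
  cen <- c(chr1 = 5e7)
  pm <- data.table::data.table(
    chrom = "chr1", pos = c(1e6, 9e7, 9.5e7), strand = "top_CS2",
    barcode1 = ac_barcodes(3, 310), barcode2 = ac_barcodes(3, 315),
    allele = "BL6")
  sv <- classify_sv(list(barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[2]),
                    pm)
  expect_true(classify_arm_spanning(sv, cen))
  sv2 <- classify_sv(list(barcode1 = pm$barcode1[2], barcode2 = pm$barcode2[3]),
                     pm)
  expect_false(classify_arm_spanning(sv2, cen))
  sv$class <- "translocation"
  expect_error(classify_arm_spanning(sv, cen), "cis")
})

test_that("SV classification agrees with the chromosome-string oracle", {
  compared <- run_oracle_comparison(150, seed_offset = 5000L)
  expect_gt(compared, 80)
})

test_that("reciprocal scar/ecDNA calls match with complementary labels", {
  pm <- toy_parental_map()
  calls <- data.table::data.table(
    barcode1 = c(pm$barcode1[1], pm$barcode1[2], pm$barcode1[3]),
    barcode2 = c(pm$barcode2[2], pm$barcode2[1], pm$barcode2[1]),
    class = "deletion",
    deletion_product = c("scar", "ecdna", "scar"),
    reciprocal_group = c("1_2", "1_2", "1_3"),
    umi_count = c(10, 9, 4))
  res <- match_reciprocal_pairs(calls)
  matched <- res$pairs[reciprocal_group == "1_2"]
  expect_true(matched$matched)
  expect_equal(matched$ratio, 0.9)
  expect_true(is.na(res$pairs[reciprocal_group == "1_3"]$ratio))
  expect_equal(res$fraction_matched, 0.5)
})

test_that("weighted size bootstrap behaves at the null and at separation", {
  set.seed(2)
  a <- data.table::data.table(size = c(10, 20, 30, 40, 50),
                              read_count = c(1, 1, 1, 1, 6))
  # weighted median closed form on the toy table: cumulative weight crosses
  # half of 10 at the last row
  expect_identical(shufflekit:::weighted_median(a$size, a$read_count), 50)

  same <- weighted_size_bootstrap(a, a, iters = 400, seed = 1)
  expect_gt(same$p_value, 0.5)

  b <- data.table::copy(a)[, size := size + 1000]
  sep <- weighted_size_bootstrap(a, b, iters = 400, seed = 1)
  expect_lte(sep$p_value, 1 / 400 + 1e-12)
})

test_that("clone wells drop below the read floor and keep outlier pairs", {
  tb <- function(counts) data.table::data.table(
    barcode1 = ac_barcodes(length(counts), 320),
    barcode2 = ac_barcodes(length(counts), 340),
    read_count = counts)
  wells <- list(
    low = tb(rep(24999L, 4)),                    # 99,996 reads: dropped
    mix = tb(c(1e5, 1e5, 1e5, 1e5 + 90L)),      # uniform-ish: nothing retained
    hit = tb(c(30000L, 30000L, 30000L, 90000L)))
  out <- clone_well_genotyping(wells, parental_map = NULL,
                               clones_per_well = c(hit = 2))
  expect_false("low" %in% out$well)
  # population SD on {10,10,10,100}-shaped counts keeps only the outlier
  expect_identical(out[well == "hit"]$read_count, 90000)
  expect_identical(out[well == "hit"]$norm_count, 45000)
  expect_false("mix" %in% out$well & FALSE)
  expect_identical(nrow(out[well == "mix"]),
                   nrow(wells$mix[read_count > mean(read_count) +
                                    sqrt(mean((read_count - mean(read_count))^2))]))
})

test_that("a non-targeting control sample yields zero novel pairs", {
  cfg <- small_cfg()          # default chimera rate, no recombinase action
  amp1 <- emit_amplicon_reads(FIX_CLONES, cfg, "two_primer", replicate = 1)
  amp2 <- emit_amplicon_reads(FIX_CLONES, cfg, "two_primer", replicate = 2)
  tal <- tally_amplicons(rbind(amp1, amp2)[, .(seq, replicate)])
  avg <- normalize_and_average(tal)
  pm <- FIX_CLONES[, .(chrom, pos, strand, barcode1, barcode2, allele)]
  novel <- call_novel_pairs(avg, pm, min_umi = 2)
  expect_identical(nrow(novel), 0L)
})

test_that("IVT support validates true junctions and rejects absent ones", {
  pm <- toy_parental_map()
  novel <- data.table::data.table(
    barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[2],
    umi_count = 5L, read_count = 20L, reciprocal_group = "1_2")
  svs <- classify_all_svs(novel, pm)
  clusters <- data.table::data.table(
    chrom = "chr1", position = pm$pos[1] + 3L, genome_strand = "+",
    barcode1 = pm$barcode1[1], barcode2 = pm$barcode2[2],
    cassette_strand = "top_CS2", allele = "BL6", read_count = 4L,
    read1_umi_count = 4L, read2_umi_count = 4L, n_unique_aligned_lengths = 3L)
  out <- validate_with_ivt(svs, clusters)
  expect_true(out$supported_by_ivt)
  out2 <- validate_with_ivt(svs, clusters[0])
  expect_false(out2$supported_by_ivt)
  # a cluster elsewhere does not support the call
  far <- data.table::copy(clusters)[, position := 999L]
  expect_false(validate_with_ivt(svs, far)$supported_by_ivt)
})
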