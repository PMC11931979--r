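test_that("derive_position follows the strand rule", {
  expect_identical(derive_position(genome_strand = "+", aln_start = 100,
                                   aln_end = 150), 150)
  expect_identical(derive_position(genome_strand = "-", aln_start = 100,
                                   aln_end = 150), 100)
  expect_error(derive_position(genome_strand = "+", aln_start = 100,
                               aln_end = 100), "degenerate")
})

test_that("allele assignment distinguishes reference, alternate and mixed evidence", {
  vt <- data.table::data.table(chrom = "chr1", pos = c(120L, 140L),
                               ref = c("A", "C"), alt = c("G", "T"))
  aln <- list(chrom = "chr1", aln_start = 100L, aln_end = 130L,
              mismatch_pos = integer(0))
  expect_identical(assign_allele(aln, vt), "BL6")
  aln$mismatch_pos <- 120L
  expect_identical(assign_allele(aln, vt), "CAST")
  aln2 <- list(chrom = "chr1", aln_start = 100L, aln_end = 150L,
               mismatch_pos = 120L)   # one variant alt, one ref
  expect_identical(assign_allele(aln2, vt), "inconclusive")
  aln3 <- list(chrom = "chr1", aln_start = 200L, aln_end = 250L,
               mismatch_pos = integer(0))
  expect_identical(assign_allele(aln3, vt), "noVariant")
  # the fast path agrees
  vidx <- shufflekit:::variant_index(vt)
  for (a in list(aln, aln2, aln3)) {
    expect_identical(shufflekit:::fast_allele(vidx, a), assign_allele(a, vt))
  }
})

test_that("flank alignment maps uniquely, filters multi-mappers and non-TTAA junctions", {
  idx <- build_genome_index(FIX_GENOME)
  cl <- FIX_CLONES[1]
  hap <- FIX_GENOME$haps[[cl$chrom]][[cl$allele]]
  itr <- "CCCTAGAAAGATA"
  # right-side flank read: - strand alignment starting at the TTAA
  r_right <- paste0(strrep("A", 8), revcomp(substr(hap, cl$pos, cl$pos + 49L)),
                    itr)
  a <- trim_and_align_flank(r_right, idx)
  expect_identical(a$genome_strand, "-")
  expect_identical(derive_position(a), cl$pos - 1L)
  # left-side flank read: + strand alignment ending at the TTAA
  r_left <- paste0(strrep("A", 8),
                   substr(hap, cl$pos - 46L, cl$pos + 3L), itr)
  b <- trim_and_align_flank(r_left, idx)
  expect_identical(b$genome_strand, "+")
  expect_identical(derive_position(b), cl$pos + 3L)

  # a junction away from any TTAA is rejected
  off_t <- paste0(strrep("A", 8), substr(hap, cl$pos - 46L, cl$pos + 23L), itr)
  expect_null(trim_and_align_flank(off_t, idx))

  # reads without the ITR remnant are discarded as untrimmed
  expect_null(trim_and_align_flank(paste0(strrep("A", 8),
                                          substr(hap, cl$pos, cl$pos + 49L)),
                                   idx))

  # a flank occurring twice in the genome is a multi-mapper
  dup_seg <- paste0(substr(hap, 1000, 1045), "TTAA")
  gdup <- structure(list(
    chrom_lengths = c(chrX = 4000L), centromeres = c(chrX = 2000L),
    haps = list(chrX = c(
      BL6 = paste0(substr(hap, 1, 500), dup_seg, substr(hap, 551, 2000),
                   dup_seg, substr(hap, 2051, 2500)),
      CAST = paste0(substr(hap, 1, 500), dup_seg, substr(hap, 551, 2000),
                    dup_seg, substr(hap, 2051, 2500)))),
    variants = data.table::data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
    ttaa = list(chrX = integer())), class = "shuffle_genome")
  idx_dup <- build_genome_index(gdup)
  dup_read <- paste0(strrep("A", 8), revcomp(dup_seg), itr)
  expect_null(trim_and_align_flank(dup_read, idx_dup))
})

test_that("clustering is single-linkage at Levenshtein 6 with modal representatives", {
  base <- ac_barcode(50)
  mut <- function(bc, k) {
    # substitutions to G at spread positions: edit distance equals k exactly
    s <- strsplit(bc, "")[[1]]
    pos <- c(2, 5, 8, 11, 14, 17, 20)[seq_len(k)]
    s[pos] <- "G"
    out <- paste(s, collapse = "")
    stopifnot(utils::adist(bc, out) == k)
    out
  }
  mk <- function(bc1, allele = "BL6", n = 1) {
    data.table::data.table(chrom = "chr1", position = 500L,
                           genome_strand = "-", barcode1 = bc1,
                           barcode2 = ac_barcode(60),
                           cassette_strand = "top_CS2", allele = allele,
                           umi1 = replicate(n, paste(sample(c("A","C","G","T"),
                                                            10, TRUE),
                                                     collapse = "")),
                           umi2 = "AAAAAAAA", aligned_length = 40L,
                           aln_start = 499L, aln_end = 539L)
  }
  # distance 6 joins, distance 7 splits
  two <- rbind(mk(base), mk(mut(base, 6)))
  expect_identical(nrow(cluster_alignments(two)), 1L)
  two7 <- rbind(mk(base), mk(mut(base, 7)))
  expect_identical(nrow(cluster_alignments(two7)), 2L)

  # modal allele ignores noVariant; counts are tallied
  grp <- rbind(mk(base, "BL6"), mk(base, "BL6"), mk(base, "noVariant"),
               mk(base, "noVariant"), mk(base, "noVariant"))
  cl <- cluster_alignments(grp)
  expect_identical(cl$allele, "BL6")
  expect_identical(cl$read_count, 5L)
  expect_identical(cl$n_unique_aligned_lengths, 1L)
})

test_that("replicate merging applies the anchor-replicate support filter", {
  mkc <- function(reads, lengths, allele = "BL6", pos = 500L, bc1 = NULL) {
    data.table::data.table(
      chrom = "chr1", position = pos, genome_strand = "-",
      barcode1 = if (is.null(bc1)) ac_barcode(70) else bc1,
      barcode2 = ac_barcode(71), cassette_strand = "top_CS2",
      allele = allele, read_count = reads, read1_umi_count = reads,
      read2_umi_count = reads, n_unique_aligned_lengths = lengths)
  }
  # (5 reads, 2 lengths) in rep2 -> removed; (5, 3) -> kept
  expect_identical(nrow(merge_and_filter_replicates(mkc(10, 5), mkc(5, 2))), 0L)
  expect_identical(nrow(merge_and_filter_replicates(mkc(10, 5), mkc(5, 3))), 1L)
  expect_identical(nrow(merge_and_filter_replicates(mkc(10, 5), mkc(6, 1))), 1L)

  # conflicting replicate alleles become inconclusive; noVariant defers
  m <- merge_and_filter_replicates(mkc(10, 5, "BL6"), mkc(10, 5, "CAST"))
  expect_identical(m$allele, "inconclusive")
  m2 <- merge_and_filter_replicates(mkc(10, 5, "noVariant"), mkc(10, 5, "CAST"))
  expect_identical(m2$allele, "CAST")

  # a barcode pair at two genomic locations is removed entirely
  bc <- ac_barcode(72)
  r1 <- rbind(mkc(10, 5, pos = 500L, bc1 = bc), mkc(10, 5, pos = 900L, bc1 = bc))
  r2 <- rbind(mkc(10, 5, pos = 500L, bc1 = bc), mkc(10, 5, pos = 900L, bc1 = bc))
  expect_identical(nrow(merge_and_filter_replicates(r1, r2)), 0L)
})

test_that("insertion calls demand the 4-bp offset with consistent geometry", {
  bc1 <- ac_barcode(80); bc2 <- ac_barcode(81)
  mkm <- function(pos, strand, cstrand, b1, b2, lens2 = 5L) {
    data.table::data.table(
      chrom = "chr1", position = pos, genome_strand = strand,
      barcode1 = b1, barcode2 = b2, cassette_strand = cstrand,
      allele_rep1 = "BL6", allele_rep2 = "BL6", allele = "BL6",
      read_count_rep1 = 10L, read_count_rep2 = 10L,
      read1_umi_count_rep1 = 10L, read1_umi_count_rep2 = 10L,
      read2_umi_count_rep1 = 10L, read2_umi_count_rep2 = 10L,
      n_unique_aligned_lengths_rep1 = 5L,
      n_unique_aligned_lengths_rep2 = lens2)
  }
  good <- rbind(
    mkm(996L, "-", "top_CS2", bc1, bc2),
    mkm(1000L, "+", "bottom_CS1", revcomp(bc1), revcomp(bc2)))
  ins <- call_insertions(good)
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$pos, 997L)
  expect_identical(ins$strand, "top_CS2")
  expect_identical(ins$barcode1, bc1)

  # offset 5 violates the pairing rule
  off5 <- rbind(
    mkm(996L, "-", "top_CS2", bc1, bc2),
    mkm(1001L, "+", "bottom_CS1", revcomp(bc1), revcomp(bc2)))
  expect_identical(nrow(call_insertions(off5)), 0L)

  # same cassette strand on both sides is rejected
  same <- rbind(
    mkm(996L, "-", "top_CS2", bc1, bc2),
    mkm(1000L, "+", "top_CS2", revcomp(bc1), revcomp(bc2)))
  expect_identical(nrow(call_insertions(same)), 0L)

  # non-reverse-complementary barcodes are rejected
  bad_bc <- rbind(
    mkm(996L, "-", "top_CS2", bc1, bc2),
    mkm(1000L, "+", "bottom_CS1", revcomp(bc1), ac_barcode(82)))
  expect_identical(nrow(call_insertions(bad_bc)), 0L)
})

test_that("parental map intersection keeps amplicon-confirmed insertions only", {
  ins <- data.table::data.table(chrom = "chr1", pos = c(100L, 200L),
                                strand = "top_CS2",
                                barcode1 = ac_barcodes(2, 90),
                                barcode2 = ac_barcodes(2, 95),
                                allele = "BL6")
  amp <- ins[1, .(barcode1, barcode2)]
  expect_identical(nrow(finalize_parental_map(ins, amp)), 1L)
  expect_warning(out <- finalize_parental_map(ins, amp[0]), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("the pipeline recovers the truth map exactly on noiseless reads", {
  cfg <- FIX_CFG; g <- FIX_GENOME; cl <- FIX_CLONES
  ivt1 <- emit_ivt_reads(cl, g, cfg, replicate = 1)
  ivt2 <- emit_ivt_reads(cl, g, cfg, replicate = 2)
  idx <- build_genome_index(g)
  res <- map_insertions(ivt1, ivt2, idx)
  ins <- res$insertions

  expect_identical(nrow(ins), nrow(cl))
  m <- merge(ins, cl, by = c("chrom", "pos"), suffixes = c("", ".t"))
  expect_identical(nrow(m), nrow(cl))     # 100% precision and recall
  expect_true(all(m$barcode1 == m$barcode1.t))
  expect_true(all(m$barcode2 == m$barcode2.t))
  expect_true(all(m$strand == m$strand.t))
  expect_true(all(m$allele == m$allele.t | m$allele == "noVariant"))
  expect_true(all(ins$right_position - ins$left_position == 4L))

  # permutation invariance: shuffled read order gives the same map
  set.seed(1)
  res2 <- map_insertions(ivt1[sample(.N)], ivt2[sample(.N)], idx)
  data.table::setorder(ins, chrom, pos)
  ins2 <- res2$insertions
  data.table::setorder(ins2, chrom, pos)
  expect_identical(ins2[, .(chrom, pos, strand, barcode1, barcode2, allele)],
                   ins[, .(chrom, pos, strand, barcode1, barcode2, allele)])

  # amplicon intersection: full coverage keeps the whole map
  amp_pairs <- cl[, .(barcode1, barcode2)]
  expect_identical(nrow(finalize_parental_map(ins, amp_pairs)), nrow(cl))
})
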