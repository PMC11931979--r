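make_records <- function(rows) {
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(cell = r$cell, umi = r$umi,
                           barcode1 = r$b1, barcode2 = r$b2,
                           capture = if (is.null(r$capture)) "CS1" else r$capture,
                           site = "attL",
                           reads = r$reads)
  }))
}

test_that("T7 matrix construction filters chimeric UMIs and collapses by Hamming", {
  b <- ac_barcodes(4, 400)
  # one UMI split 1:9 across two combinations: the 10% assignment is chimeric
  rec <- make_records(list(
    list(cell = "c1", umi = "AAAAAAAAAA", b1 = b[1], b2 = b[2], reads = 9L),
    list(cell = "c1", umi = "AAAAAAAAAA", b1 = b[3], b2 = b[4], reads = 1L)))
  t7 <- build_t7_matrix(rec)
  expect_identical(nrow(t7$entries), 1L)
  expect_identical(t7$entries$barcode1, b[1])
  expect_identical(t7$qc$chimeric_umi_assignments, 1L)

  # Hamming components: {AAAAAAAAAA, AAAAAAAAAT, TTTTTTTTTT} -> 2 UMIs
  rec2 <- make_records(list(
    list(cell = "c1", umi = "AAAAAAAAAA", b1 = b[1], b2 = b[2], reads = 20L),
    list(cell = "c1", umi = "AAAAAAAAAT", b1 = b[1], b2 = b[2], reads = 20L),
    list(cell = "c1", umi = "TTTTTTTTTT", b1 = b[1], b2 = b[2], reads = 20L)))
  t7b <- build_t7_matrix(rec2)
  expect_identical(t7b$entries$umis, 2L)

  # reads-per-UMI floor: 14 reads / 1 UMI at floor 15 is removed
  rec3 <- make_records(list(
    list(cell = "c1", umi = "GGGGGGGGGG", b1 = b[1], b2 = b[2], reads = 14L)))
  expect_identical(nrow(build_t7_matrix(rec3, reads_per_umi_floor = 15)$entries),
                   0L)
  expect_identical(nrow(build_t7_matrix(rec3, reads_per_umi_floor = 9)$entries),
                   1L)
})

test_that("Hamming UMI collapse equals brute-force connected components", {
  brute_components <- function(umis) {
    umis <- unique(umis)
    n <- length(umis)
    comp <- seq_len(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sum(strsplit(umis[i], "")[[1]] != strsplit(umis[j], "")[[1]])
        if (d <= 1) {
          old <- comp[j]; comp[comp == old] <- comp[i]
        }
      }
    }
    length(unique(comp))
  }
  set.seed(11)
  for (trial in 1:40) {
    n <- sample(1:12, 1)
    # a small alphabet forces frequent 1-mismatch neighbours
    umis <- replicate(n, paste(sample(c("A", "T"), 6, replace = TRUE),
                               collapse = ""))
    expect_identical(hamming_components(umis), brute_components(umis))
  }
})

test_that("cell QC applies species windows and a strict doublet ceiling", {
  md <- data.table::data.table(
    cell = c("k1", "k2", "k3", "k4", "m1"),
    transcriptome_umis = c(1600L, 1600L, 1400L, 1600L, 1200L),
    mito_frac = c(0.05, 0.09, 0.05, 0.05, 0.03),
    doublet_score = c(0.1, 0.1, 0.1, 0.4, 0.1),
    species = c("K562", "K562", "K562", "K562", "mESC"))
  keep <- qc_cells(md)
  expect_setequal(keep, c("k1", "m1"))   # k2: mito; k3: UMIs; k4: score == 0.4
})

test_that("barnyard calls flag insufficiently separated ratio cells as doublets", {
  expect_identical(barnyard_species_call(120, 100), "doublet")     # 1.2 < 1.42
  expect_identical(barnyard_species_call(100, 250), "doublet")     # 2.5 < 3
  expect_identical(barnyard_species_call(2, 100), "speciesB")      # 50x
  expect_identical(barnyard_species_call(300, 100), "speciesA")
  expect_identical(barnyard_species_call(c(120, 2), c(100, 100)),
                   c("doublet", "speciesB"))
})

test_that("the inflection cut finds the fold-change break or the absolute floor", {
  # (0.9, 0.85, 0.8, 0.3): 0.8/0.3 > 2 cuts after rank 3
  expect_identical(shufflekit:::inflection_cut(c(0.9, 0.85, 0.8, 0.3)), 3L)
  # absolute floor binds when the fold rule never fires
  expect_identical(shufflekit:::inflection_cut(c(0.9, 0.6, 0.4, 0.3, 0.05),
                                               fc_thresh = 10), 4L)
  # no break: the whole list is kept
  expect_identical(shufflekit:::inflection_cut(c(0.9, 0.8, 0.7, 0.6)), 4L)
})

test_that("cell assignment computes precision/recall and flags doublets", {
  K <- ac_barcodes(20, 500)
  other <- ac_barcodes(30, 550)
  clonotypes <- data.table::data.table(
    clonotype = c("K", "L"),
    members = list(sort(K), sort(other)),
    n_pairs = c(20L, 30L), top_fraction = c(0.9, 0.9),
    n_cells = c(50L, 50L), round = 1L)

  # 10 detected barcodes, 8 from K (|K| = 20): precision 0.8, recall 0.4
  det <- c(K[1:8], ac_barcodes(2, 600))
  rec <- make_records(lapply(seq_along(det), function(i)
    list(cell = "c1", umi = sprintf("UMI%07d", i), b1 = ac_barcode(700 + i),
         b2 = det[i], reads = 30L)))
  rec[, umi := sprintf("%010d", .I)]
  rec <- rbind(rec, data.table::copy(rec)[, umi := paste0("GG", substr(umi, 3, 10))])
  t7 <- build_t7_matrix(rec)
  asg <- assign_cells_to_clonotypes(t7, clonotypes, min_umi = 2)
  expect_identical(asg$reason, "assigned")
  expect_identical(asg$clonotype, "K")
  expect_equal(asg$top_precision, 0.8)
  expect_equal(asg$top_recall, 0.4)

  # recall below the floor: low capture
  asg2 <- assign_cells_to_clonotypes(t7, clonotypes, min_umi = 2,
                                     recall_floor = 0.5)
  expect_identical(asg2$reason, "low_capture")
  expect_true(is.na(asg2$clonotype))

  # a second clonotype with recall above the doublet threshold removes the cell
  clon2 <- data.table::copy(clonotypes)
  clon2$members[[2]] <- sort(c(other[1:10], det[9:10]))
  asg3 <- assign_cells_to_clonotypes(t7, clon2, min_umi = 2,
                                     doublet_recall = 0.1)
  expect_identical(asg3$reason, "doublet")
})

test_that("precision rises and recall falls along the UMI threshold grid", {
  cfg <- small_cfg(ambient_fraction = 0.05, sc_chimera_rate = 0,
                   doublet_rate = 0, cells_per_clone = 30,
                   t7_umi_mean = 6)
  cells <- induce_rearrangements(FIX_CLONES, cfg)
  sc <- emit_single_cell_readout(cells, cfg)
  t7 <- build_t7_matrix(sc$records)
  clonotypes <- data.table::data.table(
    clonotype = unique(FIX_CLONES$clone),
    members = lapply(unique(FIX_CLONES$clone), function(cl)
      sort(FIX_CLONES[clone == cl]$barcode2)),
    n_pairs = 10L, top_fraction = 0.9, n_cells = 30L, round = 1L)
  asg <- assign_cells_to_clonotypes(t7, clonotypes)
  expect_gt(mean(asg$reason == "assigned"), 0.9)
  pr <- threshold_precision_recall(t7, clonotypes, asg, umi_grid = 1:6)
  expect_true(all(diff(pr$mean_recall) <= 1e-9))
  expect_gte(pr$mean_precision[2], pr$mean_precision[1])
})

test_that("de novo clonotype identification recovers a simulated clone structure", {
  cfg <- sim_config(seed = 17, chrom_lengths = c(chr1 = 4e5, chr2 = 4e5),
                    n_clones = 20, cassettes_per_clone = 30,
                    cells_per_clone = 50, event_prob = 0,
                    ambient_fraction = 0.01, sc_chimera_rate = 0.005,
                    doublet_rate = 0, t7_umi_mean = 5, t7_umi_size = 3)
  g <- simulate_genome(cfg)
  clones <- integrate_cassettes(g, cfg)
  cells <- induce_rearrangements(clones, cfg)
  sc <- emit_single_cell_readout(cells, cfg)
  t7 <- build_t7_matrix(sc$records)
  clonotypes <- identify_clonotypes(t7, seed = 1)

  expect_gte(nrow(clonotypes), 19L)
  # recovered member sets match the truth clones at Jaccard >= 0.9
  truth_sets <- lapply(split(clones$barcode2, clones$clone), sort)
  jac <- vapply(clonotypes$members, function(m) {
    max(vapply(truth_sets, function(tr)
      length(intersect(m, tr)) / length(union(m, tr)), numeric(1)))
  }, numeric(1))
  expect_gte(mean(jac >= 0.9), 0.95)

  # cell-to-clonotype agreement with truth labels
  asg <- assign_cells_to_clonotypes(t7, clonotypes)
  truth_lab <- sc$truth_cells$clone[match(asg$cell, sc$truth_cells$cell)]
  ok <- !is.na(asg$clonotype)
  expect_gt(mean(ok), 0.9)
  expect_gte(adjusted_rand(asg$clonotype[ok], truth_lab[ok]), 0.95)
})

test_that("per-cell rearrangements are congruent with the clonotype on clean data", {
  cfg <- small_cfg(ambient_fraction = 0, sc_chimera_rate = 0, doublet_rate = 0,
                   cells_per_clone = 20, event_prob = 0.6, t7_umi_mean = 6)
  cells <- induce_rearrangements(FIX_CLONES, cfg, FIX_GENOME)
  sc <- emit_single_cell_readout(cells, cfg)
  t7 <- build_t7_matrix(sc$records)
  pm <- FIX_CLONES[, .(chrom, pos, strand, barcode1, barcode2, allele)]
  clonotypes <- data.table::data.table(
    clonotype = unique(FIX_CLONES$clone),
    members = lapply(unique(FIX_CLONES$clone), function(cl)
      sort(FIX_CLONES[clone == cl]$barcode2)),
    n_pairs = 10L, top_fraction = 0.9, n_cells = 20L, round = 1L)
  asg <- assign_cells_to_clonotypes(t7, clonotypes)
  svs <- call_cell_rearrangements(t7, pm, asg, clonotypes,
                                  centromere_table = FIX_GENOME$centromeres)
  expect_gt(nrow(svs), 0L)
  expect_true(all(svs$congruence == "congruent"))

  # every called rearrangement matches a truth event of that cell in class
  ev <- cells$truth$events
  for (i in seq_len(nrow(svs))) {
    e <- ev[cell == svs$cell[i]]
    expect_identical(nrow(e), 1L)
    expect_identical(svs$class[i], e$class)
  }
})
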