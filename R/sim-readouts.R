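# Emitters for the three sequencing readouts: IVT-seq paired reads,
# amplicon-seq reads with UMIs, and the single-cell T7 capture records plus a
# transcriptome count matrix.

ITR_SEQ <- "CCCTAGAAAGATA"
IVT_UMI_LEN <- 8L
AMP_UMI_LEN <- 8L
SC_UMI_LEN <- 10L

coerce_cells <- function(cells) {
  if (inherits(cells, "shuffle_cells")) return(cells)
  # a plain parental cassette table: treat each clone as one pseudo-cell
  cas <- as_cassette_rows(as.data.table(cells))
  cas[, subtype := NA_character_]
  structure(list(cassettes = cas,
                 cells = unique(cas[, .(cell, clone)])[, event_id := NA_character_][],
                 truth = list(clones = as.data.table(cells),
                              events = data.table())),
            class = "shuffle_cells")
}

hap_flank <- function(genome, chrom, pos, side, allele, len) {
  hap <- genome$haps[[chrom]][[if (identical(allele, "CAST")) "CAST" else "BL6"]]
  if (side == "L") {
    a <- max(1L, pos + 3L - len + 1L)
    substr(hap, a, pos + 3L)
  } else {
    b <- min(nchar(hap), pos + len - 1L)
    revcomp(substr(hap, pos, b))
  }
}

#' Emit IVT-seq paired reads
#'
#' For every cassette instance and each of its two ends, emits Poisson(`depth`)
#' read pairs for the transcript exiting that end: read 1 carries the cassette
#' (forward sequence for transcripts exiting the right end, reverse complement
#' for the left end), read 2 carries an 8-nt degenerate UMI, the genomic flank
#' read back towards the junction, and the transposon ITR remnant. Flank
#' lengths vary uniformly over `cfg$flank_len_range` so that clusters
#' accumulate distinct aligned lengths. Substitution noise at `sub_rate` is
#' applied to both reads.
#'
#' @param cells a `shuffle_cells` object (or a parental cassette table, in
#'   which case each clone is emitted once as a pseudo-cell).
#' @param genome the matching [simulate_genome()] result.
#' @param cfg a [sim_config()].
#' @param replicate integer replicate id (shifts the random stream).
#' @param sub_rate substitution rate; defaults to `cfg$sub_rate`.
#' @param depth mean reads per cassette end; defaults to `cfg$ivt_depth`.
#' @return a `data.table` of reads: `read_id`, `replicate`, `cell`, `read1`,
#'   `umi1`, `read2`, plus truth columns `t_chrom`, `t_pos`, `t_side`,
#'   `t_allele`, `t_origin`, `t_cassette`.
#' @export
emit_ivt_reads <- function(cells, genome, cfg, replicate = 1L,
                           sub_rate = cfg$sub_rate, depth = cfg$ivt_depth) {
  stopifnot(inherits(genome, "shuffle_genome"), inherits(cfg, "sim_config"))
  cells <- coerce_cells(cells)
  set.seed((stage_seed(cfg, "ivt") + 1000L * replicate) %% .Machine$integer.max)
  cas <- cells$cassettes
  out <- vector("list", 2L * nrow(cas))
  k <- 0L
  for (i in seq_len(nrow(cas))) {
    row <- as.list(cas[i])
    fwd_seq <- build_product_sequence(row$barcode_left, row$capture_left,
                                      row$barcode_right, row$capture_right,
                                      row$site)
    for (end in c("right", "left")) {
      d <- if (end == "right")
        list(chrom = row$fr_chrom, pos = row$fr_pos, side = row$fr_side,
             allele = row$fr_allele)
      else
        list(chrom = row$fl_chrom, pos = row$fl_pos, side = row$fl_side,
             allele = row$fl_allele)
      if (is.na(d$chrom)) next
      n <- stats::rpois(1L, depth)
      if (n == 0L) next
      lens <- sample(seq(cfg$flank_len_range[1], cfg$flank_len_range[2]), n,
                     replace = TRUE)
      r1 <- if (end == "right") fwd_seq else revcomp(fwd_seq)
      flanks <- vapply(lens, function(L)
        hap_flank(genome, d$chrom, d$pos, d$side, d$allele, L), character(1))
      k <- k + 1L
      out[[k]] <- data.table(
        replicate = replicate, cell = row$cell,
        read1 = r1, umi1 = random_dna(n, 10L),
        read2 = paste0(random_dna(n, IVT_UMI_LEN), flanks, ITR_SEQ),
        t_chrom = d$chrom, t_pos = d$pos, t_side = d$side,
        t_allele = d$allele, t_origin = row$origin, t_cassette = row$cassette_id
      )
    }
  }
  reads <- rbindlist(out[seq_len(k)])
  if (nrow(reads) == 0L) return(reads)
  if (sub_rate > 0) {
    reads[, read1 := add_substitutions(read1, sub_rate)]
    reads[, read2 := add_substitutions(read2, sub_rate)]
  }
  reads[, read_id := sprintf("ivt_r%d_%06d", replicate, .I)]
  setcolorder(reads, "read_id")
  reads[]
}

#' Emit amplicon-seq reads
#'
#' One amplicon per detectable cassette instance (see [amplicon_detectable()]);
#' under the four-primer scheme both amplicon orientations are emitted per
#' cassette. Read counts are Poisson with mean `amp_depth` per cassette
#' instance (so proportional to the number of cells carrying it); molecule
#' (UMI) counts are Poisson(`amp_umi_rate`) + 1. PCR chimeras are injected at
#' `chimera_rate` by re-pairing a read's CS1-side barcode with a random other
#' template's, on a fresh UMI.
#'
#' @param cells a `shuffle_cells` object or parental cassette table.
#' @param cfg a [sim_config()].
#' @param scheme `"two_primer"` or `"four_primer"`.
#' @param replicate replicate id (shifts the random stream).
#' @param detect_homotypic passed to [amplicon_detectable()].
#' @param chimera_rate override of `cfg$chimera_rate`.
#' @return a `data.table` of reads: `read_id`, `replicate`, `seq` (UMI followed
#'   by the barcode/site portion of the template), `orientation`
#'   (`"fwd"`/`"rev"`), plus truth columns `t_bc_left`, `t_bc_right`,
#'   `t_origin`, `t_chimera`.
#' @export
emit_amplicon_reads <- function(cells, cfg, scheme = c("two_primer", "four_primer"),
                                replicate = 1L, detect_homotypic = FALSE,
                                chimera_rate = cfg$chimera_rate) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cfg, "sim_config"))
  cells <- coerce_cells(cells)
  set.seed((stage_seed(cfg, "amplicon") + 1000L * replicate) %%
             .Machine$integer.max)

  # aggregate identical templates across cells
  tmpl <- cells$cassettes[, .(n_cells = .N),
                          by = .(barcode_left, capture_left, barcode_right,
                                 capture_right, site, origin)]
  det <- vapply(seq_len(nrow(tmpl)), function(i)
    amplicon_detectable(tmpl[i], scheme, detect_homotypic), logical(1))
  tmpl <- tmpl[det]
  if (nrow(tmpl) == 0L) {
    return(data.table(read_id = character(), replicate = integer(),
                      seq = character(), orientation = character(),
                      t_bc_left = character(), t_bc_right = character(),
                      t_origin = character(), t_chimera = logical()))
  }

  amp_core <- function(bl, cl, br, cr, site) {
    paste0(barcode_block(bl, cl, site, "left"), SITE_CORES[[site]],
           barcode_block(br, cr, site, "right"))
  }

  out <- vector("list", nrow(tmpl))
  for (i in seq_len(nrow(tmpl))) {
    tp <- as.list(tmpl[i])
    n_reads <- stats::rpois(1L, cfg$amp_depth * tp$n_cells)
    if (n_reads == 0L) { out[[i]] <- NULL; next }
    n_umi <- stats::rpois(1L, cfg$amp_umi_rate * tp$n_cells) + 1L
    umis <- random_dna(n_umi, AMP_UMI_LEN)
    core <- amp_core(tp$barcode_left, tp$capture_left,
                     tp$barcode_right, tp$capture_right, tp$site)
    ori <- if (scheme == "four_primer")
      sample(c("fwd", "rev"), n_reads, replace = TRUE) else rep("fwd", n_reads)
    out[[i]] <- data.table(
      replicate = replicate,
      seq = paste0(sample(umis, n_reads, replace = TRUE),
                   ifelse(ori == "fwd", core, revcomp(core))),
      orientation = ori,
      t_bc_left = tp$barcode_left, t_bc_right = tp$barcode_right,
      t_origin = tp$origin, t_chimera = FALSE,
      t_site = tp$site, t_capture_left = tp$capture_left,
      t_capture_right = tp$capture_right
    )
  }
  reads <- rbindlist(out)

  # PCR chimeras: re-pair the CS1-side barcode across templates, fresh UMI
  if (chimera_rate > 0 && nrow(reads) > 1L && nrow(tmpl) > 1L) {
    n_chim <- stats::rbinom(1L, nrow(reads), chimera_rate)
    if (n_chim > 0L) {
      idx <- sample.int(nrow(reads), n_chim)
      for (j in idx) {
        src <- as.list(reads[j])
        other <- tmpl[sample.int(nrow(tmpl), 1L)]
        core <- amp_core(src$t_bc_left, src$t_capture_left,
                         other$barcode_right, other$capture_right, src$t_site)
        s <- paste0(random_dna(1L, AMP_UMI_LEN),
                    if (src$orientation == "fwd") core else revcomp(core))
        reads[j, `:=`(seq = s, t_bc_right = other$barcode_right,
                      t_chimera = TRUE)]
      }
    }
  }
  if (cfg$sub_rate > 0) reads[, seq := add_substitutions(seq, cfg$sub_rate)]
  reads[, read_id := sprintf("amp_r%d_%06d", replicate, .I)]
  setcolorder(reads, "read_id")
  reads[]
}

#' Simulate a heterozygous-deletion dosage experiment
#'
#' Generates transcriptome counts for one clonotype split into
#' deletion-bearing and control cells: per-gene counts are Poisson with rate
#' proportional to copy number (in-deletion genes drop from `ploidy` to
#' `ploidy - 1` copies in deletion cells) times a log-normal per-cell library
#' factor. Mirrors the readout used to quantify expression consequences of a
#' deletion on a chromosome present in `ploidy` copies.
#'
#' @param n_sv,n_ctrl numbers of deletion-bearing and control cells.
#' @param n_genes genes on the scanned chromosome.
#' @param del_genes indices of the genes inside the deletion.
#' @param ploidy chromosome copy number in control cells (3 for a triploid
#'   chromosome).
#' @param base_rate mean counts per gene at full copy number.
#' @param lib_sd log-normal sd of the per-cell library factor.
#' @param seed seed.
#' @return list with `counts` (genes x cells), `genes` (annotation on one
#'   synthetic chromosome), `sv_cells`, `ctrl_cells`, `del_genes` (gene ids).
#' @export
simulate_deletion_dosage <- function(n_sv = 465L, n_ctrl = 680L,
                                     n_genes = 60L, del_genes = 29:31,
                                     ploidy = 3L, base_rate = 20,
                                     lib_sd = 0.2, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  n_cells <- n_sv + n_ctrl
  cells <- sprintf("cell%04d", seq_len(n_cells))
  sv_cells <- cells[seq_len(n_sv)]
  ctrl_cells <- cells[(n_sv + 1L):n_cells]
  genes <- data.table(gene = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = "chr15",
                      start = seq_len(n_genes) * 10000L)
  genes[, end := start + 999L]
  copy <- matrix(ploidy, n_genes, n_cells, dimnames = list(genes$gene, cells))
  copy[del_genes, sv_cells] <- ploidy - 1L
  libf <- exp(stats::rnorm(n_cells, 0, lib_sd))
  lam <- sweep(copy * base_rate / ploidy, 2L, libf, `*`)
  counts <- matrix(stats::rpois(length(lam), lam), n_genes,
                   dimnames = dimnames(lam))
  list(counts = counts, genes = genes, sv_cells = sv_cells,
       ctrl_cells = ctrl_cells, del_genes = genes$gene[del_genes])
}

#' Emit the single-cell T7 readout and transcriptome
#'
#' Per cell and cassette instance, the number of captured T7 molecules (UMIs)
#' is negative binomial (`t7_umi_mean`, `t7_umi_size`); each molecule is
#' captured from the CS1 or CS2 end at random and observed with
#' Poisson(`t7_reads_per_umi` - 1) + 1 reads. Ambient contamination reassigns
#' a fraction of records to random cells; chimeric UMIs are injected by
#' duplicating an existing (cell, UMI) under a different barcode combination at
#' a low read count. Transcriptome counts per gene are
#' Poisson(copy_number x base_rate x library factor), where the copy number
#' reflects truth deletions (a heterozygous deletion on a `ploidy`-copy
#' chromosome reduces the covered genes from `ploidy` to `ploidy - 1` copies).
#' Doublets merge two cells' records and transcriptomes.
#'
#' @param cells a `shuffle_cells` object.
#' @param cfg a [sim_config()].
#' @param genome optional genome (used to lay out gene annotations).
#' @param species label stored in the per-cell metadata.
#' @return a list with `records` (`data.table`: cell, umi, barcode1, barcode2,
#'   capture, site, reads, ambient, chimeric), `metadata` (per-cell QC fields),
#'   `expr` (genes x cells sparse counts), `genes` (annotation table) and
#'   `truth_cells` (cell to clone map after doublet merging).
#' @export
emit_single_cell_readout <- function(cells, cfg, genome = NULL,
                                     species = "speciesA") {
  stopifnot(inherits(cells, "shuffle_cells"), inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "singlecell"))
  cas <- cells$cassettes
  meta <- copy(cells$cells)

  # T7 capture records
  n_mol <- stats::rnbinom(nrow(cas), mu = cfg$t7_umi_mean, size = cfg$t7_umi_size)
  rows <- rep(seq_len(nrow(cas)), n_mol)
  nrec <- length(rows)
  rec <- data.table(
    cell = cas$cell[rows],
    umi = random_dna(nrec, SC_UMI_LEN),
    barcode1 = cas$barcode_left[rows],
    barcode2 = cas$barcode_right[rows],
    capture = sample(c("CS1", "CS2"), nrec, replace = TRUE),
    site = cas$site[rows],
    reads = stats::rpois(nrec, max(cfg$t7_reads_per_umi - 1, 0)) + 1L,
    ambient = FALSE, chimeric = FALSE
  )

  if (cfg$ambient_fraction > 0 && nrec > 1L) {
    n_amb <- stats::rbinom(1L, nrec, cfg$ambient_fraction)
    if (n_amb > 0L) {
      idx <- sample.int(nrec, n_amb)
      rec[idx, `:=`(cell = sample(meta$cell, n_amb, replace = TRUE),
                    umi = random_dna(n_amb, SC_UMI_LEN),
                    reads = 1L, ambient = TRUE)]
    }
  }
  if (cfg$sc_chimera_rate > 0 && nrec > 1L) {
    n_chim <- stats::rbinom(1L, nrec, cfg$sc_chimera_rate)
    if (n_chim > 0L) {
      src <- rec[sample.int(nrow(rec), n_chim)]
      don <- rec[sample.int(nrow(rec), n_chim)]
      chim <- copy(src)[, `:=`(barcode1 = don$barcode1, barcode2 = don$barcode2,
                               site = don$site, reads = 1L, chimeric = TRUE)]
      rec <- rbindlist(list(rec, chim))
    }
  }

  # gene annotations along the synthetic chromosomes
  chroms <- names(cfg$chrom_lengths)
  genes <- data.table(
    gene = sprintf("gene%03d", seq_len(cfg$n_genes)),
    chrom = rep(chroms, length.out = cfg$n_genes)
  )
  genes[, idx_on_chrom := seq_len(.N), by = chrom]
  genes[, n_on_chrom := .N, by = chrom]
  genes[, start := as.integer(round(cfg$chrom_lengths[chrom] *
                                      (idx_on_chrom - 0.5) / n_on_chrom))]
  genes[, end := start + 999L]
  genes[, c("idx_on_chrom", "n_on_chrom") := NULL]
  setorder(genes, chrom, start)

  # copy number per cell x gene from truth deletions
  copy_num <- matrix(cfg$ploidy, nrow = nrow(genes), ncol = nrow(meta),
                     dimnames = list(genes$gene, meta$cell))
  ev <- cells$truth$events
  if (nrow(ev) > 0L) {
    dels <- ev[class == "deletion"]
    for (i in seq_len(nrow(dels))) {
      e <- dels[i]
      hit <- genes$chrom == e$chromA & genes$start >= min(e$posA, e$posB) &
        genes$end <= max(e$posA, e$posB)
      if (any(hit)) {
        copy_num[hit, e$cell] <- pmax(copy_num[hit, e$cell] - 1L, 0L)
      }
    }
  }
  lib_factor <- exp(stats::rnorm(nrow(meta), 0, 0.2))
  lam <- sweep(copy_num * cfg$base_rate / cfg$ploidy, 2L, lib_factor, `*`)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))

  # doublets: merge pairs of cells
  doublet_of <- setNames(rep(NA_character_, nrow(meta)), meta$cell)
  if (cfg$doublet_rate > 0 && nrow(meta) >= 4L) {
    n_dbl <- floor(cfg$doublet_rate * nrow(meta) / 2)
    if (n_dbl > 0L) {
      pick <- sample(meta$cell, 2L * n_dbl)
      for (j in seq_len(n_dbl)) {
        a <- pick[2L * j - 1L]; b <- pick[2L * j]
        rec[cell == b, cell := a]
        counts[, a] <- counts[, a] + counts[, b]
        doublet_of[a] <- b
      }
      drop <- pick[seq(2L, 2L * n_dbl, by = 2L)]
      keep <- setdiff(meta$cell, drop)
      meta <- meta[cell %in% keep]
      counts <- counts[, keep, drop = FALSE]
      doublet_of <- doublet_of[keep]
    }
  }

  tumi <- colSums(counts)
  metadata <- data.table(
    cell = meta$cell, clone = meta$clone,
    transcriptome_umis = as.integer(tumi[meta$cell]),
    mito_frac = stats::runif(nrow(meta), 0.02, 0.06),
    doublet_score = ifelse(is.na(doublet_of[meta$cell]),
                           stats::runif(nrow(meta), 0, 0.2),
                           stats::runif(nrow(meta), 0.6, 0.9)),
    species = species,
    is_doublet_truth = !is.na(doublet_of[meta$cell])
  )

  list(records = rec[cell %in% meta$cell],
       metadata = metadata,
       expr = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       genes = genes,
       truth_cells = meta)
}
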