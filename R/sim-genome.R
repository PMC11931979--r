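# Synthetic-genome and clone-population simulator. A single master seed is
# split into per-stage sub-streams so every stage is independently
# reproducible.

#' Simulation configuration
#'
#' Bundles every tunable of the simulator with defaults describing a small
#' F1-hybrid-like diploid genome carrying a high-MOI shuffle-cassette library.
#' Haplotypes differ by SNVs with exponential spacing (mean
#' `variant_spacing_mean` bp, emulating a heterozygous variant every ~150 bp).
#' Cis recombination propensity decays exponentially with genomic distance
#' (`distance_rate_scale`); inter-chromosomal pairs recombine at the flat
#' `trans_rate` relative weight.
#'
#' @param seed master seed; all stages derive sub-seeds from it.
#' @param chrom_lengths integer vector of chromosome lengths (bp).
#' @param ploidy copies per chromosome (used for expression copy number).
#' @param centromere_frac centromere position as a fraction of each length.
#' @param variant_spacing_mean mean heterozygous SNV spacing (bp).
#' @param n_clones,cassettes_per_clone clone population design (MOI =
#'   `cassettes_per_clone`).
#' @param cells_per_clone cells expanded per clone.
#' @param recombinase `"Cre"` or `"Bxb1"`.
#' @param event_prob probability that a cell acquires one recombination event.
#' @param distance_rate_scale exponential decay constant (bp) for cis pairs.
#' @param trans_rate flat relative weight for inter-chromosomal pairs.
#' @param selection_weights named per-generation survival multipliers for SV
#'   classes (`deletion`, `inversion`, `balanced`, `dicentric`, `acentric`,
#'   `centromere_deletion`).
#' @param generations generations of selection in [apply_selection()].
#' @param sub_rate uniform substitution rate applied to emitted reads.
#' @param ivt_depth mean reads per cassette end in IVT-seq.
#' @param flank_len_range genomic flank length range (bp) for IVT read 2.
#' @param amp_depth mean amplicon reads per cassette per cell.
#' @param amp_umi_rate mean amplicon molecules (UMIs) per cassette per cell.
#' @param chimera_rate fraction of amplicon reads turned into PCR chimeras.
#' @param t7_umi_mean,t7_umi_size negative-binomial UMI count parameters per
#'   cassette per cell in the single-cell readout.
#' @param t7_reads_per_umi mean reads per captured UMI.
#' @param ambient_fraction fraction of single-cell records re-assigned to a
#'   random cell (ambient contamination).
#' @param sc_chimera_rate rate of chimeric-UMI injection per cell.
#' @param doublet_rate fraction of cells merged into doublets.
#' @param n_genes genes annotated on the synthetic genome.
#' @param base_rate mean transcriptome counts per gene per copy.
#' @param ... additional overrides stored verbatim.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       ploidy = 2L,
                       centromere_frac = 0.4,
                       variant_spacing_mean = 150,
                       n_clones = 20L,
                       cassettes_per_clone = 30L,
                       cells_per_clone = 50L,
                       recombinase = c("Cre", "Bxb1"),
                       event_prob = 0.5,
                       distance_rate_scale = 2e6,
                       trans_rate = 0.05,
                       selection_weights = c(deletion = 0.95, inversion = 1,
                                             balanced = 1, dicentric = 0.7,
                                             acentric = 0.4,
                                             centromere_deletion = 0.5),
                       generations = 5L,
                       sub_rate = 0.001,
                       ivt_depth = 20,
                       flank_len_range = c(35L, 70L),
                       amp_depth = 5,
                       amp_umi_rate = 3,
                       chimera_rate = 0.01,
                       t7_umi_mean = 4,
                       t7_umi_size = 2,
                       t7_reads_per_umi = 20,
                       ambient_fraction = 0.02,
                       sc_chimera_rate = 0.01,
                       doublet_rate = 0,
                       n_genes = 60L,
                       base_rate = 5,
                       ...) {
  recombinase <- match.arg(recombinase)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  stopifnot(all(chrom_lengths > 0), centromere_frac > 0, centromere_frac < 1,
            variant_spacing_mean > 0)
  cfg <- c(list(seed = as.integer(seed),
                chrom_lengths = chrom_lengths,
                ploidy = as.integer(ploidy),
                centromere_frac = centromere_frac,
                variant_spacing_mean = variant_spacing_mean,
                n_clones = as.integer(n_clones),
                cassettes_per_clone = as.integer(cassettes_per_clone),
                cells_per_clone = as.integer(cells_per_clone),
                recombinase = recombinase,
                event_prob = event_prob,
                distance_rate_scale = distance_rate_scale,
                trans_rate = trans_rate,
                selection_weights = selection_weights,
                generations = as.integer(generations),
                sub_rate = sub_rate,
                ivt_depth = ivt_depth,
                flank_len_range = as.integer(flank_len_range),
                amp_depth = amp_depth,
                amp_umi_rate = amp_umi_rate,
                chimera_rate = chimera_rate,
                t7_umi_mean = t7_umi_mean,
                t7_umi_size = t7_umi_size,
                t7_reads_per_umi = t7_reads_per_umi,
                ambient_fraction = ambient_fraction,
                sc_chimera_rate = sc_chimera_rate,
                doublet_rate = doublet_rate,
                n_genes = as.integer(n_genes),
                base_rate = base_rate),
           list(...))
  structure(cfg, class = "sim_config")
}

# Deterministic per-stage sub-seed below 2^31.
stage_seed <- function(cfg, stage) {
  offsets <- c(genome = 11L, integrate = 23L, events = 37L, selection = 41L,
               ivt = 53L, amplicon = 67L, singlecell = 79L)
  (cfg$seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate a synthetic phased genome
#'
#' Generates a random sequence per chromosome, guarantees piggyBac TTAA target
#' sites in every 1-kb window (spiking one at the window centre when absent),
#' and derives two haplotypes (`BL6`, `CAST`) differing at SNV positions drawn
#' with exponential spacing. Variants never overlap a TTAA site, so every
#' integration site exists on both haplotypes. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `shuffle_genome`: list with `chrom_lengths`,
#'   `centromeres`, `haps` (per chromosome, character vectors
#'   `c(BL6 =, CAST =)`), `variants` (`data.table`: chrom, pos, ref, alt) and
#'   `ttaa` (per chromosome, integer vector of TTAA start positions).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "genome"))
  haps <- list(); ttaa <- list(); vars <- list()
  cens <- round(cfg$chrom_lengths * cfg$centromere_frac)
  for (chrom in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chrom]]
    base <- sample(DNA_BASES, len, replace = TRUE)

    # guarantee a TTAA in every 1-kb window
    seq1 <- paste(base, collapse = "")
    starts <- unlist(gregexpr("TTAA", seq1, fixed = TRUE))
    starts <- starts[starts > 0L]
    win <- seq(1L, len, by = 1000L)
    have <- findInterval(starts, win)
    missing_win <- setdiff(seq_along(win), have)
    for (w in missing_win) {
      centre <- min(win[w] + 498L, len - 3L)
      base[centre:(centre + 3L)] <- c("T", "T", "A", "A")
    }
    seq1 <- paste(base, collapse = "")
    starts <- unlist(gregexpr("TTAA", seq1, fixed = TRUE))
    starts <- sort(starts[starts > 0L])

    # SNVs with exponential spacing, never inside a TTAA
    gaps <- pmax(1, round(stats::rexp(ceiling(len / cfg$variant_spacing_mean * 1.3),
                                      rate = 1 / cfg$variant_spacing_mean)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= len - 1L]
    in_ttaa <- rep(FALSE, len)
    idx <- rep(starts, each = 4L) + 0:3
    in_ttaa[idx[idx <= len]] <- TRUE
    pos <- pos[!in_ttaa[pos]]
    ref <- base[pos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))

    hap2 <- base
    hap2[pos] <- alt
    haps[[chrom]] <- c(BL6 = seq1, CAST = paste(hap2, collapse = ""))
    ttaa[[chrom]] <- starts
    vars[[chrom]] <- data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
  }
  structure(list(chrom_lengths = cfg$chrom_lengths,
                 centromeres = cens,
                 haps = haps,
                 variants = rbindlist(vars),
                 ttaa = ttaa),
            class = "shuffle_genome")
}

#' @export
print.shuffle_genome <- function(x, ...) {
  cat(sprintf("<shuffle_genome> %d chromosome(s), %s bp total, %d variants\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$variants)))
  invisible(x)
}

#' Integrate shuffle cassettes into clones
#'
#' Each clone receives `cfg$cassettes_per_clone` cassettes at TTAA target
#' sites sampled uniformly without replacement (within a clone), on a random
#' haplotype and strand, with globally unique random 20-nt barcodes. For Bxb1
#' the site type is attB or attP with equal probability; for Cre all sites are
#' loxPsym.
#'
#' @param genome a [simulate_genome()] result.
#' @param cfg the same [sim_config()].
#' @return a `data.table` of parental cassettes with columns `clone`,
#'   `cassette_id`, `barcode1`, `barcode2`, `site`, `chrom`, `pos`, `strand`,
#'   `allele`.
#' @export
integrate_cassettes <- function(genome, cfg) {
  stopifnot(inherits(genome, "shuffle_genome"), inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "integrate"))
  n_total <- cfg$n_clones * cfg$cassettes_per_clone
  site_pool <- rbindlist(lapply(names(genome$ttaa), function(ch) {
    data.table(chrom = ch, pos = genome$ttaa[[ch]])
  }))
  if (nrow(site_pool) < cfg$cassettes_per_clone) {
    stop("capacity error: ", cfg$cassettes_per_clone,
         " cassettes requested per clone but only ", nrow(site_pool),
         " TTAA sites available", call. = FALSE)
  }
  bcs <- random_barcodes(2L * n_total)
  out <- vector("list", cfg$n_clones)
  for (k in seq_len(cfg$n_clones)) {
    idx <- sample.int(nrow(site_pool), cfg$cassettes_per_clone)
    m <- cfg$cassettes_per_clone
    off <- (k - 1L) * m
    sites <- if (cfg$recombinase == "Cre") rep("loxPsym", m) else
      sample(c("attB", "attP"), m, replace = TRUE)
    out[[k]] <- data.table(
      clone = paste0("clone", k),
      cassette_id = paste0("cas", off + seq_len(m)),
      barcode1 = bcs[2L * off + seq_len(m)],
      barcode2 = bcs[2L * off + m + seq_len(m)],
      site = sites,
      chrom = site_pool$chrom[idx],
      pos = site_pool$pos[idx],
      strand = sample(c("top_CS2", "bottom_CS1"), m, replace = TRUE),
      allele = sample(c("BL6", "CAST"), m, replace = TRUE)
    )
  }
  res <- rbindlist(out)
  setorder(res, clone, chrom, pos)
  res[]
}
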