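# Staged command-line style entry point over the package's pipelines. Each
# stage reads/writes plain-text artifacts in a working directory and drops a
# JSON manifest for provenance.

#' Run one pipeline stage
#'
#' Stages:
#' \describe{
#'   \item{simulate}{genome + clones + cells + all three readouts into
#'     `out_dir` (truth tables included).}
#'   \item{map-insertions}{IVT replicate TSVs -> parental map TSV + BED.}
#'   \item{call-svs}{amplicon reads + parental map -> SV call TSV + BEDPE.}
#'   \item{sc-genotype}{T7 records + parental map -> clonotypes JSON +
#'     assignment TSV + per-cell SV TSV.}
#'   \item{expression}{counts MTX + gene TSV + cell groups -> per-gene TSV.}
#' }
#'
#' @param stage stage name.
#' @param cfg a [sim_config()] (simulate) or named list of stage parameters;
#'   see the stage implementations for the recognised fields.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of written paths.
#' @export
run_stage <- function(stage = c("simulate", "map-insertions", "call-svs",
                                "sc-genotype", "expression"),
                      cfg, out_dir) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- switch(stage,
    "simulate" = stage_simulate(cfg, out_dir),
    "map-insertions" = stage_map_insertions(cfg, out_dir),
    "call-svs" = stage_call_svs(cfg, out_dir),
    "sc-genotype" = stage_sc_genotype(cfg, out_dir),
    "expression" = stage_expression(cfg, out_dir))
  write_manifest(cfg, file.path(out_dir, paste0(stage, ".manifest.json")),
                 extra = list(stage = stage))
  invisible(paths)
}

stage_path <- function(cfg, key, required = TRUE) {
  p <- cfg[[key]]
  if (required && (is.null(p) || !file.exists(p))) {
    stop("missing input for '", key, "': ",
         if (is.null(p)) "not set" else p, call. = FALSE)
  }
  p
}

stage_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- simulate_genome(cfg)
  clones <- integrate_cassettes(genome, cfg)
  cells <- induce_rearrangements(clones, cfg, genome)
  ivt1 <- emit_ivt_reads(clones, genome, cfg, replicate = 1L)
  ivt2 <- emit_ivt_reads(clones, genome, cfg, replicate = 2L)
  amp1 <- emit_amplicon_reads(clones, cfg, replicate = 1L)
  amp2 <- emit_amplicon_reads(clones, cfg, replicate = 2L)
  sc <- emit_single_cell_readout(cells, cfg, genome)
  p <- list(
    clones = file.path(out_dir, "clones.tsv"),
    variants = file.path(out_dir, "variants.tsv"),
    centromeres = file.path(out_dir, "centromeres.tsv"),
    ivt_rep1 = file.path(out_dir, "ivt_rep1.tsv"),
    ivt_rep2 = file.path(out_dir, "ivt_rep2.tsv"),
    amplicon_rep1 = file.path(out_dir, "amplicon_rep1.tsv"),
    amplicon_rep2 = file.path(out_dir, "amplicon_rep2.tsv"),
    t7_records = file.path(out_dir, "t7_records.tsv"),
    cell_metadata = file.path(out_dir, "cell_metadata.tsv"),
    genes = file.path(out_dir, "genes.tsv"),
    truth_events = file.path(out_dir, "truth_events.tsv"),
    expr = file.path(out_dir, "expr"),
    genome = file.path(out_dir, "genome")
  )
  write_tsv_table(clones, p$clones)
  write_tsv_table(genome$variants, p$variants)
  write_tsv_table(data.table(chrom = names(genome$centromeres),
                             pos = as.integer(genome$centromeres)),
                  p$centromeres)
  write_tsv_table(ivt1, p$ivt_rep1); write_tsv_table(ivt2, p$ivt_rep2)
  write_tsv_table(amp1, p$amplicon_rep1); write_tsv_table(amp2, p$amplicon_rep2)
  write_tsv_table(sc$records, p$t7_records)
  write_tsv_table(sc$metadata, p$cell_metadata)
  write_tsv_table(sc$genes, p$genes)
  write_tsv_table(cells$truth$events, p$truth_events)
  write_sparse_mtx(sc$expr, p$expr)
  write_genome_fasta(genome, p$genome)
  p
}

stage_map_insertions <- function(cfg, out_dir) {
  genome <- cfg[["genome"]]
  if (is.null(genome) && !is.null(cfg[["genome_stem"]])) {
    genome <- read_genome_fasta(cfg[["genome_stem"]])
  }
  if (is.null(genome)) {
    stop("cfg$genome (a shuffle_genome) or cfg$genome_stem is required")
  }
  index <- build_genome_index(genome)
  r1 <- read_tsv_table(stage_path(cfg, "ivt_rep1"))
  r2 <- read_tsv_table(stage_path(cfg, "ivt_rep2"))
  amp <- if (!is.null(cfg$parental_amplicons))
    read_tsv_table(stage_path(cfg, "parental_amplicons")) else NULL
  res <- map_insertions(r1, r2, index, parental_amplicon_pairs = amp)
  p <- list(map = file.path(out_dir, "parental_map.tsv"),
            bed = file.path(out_dir, "parental_map.bed"),
            clusters = file.path(out_dir, "clusters_qc.tsv"))
  write_tsv_table(res$insertions, p$map)
  write_insertions_bed(res$insertions, p$bed)
  write_tsv_table(res$clusters, p$clusters)
  p
}

stage_call_svs <- function(cfg, out_dir) {
  reads <- read_tsv_table(stage_path(cfg, "amplicon_reads"))
  pm <- read_tsv_table(stage_path(cfg, "parental_map"))
  cen <- if (!is.null(cfg$centromeres))
    read_tsv_table(stage_path(cfg, "centromeres")) else NULL
  tally <- tally_amplicons(reads)
  if (identical(cfg$scheme, "four_primer")) tally <- collapse_four_primer(tally)
  avg <- normalize_and_average(tally)
  novel <- call_novel_pairs(avg, pm,
                            min_umi = if (is.null(cfg$min_umi)) 2L else
                              cfg$min_umi)
  svs <- classify_all_svs(novel, pm, cen)
  p <- list(svs = file.path(out_dir, "sv_calls.tsv"),
            bedpe = file.path(out_dir, "sv_calls.bedpe"))
  write_tsv_table(svs, p$svs)
  write_svs_bedpe(svs, p$bedpe)
  p
}

stage_sc_genotype <- function(cfg, out_dir) {
  rec <- read_tsv_table(stage_path(cfg, "t7_records"))
  pm <- read_tsv_table(stage_path(cfg, "parental_map"))
  md <- read_tsv_table(stage_path(cfg, "cell_metadata"))
  t7 <- build_t7_matrix(rec,
                        reads_per_umi_floor = if (is.null(cfg$reads_per_umi_floor))
                          1 else cfg$reads_per_umi_floor)
  keep <- qc_cells(md)
  clonotypes <- identify_clonotypes(t7, cells = keep)
  asg <- assign_cells_to_clonotypes(t7, clonotypes, cells = keep)
  svs <- call_cell_rearrangements(t7, pm, asg, clonotypes)
  p <- list(clonotypes = file.path(out_dir, "clonotypes.json"),
            assignments = file.path(out_dir, "assignments.tsv"),
            cell_svs = file.path(out_dir, "cell_svs.tsv"))
  jsonlite::write_json(
    lapply(seq_len(nrow(clonotypes)), function(i) list(
      clonotype = clonotypes$clonotype[i],
      members = clonotypes$members[[i]],
      top_fraction = clonotypes$top_fraction[i],
      n_cells = clonotypes$n_cells[i])),
    p$clonotypes, auto_unbox = TRUE, digits = NA)
  write_tsv_table(asg, p$assignments)
  write_tsv_table(svs, p$cell_svs)
  p
}

stage_expression <- function(cfg, out_dir) {
  stem <- cfg$expr_stem
  if (is.null(stem) || !file.exists(paste0(stem, ".mtx"))) {
    stop("missing input for 'expr_stem': ",
         if (is.null(stem)) "not set" else paste0(stem, ".mtx"), call. = FALSE)
  }
  counts <- read_sparse_mtx(stem)
  genes <- read_tsv_table(stage_path(cfg, "genes"))
  sv_cells <- readLines(stage_path(cfg, "sv_cells"))
  ctrl_cells <- readLines(stage_path(cfg, "control_cells"))
  norm <- normalize_expression(counts, genes)
  res <- genotype_fold_change_test(norm, sv_cells, ctrl_cells)
  scan <- rolling_window_scan(
    stats::setNames(res$fold_change, res$gene), norm$genes,
    target_genes = cfg$target_genes)
  p <- list(fold_changes = file.path(out_dir, "fold_changes.tsv"),
            windows = file.path(out_dir, "windows.tsv"))
  write_tsv_table(res, p$fold_changes)
  write_tsv_table(scan, p$windows)
  p
}
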