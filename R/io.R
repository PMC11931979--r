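# Readers/writers for the tabular and matrix interchange formats: TSV is the
# canonical interchange, BED/BEDPE for genomic exports (0-based half-open),
# MTX + index TSVs for sparse matrices, FASTQ for reads, JSON for manifests.

#' Read / write interchange TSV
#'
#' Thin wrappers over `data.table::fread`/`fwrite` fixing the separator and
#' keeping headers; round trips are lossless for the package's tables.
#'
#' @param x a table; `path` a file path.
#' @return `read_tsv_table` returns a `data.table`.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Export insertions as BED
#'
#' Internal coordinates are 1-based (the first base of the TTAA duplication);
#' BED uses 0-based half-open intervals, so an insertion at `pos` P becomes
#' the interval [P-1, P+3) covering the TTAA.
#'
#' @param insertions insertion table (needs `chrom`, `pos`, `strand`,
#'   `barcode1`, `barcode2`).
#' @param path output path.
#' @export
write_insertions_bed <- function(insertions, path) {
  ins <- as.data.table(insertions)
  bed <- ins[, .(chrom,
                 start = pos - 1L,
                 end = pos + 3L,
                 name = paste(barcode1, barcode2, sep = "|"),
                 score = 0L,
                 strand = fifelse(strand == "top_CS2", "+", "-"))]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export SV calls as BEDPE
#'
#' Junction parents as paired 0-based half-open TTAA intervals.
#'
#' @param svcalls table from [classify_all_svs()].
#' @param path output path.
#' @export
write_svs_bedpe <- function(svcalls, path) {
  sv <- as.data.table(svcalls)
  bedpe <- sv[, .(chrom1 = chromA, start1 = posA - 1L, end1 = posA + 3L,
                  chrom2 = chromB, start2 = posB - 1L, end2 = posB + 3L,
                  name = paste(class,
                               fifelse(is.na(deletion_product), "",
                                       deletion_product), sep = ":"),
                  score = umi_count, strand1 = ".", strand2 = ".")]
  data.table::fwrite(bedpe, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a sparse matrix as MTX with index TSVs
#'
#' Writes `<stem>.mtx`, `<stem>.rows.tsv`, `<stem>.cols.tsv`; reading restores
#' the dimnames. Sparsity pattern and counts round-trip exactly.
#'
#' @param m a sparse `Matrix` with dimnames.
#' @param stem path stem (without extension).
#' @return `read_sparse_mtx` returns the sparse matrix.
#' @export
write_sparse_mtx <- function(m, stem) {
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".rows.tsv"))
  writeLines(colnames(m), paste0(stem, ".cols.tsv"))
  invisible(stem)
}

#' @rdname write_sparse_mtx
#' @export
read_sparse_mtx <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  dimnames(m) <- list(readLines(paste0(stem, ".rows.tsv")),
                      readLines(paste0(stem, ".cols.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' Write reads as FASTQ
#'
#' @param seqs named character vector of sequences (names become read ids).
#' @param path output path (`.fastq`).
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path input path.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write / read a synthetic phased genome as FASTA + TSVs
#'
#' The two haplotypes of every chromosome are written as FASTA records named
#' `<chrom>|<haplotype>`, alongside the variant and centromere tables;
#' `read_genome_fasta` reconstructs the `shuffle_genome` (TTAA positions are
#' recomputed from the reference haplotype).
#'
#' @param genome a [simulate_genome()] result.
#' @param stem path stem; writes `<stem>.fa`, `<stem>.variants.tsv`,
#'   `<stem>.centromeres.tsv`.
#' @return `read_genome_fasta` returns a `shuffle_genome`.
#' @export
write_genome_fasta <- function(genome, stem) {
  seqs <- list()
  for (chrom in names(genome$haps)) {
    for (h in names(genome$haps[[chrom]])) {
      seqs[[paste(chrom, h, sep = "|")]] <- genome$haps[[chrom]][[h]]
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)),
                              paste0(stem, ".fa"))
  write_tsv_table(genome$variants, paste0(stem, ".variants.tsv"))
  write_tsv_table(data.table(chrom = names(genome$centromeres),
                             pos = as.integer(genome$centromeres)),
                  paste0(stem, ".centromeres.tsv"))
  invisible(stem)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(stem) {
  ss <- Biostrings::readDNAStringSet(paste0(stem, ".fa"))
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  chroms <- unique(vapply(parts, `[[`, character(1), 1L))
  haps <- list(); ttaa <- list()
  for (chrom in chroms) {
    idx <- vapply(parts, function(p) p[1L] == chrom, logical(1))
    h <- stats::setNames(as.character(ss[idx]),
                         vapply(parts[idx], `[[`, character(1), 2L))
    haps[[chrom]] <- h
    starts <- unlist(gregexpr("TTAA", h[["BL6"]], fixed = TRUE))
    ttaa[[chrom]] <- sort(starts[starts > 0L])
  }
  cen_tab <- read_tsv_table(paste0(stem, ".centromeres.tsv"))
  structure(list(
    chrom_lengths = vapply(haps, function(h) nchar(h[["BL6"]]), numeric(1)),
    centromeres = stats::setNames(cen_tab$pos, cen_tab$chrom),
    haps = haps,
    variants = read_tsv_table(paste0(stem, ".variants.tsv")),
    ttaa = ttaa), class = "shuffle_genome")
}

#' Write a run manifest
#'
#' Serializes the configuration, seed and package version next to a stage's
#' outputs for provenance.
#'
#' @param cfg a [sim_config()] or parameter list.
#' @param path output JSON path.
#' @param extra optional named list appended to the manifest.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(list(
    package = "shufflekit",
    version = as.character(utils::packageVersion("shufflekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
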