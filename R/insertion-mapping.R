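# IVT-seq decoding: flank alignment with a built-in exact-seed mapper,
# allele assignment against the phased variant table, position-sharing
# Levenshtein clustering, replicate merging and the paired-cluster insertion
# call.
#
# Alignment coordinates follow the BED convention used throughout bulk
# short-read pipelines: `aln_start` is 0-based, `aln_end` exclusive. The
# derived junction position of a + strand alignment is its end, of a - strand
# alignment its start; the two clusters flanking one TTAA insertion then sit
# exactly 4 bp apart.

#' Build an alignment index over a synthetic genome
#'
#' Wraps the reference haplotype (`BL6`) of every chromosome as a
#' `Biostrings::DNAString` for exact-seed matching.
#'
#' @param genome a [simulate_genome()] result.
#' @return a list of class `genome_index`.
#' @export
build_genome_index <- function(genome) {
  stopifnot(inherits(genome, "shuffle_genome"))
  ref <- lapply(genome$haps, function(h) Biostrings::DNAString(h[["BL6"]]))
  chr <- lapply(genome$haps, function(h) h[["BL6"]])
  structure(list(ref = ref, chr = chr,
                 len = vapply(chr, nchar, integer(1)),
                 variants = copy(genome$variants)),
            class = "genome_index")
}

# All exact occurrences of `pattern` in the reference, both strands.
# Returns data.table(chrom, start0, end0, strand) in BED convention.
seed_hits <- function(index, pattern) {
  batch_seed_hits(index, pattern)[[1L]]
}

# Vectorised seed matching: one PDict scan per chromosome and strand for a
# whole batch of equal-length seeds. Returns a list (one table per seed).
batch_seed_hits <- function(index, seeds) {
  k <- unique(nchar(seeds))
  stopifnot(length(k) == 1L)
  ss <- Biostrings::DNAStringSet(seeds)
  pd_f <- Biostrings::PDict(ss)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(ss))
  out <- rep(list(NULL), length(seeds))
  for (chrom in names(index$ref)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r,
                                  index$ref[[chrom]])
      cnt <- S4Vectors::elementNROWS(m)
      for (i in which(cnt > 0L)) {
        st <- Biostrings::start(m[[i]])
        out[[i]] <- rbindlist(list(out[[i]], data.table(
          chrom = chrom, start0 = st - 1L, end0 = st + k - 1L, strand = str)))
      }
    }
  }
  empty <- data.table(chrom = character(), start0 = integer(),
                      end0 = integer(), strand = character())
  lapply(out, function(x) if (is.null(x)) empty else x)
}

# Extend one seed hit over the full genomic portion of a read and verify it;
# returns the alignment (without junction check) or NULL. `rc_gseq` is the
# precomputed reverse complement of `gseq`.
extend_seed_hit <- function(index, chrom, strand, start0, end0, off, gseq,
                            rc_gseq, max_mismatch_frac) {
  n <- nchar(gseq)
  if (strand == "+") {
    a0 <- start0 - (off - 1L)
    b0 <- a0 + n
  } else {
    b0 <- end0 + (off - 1L)
    a0 <- b0 - n
  }
  if (a0 < 0L || b0 > index$len[[chrom]]) return(NULL)
  refseq <- substr(index$chr[[chrom]], a0 + 1L, b0)
  qry <- if (strand == "+") gseq else rc_gseq
  mm <- which(utf8ToInt(refseq) != utf8ToInt(qry))
  if (length(mm) > max_mismatch_frac * n) return(NULL)
  list(chrom = chrom, aln_start = a0, aln_end = b0,
       genome_strand = strand, mismatch_pos = a0 + mm)
}

# The implied junction of an alignment must fall at a TTAA: + strand junction
# at the alignment end, - strand at the start.
junction_at_ttaa <- function(index, aln) {
  jseq <- if (aln$genome_strand == "+") {
    if (aln$aln_end < 4L) return(FALSE)
    substr(index$chr[[aln$chrom]], aln$aln_end - 3L, aln$aln_end)
  } else {
    if (aln$aln_start + 4L > index$len[[aln$chrom]]) return(FALSE)
    substr(index$chr[[aln$chrom]], aln$aln_start + 1L, aln$aln_start + 4L)
  }
  jseq == "TTAA"
}

#' Trim and align one IVT read 2
#'
#' Strips the 8-nt degenerate UMI and the trailing transposon ITR remnant,
#' then maps the genomic portion with an exact seed (k = `seed_len`, tried at
#' several offsets so a heterozygous variant inside one seed window does not
#' lose the read) extended over the full read allowing at most
#' `max_mismatch_frac` mismatching bases. Returns `NULL` ("unmapped") when the
#' ITR is absent, when zero or more than one locus matches, or when the implied
#' junction does not sit at a TTAA target site.
#'
#' @param read2 one read-2 sequence.
#' @param index a [build_genome_index()].
#' @param seed_len exact seed length.
#' @param max_mismatch_frac maximum mismatch fraction over the aligned length.
#' @return a list with `chrom`, `aln_start` (0-based), `aln_end` (exclusive),
#'   `genome_strand`, `aligned_length`, `umi`, `mismatch_pos` (1-based
#'   reference positions of mismatches), or `NULL` when unmapped/filtered.
#' @export
trim_and_align_flank <- function(read2, index, seed_len = 31L,
                                 max_mismatch_frac = 0.1) {
  stopifnot(inherits(index, "genome_index"))
  umi <- substr(read2, 1L, IVT_UMI_LEN)
  rest <- substr(read2, IVT_UMI_LEN + 1L, nchar(read2))
  itr_at <- regexpr(ITR_SEQ, rest, fixed = TRUE)
  if (itr_at < 1L) return(NULL)            # untrimmed reads are discarded
  gseq <- substr(rest, 1L, itr_at - 1L)
  n <- nchar(gseq)
  if (n < 15L) return(NULL)
  k <- min(seed_len, n)

  rc_gseq <- revcomp(gseq)
  aln <- NULL
  for (tier in seed_tiers(k)) {
    offsets <- unique(pmax(1L, pmin(tier$offsets, n - tier$k + 1L)))
    for (off in offsets) {
      seed <- substr(gseq, off, off + tier$k - 1L)
      if (grepl("[^ACGT]", seed)) next
      hits <- seed_hits(index, seed)
      if (nrow(hits) == 0L) next
      full <- lapply(seq_len(nrow(hits)), function(i)
        extend_seed_hit(index, hits$chrom[i], hits$strand[i], hits$start0[i],
                        hits$end0[i], off, gseq, rc_gseq, max_mismatch_frac))
      full <- Filter(Negate(is.null), full)
      # deduplicate loci found through multiple seeds of the same read
      if (length(full) > 0L) {
        key <- vapply(full, function(f)
          paste(f$chrom, f$aln_start, f$genome_strand), character(1))
        full <- full[!duplicated(key)]
        if (length(full) > 1L) return(NULL)   # multi-mapper filter
        aln <- full[[1L]]
        break
      }
    }
    if (!is.null(aln)) break
  }
  if (is.null(aln)) return(NULL)
  if (!junction_at_ttaa(index, aln)) return(NULL)
  aln$aligned_length <- aln$aln_end - aln$aln_start
  aln$umi <- umi
  aln
}

# Seed tiers: the primary exact seed (k = 31) at coarse offsets; shorter
# fallback seeds at denser offsets rescue reads whose every long seed window
# overlaps a haplotype variant. False seed hits are harmless: the full-read
# extension verifies every candidate locus.
seed_tiers <- function(k = 31L) {
  list(list(k = k, offsets = seq(1L, 25L, by = 8L)),
       list(k = 17L, offsets = seq(1L, 41L, by = 4L)),
       list(k = 13L, offsets = seq(1L, 49L, by = 2L)))
}

# Batch flank alignment: same semantics as trim_and_align_flank per read, but
# seed matching is pooled into PDict scans per offset round. Returns a list of
# alignments (NULL where unmapped).
batch_align_flanks <- function(read2, index, seed_len = 31L,
                               max_mismatch_frac = 0.1) {
  n_reads <- length(read2)
  umis <- substr(read2, 1L, IVT_UMI_LEN)
  rest <- substring(read2, IVT_UMI_LEN + 1L)
  itr_at <- regexpr(ITR_SEQ, rest, fixed = TRUE)
  gseqs <- ifelse(itr_at > 0L, substr(rest, 1L, itr_at - 1L), NA_character_)
  lens <- nchar(gseqs)
  rc_gseqs <- rep(NA_character_, n_reads)
  valid <- which(!is.na(gseqs) & !grepl("[^ACGT]", gseqs))
  rc_gseqs[valid] <- revcomp(gseqs[valid])
  out <- rep(list(NULL), n_reads)
  active <- intersect(valid, which(lens >= 15L))

  # reads too short for the constant-width batch seed take the per-read path
  short <- active[lens[active] < seed_len]
  for (i in short) {
    out[[i]] <- trim_and_align_flank(read2[i], index, seed_len,
                                     max_mismatch_frac)
  }
  active <- setdiff(active, short)

  for (tier in seed_tiers(seed_len)) {
    for (off in tier$offsets) {
      if (length(active) == 0L) break
      ok <- active[lens[active] >= off + tier$k - 1L]
      if (length(ok) == 0L) next
      seeds <- substr(gseqs[ok], off, off + tier$k - 1L)
      useed <- unique(seeds)
      hit_list <- batch_seed_hits(index, useed)
      names(hit_list) <- useed
      resolved <- logical(length(ok))
      for (j in seq_along(ok)) {
        i <- ok[j]
        hits <- hit_list[[seeds[j]]]
        if (nrow(hits) == 0L) next
        full <- lapply(seq_len(nrow(hits)), function(h)
          extend_seed_hit(index, hits$chrom[h], hits$strand[h], hits$start0[h],
                          hits$end0[h], off, gseqs[i], rc_gseqs[i],
                          max_mismatch_frac))
        full <- Filter(Negate(is.null), full)
        if (length(full) == 0L) next
        key <- vapply(full, function(f)
          paste(f$chrom, f$aln_start, f$genome_strand), character(1))
        full <- full[!duplicated(key)]
        resolved[j] <- TRUE
        if (length(full) > 1L) next            # multi-mapper: stays unmapped
        aln <- full[[1L]]
        if (!junction_at_ttaa(index, aln)) next
        aln$aligned_length <- aln$aln_end - aln$aln_start
        aln$umi <- umis[i]
        out[[i]] <- aln
      }
      active <- setdiff(active, ok[resolved])
    }
    if (length(active) == 0L) break
  }
  out
}

#' Derive the junction position of an alignment
#'
#' The position of an alignment is determined by the genomic strand it maps
#' to: the end for + strand alignments, the start for - strand alignments
#' (BED-convention coordinates).
#'
#' @param aln a list with `genome_strand`, `aln_start`, `aln_end` (or the
#'   three values passed separately).
#' @param genome_strand,aln_start,aln_end alternative scalar interface.
#' @return integer position.
#' @export
derive_position <- function(aln = NULL, genome_strand = aln$genome_strand,
                            aln_start = aln$aln_start, aln_end = aln$aln_end) {
  if (aln_end <= aln_start) {
    stop("degenerate alignment: aln_end must exceed aln_start", call. = FALSE)
  }
  if (genome_strand == "+") aln_end else aln_start
}

#' Assign haplotype evidence to an alignment
#'
#' `BL6` when every overlapped variant position matches the reference allele,
#' `CAST` when every one matches the alternate, `noVariant` when the alignment
#' overlaps no variant, `inconclusive` on mixed evidence.
#'
#' @param aln an alignment from [trim_and_align_flank()].
#' @param variant_table `data.table` with `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @return one of `"BL6"`, `"CAST"`, `"noVariant"`, `"inconclusive"`.
#' @export
assign_allele <- function(aln, variant_table) {
  v <- variant_table[chrom == aln$chrom & pos > aln$aln_start &
                       pos <= aln$aln_end]
  if (nrow(v) == 0L) return("noVariant")
  mm <- aln$mismatch_pos
  matches_alt <- v$pos %in% mm
  # a mismatch at a variant position means the read carries the alternate
  # allele (mismatches elsewhere are noise and ignored here)
  if (all(matches_alt)) "CAST" else if (!any(matches_alt)) "BL6" else
    "inconclusive"
}

# binary-search variant lookup used by the batch aligner
variant_index <- function(variant_table) {
  lapply(split(variant_table$pos, variant_table$chrom), sort)
}

fast_allele <- function(vidx, aln) {
  vp <- vidx[[aln$chrom]]
  if (is.null(vp)) return("noVariant")
  i1 <- findInterval(aln$aln_start, vp) + 1L
  i2 <- findInterval(aln$aln_end, vp)
  if (i2 < i1) return("noVariant")
  matches_alt <- vp[i1:i2] %in% aln$mismatch_pos
  if (all(matches_alt)) "CAST" else if (!any(matches_alt)) "BL6" else
    "inconclusive"
}

#' Align an IVT read table
#'
#' Runs barcode extraction on read 1 and [trim_and_align_flank()] plus
#' [assign_allele()] on read 2 for every read, producing the per-read flank
#' alignment table consumed by [cluster_alignments()].
#'
#' @param reads read table from [emit_ivt_reads()] (needs `read1`, `umi1`,
#'   `read2`).
#' @param index a [build_genome_index()].
#' @param signatures signature table.
#' @return a `data.table` with one row per mapped read: `chrom`, `position`,
#'   `genome_strand`, `barcode1`, `barcode2`, `cassette_strand`, `allele`,
#'   `umi1`, `umi2`, `aligned_length`, `aln_start`, `aln_end`.
#' @export
align_ivt_reads <- function(reads, index, signatures = site_signatures()) {
  reads <- as.data.table(reads)
  out <- vector("list", nrow(reads))
  # extraction is deterministic per distinct read-1 sequence: cache it
  r1_cache <- new.env(parent = emptyenv())
  extract_r1 <- function(r1) {
    key <- r1
    if (!is.null(r1_cache[[key]])) return(r1_cache[[key]])
    hits <- extract_cassette_hits(r1, signatures)
    val <- NULL
    pair <- pick_cassette_pair(hits)
    if (!is.null(pair)) {
      val <- list(barcode1 = pair$barcode1, barcode2 = pair$barcode2,
                  cassette_strand = if (pair$orientation == "+")
                    "top_CS2" else "bottom_CS1")
    } else if (nrow(hits) >= 2L) {
      # homotypic product read: two same-side hits in one orientation
      for (o in unique(hits$orientation)) {
        sub <- hits[orientation == o]
        if (nrow(sub) >= 2L) {
          val <- list(barcode1 = sub$barcode[1L], barcode2 = sub$barcode[2L],
                      cassette_strand = if (o == "+") "top_CS2" else
                        "bottom_CS1")
          break
        }
      }
    }
    r1_cache[[key]] <- if (is.null(val)) list() else val
    r1_cache[[key]]
  }

  alns <- batch_align_flanks(reads$read2, index)
  vidx <- variant_index(index$variants)
  for (i in seq_len(nrow(reads))) {
    bcs <- extract_r1(reads$read1[i])
    if (length(bcs) == 0L) next
    aln <- alns[[i]]
    if (is.null(aln)) next
    out[[i]] <- list(
      chrom = aln$chrom,
      position = derive_position(aln),
      genome_strand = aln$genome_strand,
      barcode1 = bcs$barcode1, barcode2 = bcs$barcode2,
      cassette_strand = bcs$cassette_strand,
      allele = fast_allele(vidx, aln),
      umi1 = reads$umi1[i], umi2 = aln$umi,
      aligned_length = aln$aligned_length,
      aln_start = aln$aln_start, aln_end = aln$aln_end
    )
  }
  res <- rbindlist(Filter(Negate(is.null), out))
  if (nrow(res) > 0L) res <- res[allele != "inconclusive"]
  res
}

# single-linkage clusters under Levenshtein <= radius on concatenated barcodes
levenshtein_clusters <- function(bc, radius = 6L) {
  n <- length(bc)
  if (n == 1L) return(1L)
  d <- utils::adist(bc)
  g <- igraph::graph_from_adjacency_matrix(d <= radius, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

modal_value <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  # ties broken lexicographically
  cand <- names(tb)[tb == tb[1L]]
  sort(cand)[1L]
}

cluster_allele <- function(alleles) {
  a <- alleles[alleles != "noVariant"]
  if (length(a) == 0L) return("noVariant")
  modal_value(a)
}

#' Cluster flank alignments
#'
#' Groups alignments sharing (chromosome, position), then single-linkage
#' clusters each group under Levenshtein distance <= `radius` on the
#' concatenated barcode pair. Representative values are modal (ties broken
#' lexicographically); the cluster allele is the modal allele ignoring
#' `noVariant` evidence.
#'
#' @param alignments table from [align_ivt_reads()].
#' @param radius Levenshtein clustering radius (joint over bc1+bc2).
#' @return a `data.table` of clusters: `chrom`, `position`, `genome_strand`,
#'   `barcode1`, `barcode2`, `cassette_strand`, `allele`, `read_count`,
#'   `read1_umi_count`, `read2_umi_count`, `n_unique_aligned_lengths`.
#' @export
cluster_alignments <- function(alignments, radius = 6L) {
  aln <- as.data.table(alignments)
  if (nrow(aln) == 0L) {
    return(data.table(chrom = character(), position = integer(),
                      genome_strand = character(), barcode1 = character(),
                      barcode2 = character(), cassette_strand = character(),
                      allele = character(), read_count = integer(),
                      read1_umi_count = integer(), read2_umi_count = integer(),
                      n_unique_aligned_lengths = integer()))
  }
  aln[, grp := .GRP, by = .(chrom, position)]
  res <- aln[, {
    memb <- levenshtein_clusters(paste0(barcode1, barcode2), radius)
    .SD[, .(
      genome_strand = modal_value(genome_strand),
      barcode1 = modal_value(barcode1),
      barcode2 = modal_value(barcode2),
      cassette_strand = modal_value(cassette_strand),
      allele = cluster_allele(allele),
      read_count = .N,
      read1_umi_count = uniqueN(umi1),
      read2_umi_count = uniqueN(umi2),
      n_unique_aligned_lengths = uniqueN(aligned_length)
    ), by = .(sub = memb)][, sub := NULL]
  }, by = .(chrom, position)]
  setorder(res, chrom, position)
  res[]
}

#' Merge replicate cluster sets and filter
#'
#' Joins two replicate cluster tables on (chrom, position, genome strand,
#' barcodes, cassette strand). A cluster is removed iff its replicate-2 support
#' has fewer than `min_reads` reads AND fewer than `min_lengths` unique aligned
#' lengths (replicate 2 is the designated anchor replicate). Conflicting
#' replicate alleles give `inconclusive` (noVariant defers to the informative
#' replicate). Barcode pairs mapping to more than one genomic location are
#' removed entirely.
#'
#' @param rep1,rep2 cluster tables from [cluster_alignments()].
#' @param min_reads,min_lengths anchor-replicate support floor.
#' @return merged cluster `data.table` with per-replicate support columns.
#' @export
merge_and_filter_replicates <- function(rep1, rep2, min_reads = 6L,
                                        min_lengths = 3L) {
  key <- c("chrom", "position", "genome_strand", "barcode1", "barcode2",
           "cassette_strand")
  r1 <- as.data.table(rep1); r2 <- as.data.table(rep2)
  m <- merge(r1, r2, by = key, suffixes = c("_rep1", "_rep2"))
  if (nrow(m) == 0L) return(m)

  # anchor-replicate support filter (conjunction: weak in BOTH measures)
  m <- m[!(read_count_rep2 < min_reads &
             n_unique_aligned_lengths_rep2 < min_lengths)]
  if (nrow(m) == 0L) return(m)

  resolve <- function(a1, a2) {
    if (a1 == "noVariant") return(a2)
    if (a2 == "noVariant") return(a1)
    if (a1 == a2) a1 else "inconclusive"
  }
  m[, allele := mapply(resolve, allele_rep1, allele_rep2)]

  # barcode combinations must map to a unique genomic location
  m[, n_loc := uniqueN(paste(chrom, position)), by = .(barcode1, barcode2)]
  # the two clusters of one insertion carry reverse-complementary barcode
  # pairs, so uniqueness is assessed per oriented pair; a pair recurring at a
  # second locus is an artefact
  m <- m[n_loc == 1L][, n_loc := NULL]
  setorder(m, chrom, position)
  m[]
}

#' Call insertions from merged clusters
#'
#' A bona fide insertion is a pair of clusters whose positions differ by
#' exactly 4 bp, where the lower cluster maps to the - strand and the upper to
#' the + strand, the two clusters carry different cassette-strand labels, and
#' their barcodes are reverse complements of one another. The insertion allele
#' is resolved across the pair (conflict gives `inconclusive`; one-sided
#' noVariant adopts the other side). When several barcode pairs are called at
#' one position, the row with the higher replicate-2 unique-length support on
#' the left side wins.
#'
#' @param clusters merged cluster table from [merge_and_filter_replicates()].
#' @return a `data.table` of insertions: `chrom`, `pos` (1-based first base of
#'   the TTAA), `strand` (cassette orientation), `barcode1`, `barcode2`,
#'   `allele`, plus left/right cluster support columns.
#' @export
call_insertions <- function(clusters) {
  cl <- as.data.table(clusters)
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), barcode1 = character(),
                      barcode2 = character(), allele = character())
  if (nrow(cl) == 0L) return(empty)
  setorder(cl, chrom, position)
  left <- cl[genome_strand == "-"]
  right <- cl[genome_strand == "+"]
  if (nrow(left) == 0L || nrow(right) == 0L) return(empty)

  right_key <- right[, .(chrom, match_pos = position - 4L, idx_r = .I)]
  cand <- merge(left[, .(chrom, match_pos = position, idx_l = .I)],
                right_key, by = c("chrom", "match_pos"),
                allow.cartesian = TRUE)
  if (nrow(cand) == 0L) return(empty)

  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    L <- left[cand$idx_l[i]]; R <- right[cand$idx_r[i]]
    if (L$cassette_strand == R$cassette_strand) next
    if (!identical(revcomp(L$barcode1), R$barcode1) ||
        !identical(revcomp(L$barcode2), R$barcode2)) next
    # canonical barcodes from the top_CS2-labelled cluster
    topside <- if (L$cassette_strand == "top_CS2") L else R
    allele <- if (L$allele == "noVariant") R$allele
      else if (R$allele == "noVariant") L$allele
      else if (L$allele == R$allele) L$allele else "inconclusive"
    out[[i]] <- data.table(
      chrom = L$chrom, pos = L$position + 1L,
      strand = if (L$cassette_strand == "top_CS2") "top_CS2" else "bottom_CS1",
      barcode1 = topside$barcode1, barcode2 = topside$barcode2,
      allele = allele,
      left_reads_rep1 = L$read_count_rep1, left_reads_rep2 = L$read_count_rep2,
      right_reads_rep1 = R$read_count_rep1, right_reads_rep2 = R$read_count_rep2,
      left_lengths_rep2 = L$n_unique_aligned_lengths_rep2,
      right_lengths_rep2 = R$n_unique_aligned_lengths_rep2,
      left_position = L$position, right_position = R$position
    )
  }
  res <- rbindlist(Filter(Negate(is.null), out))
  if (nrow(res) == 0L) return(empty)
  # duplicate barcode sets at one position: keep the best-supported row
  setorder(res, chrom, pos, -left_lengths_rep2)
  res <- res[, .SD[1L], by = .(chrom, pos)]
  setorder(res, chrom, pos)
  res[]
}

#' Intersect insertions with parental amplicon barcode pairs
#'
#' Only insertions whose (barcode1, barcode2) combination is detected in the
#' parental amplicon-seq data are retained; the result is the experiment's
#' authoritative barcode-to-locus map.
#'
#' @param insertions table from [call_insertions()].
#' @param parental_amplicon_pairs `data.table` with `barcode1`, `barcode2`
#'   (e.g. from [tally_amplicons()]).
#' @return the filtered insertion table (the parental map).
#' @export
finalize_parental_map <- function(insertions, parental_amplicon_pairs) {
  ins <- as.data.table(insertions)
  amp <- as.data.table(parental_amplicon_pairs)
  if (nrow(amp) == 0L) {
    warning("empty parental amplicon table: parental map is empty")
    return(ins[0L])
  }
  keep <- paste(ins$barcode1, ins$barcode2) %in%
    paste(amp$barcode1, amp$barcode2)
  ins[keep]
}

#' Run the full insertion-mapping pipeline
#'
#' Convenience wrapper: aligns two IVT replicates, clusters, merges, calls
#' insertions and (optionally) intersects with parental amplicon pairs.
#'
#' @param reads_rep1,reads_rep2 read tables from [emit_ivt_reads()].
#' @param index a [build_genome_index()].
#' @param parental_amplicon_pairs optional amplicon pair table.
#' @param radius Levenshtein clustering radius.
#' @param min_reads,min_lengths anchor-replicate support floor.
#' @return list with `alignments` (per replicate), `clusters` (merged) and
#'   `insertions`.
#' @export
map_insertions <- function(reads_rep1, reads_rep2, index,
                           parental_amplicon_pairs = NULL, radius = 6L,
                           min_reads = 6L, min_lengths = 3L) {
  a1 <- align_ivt_reads(reads_rep1, index)
  a2 <- align_ivt_reads(reads_rep2, index)
  c1 <- cluster_alignments(a1, radius)
  c2 <- cluster_alignments(a2, radius)
  merged <- merge_and_filter_replicates(c1, c2, min_reads, min_lengths)
  ins <- call_insertions(merged)
  if (!is.null(parental_amplicon_pairs)) {
    ins <- finalize_parental_map(ins, parental_amplicon_pairs)
  }
  list(alignments = list(rep1 = a1, rep2 = a2),
       clusters = merged, insertions = ins)
}
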