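# Amplicon-seq decoding and structural-variant inference: barcode-pair
# tallies, four-primer collapse, depth normalization, novel-pair detection,
# event classification (deletion / inversion / translocation), scar vs ecDNA
# splitting, translocation subclassification, arm-spanning labels, IVT
# validation, reciprocal-pair matching, bootstrap size statistics and
# clone-well genotyping.

#' Tally amplicon reads into barcode-pair counts
#'
#' Extracts the two barcodes, the site evidence and the UMI (first
#' `umi_len` bases) from each read, and tallies read and unique-UMI counts per
#' (barcode1, barcode2, site, orientation). Reads whose barcodes cannot both
#' be extracted are excluded and counted in the `qc` attribute. The site is
#' decoded from the combination of signature bases on the two sides;
#' reverse-orientation reads are re-oriented so `barcode1` is always the
#' CS2-adjacent barcode.
#'
#' @param reads read table from [emit_amplicon_reads()] (needs `seq`; a
#'   `replicate` column is carried through when present).
#' @param signatures signature table.
#' @param umi_len UMI length at the start of each read.
#' @return a `data.table` with `barcode1`, `barcode2`, `site`, `orientation`,
#'   `read_count`, `umi_count` (plus `replicate`); attribute `qc` holds the
#'   number of unparseable reads.
#' @export
tally_amplicons <- function(reads, signatures = site_signatures(),
                            umi_len = AMP_UMI_LEN) {
  reads <- as.data.table(reads)
  has_rep <- "replicate" %in% names(reads)
  n_bad <- 0L
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    umi <- substr(s, 1L, umi_len)
    body <- substr(s, umi_len + 1L, nchar(s))
    hits <- extract_cassette_hits(body, signatures)
    pair <- pick_cassette_pair(hits)
    if (is.null(pair)) { n_bad <- n_bad + 1L; next }
    # re-orient reverse reads back to the cassette-intrinsic frame
    if (pair$orientation == "-") {
      pair$barcode1 <- revcomp(pair$barcode1)
      pair$barcode2 <- revcomp(pair$barcode2)
    }
    rows[[i]] <- data.table(
      barcode1 = pair$barcode1, barcode2 = pair$barcode2, site = pair$site,
      orientation = if (pair$orientation == "-") "rev" else "fwd", umi = umi,
      replicate = if (has_rep) reads$replicate[i] else 1L)
  }
  long <- rbindlist(Filter(Negate(is.null), rows))
  if (nrow(long) == 0L) {
    out <- data.table(barcode1 = character(), barcode2 = character(),
                      site = character(), orientation = character(),
                      replicate = integer(), read_count = integer(),
                      umi_count = integer())
  } else {
    out <- long[, .(read_count = .N, umi_count = uniqueN(umi)),
                by = .(barcode1, barcode2, site, orientation, replicate)]
    # majority-rule site per barcode pair
    out[, site := site[which.max(read_count)], by = .(barcode1, barcode2)]
    out <- out[, .(read_count = sum(read_count), umi_count = sum(umi_count)),
               by = .(barcode1, barcode2, site, orientation, replicate)]
  }
  setattr(out, "qc", list(unparseable_reads = n_bad))
  out[]
}

# site identity from the two half-site evidences of one read
decode_site <- function(h1, h2) {
  l <- h1$half; r <- h2$half
  if (l == "sym" && r == "sym") return("loxPsym")
  if (l == "B" && r == "B") return("attB")
  if (l == "P" && r == "P") return("attP")
  if (l == "B" && r == "P") return("attL")
  if (l == "P" && r == "B") return("attR")
  NA_character_
}

#' Collapse four-primer amplicon orientations
#'
#' The four-primer scheme yields two distinct amplicons per cassette; reads
#' from the same cassette are collapsed on the shared barcode set with read
#' and UMI counts summed. Barcode pairs observed in only one orientation are
#' discarded.
#'
#' @param table a [tally_amplicons()] result containing both orientations.
#' @return collapsed `data.table` without the `orientation` column.
#' @export
collapse_four_primer <- function(table) {
  tb <- as.data.table(table)
  if (uniqueN(tb$orientation) < 2L) {
    stop("collapse_four_primer expects a four-primer tally with both ",
         "amplicon orientations present", call. = FALSE)
  }
  coll <- tb[, .(read_count = sum(read_count), umi_count = sum(umi_count),
                 n_orientations = uniqueN(orientation)),
             by = .(barcode1, barcode2, site, replicate)]
  coll <- coll[n_orientations == 2L][, n_orientations := NULL]
  coll[]
}

#' Depth-normalize and replicate-average barcode-pair counts
#'
#' Counts are scaled to counts-per-million within each replicate, then
#' averaged across replicates; raw totals are preserved.
#'
#' @param table barcode-pair count table with a `replicate` column.
#' @return a `data.table` per (barcode1, barcode2, site) with `read_count`,
#'   `umi_count` (summed raw), `norm_reads`, `norm_umis` (mean CPM) and
#'   `n_replicates`.
#' @export
normalize_and_average <- function(table) {
  tb <- as.data.table(table)
  stopifnot(nrow(tb) > 0L)
  tb[, norm_reads := read_count / sum(read_count) * 1e6, by = replicate]
  tb[, norm_umis := umi_count / sum(umi_count) * 1e6, by = replicate]
  n_rep <- uniqueN(tb$replicate)
  out <- tb[, .(read_count = sum(read_count), umi_count = sum(umi_count),
                norm_reads = sum(norm_reads) / n_rep,
                norm_umis = sum(norm_umis) / n_rep,
                n_replicates = uniqueN(replicate)),
            by = .(barcode1, barcode2, site)]
  out[]
}

#' Detect novel (rearranged) barcode pairs
#'
#' A candidate rearranged pair has both barcodes in the bona fide parental
#' list (`barcode1` among parental CS2-side barcodes, `barcode2` among
#' CS1-side), a combination not present in the parental map, and at least
#' `min_umi` UMIs. Reciprocal pairs explained by a single recombination event
#' (the two novel combinations swapping the same two parents) are linked via
#' `reciprocal_group`.
#'
#' @param table barcode-pair count table (raw UMI counts are used for the
#'   threshold).
#' @param parental_map insertion table from [finalize_parental_map()].
#' @param min_umi minimum UMI support.
#' @param max_dist optional Levenshtein tolerance for matching barcodes to the
#'   parental list (0 = exact, the default).
#' @return candidate table with parent annotations.
#' @export
call_novel_pairs <- function(table, parental_map, min_umi = 2L, max_dist = 0L) {
  tb <- as.data.table(table)
  pm <- as.data.table(parental_map)
  if (!"umi_count" %in% names(tb)) stop("table must carry umi_count")

  match_bc <- function(q, ref) {
    i <- match(q, ref)
    if (max_dist > 0L) {
      todo <- which(is.na(i) & !is.na(q))
      for (j in todo) {
        d <- utils::adist(q[j], ref)
        k <- which(d <= max_dist)
        if (length(k) == 1L) i[j] <- k
      }
    }
    i
  }
  i1 <- match_bc(tb$barcode1, pm$barcode1)
  i2 <- match_bc(tb$barcode2, pm$barcode2)
  parental_combo <- !is.na(i1) & !is.na(i2) & i1 == i2
  cand <- tb[!is.na(i1) & !is.na(i2) & !parental_combo & umi_count >= min_umi]
  idx1 <- i1[!is.na(i1) & !is.na(i2) & !parental_combo & tb$umi_count >= min_umi]
  idx2 <- i2[!is.na(i1) & !is.na(i2) & !parental_combo & tb$umi_count >= min_umi]
  if (nrow(cand) == 0L) {
    cand[, `:=`(parent1 = integer(), parent2 = integer(),
                reciprocal_group = character())]
    return(cand[])
  }
  cand[, `:=`(parent1 = idx1, parent2 = idx2)]
  # reciprocal linkage: (X.bc1, Y.bc2) and (Y.bc1, X.bc2) share {X, Y}
  cand[, reciprocal_group := paste(pmin(parent1, parent2),
                                   pmax(parent1, parent2), sep = "_")]
  cand[]
}

#' Classify a rearranged barcode pair
#'
#' Deletions are rearranged pairs between same-chromosome cassettes inserted
#' in the same orientation; inversions the same in opposite orientation;
#' translocations involve different chromosomes. The size of a cis event is
#' the distance between the two parental insertion positions. Same-chromosome
#' pairs with discordant parental allele labels are still classified cis but
#' flagged (`allele_discordant`).
#'
#' @param pair one row of [call_novel_pairs()] output (needs `parent1`,
#'   `parent2`) or a list with `barcode1`, `barcode2`.
#' @param parental_map the parental insertion table.
#' @return a list of class `sv_call`: `class`, `size`, `chromA`, `posA`,
#'   `strandA`, `chromB`, `posB`, `strandB`, `allele_discordant`, `barcode1`,
#'   `barcode2`, parent row indices.
#' @export
classify_sv <- function(pair, parental_map) {
  pm <- as.data.table(parental_map)
  p <- as.list(pair)
  i1 <- p$parent1; i2 <- p$parent2
  if (is.null(i1) || is.null(i2) || is.na(i1) || is.na(i2)) {
    i1 <- match(p$barcode1, pm$barcode1)
    i2 <- match(p$barcode2, pm$barcode2)
  }
  if (is.na(i1) || is.na(i2)) {
    stop("both barcodes must resolve to parental insertions", call. = FALSE)
  }
  A <- as.list(pm[i1]); B <- as.list(pm[i2])
  cls <- if (A$chrom != B$chrom) "translocation"
    else if (A$strand == B$strand) "deletion" else "inversion"
  structure(list(
    class = cls,
    size = if (cls == "translocation") NA_integer_ else abs(A$pos - B$pos),
    chromA = A$chrom, posA = A$pos, strandA = A$strand, alleleA = A$allele,
    chromB = B$chrom, posB = B$pos, strandB = B$strand, alleleB = B$allele,
    allele_discordant = cls != "translocation" &&
      all(c(A$allele, B$allele) %in% c("BL6", "CAST")) && A$allele != B$allele,
    barcode1 = p$barcode1, barcode2 = p$barcode2,
    parent1 = i1, parent2 = i2
  ), class = "sv_call")
}

#' Label a deletion barcode pair as genomic scar or ecDNA
#'
#' For a deletion between upstream insertion X and downstream insertion Y in
#' top-CS2 orientation, the chromosomal scar carries (X.barcode1, Y.barcode2)
#' and the excised circle (Y.barcode1, X.barcode2); for bottom-CS1 pairs the
#' assignment is mirrored.
#'
#' @param pair a novel pair (with `parent1`/`parent2` or barcodes).
#' @param parental_map the parental insertion table.
#' @return `"scar"` or `"ecdna"`.
#' @export
label_deletion_products <- function(pair, parental_map) {
  sv <- if (inherits(pair, "sv_call")) pair else classify_sv(pair, parental_map)
  if (sv$class != "deletion") {
    stop("label_deletion_products applies to deletions only", call. = FALSE)
  }
  # parent1 contributed barcode1 (CS2 side), parent2 barcode2 (CS1 side)
  upstream_is_parent1 <- sv$posA <= sv$posB
  if (sv$strandA == "top_CS2") {
    if (upstream_is_parent1) "scar" else "ecdna"
  } else {
    if (upstream_is_parent1) "ecdna" else "scar"
  }
}

#' Classify a translocation as balanced, acentric or dicentric
#'
#' Each barcode of the pair marks the chromosome fragment retained with it on
#' the derivative chromosome: the fragment on the side of the junction that
#' the barcode's capture end faces. A barcode is centromere-proximal when that
#' fragment contains the centromere. Both proximal gives a dicentric product,
#' both distal an acentric one, mixed a balanced translocation.
#'
#' @param pair a novel pair or `sv_call`.
#' @param parental_map the parental insertion table.
#' @param centromere_table named vector or `data.table` (`chrom`, `pos`) of
#'   centromere positions.
#' @return `"balanced"`, `"acentric"` or `"dicentric"`.
#' @export
classify_translocation <- function(pair, parental_map, centromere_table) {
  sv <- if (inherits(pair, "sv_call")) pair else classify_sv(pair, parental_map)
  if (sv$class != "translocation") {
    stop("classify_translocation applies to translocations only", call. = FALSE)
  }
  cen <- centromere_positions(centromere_table)
  # barcode1 is a CS2-side barcode: a top_CS2 parent's CS2 end faces the
  # lower-coordinate side; barcode2 (CS1 side) faces the other way
  side1 <- if (sv$strandA == "top_CS2") "L" else "R"
  side2 <- if (sv$strandB == "top_CS2") "R" else "L"
  prox1 <- fragment_has_centromere(sv$chromA, sv$posA, side1, cen)
  prox2 <- fragment_has_centromere(sv$chromB, sv$posB, side2, cen)
  if (prox1 && prox2) "dicentric" else if (!prox1 && !prox2) "acentric"
    else "balanced"
}

centromere_positions <- function(centromere_table) {
  if (is.numeric(centromere_table) && !is.null(names(centromere_table))) {
    return(as.list(centromere_table))
  }
  ct <- as.data.table(centromere_table)
  stats::setNames(as.list(ct$pos), ct$chrom)
}

#' Does a cis event span the centromere?
#'
#' @param svcall an `sv_call` (cis classes only).
#' @param centromere_table centromere positions.
#' @return logical.
#' @export
classify_arm_spanning <- function(svcall, centromere_table) {
  if (svcall$class == "translocation") {
    stop("arm-spanning classification applies to cis events only",
         call. = FALSE)
  }
  cen <- centromere_positions(centromere_table)[[svcall$chromA]]
  min(svcall$posA, svcall$posB) < cen && cen < max(svcall$posA, svcall$posB)
}

#' Classify all novel pairs into SV calls
#'
#' Vectorised driver over [classify_sv()], [label_deletion_products()],
#' [classify_translocation()] and [classify_arm_spanning()].
#'
#' @param novel table from [call_novel_pairs()].
#' @param parental_map parental insertion table.
#' @param centromere_table optional centromere positions.
#' @return a `data.table` of SV calls, one row per novel pair.
#' @export
classify_all_svs <- function(novel, parental_map, centromere_table = NULL) {
  nv <- as.data.table(novel)
  out <- vector("list", nrow(nv))
  for (i in seq_len(nrow(nv))) {
    sv <- classify_sv(nv[i], parental_map)
    del_prod <- if (sv$class == "deletion")
      label_deletion_products(sv, parental_map) else NA_character_
    tsub <- if (sv$class == "translocation" && !is.null(centromere_table))
      classify_translocation(sv, parental_map, centromere_table) else
      NA_character_
    arm <- if (sv$class != "translocation" && !is.null(centromere_table))
      classify_arm_spanning(sv, centromere_table) else NA
    out[[i]] <- data.table(
      barcode1 = nv$barcode1[i], barcode2 = nv$barcode2[i],
      class = sv$class, size = sv$size,
      chromA = sv$chromA, posA = sv$posA, strandA = sv$strandA,
      chromB = sv$chromB, posB = sv$posB, strandB = sv$strandB,
      deletion_product = del_prod, translocation_subtype = tsub,
      arm_spanning = arm, allele_discordant = sv$allele_discordant,
      read_count = if ("read_count" %in% names(nv)) nv$read_count[i] else NA,
      umi_count = if ("umi_count" %in% names(nv)) nv$umi_count[i] else NA,
      reciprocal_group = if ("reciprocal_group" %in% names(nv))
        nv$reciprocal_group[i] else NA_character_
    )
  }
  rbindlist(out)
}

#' Validate SV calls against IVT-seq clusters
#'
#' An SV call is supported when at least one IVT cluster from the same sample
#' carries its novel barcode pair (as read or reverse-complemented, the two
#' transcripts of a junction read opposite strands) with a flank mapping
#' consistent with the inferred junction: the cluster position within
#' `tol` bp of either parental insertion position.
#'
#' @param svcalls table from [classify_all_svs()].
#' @param ivt_clusters cluster table from [cluster_alignments()] on the
#'   rearranged sample.
#' @param tol position tolerance (bp).
#' @return `svcalls` with a logical `supported_by_ivt` column.
#' @export
validate_with_ivt <- function(svcalls, ivt_clusters, tol = 10L) {
  sv <- copy(as.data.table(svcalls))
  cl <- as.data.table(ivt_clusters)
  sv[, supported_by_ivt := FALSE]
  if (nrow(cl) == 0L || nrow(sv) == 0L) return(sv[])
  for (i in seq_len(nrow(sv))) {
    b1 <- sv$barcode1[i]; b2 <- sv$barcode2[i]
    hit <- cl[(barcode1 == b1 & barcode2 == b2) |
                (barcode1 == revcomp(b1) & barcode2 == revcomp(b2))]
    if (nrow(hit) == 0L) next
    ok <- hit[(chrom == sv$chromA[i] & abs(position - sv$posA[i]) <= tol + 4L) |
                (chrom == sv$chromB[i] & abs(position - sv$posB[i]) <= tol + 4L)]
    sv[i, supported_by_ivt := nrow(ok) > 0L]
  }
  sv[]
}

#' Match reciprocal scar/ecDNA deletion calls
#'
#' Joins scar and ecDNA calls sharing the same parent pair and reports the
#' per-pair ecDNA/scar count ratio and the overall matched fraction.
#'
#' @param deletion_calls deletion rows from [classify_all_svs()] (needs
#'   `deletion_product`, `reciprocal_group` and a count column).
#' @param count_col column used for the stoichiometry ratio.
#' @return a list with `pairs` (`data.table`: one row per parent pair, scar
#'   and ecdna counts, `ratio` — `NA` when unmatched) and `fraction_matched`.
#' @export
match_reciprocal_pairs <- function(deletion_calls, count_col = "umi_count") {
  dl <- as.data.table(deletion_calls)[class == "deletion"]
  if (nrow(dl) == 0L) {
    return(list(pairs = data.table(), fraction_matched = NA_real_))
  }
  wide <- dcast(dl, reciprocal_group ~ deletion_product,
                value.var = count_col, fun.aggregate = sum, fill = NA)
  for (col in c("scar", "ecdna")) {
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  }
  wide[, ratio := as.numeric(ecdna) / as.numeric(scar)]
  wide[, matched := !is.na(ecdna) & !is.na(scar)]
  list(pairs = wide[], fraction_matched = mean(wide$matched))
}

# weighted median: smallest x with cumulative weight >= half the total
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Bootstrap comparison of read-count-weighted event sizes
#'
#' Compares the read-count-weighted median event size of two call sets by
#' resampling events with replacement (probability proportional to read
#' counts) for `iters` iterations; the two-sided p-value is derived from the
#' bootstrap distribution of the difference of weighted medians.
#'
#' @param callsA,callsB tables with `size` and a weight column.
#' @param iters bootstrap iterations.
#' @param weight_col weight column name.
#' @param seed optional seed.
#' @return list with `median_A`, `median_B`, `difference`, `p_value`,
#'   `boot_diffs`.
#' @export
weighted_size_bootstrap <- function(callsA, callsB, iters = 10000L,
                                    weight_col = "read_count", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- as.data.table(callsA); b <- as.data.table(callsB)
  xa <- a$size; wa <- a[[weight_col]]
  xb <- b$size; wb <- b[[weight_col]]
  stopifnot(length(xa) > 0L, length(xb) > 0L)
  obs <- weighted_median(xa, wa) - weighted_median(xb, wb)
  diffs <- numeric(iters)
  na <- length(xa); nb <- length(xb)
  pa <- wa / sum(wa); pb <- wb / sum(wb)
  for (i in seq_len(iters)) {
    sa <- xa[sample.int(na, na, replace = TRUE, prob = pa)]
    sb <- xb[sample.int(nb, nb, replace = TRUE, prob = pb)]
    diffs[i] <- stats::median(sa) - stats::median(sb)
  }
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  list(median_A = weighted_median(xa, wa), median_B = weighted_median(xb, wb),
       difference = obs, p_value = min(1, max(p, 1 / iters)),
       boot_diffs = diffs)
}

#' Genotype single-cell-sorted clone wells
#'
#' Wells with fewer than `min_reads` total reads are discarded. Within each
#' kept well, the well's barcode set is the barcode pairs whose read counts
#' exceed the well mean by more than one population standard deviation,
#' restricted to parental pairs; counts are then normalized by the observed
#' clone count per well.
#'
#' @param well_tables named list of per-well barcode-pair count tables
#'   (columns `barcode1`, `barcode2`, `read_count`).
#' @param parental_map parental insertion table (or `NULL` to skip the
#'   restriction).
#' @param clones_per_well optional named numeric vector of observed clone
#'   counts per well.
#' @param min_reads well read floor.
#' @param sd_mult standard-deviation multiplier for retention.
#' @return a `data.table` with one row per retained barcode pair per well.
#' @export
clone_well_genotyping <- function(well_tables, parental_map = NULL,
                                  clones_per_well = NULL, min_reads = 1e5,
                                  sd_mult = 1) {
  out <- vector("list", length(well_tables))
  for (w in names(well_tables)) {
    tb <- as.data.table(well_tables[[w]])
    if (sum(tb$read_count) < min_reads) next
    mu <- mean(tb$read_count)
    sdev <- sqrt(mean((tb$read_count - mu)^2))   # population SD (ddof = 0)
    keep <- tb[read_count > mu + sd_mult * sdev]
    if (!is.null(parental_map)) {
      pm <- as.data.table(parental_map)
      keep <- keep[paste(barcode1, barcode2) %in%
                     paste(pm$barcode1, pm$barcode2)]
    }
    if (nrow(keep) == 0L) next
    keep[, well := w]
    if (!is.null(clones_per_well) && w %in% names(clones_per_well)) {
      keep[, norm_count := read_count / clones_per_well[[w]]]
    } else {
      keep[, norm_count := NA_real_]
    }
    out[[w]] <- keep
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(barcode1 = character(), barcode2 = character(),
                      read_count = numeric(), well = character(),
                      norm_count = numeric()))
  }
  res[]
}
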