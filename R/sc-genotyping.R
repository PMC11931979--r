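# Single-cell T7 readout processing: chimera-filtered, Hamming-collapsed
# count-matrix construction, cell QC, barnyard species calls, de novo
# clonotype reconstruction, precision/recall cell assignment and per-cell
# rearrangement calls.

#' Build the corrected T7 barcode count matrix
#'
#' Per cell: (1) UMIs whose reads are split across several barcode
#' combinations are de-chimerised — the assignments holding less than
#' `chimera_floor` of that UMI's reads in the cell are discarded; (2) UMIs of
#' one (barcode1, barcode2, capture) combination are collapsed to the number
#' of connected components of the Hamming-distance <= 1 graph; (3) entries
#' with reads per corrected UMI below `reads_per_umi_floor` are removed.
#'
#' @param records record table (columns `cell`, `umi`, `barcode1`, `barcode2`,
#'   `capture`, `site`, `reads`; one row per (cell, umi, combination)).
#' @param cell_whitelist optional cells to keep.
#' @param reads_per_umi_floor minimum reads per corrected UMI per entry.
#' @param chimera_floor minimum read fraction of a UMI's reads in its cell.
#' @return an object of class `t7_matrix`: list with `entries` (`data.table`:
#'   cell, barcode1, barcode2, capture, site, umis, reads) and `qc` counts.
#' @export
build_t7_matrix <- function(records, cell_whitelist = NULL,
                            reads_per_umi_floor = 1, chimera_floor = 0.2) {
  rec <- as.data.table(records)
  need <- c("cell", "umi", "barcode1", "barcode2", "capture", "reads")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (!"site" %in% names(rec)) rec[, site := NA_character_]
  n_in <- nrow(rec)
  rec <- rec[!is.na(barcode1) & !is.na(barcode2)]
  n_noextract <- n_in - nrow(rec)
  if (!is.null(cell_whitelist)) rec <- rec[cell %in% cell_whitelist]

  # collapse duplicate rows of the same (cell, umi, combination)
  rec <- rec[, .(reads = sum(reads)),
             by = .(cell, umi, barcode1, barcode2, capture, site)]

  # chimeric-UMI filter: fraction of the UMI's reads in this cell
  rec[, umi_total := sum(reads), by = .(cell, umi)]
  n_chim <- sum(rec$reads / rec$umi_total < chimera_floor)
  rec <- rec[reads / umi_total >= chimera_floor][, umi_total := NULL]

  # Hamming <= 1 UMI collapse per entry
  entries <- rec[, .(umis = hamming_components(umi), reads = sum(reads)),
                 by = .(cell, barcode1, barcode2, capture, site)]
  entries <- entries[reads / umis >= reads_per_umi_floor]

  structure(list(entries = entries[],
                 qc = list(input_rows = n_in, unextractable = n_noextract,
                           chimeric_umi_assignments = n_chim)),
            class = "t7_matrix")
}

#' Number of Hamming-distance <= 1 connected components
#'
#' @param umis character vector of equal-length UMI sequences.
#' @return integer component count.
#' @export
hamming_components <- function(umis) {
  umis <- unique(umis)
  n <- length(umis)
  if (n == 1L) return(1L)
  m <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <- sum(m[i, ] != m[j, ]) <= 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$no)
}

#' @export
print.t7_matrix <- function(x, ...) {
  cat(sprintf("<t7_matrix> %d entries, %d cells, %d barcode pairs\n",
              nrow(x$entries), uniqueN(x$entries$cell),
              uniqueN(paste(x$entries$barcode1, x$entries$barcode2))))
  invisible(x)
}

# sum capture orientations; key each pair by its CS1-side barcode when asked
t7_pair_umis <- function(t7, cs1_only = FALSE, min_umi = 1L) {
  e <- t7$entries[, .(umis = sum(umis), reads = sum(reads)),
                  by = .(cell, barcode1, barcode2)]
  e <- e[umis >= min_umi]
  if (cs1_only) e[, feature := barcode2] else
    e[, feature := paste(barcode1, barcode2, sep = "|")]
  e[]
}

#' Quality-filter cells
#'
#' Boolean mask from per-species windows on transcriptome UMIs and
#' mitochondrial fraction, plus a strict doublet-score ceiling.
#'
#' @param metadata per-cell table (columns `cell`, `transcriptome_umis`,
#'   `mito_frac`, `doublet_score`, optional `species`).
#' @param min_umis minimum transcriptome UMIs (named by species or scalar).
#' @param mito_range mitochondrial-fraction window (list named by species or a
#'   length-2 vector).
#' @param max_doublet_score retained iff doublet score is strictly below.
#' @return character vector of retained cell ids.
#' @export
qc_cells <- function(metadata, min_umis = c(K562 = 1500, mESC = 1000),
                     mito_range = list(K562 = c(0.02, 0.08),
                                       mESC = c(0.013, 0.06)),
                     max_doublet_score = 0.4) {
  md <- as.data.table(metadata)
  if (!"species" %in% names(md)) md[, species := NA_character_]
  get_min <- function(sp) {
    if (length(min_umis) == 1L && is.null(names(min_umis))) return(min_umis)
    if (!is.na(sp) && sp %in% names(min_umis)) min_umis[[sp]] else min(min_umis)
  }
  get_rng <- function(sp) {
    if (is.numeric(mito_range)) return(mito_range)
    if (!is.na(sp) && sp %in% names(mito_range)) mito_range[[sp]] else
      mito_range[[1L]]
  }
  keep <- vapply(seq_len(nrow(md)), function(i) {
    sp <- md$species[i]
    rng <- get_rng(sp)
    md$transcriptome_umis[i] > get_min(sp) &&
      md$mito_frac[i] >= rng[1] && md$mito_frac[i] <= rng[2] &&
      md$doublet_score[i] < max_doublet_score
  }, logical(1))
  md$cell[keep]
}

#' Barnyard species call per cell
#'
#' Calls each cell for the dominant species unless the transcriptome UMI
#' ratios are not sufficiently separated, in which case the cell is a doublet:
#' a mouse-dominant cell with mouse/human ratio below `ratio_a` or a
#' human-dominant cell with human/mouse ratio below `ratio_b` is flagged.
#'
#' @param umis_a,umis_b per-cell transcriptome UMI counts for species A
#'   (e.g. mouse) and species B (e.g. human).
#' @param ratio_a minimum A/B ratio for an A singlet.
#' @param ratio_b minimum B/A ratio for a B singlet.
#' @param labels species labels.
#' @return character vector: one of `labels` or `"doublet"` per cell.
#' @export
barnyard_species_call <- function(umis_a, umis_b, ratio_a = 1.42, ratio_b = 3,
                                  labels = c("speciesA", "speciesB")) {
  stopifnot(length(umis_a) == length(umis_b))
  vapply(seq_along(umis_a), function(i) {
    a <- umis_a[i]; b <- umis_b[i]
    if (a >= b) {
      if (b == 0 || a / b >= ratio_a) labels[1] else "doublet"
    } else {
      if (a == 0 || b / a >= ratio_b) labels[2] else "doublet"
    }
  }, character(1))
}

# rank-ordered detection fractions -> clonotype member set.
# Two stopping rules give candidate cuts: the first rank whose fold-change to
# the next fraction exceeds fc_thresh, and the first rank whose next fraction
# falls below abs_thresh. A rule that never fires abstains; when both fire,
# the larger resulting barcode set is taken; when neither fires the whole
# list is kept.
inflection_cut <- function(fracs, fc_thresh = 2, abs_thresh = 0.075) {
  n <- length(fracs)
  if (n == 1L) return(1L)
  fc_cut <- abs_cut <- NA_integer_
  for (r in seq_len(n - 1L)) {
    if (fracs[r + 1L] <= 0 || fracs[r] / fracs[r + 1L] > fc_thresh) {
      fc_cut <- r; break
    }
  }
  for (r in seq_len(n - 1L)) {
    if (fracs[r + 1L] < abs_thresh) { abs_cut <- r; break }
  }
  if (is.na(fc_cut) && is.na(abs_cut)) return(n)
  max(fc_cut, abs_cut, na.rm = TRUE)
}

#' De novo clonotype identification
#'
#' Reconstructs clonotypes (the set of barcode pairs carried by one founding
#' clone) from co-detection in single cells. Only the CS1-side barcode keys a
#' pair, so rearranged cassettes do not split clones. Steps: (1) keep pair
#' detections with >= `min_umi_per_pair` UMIs per cell, cells with >=
#' `min_cell_umis` total UMIs and pairs with >= `min_pair_umis` UMIs overall;
#' (2) relative-count normalization (scale 1e4), PCA (<= `n_pcs` components),
#' exact k-nearest-neighbour graph (k = `k_param`), Louvain communities at
#' `resolution`; (3) per community, rank pair detection fractions and cut at
#' the inflection ([inflection_cut()]); (4) keep clonotypes with top detection
#' fraction > `min_top_fraction` and > 1 member pairs; (5) merge clonotypes
#' with Jaccard index > `jaccard_merge` (graph components, union of members);
#' (6) optionally iterate after removing assignable cells, and optionally
#' exclude dominant clones first.
#'
#' @param t7 a [build_t7_matrix()] result.
#' @param cells optional cell whitelist (QC-passing cells).
#' @param min_umi_per_pair,min_cell_umis,min_pair_umis signal filters.
#' @param k_param,resolution,n_pcs graph-clustering parameters.
#' @param fc_thresh,abs_thresh inflection-cut parameters.
#' @param min_top_fraction clonotype QC floor on the top detection fraction.
#' @param jaccard_merge Jaccard threshold for merging redundant clonotypes.
#' @param iterate number of discovery rounds (assignable cells are removed
#'   between rounds).
#' @param exclude_dominant integer; when > 0, the largest `exclude_dominant`
#'   first-pass clonotypes are set aside, discovery is re-run without their
#'   cells and barcodes, and they are added back afterwards.
#' @param seed seed for the community detection.
#' @return a `data.table` of clonotypes: `clonotype`, `members` (list of
#'   CS1 barcodes), `n_pairs`, `top_fraction`, `n_cells`, `round`.
#' @export
identify_clonotypes <- function(t7, cells = NULL,
                                min_umi_per_pair = 3L, min_cell_umis = 11L,
                                min_pair_umis = 11L, k_param = 10L,
                                resolution = 1, n_pcs = 100L,
                                fc_thresh = 2, abs_thresh = 0.075,
                                min_top_fraction = 0.45, jaccard_merge = 0.5,
                                iterate = 1L, exclude_dominant = 0L,
                                seed = 1L) {
  e <- t7_pair_umis(t7, cs1_only = TRUE)
  if (!is.null(cells)) e <- e[cell %in% cells]
  e <- e[umis >= min_umi_per_pair]
  empty <- data.table(clonotype = character(), members = list(),
                      n_pairs = integer(), top_fraction = numeric(),
                      n_cells = integer(), round = integer())

  discover <- function(e, round_id) {
    e <- copy(e)
    e[, cell_total := sum(umis), by = cell]
    e <- e[cell_total >= min_cell_umis][, cell_total := NULL]
    if (nrow(e) == 0L) return(empty)
    e[, pair_total := sum(umis), by = feature]
    e <- e[pair_total >= min_pair_umis][, pair_total := NULL]
    if (nrow(e) == 0L || uniqueN(e$cell) < k_param + 1L) return(empty)

    cells_u <- sort(unique(e$cell)); feats_u <- sort(unique(e$feature))
    m <- Matrix::sparseMatrix(i = match(e$cell, cells_u),
                              j = match(e$feature, feats_u),
                              x = e$umis,
                              dims = c(length(cells_u), length(feats_u)),
                              dimnames = list(cells_u, feats_u))
    # relative counts at scale 1e4, log1p, PCA
    rc <- m / Matrix::rowSums(m) * 1e4
    x <- log1p(as.matrix(rc))
    npc <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
    pc <- stats::prcomp(x, rank. = npc, center = TRUE, scale. = FALSE)$x
    # exact kNN graph
    d <- as.matrix(stats::dist(pc))
    diag(d) <- Inf
    k <- min(k_param, nrow(d) - 1L)
    nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
    edges <- cbind(rep(seq_len(nrow(nn)), k), as.vector(nn))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- igraph::membership(comm)

    det <- as.matrix(m > 0)
    clones <- list()
    for (cm in sort(unique(memb))) {
      idx <- which(memb == cm)
      if (length(idx) < 2L) next
      fr <- colMeans(det[idx, , drop = FALSE])
      fr <- sort(fr[fr > 0], decreasing = TRUE)
      if (length(fr) == 0L) next
      cut <- inflection_cut(unname(fr), fc_thresh, abs_thresh)
      members <- names(fr)[seq_len(cut)]
      if (length(members) < 2L) next            # >1 pairs required
      if (fr[1L] <= min_top_fraction) next
      clones[[length(clones) + 1L]] <- data.table(
        clonotype = sprintf("r%d_c%02d", round_id, cm),
        members = list(sort(members)), n_pairs = length(members),
        top_fraction = unname(fr[1L]), n_cells = length(idx),
        round = round_id)
    }
    if (length(clones) == 0L) return(empty)
    res <- rbindlist(clones)
    merge_jaccard(res, jaccard_merge)
  }

  run_rounds <- function(e) {
    found <- empty
    remaining <- copy(e)
    for (r in seq_len(max(1L, iterate))) {
      cl <- discover(remaining, r)
      if (nrow(cl) == 0L) break
      found <- rbindlist(list(found, cl))
      if (r == iterate) break
      asg <- assign_cells_to_clonotypes(t7, found,
                                        cells = unique(remaining$cell))
      assigned <- asg[!is.na(clonotype)]$cell
      remaining <- remaining[!cell %in% assigned]
      if (nrow(remaining) == 0L) break
    }
    found
  }

  if (exclude_dominant > 0L) {
    first <- discover(e, 0L)
    if (nrow(first) > exclude_dominant) {
      setorder(first, -n_cells)
      big <- first[seq_len(exclude_dominant)]
      big_bcs <- unique(unlist(big$members))
      asg <- assign_cells_to_clonotypes(t7, big, cells = unique(e$cell))
      big_cells <- asg[!is.na(clonotype)]$cell
      rest <- run_rounds(e[!cell %in% big_cells & !feature %in% big_bcs])
      out <- rbindlist(list(big, rest))
      return(merge_jaccard(out, jaccard_merge))
    }
  }
  run_rounds(e)
}

# merge clonotypes whose member sets overlap at Jaccard > threshold
merge_jaccard <- function(clones, threshold = 0.5) {
  n <- nrow(clones)
  if (n <= 1L) return(clones)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- clones$members[[i]]; b <- clones$members[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      adj[i, j] <- adj[j, i] <- jac > threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  grp <- igraph::components(g)$membership
  out <- lapply(sort(unique(grp)), function(k) {
    idx <- which(grp == k)
    data.table(clonotype = clones$clonotype[idx[1L]],
               members = list(sort(unique(unlist(clones$members[idx])))),
               n_pairs = length(unique(unlist(clones$members[idx]))),
               top_fraction = max(clones$top_fraction[idx]),
               n_cells = sum(clones$n_cells[idx]),
               round = min(clones$round[idx]))
  })
  rbindlist(out)
}

#' Assign cells to clonotypes
#'
#' Per cell, the detected set is its CS1-side barcodes at >= `min_umi` UMIs
#' (capture orientations summed). For the best clonotype, precision is the
#' fraction of detected barcodes belonging to it and recall the fraction of
#' its members detected. Cells pass when `top_precision > precision_floor` and
#' `top_recall > recall_floor`; cells whose second-best clonotype still shows
#' recall > `doublet_recall` are removed as putative doublets.
#'
#' @param t7 a [build_t7_matrix()] result.
#' @param clonotypes table from [identify_clonotypes()].
#' @param cells optional cell whitelist.
#' @param min_umi UMI floor per pair per cell.
#' @param precision_floor,recall_floor,doublet_recall thresholds.
#' @param exclude_members optional barcodes excluded from cells' detected sets
#'   (dominant-clone remedy for ambient contamination).
#' @return a `data.table`: `cell`, `clonotype` (`NA` when unassigned),
#'   `reason` (`assigned`, `low_capture`, `low_purity`, `doublet`,
#'   `no_signal`), `top_precision`, `top_recall`, `second_recall`.
#' @export
assign_cells_to_clonotypes <- function(t7, clonotypes, cells = NULL,
                                       min_umi = 2L, precision_floor = 0.75,
                                       recall_floor = 0.1,
                                       doublet_recall = 0.1,
                                       exclude_members = NULL) {
  e <- t7_pair_umis(t7, cs1_only = TRUE, min_umi = min_umi)
  if (!is.null(cells)) e <- e[cell %in% cells]
  if (!is.null(exclude_members)) e <- e[!feature %in% exclude_members]
  det <- split(e$feature, e$cell)
  cl_members <- clonotypes$members
  names(cl_members) <- clonotypes$clonotype
  if (length(cl_members) == 0L) {
    return(data.table(cell = names(det), clonotype = NA_character_,
                      reason = "no_signal", top_precision = NA_real_,
                      top_recall = NA_real_, second_recall = NA_real_))
  }

  out <- vector("list", length(det))
  for (i in seq_along(det)) {
    cell_id <- names(det)[i]
    bcs <- unique(det[[i]])
    prec <- vapply(cl_members, function(m)
      length(intersect(bcs, m)) / length(bcs), numeric(1))
    rec <- vapply(cl_members, function(m)
      length(intersect(bcs, m)) / length(m), numeric(1))
    o <- order(-prec, -rec, names(cl_members))
    top <- o[1L]
    second_rec <- if (length(o) > 1L) max(rec[o[-1L]]) else 0
    reason <- if (rec[top] <= recall_floor) "low_capture"
      else if (prec[top] <= precision_floor) "low_purity"
      else if (second_rec > doublet_recall) "doublet"
      else "assigned"
    out[[i]] <- data.table(
      cell = cell_id,
      clonotype = if (reason == "assigned") names(cl_members)[top] else
        NA_character_,
      reason = reason,
      top_precision = unname(prec[top]), top_recall = unname(rec[top]),
      second_recall = unname(second_rec))
  }
  res <- rbindlist(out)
  if (!is.null(cells)) {
    missing <- setdiff(cells, res$cell)
    if (length(missing)) {
      res <- rbindlist(list(res, data.table(
        cell = missing, clonotype = NA_character_, reason = "no_signal",
        top_precision = NA_real_, top_recall = NA_real_,
        second_recall = NA_real_)))
    }
  }
  res[]
}

#' Precision/recall over a UMI-threshold grid
#'
#' For each UMI threshold, recomputes each assigned cell's detected barcode
#' set and reports mean precision and recall against its assigned clonotype.
#'
#' @param t7 a [build_t7_matrix()] result.
#' @param clonotypes clonotype table.
#' @param assignments result of [assign_cells_to_clonotypes()].
#' @param umi_grid integer thresholds to scan.
#' @return a `data.table`: `umi_threshold`, `mean_precision`, `mean_recall`,
#'   `n_cells` (precision is `NA` when no cell retains any barcode).
#' @export
threshold_precision_recall <- function(t7, clonotypes, assignments,
                                       umi_grid = 1:10) {
  asg <- as.data.table(assignments)[!is.na(clonotype)]
  cl_members <- clonotypes$members
  names(cl_members) <- clonotypes$clonotype
  pairs <- t7_pair_umis(t7, cs1_only = TRUE)
  out <- vector("list", length(umi_grid))
  for (k in seq_along(umi_grid)) {
    thr <- umi_grid[k]
    e <- pairs[umis >= thr & cell %in% asg$cell]
    det <- split(e$feature, e$cell)
    pr <- re <- numeric(0)
    for (i in seq_len(nrow(asg))) {
      bcs <- unique(det[[asg$cell[i]]])
      m <- cl_members[[asg$clonotype[i]]]
      if (is.null(bcs) || length(bcs) == 0L) { re <- c(re, 0); next }
      pr <- c(pr, length(intersect(bcs, m)) / length(bcs))
      re <- c(re, length(intersect(bcs, m)) / length(m))
    }
    out[[k]] <- data.table(
      umi_threshold = thr,
      mean_precision = if (length(pr)) mean(pr) else NA_real_,
      mean_recall = if (length(re)) mean(re) else NA_real_,
      n_cells = length(pr))
  }
  rbindlist(out)
}

#' Call rearrangements per cell
#'
#' Novel barcode pairs per cell at >= `min_umi` UMIs (capture orientations
#' summed), annotated for congruence with the cell's assigned clonotype: both
#' parents' pairs in the clonotype (`congruent`), one in it (`partial`), or
#' none/other (`incongruent`). Classification is delegated to [classify_sv()]
#' via [classify_all_svs()].
#'
#' @param t7 a [build_t7_matrix()] result.
#' @param parental_map the parental insertion table.
#' @param assignments result of [assign_cells_to_clonotypes()].
#' @param clonotypes clonotype table (CS1-barcode member sets).
#' @param min_umi UMI floor.
#' @param centromere_table optional centromeres for subclassification.
#' @return a `data.table` of per-cell SV calls with a `congruence` column.
#' @export
call_cell_rearrangements <- function(t7, parental_map, assignments,
                                     clonotypes, min_umi = 2L,
                                     centromere_table = NULL) {
  pm <- as.data.table(parental_map)
  asg <- as.data.table(assignments)[!is.na(clonotype)]
  e <- t7$entries[, .(umis = sum(umis), reads = sum(reads)),
                  by = .(cell, barcode1, barcode2)]
  e <- e[umis >= min_umi & cell %in% asg$cell]
  e[, umi_count := umis][, read_count := reads]
  novel <- call_novel_pairs(e, pm, min_umi = min_umi)
  if (nrow(novel) == 0L) {
    return(data.table(cell = character(), barcode1 = character(),
                      barcode2 = character(), class = character(),
                      congruence = character()))
  }
  svs <- classify_all_svs(novel, pm, centromere_table)
  svs[, cell := novel$cell]
  cl_members <- clonotypes$members
  names(cl_members) <- clonotypes$clonotype
  asg_map <- stats::setNames(asg$clonotype, asg$cell)
  svs[, congruence := NA_character_]
  # congruence: the CS1-side barcodes of the two parental cassettes must
  # belong to the cell's clonotype member set
  for (i in seq_len(nrow(svs))) {
    members <- cl_members[[asg_map[[svs$cell[i]]]]]
    par1_cs1 <- pm$barcode2[novel$parent1[i]]
    par2_cs1 <- pm$barcode2[novel$parent2[i]]
    n_in <- sum(c(par1_cs1, par2_cs1) %in% members)
    svs[i, congruence := c("incongruent", "partial", "congruent")[n_in + 1L]]
  }
  svs[]
}
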