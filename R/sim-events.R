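# Expansion of clones into cells, recombinase action under a distance-decay
# rate model, and multi-generation selection.

# Convert parental cassette rows into the internal per-cell cassette schema.
# Each cassette row carries its two ends explicitly (barcode + capture), plus
# per-end genomic flank descriptors used by the IVT read emitter:
# (f*_chrom, f*_pos, f*_side, f*_allele) where side "L" means the end faces the
# lower-coordinate flank (reads exiting it align on the + strand ending at the
# TTAA) and "R" the higher-coordinate flank (- strand starting at the TTAA).
as_cassette_rows <- function(cassettes, cell = cassettes$clone) {
  x <- as.data.table(cassettes)
  top <- x$strand == "top_CS2"
  data.table(
    cell = cell, clone = x$clone, cassette_id = x$cassette_id,
    origin = "parental", event_id = NA_character_,
    barcode_left = x$barcode1, capture_left = "CS2",
    barcode_right = x$barcode2, capture_right = "CS1",
    site = x$site, chrom = x$chrom, pos = x$pos, strand = x$strand,
    allele = x$allele,
    fl_chrom = x$chrom, fl_pos = x$pos, fl_side = fifelse(top, "L", "R"),
    fl_allele = x$allele,
    fr_chrom = x$chrom, fr_pos = x$pos, fr_side = fifelse(top, "R", "L"),
    fr_allele = x$allele
  )
}

# End descriptors of a parental cassette row, as a list of two ends.
row_ends <- function(row) {
  list(
    left = list(barcode = row$barcode_left, capture = row$capture_left,
                chrom = row$fl_chrom, pos = row$fl_pos, side = row$fl_side,
                allele = row$fl_allele),
    right = list(barcode = row$barcode_right, capture = row$capture_right,
                 chrom = row$fr_chrom, pos = row$fr_pos, side = row$fr_side,
                 allele = row$fr_allele)
  )
}

product_row_from_ends <- function(end_l, end_r, site, origin, event_id,
                                  cell, clone, chrom = NA_character_,
                                  pos = NA_integer_) {
  data.table(
    cell = cell, clone = clone, cassette_id = paste0(event_id, "_", origin),
    origin = origin, event_id = event_id,
    barcode_left = end_l$barcode, capture_left = end_l$capture,
    barcode_right = end_r$barcode, capture_right = end_r$capture,
    site = site, chrom = chrom, pos = pos, strand = NA_character_,
    allele = NA_character_,
    fl_chrom = end_l$chrom, fl_pos = end_l$pos, fl_side = end_l$side,
    fl_allele = end_l$allele,
    fr_chrom = end_r$chrom, fr_pos = end_r$pos, fr_side = end_r$side,
    fr_allele = end_r$allele
  )
}

# A genomic fragment retained with an end facing `side` at `pos` contains the
# centromere iff the centromere lies on that side of the junction.
fragment_has_centromere <- function(chrom, pos, side, centromeres) {
  cen <- centromeres[[chrom]]
  if (side == "L") cen < pos else cen > pos
}

#' Induce recombination events in a clone population
#'
#' Expands each clone into `cfg$cells_per_clone` cells; each cell acquires one
#' recombination event with probability `cfg$event_prob`. The recombining pair
#' is drawn among the clone's compatible cassette pairs with weight
#' `exp(-d / distance_rate_scale)` for intra-chromosomal pairs (d = coordinate
#' distance) and the flat `trans_rate` for inter-chromosomal pairs. Cre picks
#' one of the two symmetric loxPsym alignment modes uniformly; Bxb1 pairs must
#' be attB x attP and recombine in the directional mode. Parent cassettes are
#' replaced by the two product cassettes in the cell.
#'
#' @param clones parental cassette table from [integrate_cassettes()].
#' @param cfg a [sim_config()].
#' @param genome optional [simulate_genome()] result; when given, translocation
#'   products are labelled balanced/acentric/dicentric and deletions spanning
#'   the centromere are flagged in the truth table.
#' @return an object of class `shuffle_cells`: list with `cassettes` (one row
#'   per cassette instance per cell), `cells` (cell metadata) and `truth`
#'   (list with `clones` and `events`).
#' @export
induce_rearrangements <- function(clones, cfg, genome = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "events"))
  clones <- as.data.table(clones)
  centromeres <- if (!is.null(genome)) genome$centromeres else NULL

  clone_ids <- unique(clones$clone)
  cass_rows <- vector("list", length(clone_ids) * cfg$cells_per_clone)
  cells_meta <- vector("list", length(cass_rows))
  events <- list()
  ridx <- 0L

  for (cl in clone_ids) {
    cl_cas <- clones[clone == cl]
    base_rows <- as_cassette_rows(cl_cas, cell = NA_character_)
    # candidate pair weights (clone-level, reused across cells)
    n <- nrow(cl_cas)
    pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(0), ncol = 2)
    if (nrow(pairs) > 0L) {
      same_chr <- cl_cas$chrom[pairs[, 1]] == cl_cas$chrom[pairs[, 2]]
      d <- abs(cl_cas$pos[pairs[, 1]] - cl_cas$pos[pairs[, 2]])
      w <- ifelse(same_chr,
                  if (cfg$distance_rate_scale > 0)
                    exp(-d / cfg$distance_rate_scale) else 0,
                  cfg$trans_rate)
      if (cfg$recombinase == "Bxb1") {
        compat <- (cl_cas$site[pairs[, 1]] != cl_cas$site[pairs[, 2]])
        w <- w * compat
      }
    } else w <- numeric(0)

    for (i in seq_len(cfg$cells_per_clone)) {
      ridx <- ridx + 1L
      cell_id <- sprintf("%s_cell%03d", cl, i)
      rows <- copy(base_rows)[, cell := cell_id]
      ev_id <- NA_character_
      if (length(w) > 0L && sum(w) > 0 &&
          stats::runif(1) < cfg$event_prob) {
        k <- sample.int(nrow(pairs), 1L, prob = w)
        ia <- pairs[k, 1L]; ib <- pairs[k, 2L]
        mode <- if (cfg$recombinase == "Cre")
          sample(c("parallel", "antiparallel"), 1L) else "parallel"
        rp <- recombine_pair(as.list(cl_cas[ia]), as.list(cl_cas[ib]),
                             cfg$recombinase, mode)
        ev_id <- sprintf("ev_%s_%03d", cl, i)
        a <- rp$left_parent; b <- rp$right_parent
        ra <- rows[cassette_id == a$cassette_id]
        rb <- rows[cassette_id == b$cassette_id]
        ea <- row_ends(as.list(ra)); eb <- row_ends(as.list(rb))

        if (rp$mode == "parallel") {
          p1 <- product_row_from_ends(ea$left, eb$right, rp$products$site[1],
                                      rp$products$role[1], ev_id, cell_id, cl)
          p2 <- product_row_from_ends(eb$left, ea$right, rp$products$site[2],
                                      rp$products$role[2], ev_id, cell_id, cl)
        } else {
          p1 <- product_row_from_ends(ea$left, eb$left, rp$products$site[1],
                                      rp$products$role[1], ev_id, cell_id, cl)
          p2 <- product_row_from_ends(ea$right, eb$right, rp$products$site[2],
                                      rp$products$role[2], ev_id, cell_id, cl)
        }
        # genomic placement: scar / junction products stay on the chromosome
        for (p in list(p1, p2)) {
          if (p$origin[1] %in% c("scar", "junction1", "der1")) {
            p[, `:=`(chrom = a$chrom, pos = a$pos)]
          } else if (p$origin[1] %in% c("junction2", "der2")) {
            p[, `:=`(chrom = b$chrom, pos = b$pos)]
          }
        }

        subtype <- NA_character_
        spans_cen <- NA
        if (!is.null(centromeres)) {
          if (rp$event_class == "translocation") {
            lab <- vapply(list(p1, p2), function(p) {
              ncen <- fragment_has_centromere(p$fl_chrom, p$fl_pos, p$fl_side,
                                              centromeres) +
                fragment_has_centromere(p$fr_chrom, p$fr_pos, p$fr_side,
                                        centromeres)
              c("acentric", "balanced", "dicentric")[ncen + 1L]
            }, character(1))
            p1[, subtype := lab[1]]; p2[, subtype := lab[2]]
            subtype <- if (all(lab == "balanced")) "balanced" else "unbalanced"
          } else if (rp$event_class == "deletion") {
            cen <- centromeres[[a$chrom]]
            spans_cen <- min(a$pos, b$pos) < cen && cen < max(a$pos, b$pos)
          }
        }
        if (!"subtype" %in% names(p1)) p1[, subtype := NA_character_]
        if (!"subtype" %in% names(p2)) p2[, subtype := NA_character_]

        rows <- rows[!cassette_id %in% c(a$cassette_id, b$cassette_id)]
        rows[, subtype := NA_character_]
        rows <- rbindlist(list(rows, p1, p2), use.names = TRUE)

        events[[length(events) + 1L]] <- data.table(
          event_id = ev_id, cell = cell_id, clone = cl,
          recombinase = cfg$recombinase, mode = rp$mode,
          class = rp$event_class, ecdna_created = rp$ecdna_created,
          chromA = a$chrom, posA = a$pos, strandA = a$strand, idA = a$cassette_id,
          chromB = b$chrom, posB = b$pos, strandB = b$strand, idB = b$cassette_id,
          size = if (rp$event_class == "translocation") NA_integer_
                 else abs(b$pos - a$pos),
          subtype = subtype, spans_centromere = spans_cen,
          bc_left1 = rp$products$barcode_left[1],
          bc_right1 = rp$products$barcode_right[1],
          role1 = rp$products$role[1],
          bc_left2 = rp$products$barcode_left[2],
          bc_right2 = rp$products$barcode_right[2],
          role2 = rp$products$role[2]
        )
      } else {
        rows[, subtype := NA_character_]
      }
      cass_rows[[ridx]] <- rows
      cells_meta[[ridx]] <- data.table(cell = cell_id, clone = cl,
                                       event_id = ev_id)
    }
  }

  structure(list(
    cassettes = rbindlist(cass_rows, use.names = TRUE),
    cells = rbindlist(cells_meta),
    truth = list(clones = clones,
                 events = if (length(events)) rbindlist(events) else
                   data.table())
  ), class = "shuffle_cells")
}

#' @export
print.shuffle_cells <- function(x, ...) {
  cat(sprintf("<shuffle_cells> %d cells, %d cassette instances, %d events\n",
              nrow(x$cells), nrow(x$cassettes), nrow(x$truth$events)))
  invisible(x)
}

#' Apply multi-generation selection to a cell population
#'
#' Cell-level: each cell survives one generation with probability equal to the
#' product of its event-class weights (`deletion` — multiplied by
#' `centromere_deletion` when the deletion spans the centromere —,
#' `inversion`, `balanced`). Product-level: chromosome fragments from
#' unbalanced translocations are retained per generation with the `acentric` /
#' `dicentric` weights independently of cell survival, so the two reciprocal
#' products of one event deplete at their own geometric rates.
#'
#' @param cells a `shuffle_cells` object.
#' @param cfg the [sim_config()] (uses `selection_weights`, `generations`).
#' @param generations override for `cfg$generations`.
#' @return a filtered `shuffle_cells` object.
#' @export
apply_selection <- function(cells, cfg, generations = cfg$generations) {
  stopifnot(inherits(cells, "shuffle_cells"))
  set.seed(stage_seed(cfg, "selection"))
  w <- cfg$selection_weights
  ev <- cells$truth$events
  cas <- copy(cells$cassettes)
  meta <- copy(cells$cells)

  cell_fit <- rep(1, nrow(meta))
  names(cell_fit) <- meta$cell
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i]
      f <- switch(e$class,
        deletion = w[["deletion"]] *
          (if (isTRUE(e$spans_centromere)) w[["centromere_deletion"]] else 1),
        inversion = w[["inversion"]],
        translocation = if (identical(e$subtype, "balanced"))
          w[["balanced"]] else 1,
        1)
      cell_fit[e$cell] <- cell_fit[e$cell] * f
    }
  }
  surv_prob <- cell_fit ^ generations
  keep_cell <- stats::runif(length(surv_prob)) < surv_prob
  kept <- names(surv_prob)[keep_cell]
  meta <- meta[cell %in% kept]
  cas <- cas[cell %in% kept]

  # per-product retention of unbalanced translocation fragments
  if ("subtype" %in% names(cas)) {
    is_unbal <- !is.na(cas$subtype) & cas$subtype %in% c("acentric", "dicentric")
    if (any(is_unbal)) {
      pw <- ifelse(cas$subtype[is_unbal] == "acentric",
                   w[["acentric"]], w[["dicentric"]])
      keep_prod <- stats::runif(sum(is_unbal)) < pw ^ generations
      drop_idx <- which(is_unbal)[!keep_prod]
      if (length(drop_idx)) cas <- cas[-drop_idx]
    }
  }

  structure(list(cassettes = cas, cells = meta, truth = cells$truth),
            class = "shuffle_cells")
}
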