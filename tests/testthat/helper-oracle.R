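# Brute-force oracle for rearrangement classification: literally rebuilds the
# rearranged chromosome strings from truth by cutting the site cores and
# rejoining, then inspects the product strings — junction barcode pairs are
# read back by extraction, deletion products are labelled by which product is
# the circle, translocation subtypes by counting a centromere marker in each
# derivative. Independent of the recombination algebra under test.

CEN_MARKER <- "CGCGCGCGCGCGCGCGCGCGCGCGCGCGCG"

# build one chromosome string carrying cassettes at given coordinates;
# returns the string plus per-cassette cut positions (middle of the site core)
oracle_chrom <- function(len, cen_at, cassettes) {
  filler <- strrep("C", len)
  s <- filler
  # insert from the right so earlier coordinates stay valid
  ord <- order(-c(cen_at, cassettes$at))
  pieces <- c(list(list(at = cen_at, str = CEN_MARKER, cas = NA)),
              lapply(seq_len(nrow(cassettes)), function(i) {
                cs <- build_cassette_sequence(cassettes$barcode1[i],
                                              cassettes$barcode2[i],
                                              cassettes$site[i])
                if (cassettes$strand[i] == "bottom_CS1") cs <- revcomp(cs)
                list(at = cassettes$at[i], str = cs, cas = i)
              }))
  cuts <- integer(nrow(cassettes))
  for (k in ord) {
    p <- pieces[[k]]
    s <- paste0(substr(s, 1, p$at), p$str, substring(s, p$at + 1))
  }
  # recompute actual cut offsets after all insertions
  for (i in seq_len(nrow(cassettes))) {
    shift <- p_len <- 0L
    for (p in pieces) {
      if (!is.na(p$cas) && p$cas == i) next
      if (p$at < pieces[[i + 1L]]$at ||
          (p$at == pieces[[i + 1L]]$at && is.na(p$cas))) {
        shift <- shift + nchar(p$str)
      }
    }
    cs_len <- nchar(pieces[[i + 1L]]$str)
    core_off <- nchar("TAATACGACTCACTATAGGG") + 12L + 29L +
      (nchar(shufflekit:::SITE_CORES[[cassettes$site[i]]]) %/% 2L)
    cut_in_cas <- if (cassettes$strand[i] == "top_CS2") core_off else
      cs_len - core_off
    cuts[i] <- pieces[[i + 1L]]$at + shift + cut_in_cas
  }
  list(seq = s, cuts = cuts)
}

count_cen <- function(s) {
  m <- gregexpr(CEN_MARKER, s, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# read the single junction barcode pair of a product string in the intrinsic
# amplicon frame (barcode1 = CS2 slot); NULL for homotypic junctions
read_junction <- function(s) {
  hits <- extract_cassette_hits(s)
  hits <- hits[order(start)]
  if (nrow(hits) < 2L) return(NULL)
  # the junction is the adjacent pair of hits with opposite capture sides
  for (i in seq_len(nrow(hits) - 1L)) {
    h1 <- hits[i]; h2 <- hits[i + 1L]
    if (h1$orientation != h2$orientation) next
    if (h1$capture_side == h2$capture_side) next
    if (h1$orientation == "+") {
      if (h1$capture_side != "CS2") next
      return(list(barcode1 = h1$barcode, barcode2 = h2$barcode))
    } else {
      if (h1$capture_side != "CS1") next
      return(list(barcode1 = revcomp(h2$barcode),
                  barcode2 = revcomp(h1$barcode)))
    }
  }
  NULL
}

# simulate one random recombination case and classify it by string surgery
oracle_case <- function(case_seed, recombinase = "Cre") {
  set.seed(case_seed)
  same_chrom <- runif(1) < 0.5
  strands <- sample(c("top_CS2", "bottom_CS1"), 2, replace = TRUE)
  mode <- if (recombinase == "Cre")
    sample(c("parallel", "antiparallel"), 1) else "parallel"
  sites <- if (recombinase == "Cre") c("loxPsym", "loxPsym") else
    sample(c("attB", "attP"))
  bcs <- ac_barcodes(4, 1000L * case_seed)
  len <- 6000L

  if (same_chrom) {
    at <- sort(sample(seq(400L, len - 400L, by = 50L), 2))
    while (diff(at) < 900L) at <- sort(sample(seq(400L, len - 400L, 50L), 2))
    cen_at <- sample(setdiff(seq(200L, len - 200L, 50L), at), 1)
    cas <- data.table::data.table(
      at = at, strand = strands, site = sites,
      barcode1 = bcs[c(1, 3)], barcode2 = bcs[c(2, 4)])
    ch <- oracle_chrom(len, cen_at, cas)
    pm <- data.table::data.table(
      chrom = "c1", pos = at, strand = strands,
      barcode1 = bcs[c(1, 3)], barcode2 = bcs[c(2, 4)], allele = "BL6")
    cen_tab <- c(c1 = cen_at)

    cutA <- ch$cuts[1]; cutB <- ch$cuts[2]
    same_orient <- strands[1] == strands[2]
    eff_same <- xor(!same_orient, mode == "parallel")
    if (eff_same) {          # excision: linear scar + circle
      scar <- paste0(substr(ch$seq, 1, cutA), substring(ch$seq, cutB + 1))
      circle <- substr(ch$seq, cutA + 1, cutB)
      m <- nchar(circle) %/% 2L
      circle_rot <- paste0(substring(circle, m + 1L), substr(circle, 1, m))
      truth_class <- "deletion"
      prods <- list(list(str = scar, kind = "scar"),
                    list(str = circle_rot, kind = "ecdna"))
    } else {                 # inversion in place
      inv <- paste0(substr(ch$seq, 1, cutA),
                    revcomp(substr(ch$seq, cutA + 1, cutB)),
                    substring(ch$seq, cutB + 1))
      truth_class <- "inversion"
      # split at the midpoint: each half holds one junction
      mid <- (cutA + cutB) %/% 2L
      prods <- list(list(str = substr(inv, 1, mid), kind = "chrom"),
                    list(str = substring(inv, mid + 1L), kind = "chrom"))
    }
  } else {
    at <- c(sample(seq(400L, len - 400L, 50L), 1),
            sample(seq(400L, len - 400L, 50L), 1))
    cen_at <- c(sample(setdiff(seq(200L, len - 200L, 50L), at[1]), 1),
                sample(setdiff(seq(200L, len - 200L, 50L), at[2]), 1))
    cas1 <- data.table::data.table(at = at[1], strand = strands[1],
                                   site = sites[1], barcode1 = bcs[1],
                                   barcode2 = bcs[2])
    cas2 <- data.table::data.table(at = at[2], strand = strands[2],
                                   site = sites[2], barcode1 = bcs[3],
                                   barcode2 = bcs[4])
    ch1 <- oracle_chrom(len, cen_at[1], cas1)
    ch2 <- oracle_chrom(len, cen_at[2], cas2)
    pm <- data.table::data.table(
      chrom = c("c1", "c2"), pos = at, strand = strands,
      barcode1 = bcs[c(1, 3)], barcode2 = bcs[c(2, 4)], allele = "BL6")
    cen_tab <- c(c1 = cen_at[1], c2 = cen_at[2])

    cut1 <- ch1$cuts[1]; cut2 <- ch2$cuts[1]
    same_orient <- strands[1] == strands[2]
    eff_same <- xor(!same_orient, mode == "parallel")
    pre1 <- substr(ch1$seq, 1, cut1); post1 <- substring(ch1$seq, cut1 + 1)
    pre2 <- substr(ch2$seq, 1, cut2); post2 <- substring(ch2$seq, cut2 + 1)
    if (eff_same) {
      ders <- list(paste0(pre1, post2), paste0(pre2, post1))
    } else {
      ders <- list(paste0(pre1, revcomp(pre2)),
                   paste0(revcomp(post1), post2))
    }
    truth_class <- "translocation"
    prods <- lapply(ders, function(d) list(str = d, kind = "der"))
  }

  # inspect products: junction pairs, centromere counts
  calls <- list()
  for (p in prods) {
    j <- read_junction(p$str)
    if (is.null(j)) next
    subtype <- if (truth_class == "translocation") {
      ncen <- count_cen(p$str)
      c("acentric", "balanced", "dicentric")[ncen + 1L]
    } else NA_character_
    calls[[length(calls) + 1L]] <- data.table::data.table(
      barcode1 = j$barcode1, barcode2 = j$barcode2,
      class = truth_class,
      deletion_product = if (truth_class == "deletion") p$kind else
        NA_character_,
      translocation_subtype = subtype,
      size = if (same_chrom) abs(diff(at)) else NA_integer_)
  }
  list(pm = pm, centromeres = cen_tab,
       calls = if (length(calls)) data.table::rbindlist(calls) else
         data.table::data.table())
}

# run n oracle cases and compare with the package classifiers; returns the
# number of compared junction calls (errors out on any disagreement)
run_oracle_comparison <- function(n, seed_offset = 0L) {
  compared <- 0L
  for (k in seq_len(n)) {
    recomb <- if (k %% 3 == 0) "Bxb1" else "Cre"
    oc <- oracle_case(k + seed_offset, recomb)
    if (nrow(oc$calls) == 0L) next
    for (i in seq_len(nrow(oc$calls))) {
      pair <- oc$calls[i]
      sv <- classify_sv(list(barcode1 = pair$barcode1,
                             barcode2 = pair$barcode2), oc$pm)
      expect_identical(sv$class, pair$class)
      if (!is.na(pair$size)) expect_identical(sv$size, pair$size)
      if (sv$class == "deletion") {
        expect_identical(label_deletion_products(sv, oc$pm),
                         pair$deletion_product)
      }
      if (sv$class == "translocation") {
        expect_identical(
          classify_translocation(sv, oc$pm, oc$centromeres),
          pair$translocation_subtype)
      }
      compared <- compared + 1L
    }
  }
  compared
}
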