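# Sequence-level model of a shuffle cassette and the algebra of recombinase
# action on pairs of cassettes.
#
# A cassette is: T7fwd - CS2 body - TGAGC - barcode1 - site-left suffix -
# site core - AAAGC - barcode2 - site-right suffix - CS1 body - T7rev.
# The 5-nt prefixes (TGAGC for the CS2 side, AAAGC for the CS1 side) and the
# 4-nt site-half suffixes are the signature bases used for extraction; the
# suffix identifies which half of which recombinase site flanks the barcode.

# Constant sequence elements. Chosen so that neither prefix occurs anywhere
# outside its designated position (checked in tests).
T7_FWD   <- "TAATACGACTCACTATAGGG"
CS2_BODY <- "GCCTTGGCACCC"
CS1_BODY <- "CCGCTTAAGGGC"
CS2_PREFIX <- "TGAGC"
CS1_PREFIX <- "AAAGC"

# Full-length canonical loxPsym (34 bp, palindromic); kept for reference and
# round-tripping of configs, the extraction logic only relies on signatures.
LOXPSYM_SEQ <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

SITE_CORES <- c(
  loxPsym = "CTTCGTATAATGTACATTATACG",
  attB    = "GGCTTGTCGACGACGGC",
  attP    = "GTGGTTTGTCTGGTCAACC",
  attL    = "GGCTTGTCTGGTCAACC",
  attR    = "GTGGTTTGTCGACGACGGC"
)

# 4-nt signature suffixes per (site, capture side). The CS2-side suffix is the
# left half-site signature, the CS1-side suffix the right half-site signature:
# attL/attR are the hybrid halves produced by attB x attP recombination.
SITE_SUFFIX_CS2 <- c(loxPsym = "ATAA", attB = "GGCC", attP = "GTGG",
                     attL = "GGCC", attR = "GTGG")
SITE_SUFFIX_CS1 <- c(loxPsym = "ATAA", attB = "CCGG", attP = "TGGG",
                     attL = "TGGG", attR = "CCGG")

# Half-site type codes used when composing product sites.
HALF_CS2 <- c(loxPsym = "sym", attB = "B", attP = "P", attL = "B", attR = "P")
HALF_CS1 <- c(loxPsym = "sym", attB = "B", attP = "P", attL = "P", attR = "B")

SITE_LEVELS <- c("loxPsym", "attB", "attP", "attL", "attR")

#' Site signature set
#'
#' The constant bases flanking each 20-nt barcode in a read: a 5-nt prefix
#' identifying the capture side (CS2 or CS1) and a 4-nt suffix identifying
#' which half of which recombinase site the barcode abuts.
#'
#' @return a `data.table` with columns `site`, `side` (`"CS2"`/`"CS1"`),
#'   `prefix`, `suffix`, `half` (half-site type code `"sym"`, `"B"` or `"P"`).
#' @export
site_signatures <- function() {
  rbindlist(list(
    data.table(site = SITE_LEVELS, side = "CS2", prefix = CS2_PREFIX,
               suffix = unname(SITE_SUFFIX_CS2[SITE_LEVELS]),
               half = unname(HALF_CS2[SITE_LEVELS])),
    data.table(site = SITE_LEVELS, side = "CS1", prefix = CS1_PREFIX,
               suffix = unname(SITE_SUFFIX_CS1[SITE_LEVELS]),
               half = unname(HALF_CS1[SITE_LEVELS]))
  ))
}

#' Write / read a signature set as TSV
#' @param sig a signature table as returned by [site_signatures()].
#' @param path file path.
#' @return `read_signatures` returns the signature `data.table`.
#' @export
write_signatures <- function(sig, path) {
  data.table::fwrite(sig, path, sep = "\t")
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = "character")
}

check_site <- function(site, allowed = SITE_LEVELS) {
  if (!is.character(site) || length(site) != 1L || !site %in% allowed) {
    stop("site must be one of ", paste(allowed, collapse = ", "),
         ", got '", site, "'", call. = FALSE)
  }
  invisible(site)
}

#' Construct a shuffle cassette descriptor
#'
#' A plain list describing one integrated cassette: `barcode1` abuts the CS2
#' capture sequence, `barcode2` abuts CS1; `strand` records which cassette end
#' faces the lower genomic coordinate (`"top_CS2"` or `"bottom_CS1"`).
#'
#' @param barcode1,barcode2 20-nt barcodes.
#' @param site recombinase site type.
#' @param chrom,pos genomic location (1-based first base of the TTAA target
#'   site duplication); `NA` for extrachromosomal products.
#' @param strand `"top_CS2"` or `"bottom_CS1"`.
#' @param allele `"BL6"`, `"CAST"`, `"unassigned"` or `"inconclusive"`.
#' @return an object of class `shuffle_cassette` (a named list).
#' @export
shuffle_cassette <- function(barcode1, barcode2, site = "loxPsym",
                             chrom = NA_character_, pos = NA_integer_,
                             strand = c("top_CS2", "bottom_CS1"),
                             allele = "unassigned") {
  check_barcode(barcode1, "barcode1")
  check_barcode(barcode2, "barcode2")
  check_site(site)
  strand <- match.arg(strand)
  structure(list(barcode1 = barcode1, barcode2 = barcode2, site = site,
                 chrom = chrom, pos = as.integer(pos), strand = strand,
                 allele = allele),
            class = "shuffle_cassette")
}

#' @export
print.shuffle_cassette <- function(x, ...) {
  cat(sprintf("<shuffle_cassette> %s  %s:%s (%s, %s)\n  bc1(CS2)=%s\n  bc2(CS1)=%s\n",
              x$site, x$chrom, x$pos, x$strand, x$allele, x$barcode1, x$barcode2))
  invisible(x)
}

# Build one barcode block: capture prefix + barcode + site-half suffix.
barcode_block <- function(barcode, capture, site, end = c("left", "right")) {
  end <- match.arg(end)
  suffix <- if (end == "left") SITE_SUFFIX_CS2[[site]] else SITE_SUFFIX_CS1[[site]]
  prefix <- if (capture == "CS2") CS2_PREFIX else CS1_PREFIX
  paste0(prefix, barcode, suffix)
}

#' Build the full cassette sequence
#'
#' Returns the cassette top strand: T7 promoter, CS2 body and signature prefix,
#' `bc1`, the site (left signature, core, CS1 signature prefix), `bc2`, right
#' signature, CS1 body and the reverse T7 promoter. Extraction with
#' [extract_cassette_hits()] round-trips `(bc1, bc2, site)`.
#'
#' @param bc1,bc2 20-nt barcodes (CS2 side and CS1 side respectively).
#' @param site one of `"loxPsym"`, `"attB"`, `"attP"`, `"attL"`, `"attR"`.
#' @return a single DNA string.
#' @export
build_cassette_sequence <- function(bc1, bc2, site = "loxPsym") {
  check_barcode(bc1, "bc1")
  check_barcode(bc2, "bc2")
  check_site(site)
  build_product_sequence(bc1, "CS2", bc2, "CS1", site)
}

# Generalised builder covering homotypic recombination products, whose two
# ends can carry the same capture sequence.
build_product_sequence <- function(barcode_a, capture_a, barcode_b, capture_b,
                                   site) {
  body_a <- if (capture_a == "CS2") CS2_BODY else CS1_BODY
  body_b <- if (capture_b == "CS2") CS2_BODY else CS1_BODY
  paste0(T7_FWD, body_a,
         barcode_block(barcode_a, capture_a, site, "left"),
         SITE_CORES[[site]],
         barcode_block(barcode_b, capture_b, site, "right"),
         body_b, revcomp(T7_FWD))
}

# Regex patterns per capture side, built from a signature table.
side_patterns <- function(signatures) {
  sig <- as.data.table(signatures)
  out <- lapply(split(sig, by = "side"), function(s) {
    prefix <- unique(s$prefix)
    stopifnot(length(prefix) == 1L)
    list(prefix = prefix,
         pattern = paste0(prefix, "([ACGT]{20})(",
                          paste(unique(s$suffix), collapse = "|"), ")"),
         half = structure(s$half, names = s$suffix))
  })
  out
}

scan_one_orientation <- function(read, pats, orientation) {
  hits <- list()
  for (side in names(pats)) {
    p <- pats[[side]]
    m <- gregexpr(p$pattern, read, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      frag <- substr(read, m[i], m[i] + len[i] - 1L)
      bc <- substr(frag, 6L, 25L)
      suf <- substr(frag, 26L, nchar(frag))
      hits[[length(hits) + 1L]] <- data.table(
        barcode = bc, capture_side = side,
        half = unname(p$half[[suf]]), suffix = suf,
        start = as.integer(m[i]), orientation = orientation)
    }
  }
  if (length(hits) == 0L) return(NULL)
  rbindlist(hits)
}

#' Extract barcode hits from a read
#'
#' Scans a read for exact matches of the signature patterns
#' `prefix + (20 nt) + suffix` on both orientations. Reverse-orientation
#' matches (the read carries the bottom strand of the cassette) report the
#' literal barcode as it appears in the read (i.e. the reverse complement of
#' the cassette-intrinsic barcode), with `orientation == "-"`.
#'
#' @param read a single DNA string (length >= 29 to possibly contain a hit).
#' @param signatures signature table, default [site_signatures()].
#' @param orientation `"both"` (default) or `"forward"`.
#' @return a `data.table` with columns `barcode`, `capture_side`, `half`
#'   (half-site evidence), `suffix`, `start` (1-based position in the read),
#'   `orientation`; zero rows when nothing matches (not an error).
#' @export
extract_cassette_hits <- function(read, signatures = site_signatures(),
                                  orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  empty <- data.table(barcode = character(), capture_side = character(),
                      half = character(), suffix = character(),
                      start = integer(), orientation = character())
  if (!is.character(read) || length(read) != 1L || is.na(read)) {
    stop("read must be a single string", call. = FALSE)
  }
  if (nchar(read) < 29L) return(empty)
  pats <- side_patterns(signatures)
  fwd <- scan_one_orientation(read, pats, "+")
  out <- fwd
  if (orientation == "both") {
    rcm <- scan_one_orientation(revcomp(read), pats, "-")
    if (!is.null(rcm)) {
      # report read-local coordinates and the literal as-read barcode
      n <- nchar(read)
      rcm[, start := n - (start + 28L) + 1L]
      rcm[, barcode := revcomp(barcode)]
      out <- rbindlist(list(out, rcm))
    }
  }
  if (is.null(out)) return(empty)
  setorder(out, start)
  out[]
}

# Pick the barcode pair of one read from its extraction hits. Random barcodes
# occasionally contain signature-like bases that create spurious hits (mostly
# in the opposite orientation); the real pair is the same-orientation
# CS2 + CS1 hit pair whose spacing matches the cassette layout
# (cs1_start - cs2_start == 29 + nchar(site core)). Returns as-read barcodes
# plus the halves and orientation, or NULL when no pair is found.
pick_cassette_pair <- function(hits) {
  if (is.null(hits) || nrow(hits) < 2L) return(NULL)
  best <- NULL
  for (o in unique(hits$orientation)) {
    sub <- hits[hits$orientation == o, ]
    cs2 <- sub[sub$capture_side == "CS2", ]
    cs1 <- sub[sub$capture_side == "CS1", ]
    if (nrow(cs2) == 0L || nrow(cs1) == 0L) next
    for (i in seq_len(nrow(cs2))) {
      for (j in seq_len(nrow(cs1))) {
        site <- decode_site(cs2[i], cs1[j])
        gap <- if (o == "+") cs1$start[j] - cs2$start[i] else
          cs2$start[i] - cs1$start[j]
        spacing_ok <- !is.na(site) && gap == 29L + nchar(SITE_CORES[[site]])
        cand <- list(barcode1 = cs2$barcode[i], barcode2 = cs1$barcode[j],
                     half1 = cs2$half[i], half2 = cs1$half[j],
                     site = site, orientation = o,
                     score = 2L * isTRUE(spacing_ok) + !is.na(site))
        if (is.null(best) || cand$score > best$score) best <- cand
      }
    }
  }
  best
}

# Compose the site type of a heterotypic product from the left parent's left
# half and the right parent's right half.
combine_halves <- function(left_half, right_half) {
  if (left_half == "sym" && right_half == "sym") return("loxPsym")
  if (left_half == "B" && right_half == "P") return("attL")
  if (left_half == "P" && right_half == "B") return("attR")
  if (left_half == "B" && right_half == "B") return("attB")
  if (left_half == "P" && right_half == "P") return("attP")
  stop("cannot combine half-sites ", left_half, "/", right_half, call. = FALSE)
}

cassette_fields <- function(x) {
  if (inherits(x, "shuffle_cassette")) return(x)
  x <- as.list(x)
  need <- c("barcode1", "barcode2", "site", "chrom", "pos", "strand")
  if (!all(need %in% names(x))) {
    stop("cassette must provide fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Recombine a pair of cassettes
#'
#' Applies the recombination algebra of Cre (loxPsym x loxPsym) or Bxb1
#' (attB x attP) to two integrated cassettes. loxPsym is palindromic so the
#' synapse can form in two symmetric ways, selected by `alignment_mode`:
#' `"parallel"` joins the CS2 end of one parent to the CS1 end of the other
#' (heterotypic products), `"antiparallel"` joins like ends (homotypic
#' products). Bxb1 sites are directional, the mode is ignored and products are
#' always heterotypic, carrying attL and attR (inert to further Bxb1 action).
#'
#' For cis pairs the event class is `deletion` when the genomic outcome is an
#' excision (same integration strand with parallel mode, or opposite strands
#' with antiparallel mode) and `inversion` otherwise; pairs on different
#' chromosomes give `translocation`. A deletion creates an extrachromosomal
#' circle (`ecdna_created`), and its two products are labelled `scar`
#' (chromosome-retained junction) and `ecdna`.
#'
#' @param a,b cassettes ([shuffle_cassette()] objects or lists/rows with
#'   fields `barcode1`, `barcode2`, `site`, `chrom`, `pos`, `strand`).
#' @param recombinase `"Cre"` or `"Bxb1"`.
#' @param alignment_mode `"parallel"` or `"antiparallel"` (Cre only).
#' @return a list of class `recombination_product` with elements
#'   `event_class`, `ecdna_created`, `mode`, and `products`: a two-row
#'   `data.table` with columns `barcode_left`, `capture_left`, `barcode_right`,
#'   `capture_right`, `site`, `role`.
#' @export
recombine_pair <- function(a, b, recombinase = c("Cre", "Bxb1"),
                           alignment_mode = c("parallel", "antiparallel")) {
  recombinase <- match.arg(recombinase)
  alignment_mode <- match.arg(alignment_mode)
  a <- cassette_fields(a); b <- cassette_fields(b)
  sites <- c(a$site, b$site)

  if (recombinase == "Cre") {
    if (!all(sites == "loxPsym")) {
      stop("Cre requires loxPsym sites on both cassettes (got ",
           paste(sites, collapse = " x "), ")", call. = FALSE)
    }
  } else {
    if (any(sites %in% c("attL", "attR"))) {
      stop("incompatible sites: attL/attR products are resistant to further ",
           "Bxb1-mediated recombination", call. = FALSE)
    }
    if (!setequal(sites, c("attB", "attP"))) {
      stop("incompatible sites: Bxb1 requires one attB and one attP cassette ",
           "(got ", paste(sites, collapse = " x "), ")", call. = FALSE)
    }
    alignment_mode <- "parallel"
  }

  # order parents by genomic coordinate for cis pairs so that A is upstream
  cis <- !is.na(a$chrom) && !is.na(b$chrom) && a$chrom == b$chrom
  if (cis && !is.na(a$pos) && !is.na(b$pos) && b$pos < a$pos) {
    tmp <- a; a <- b; b <- tmp
  }
  same_strand <- identical(a$strand, b$strand)

  if (alignment_mode == "parallel") {
    products <- data.table(
      barcode_left  = c(a$barcode1, b$barcode1),
      capture_left  = "CS2",
      barcode_right = c(b$barcode2, a$barcode2),
      capture_right = "CS1",
      site = c(combine_halves(HALF_CS2[[a$site]], HALF_CS1[[b$site]]),
               combine_halves(HALF_CS2[[b$site]], HALF_CS1[[a$site]]))
    )
  } else {
    products <- data.table(
      barcode_left  = c(a$barcode1, a$barcode2),
      capture_left  = c("CS2", "CS1"),
      barcode_right = c(b$barcode1, b$barcode2),
      capture_right = c("CS2", "CS1"),
      site = "loxPsym"
    )
  }

  if (!cis) {
    event_class <- "translocation"
  } else if (same_strand == (alignment_mode == "parallel")) {
    event_class <- "deletion"
  } else {
    event_class <- "inversion"
  }
  ecdna <- event_class == "deletion"

  role <- c("junction1", "junction2")
  if (ecdna) {
    # the scar is the product that retains the genomic-left barcode of the
    # upstream parent (its lower-coordinate-facing end stays on the chromosome)
    gl_a <- if (a$strand == "top_CS2") a$barcode1 else a$barcode2
    scar_first <- gl_a %in% c(products$barcode_left[1L], products$barcode_right[1L])
    role <- if (scar_first) c("scar", "ecdna") else c("ecdna", "scar")
  } else if (event_class == "translocation") {
    role <- c("der1", "der2")
  }
  products[, role := role]

  structure(list(
    left_parent = a, right_parent = b,
    event_class = event_class, ecdna_created = ecdna, mode = alignment_mode,
    recombinase = recombinase, products = products
  ), class = "recombination_product")
}

#' @export
print.recombination_product <- function(x, ...) {
  cat(sprintf("<recombination_product> %s (%s, mode=%s, ecDNA=%s)\n",
              x$event_class, x$recombinase, x$mode, x$ecdna_created))
  print(x$products)
  invisible(x)
}

#' Is a product cassette detectable by amplicon PCR?
#'
#' Templates whose two ends carry the same capture sequence (homotypic
#' CS1-CS1 or CS2-CS2 products) fail to amplify due to suppression PCR and
#' are modelled as undetectable under both the two-primer and four-primer
#' schemes by default; `detect_homotypic = TRUE` makes the four-primer scheme
#' report them for sensitivity analyses.
#'
#' @param product one row of the `products` table from [recombine_pair()], or
#'   any list with `capture_left` and `capture_right`.
#' @param scheme `"two_primer"` or `"four_primer"`.
#' @param detect_homotypic override for the four-primer scheme.
#' @return logical.
#' @export
amplicon_detectable <- function(product, scheme = c("two_primer", "four_primer"),
                                detect_homotypic = FALSE) {
  scheme <- match.arg(scheme)
  p <- as.list(product)
  if (is.null(p$capture_left) || is.null(p$capture_right)) {
    stop("product must define capture_left and capture_right", call. = FALSE)
  }
  het <- p$capture_left != p$capture_right
  het || (scheme == "four_primer" && detect_homotypic)
}

#' Enumerate Cre recombination outcomes
#'
#' Exhaustively enumerates the products of loxPsym x loxPsym recombination
#' over the two relative integration orientations (same / opposite strand)
#' and both symmetric alignment modes, for one generic cis cassette pair.
#'
#' @return a `data.table` with one row per product and columns
#'   `rel_orientation`, `mode`, `event_class`, `capture_left`,
#'   `capture_right`, `homotypic`, `detectable`.
#' @export
enumerate_cre_outcomes <- function() {
  bcs <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20), strrep("T", 20))
  out <- list()
  for (rel in c("same", "opposite")) {
    for (mode in c("parallel", "antiparallel")) {
      a <- shuffle_cassette(bcs[1], bcs[2], "loxPsym", "chr1", 1000L, "top_CS2")
      b <- shuffle_cassette(bcs[3], bcs[4], "loxPsym", "chr1", 5000L,
                            if (rel == "same") "top_CS2" else "bottom_CS1")
      r <- recombine_pair(a, b, "Cre", mode)
      p <- copy(r$products)
      p[, `:=`(rel_orientation = rel, mode = mode, event_class = r$event_class)]
      out[[length(out) + 1L]] <- p
    }
  }
  res <- rbindlist(out)
  res[, homotypic := capture_left == capture_right]
  res[, detectable := !homotypic]
  res[, .(rel_orientation, mode, event_class, capture_left, capture_right,
          homotypic, detectable)]
}

#' Fraction of homotypic (amplicon-undetectable) Cre products
#'
#' @return percentage (0-100) of products from [enumerate_cre_outcomes()]
#'   whose two ends carry the same capture sequence.
#' @export
cre_homotypic_percent <- function() {
  res <- enumerate_cre_outcomes()
  100 * mean(res$homotypic)
}

#' Fraction of Bxb1-competent cassette pairs
#'
#' With attB and attP cassettes present in fractions `p` and `q`, only
#' attB x attP pairs can recombine. For proportions the large-population
#' competent fraction of unordered pairs is `2pq / (p + q)^2`; for a finite
#' population of `n_attB` + `n_attP` cassettes the exact enumeration is
#' `n_attB * n_attP / choose(n, 2)`.
#'
#' @param p,q relative proportions of attB and attP cassettes.
#' @param n_attB,n_attP optional integer counts for exact finite enumeration
#'   (both must be given; overrides `p`/`q`).
#' @return fraction in [0, 1].
#' @export
bxb1_competent_fraction <- function(p = 0.5, q = 0.5,
                                    n_attB = NULL, n_attP = NULL) {
  if (!is.null(n_attB) || !is.null(n_attP)) {
    stopifnot(!is.null(n_attB), !is.null(n_attP))
    n <- n_attB + n_attP
    if (n < 2L) return(0)
    return(n_attB * n_attP / choose(n, 2))
  }
  2 * p * q / (p + q)^2
}
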