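# Shared fixtures, built in code. Test barcodes use the {A,C} alphabet: the
# signature prefixes and suffixes all contain G or T, so controlled barcodes
# can never create spurious extraction hits.

ac_barcode <- function(seed_int) {
  set.seed(seed_int)
  paste(sample(c("A", "C"), 20, replace = TRUE), collapse = "")
}

ac_barcodes <- function(n, offset = 0L) {
  vapply(seq_len(n) + offset, ac_barcode, character(1))
}

make_cassette <- function(bc1, bc2, site = "loxPsym", chrom = "chr1",
                          pos = 1000L, strand = "top_CS2", allele = "BL6") {
  shuffle_cassette(bc1, bc2, site, chrom, pos, strand, allele)
}

# small genome + clone population reused across pipeline tests
small_cfg <- function(...) {
  args <- list(seed = 7, chrom_lengths = c(chr1 = 3e5, chr2 = 3e5),
               n_clones = 2, cassettes_per_clone = 10, cells_per_clone = 3,
               sub_rate = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# adjusted Rand index between two label vectors (closed form on the
# contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

FIX_CFG <- small_cfg()
FIX_GENOME <- simulate_genome(FIX_CFG)
FIX_CLONES <- integrate_cassettes(FIX_GENOME, FIX_CFG)

# a parental map table in the shape produced by the insertion pipeline
toy_parental_map <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(1000000L, 3500000L, 4200000L, 2000000L),
    strand = c("top_CS2", "top_CS2", "bottom_CS1", "top_CS2"),
    barcode1 = ac_barcodes(4, 100),
    barcode2 = ac_barcodes(4, 200),
    allele = c("BL6", "BL6", "CAST", "BL6")
  )
}
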