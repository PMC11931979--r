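# Gene-dosage consequences of an SV within a clonotype: library-size
# normalization, one-sided rank tests, genotype-stratified fold changes, a
# genome-ordered rolling-window scan and downsampling robustness.

#' Library-size normalize a count matrix
#'
#' Divides each cell's counts by its library size (x `scale` constant) after
#' masking genes expressed in fewer than `min_cells` cells.
#'
#' @param counts genes x cells matrix (dense or sparse, nonnegative integers).
#' @param genes gene annotation table (`gene`, `chrom`, `start`, `end`);
#'   row order must match `counts`.
#' @param min_cells inclusion floor (a gene must be expressed in at least this
#'   many cells).
#' @param scale scale constant.
#' @return an object of class `normalized_expression`: list with `norm`
#'   (genes x cells), `genes` (annotation with `genomic_index` ordered by
#'   chromosome then start) and `mask` (logical inclusion per input gene).
#' @export
normalize_expression <- function(counts, genes = NULL, min_cells = 10L,
                                 scale = 1e4) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative")
  expressed_in <- rowSums(m > 0)
  mask <- expressed_in >= min_cells
  lib <- colSums(m)
  lib[lib == 0] <- 1
  norm <- sweep(m[mask, , drop = FALSE], 2L, lib, `/`) * scale
  ann <- NULL
  if (!is.null(genes)) {
    ann <- as.data.table(genes)[mask]
    setorder(ann, chrom, start)
    ann[, genomic_index := .I]
    norm <- norm[ann$gene, , drop = FALSE]
  }
  structure(list(norm = norm, genes = ann, mask = mask),
            class = "normalized_expression")
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact permutation enumeration when `length(a) + length(b) <= exact_max`
#' (midranks, so exact in the presence of ties), otherwise the tie-corrected
#' normal approximation without continuity correction. `alternative` follows
#' the usual convention for the first sample: `"less"` tests for a shift of
#' `a` below `b`.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exact_max largest total sample size for exact enumeration.
#' @return list with `U` (statistic for sample `a`) and `p_value`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "less", "greater"),
                          exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    stats_all <- apply(combos, 2L, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p_less <- mean(stats_all <= U)
    p_greater <- mean(stats_all >= U)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    z <- (U - mu) / sqrt(sigma2)
    p_less <- stats::pnorm(z)
    p_greater <- stats::pnorm(z, lower.tail = FALSE)
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_less, p_greater)),
              less = p_less,
              greater = p_greater)
  list(U = U, p_value = p)
}

#' Genotype-stratified fold change with one-sided rank test
#'
#' Fold change is the ratio of mean normalized expression in SV-bearing cells
#' over control cells of the same clonotype; the one-sided p-value tests for a
#' decrease via [rank_sum_test()].
#'
#' @param norm a [normalize_expression()] result (or genes x cells matrix).
#' @param cells_with_sv,cells_without_sv disjoint cell id vectors.
#' @param genes genes to test (default: all normalized genes).
#' @return a `data.table`: `gene`, `fold_change` (`NA` when both groups are
#'   zero), `p_value` (one-sided, decrease).
#' @export
genotype_fold_change_test <- function(norm, cells_with_sv, cells_without_sv,
                                      genes = NULL) {
  m <- if (inherits(norm, "normalized_expression")) norm$norm else norm
  if (length(intersect(cells_with_sv, cells_without_sv)) > 0L) {
    stop("cell groups must be disjoint")
  }
  if (is.null(genes)) genes <- rownames(m)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    x <- m[g, cells_with_sv]
    y <- m[g, cells_without_sv]
    if (mean(y) == 0 && mean(x) == 0) {
      out[[i]] <- data.table(gene = g, fold_change = NA_real_,
                             p_value = NA_real_)
      next
    }
    fc <- if (mean(y) == 0) NA_real_ else mean(x) / mean(y)
    p <- rank_sum_test(x, y, alternative = "less")$p_value
    out[[i]] <- data.table(gene = g, fold_change = fc, p_value = p)
  }
  rbindlist(out)
}

#' Rolling-window fold-change scan
#'
#' Rolling means of per-gene fold changes over `window` consecutive genes in
#' genomic order (windows never span a chromosome boundary). For a designated
#' window (e.g. the deletion trio), a z-score against all windows sharing no
#' gene with it yields a one-sided normal p-value.
#'
#' @param fold_changes per-gene fold changes (named by gene, in the order of
#'   `gene_order`).
#' @param gene_order annotation table (`gene`, `chrom`, `start`) defining the
#'   genomic order.
#' @param window window size in genes.
#' @param target_genes optional genes designating the window to test.
#' @return a `data.table` of windows (`chrom`, `first_gene`, `mid_gene`,
#'   `mean_fc`, `contains_target`); when `target_genes` is given, attributes
#'   `z` and `p_value` hold the designated window's score (`NA` when the null
#'   windows are constant).
#' @export
rolling_window_scan <- function(fold_changes, gene_order, window = 3L,
                                target_genes = NULL) {
  ann <- as.data.table(gene_order)
  setorder(ann, chrom, start)
  if (nrow(ann) < window) stop("need at least `window` genes")
  fc <- fold_changes[ann$gene]
  out <- list()
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    if (length(idx) < window) next
    for (s in seq_len(length(idx) - window + 1L)) {
      span <- idx[s:(s + window - 1L)]
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, first_gene = ann$gene[span[1L]],
        mid_gene = ann$gene[span[(window + 1L) %/% 2L]],
        mean_fc = mean(fc[span]),
        genes = list(ann$gene[span]))
    }
  }
  res <- rbindlist(out)
  res[, contains_target := FALSE]
  z <- p <- NA_real_
  if (!is.null(target_genes)) {
    res[, contains_target := vapply(genes, function(g)
      any(g %in% target_genes), logical(1))]
    target <- res[vapply(genes, function(g)
      all(target_genes %in% g), logical(1))]
    nullw <- res[contains_target == FALSE]
    if (nrow(target) >= 1L && nrow(nullw) >= 2L &&
        stats::sd(nullw$mean_fc) > 0) {
      z <- (target$mean_fc[1L] - mean(nullw$mean_fc)) / stats::sd(nullw$mean_fc)
      p <- stats::pnorm(z)
    }
  }
  res[, genes := NULL]
  setattr(res, "z", z)
  setattr(res, "p_value", p)
  res[]
}

#' Downsampling robustness of the fold-change estimate
#'
#' Randomly subsamples the SV-bearing cells without replacement at each size
#' and re-runs [genotype_fold_change_test()], `trials` times per size.
#'
#' @param norm a [normalize_expression()] result.
#' @param cells_with_sv,cells_without_sv cell groups.
#' @param genes genes to test.
#' @param sizes subsample sizes (must not exceed `length(cells_with_sv)`).
#' @param trials trials per size.
#' @param seed seed.
#' @return a `data.table`: `size`, `trial`, `gene`, `fold_change`, `p_value`.
#' @export
downsample_robustness <- function(norm, cells_with_sv, cells_without_sv,
                                  genes, sizes, trials = 100L, seed = 1L) {
  stopifnot(all(sizes <= length(cells_with_sv)))
  set.seed(seed)
  out <- list()
  for (s in sizes) {
    for (tr in seq_len(trials)) {
      cells <- if (s == length(cells_with_sv)) cells_with_sv else
        sample(cells_with_sv, s)
      res <- genotype_fold_change_test(norm, cells, cells_without_sv, genes)
      res[, `:=`(size = s, trial = tr)]
      out[[length(out) + 1L]] <- res
    }
  }
  rbindlist(out)[, .(size, trial, gene, fold_change, p_value)]
}
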