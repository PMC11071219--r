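# Expression-side computations: FPKM normalisation, the TAU
# tissue-specificity index over group means, PAV-class expression
# summaries, a simple Welch-t two-group differential-expression test (a
# documented stand-in, not a DESeq2 reimplementation), lncRNA-mRNA
# coexpression pairing, and variant-burden tables.

#' FPKM normalisation
#'
#' value = count * 1e9 / (total * length_bp). Scaling every count and the
#' per-sample total by the same factor leaves FPKM unchanged.
#'
#' @param counts genes x samples count matrix (dimnames set).
#' @param lengths named vector of gene lengths in bp (> 0).
#' @param totals optional named per-sample totals (> 0); default column
#'   sums of `counts`.
#' @param groups optional sample-to-group map; if given, an
#'   [expression_matrix()] is returned, else a plain matrix.
#' @return FPKM matrix or [expression_matrix()].
#' @export
fpkm <- function(counts, lengths, totals = NULL, groups = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts))
      .fail("`lengths` must be named or match nrow(counts)")
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    .fail("no length for gene(s): %s", paste(head(missing, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) .fail("gene lengths must be > 0")
  if (is.null(totals)) totals <- colSums(counts)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals) | totals <= 0))
    .fail("per-sample totals must be > 0 for every sample")
  out <- sweep(counts, 2, totals, "/") * 1e9 / len
  if (!is.null(groups)) expression_matrix(out, groups, gene_lengths = lengths)
  else out
}

#' TAU tissue-specificity index
#'
#' For a vector x of non-negative per-group mean expressions of one gene,
#' tau = n/(n-1) - sum(x) / ((n-1) * max(x)), where n is the number of
#' groups. tau is 0 for uniform expression, 1 when exactly one group is
#' nonzero, and undefined (NA) when all groups are zero.
#'
#' @param x non-negative numeric vector of per-group means (length >= 2).
#' @return The TAU value in [0, 1], or NA when `max(x) == 0`.
#' @examples
#' tau(c(8, 0, 0, 0))   # 1
#' tau(c(5, 5, 5, 5))   # 0
#' tau(c(4, 2, 2, 2))   # 0.5
#' @export
tau <- function(x) {
  n <- length(x)
  if (n < 2) .fail("TAU needs at least 2 groups")
  if (any(x < 0)) .fail("TAU inputs must be non-negative")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  n / (n - 1) - sum(x) / ((n - 1) * mx)
}

#' Per-gene TAU over group means
#'
#' Group means (not per-sample values) feed the index: each gene's
#' expression is first averaged within every sample group, then [tau()] is
#' applied to the group-mean profile.
#'
#' @param x an [expression_matrix()] (or matrix plus `groups`).
#' @param groups sample-to-group map (ignored when `x` carries one).
#' @return `data.frame` with columns `gene_id`, `n_groups`, `tau` (NA for
#'   all-zero genes).
#' @export
tau_index <- function(x, groups = NULL) {
  if (inherits(x, "expression_matrix")) {
    groups <- x$groups; v <- x$values
  } else v <- .expr_values(x)
  if (is.null(groups)) .fail("`groups` is required")
  groups <- groups[colnames(v)]
  gm <- group_means(v, groups)
  data.frame(gene_id = rownames(v), n_groups = ncol(gm),
             tau = apply(gm, 1, tau), stringsAsFactors = FALSE,
             row.names = NULL)
}

# per-gene means within sample groups (genes x groups)
group_means <- function(v, groups) {
  glev <- unique(unname(groups))
  gm <- do.call(cbind, lapply(glev, function(g)
    rowMeans(v[, names(groups)[groups == g], drop = FALSE])))
  dimnames(gm) <- list(rownames(v), glev)
  gm
}

#' Expression summaries by occupancy class
#'
#' Per sample and PAV class: n, mean, median and quartiles of the
#' expression values of the class's genes. Genes without a class are put
#' in an `"NA"` stratum.
#'
#' @param x an [expression_matrix()] or matrix.
#' @param classes named character vector gene -> class (e.g. from
#'   [classify_genes()]: `setNames(cl$class, cl$gene_id)`).
#' @return `data.frame` with columns `sample_id`, `class`, `n`, `mean`,
#'   `q25`, `median`, `q75`.
#' @export
class_expression_summary <- function(x, classes) {
  v <- .expr_values(x)
  cl <- as.character(classes[rownames(v)])
  cl[is.na(cl)] <- "NA"
  rows <- list()
  for (s in colnames(v)) {
    for (k in unique(cl)) {
      vals <- v[cl == k, s]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, class = k, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        q25 = if (length(vals)) unname(quantile(vals, 0.25)) else NA_real_,
        median = if (length(vals)) median(vals) else NA_real_,
        q75 = if (length(vals)) unname(quantile(vals, 0.75)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simple two-group differential-expression test
#'
#' log2 fold change of group means (zero means replaced by half the
#' smallest positive value in the matrix) and a Welch t-test on
#' log2-transformed values, BH-corrected; DE iff q < `fdr` and the fold
#' change exceeds `min_fc` in either direction. This is a deliberately
#' plain stand-in for count-model DE tools: use DESeq2 or edgeR on real
#' count data.
#'
#' @param x an [expression_matrix()] or matrix.
#' @param group_a,group_b disjoint sample-id vectors, each >= 3 samples.
#' @param fdr FDR threshold (default 0.05).
#' @param min_fc fold-change threshold (default 2).
#' @return `data.frame` with columns `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `p`, `q`, `de`; genes all-zero in both groups are excluded
#'   (attribute `n_untested`).
#' @export
de_simple <- function(x, group_a, group_b, fdr = 0.05, min_fc = 2) {
  v <- .expr_values(x)
  if (length(intersect(group_a, group_b))) .fail("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    .fail("each group needs at least 3 samples")
  missing <- setdiff(c(group_a, group_b), colnames(v))
  if (length(missing))
    .fail("samples not in matrix: %s", paste(head(missing, 5), collapse = ", "))
  a <- v[, group_a, drop = FALSE]; b <- v[, group_b, drop = FALSE]
  untested <- rowSums(a) == 0 & rowSums(b) == 0
  a <- a[!untested, , drop = FALSE]; b <- b[!untested, , drop = FALSE]
  pos <- v[v > 0]
  pseudo <- if (length(pos)) min(pos) / 2 else 1
  ma <- rowMeans(a); mb <- rowMeans(b)
  log2fc <- log2(ifelse(ma == 0, pseudo, ma) /
                 ifelse(mb == 0, pseudo, mb))
  la <- log2(a + pseudo); lb <- log2(b + pseudo)
  p <- vapply(seq_len(nrow(a)), function(i) {
    if (sd(la[i, ]) == 0 && sd(lb[i, ]) == 0)
      return(if (mean(la[i, ]) == mean(lb[i, ])) 1 else 0)
    t.test(la[i, ], lb[i, ])$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(a), mean_a = ma, mean_b = mb,
                    log2fc = log2fc, p = p, q = q,
                    de = q < fdr & abs(log2fc) > log2(min_fc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(untested)
  out
}

#' lncRNA-mRNA coexpression pairs
#'
#' Pearson correlation over shared samples; pairs with |r| >= `min_abs_r`
#' are reported. Constant profiles are skipped with a warning.
#'
#' @param lnc lncRNA matrix (features x samples).
#' @param mrna mRNA matrix (features x samples).
#' @param min_abs_r absolute-correlation threshold (default 0.9).
#' @return `data.frame` with columns `lncrna`, `mrna`, `r`.
#' @export
coexpression_pairs <- function(lnc, mrna, min_abs_r = 0.9) {
  lnc <- .expr_values(lnc); mrna <- .expr_values(mrna)
  shared <- intersect(colnames(lnc), colnames(mrna))
  if (length(shared) < 3) .fail("need at least 3 shared samples")
  lnc <- lnc[, shared, drop = FALSE]; mrna <- mrna[, shared, drop = FALSE]
  const_l <- apply(lnc, 1, sd) == 0
  const_m <- apply(mrna, 1, sd) == 0
  if (any(const_l) || any(const_m))
    .warnf("skipping %d constant lncRNA and %d constant mRNA profiles",
           sum(const_l), sum(const_m))
  lnc <- lnc[!const_l, , drop = FALSE]; mrna <- mrna[!const_m, , drop = FALSE]
  if (!nrow(lnc) || !nrow(mrna))
    return(data.frame(lncrna = character(), mrna = character(),
                      r = numeric()))
  r <- cor(t(lnc), t(mrna))
  hit <- which(abs(r) >= min_abs_r, arr.ind = TRUE)
  out <- data.frame(lncrna = rownames(r)[hit[, 1]],
                    mrna = colnames(r)[hit[, 2]],
                    r = r[hit], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant-burden table
#'
#' Counts annotated variants per gene and sample, stratified by consequence
#' label. Records citing genes outside `genes` go into an `"unassigned"`
#' bucket with a warning. Genes with zero variants appear with zero
#' totals.
#'
#' @param variants `data.frame` with columns `gene`, `sample`,
#'   `consequence` (one row per variant record).
#' @param genes character vector of genes to tabulate.
#' @param samples optional sample universe; default samples seen in
#'   `variants`.
#' @return A list of class `burden_table`: `long` (gene x sample x
#'   consequence counts, zero rows omitted), `totals` (genes x samples
#'   matrix of overall counts, including all-zero genes) and
#'   `consequences`.
#' @export
burden_table <- function(variants, genes, samples = NULL) {
  need <- c("gene", "sample", "consequence")
  if (!all(need %in% names(variants)))
    .fail("variants need columns: %s", paste(need, collapse = ", "))
  unknown <- !variants$gene %in% genes
  if (any(unknown)) {
    .warnf("%d variant record(s) cite unknown genes; counted as 'unassigned'",
           sum(unknown))
    variants$gene[unknown] <- "unassigned"
    genes <- c(genes, "unassigned")
  }
  samples <- samples %||% sort(unique(variants$sample))
  if (!nrow(variants)) {
    return(structure(list(
      long = data.frame(gene = character(), sample = character(),
                        consequence = character(), count = integer()),
      totals = matrix(0L, length(genes), length(samples),
                      dimnames = list(genes, samples)),
      consequences = character()), class = "burden_table"))
  }
  long <- as.data.frame(table(gene = factor(variants$gene, levels = genes),
                              sample = factor(variants$sample,
                                              levels = samples),
                              consequence = variants$consequence),
                        stringsAsFactors = FALSE)
  names(long)[4] <- "count"
  long <- long[long$count > 0, , drop = FALSE]
  totals <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  tt <- table(factor(variants$gene, levels = genes),
              factor(variants$sample, levels = samples))
  totals[] <- as.integer(tt)
  rownames(long) <- NULL
  structure(list(long = long, totals = totals,
                 consequences = sort(unique(variants$consequence))),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat(sprintf("burden_table: %d genes x %d samples, %d consequence types, %d variants\n",
              nrow(x$totals), ncol(x$totals), length(x$consequences),
              sum(x$totals)))
  invisible(x)
}
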