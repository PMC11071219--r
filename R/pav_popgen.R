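# Population-level PAV statistics: occupancy classification, saturation
# (rarefaction) curves, PCA on the binary matrix, Fisher's-exact gene
# frequency selection tests with BH correction, and breed-specific genes.

utils::globalVariables(c("covered_bases", "depth_sum", ".N", ":="))

#' Occupancy-class boundaries
#'
#' One consistent reading of the usual core/softcore/shell/cloud
#' definitions: core = present in all samples; softcore = occupancy in
#' [softcore_min, 1); shell = [shell_min, softcore_min); cloud =
#' (0, shell_min). Genes observed in no sample are reported as
#' "unobserved".
#'
#' @param softcore_min lower occupancy bound of the softcore class
#'   (default 0.99).
#' @param shell_min lower occupancy bound of the shell class (default 0.01).
#' @return A `pav_class_config` list.
#' @export
pav_class_config <- function(softcore_min = 0.99, shell_min = 0.01) {
  if (!(shell_min > 0 && shell_min < softcore_min && softcore_min < 1))
    .fail("need 0 < shell_min < softcore_min < 1")
  structure(list(softcore_min = softcore_min, shell_min = shell_min),
            class = "pav_class_config")
}

#' Classify genes by occupancy
#'
#' @param x a [pav_matrix()] or binary matrix.
#' @param cfg a [pav_class_config()].
#' @return `data.frame` with columns `gene_id`, `n_present`, `occupancy`,
#'   `class` (factor: core, softcore, shell, cloud, unobserved), plus a
#'   `counts` attribute (named class counts over observed genes).
#' @export
classify_genes <- function(x, cfg = pav_class_config()) {
  if (is.matrix(x) && (nrow(x) == 0L || ncol(x) == 0L))
    .fail("empty PAV matrix")
  v <- .pav_values(x)
  if (!length(v)) .fail("empty PAV matrix")
  occ <- rowMeans(v)
  cls <- ifelse(occ == 1, "core",
         ifelse(occ >= cfg$softcore_min, "softcore",
         ifelse(occ >= cfg$shell_min, "shell",
         ifelse(occ > 0, "cloud", "unobserved"))))
  out <- data.frame(gene_id = rownames(v), n_present = rowSums(v),
                    occupancy = occ,
                    class = factor(cls, levels = c("core", "softcore",
                                                   "shell", "cloud",
                                                   "unobserved")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- table(out$class[out$class != "unobserved"])
  counts <- counts[c("core", "softcore", "shell", "cloud")]
  attr(out, "counts") <- counts
  out
}

#' Summaries derived from occupancy-class counts
#'
#' Percentage shares (of observed genes) and the usual derived totals:
#' the variable-gene share (softcore + shell + cloud) and the number of
#' PAV-related genes (softcore + shell, i.e. variable genes observed in at
#' least 1% of samples).
#'
#' @param counts named vector of gene counts with names `core`, `softcore`,
#'   `shell`, `cloud` (e.g. `attr(classify_genes(x), "counts")`).
#' @return A list: `total`, `shares` (named percentages), `core_share`,
#'   `variable_share`, `pav_related`.
#' @export
pan_size_summary <- function(counts) {
  need <- c("core", "softcore", "shell", "cloud")
  if (!all(need %in% names(counts)))
    .fail("counts must be named: %s", paste(need, collapse = ", "))
  counts <- as.numeric(counts[need])
  names(counts) <- need
  total <- sum(counts)
  shares <- 100 * counts / total
  list(total = total, counts = counts, shares = shares,
       core_share = unname(shares["core"]),
       variable_share = unname(sum(shares[c("softcore", "shell", "cloud")])),
       pav_related = unname(counts["softcore"] + counts["shell"]))
}

#' Pan- and core-gene saturation (rarefaction) curves
#'
#' For each subset size k, draws random sample subsets without replacement
#' (or enumerates all subsets when `exhaustive = TRUE`) and counts pan
#' genes (present in at least one subset member) and core genes (present in
#' all subset members).
#'
#' @param x a [pav_matrix()] or binary matrix.
#' @param replicates subsets drawn per k (default 10000).
#' @param seed RNG seed.
#' @param ks subset sizes to evaluate (default 1..n_samples).
#' @param exhaustive if `TRUE`, enumerate all C(n, k) subsets instead of
#'   sampling (feasible only for small matrices).
#' @return `data.frame` with columns `k`, `pan_mean`, `pan_min`, `pan_max`,
#'   `core_mean`, `core_min`, `core_max`, `replicates`.
#' @export
saturation <- function(x, replicates = 10000, seed = 1, ks = NULL,
                       exhaustive = FALSE) {
  v <- .pav_values(x)
  n <- ncol(v)
  if (is.null(ks)) ks <- seq_len(n)
  if (any(ks < 1 | ks > n)) .fail("subset size k out of 1..%d", n)
  if (!exhaustive) .check_count(replicates, "replicates")
  with_seed(seed, {
    rows <- lapply(ks, function(k) {
      subsets <- if (exhaustive) {
        asplit(combn(n, k), 2)
      } else {
        lapply(seq_len(replicates), function(i) sample.int(n, k))
      }
      pan <- integer(length(subsets)); core <- integer(length(subsets))
      for (i in seq_along(subsets)) {
        rs <- rowSums(v[, subsets[[i]], drop = FALSE])
        pan[i] <- sum(rs > 0L)
        core[i] <- sum(rs == k)
      }
      data.frame(k = k, pan_mean = mean(pan), pan_min = min(pan),
                 pan_max = max(pan), core_mean = mean(core),
                 core_min = min(core), core_max = max(core),
                 replicates = length(subsets))
    })
  })
  do.call(rbind, rows)
}

#' PCA on the binary PAV matrix
#'
#' Samples are the observations, genes the variables; genes are
#' mean-centered (not scaled) and decomposed by singular values. Component
#' signs are fixed by making each component's largest-magnitude gene
#' loading positive.
#'
#' @param x a [pav_matrix()] or binary matrix (genes x samples).
#' @param n_components components to return (default all).
#' @return A list of class `pav_pca`: `scores` (samples x components),
#'   `loadings` (genes x components), `explained_variance` (fractions,
#'   non-increasing), `sdev`.
#' @export
pca_binary <- function(x, n_components = NULL) {
  v <- .pav_values(x)
  if (ncol(v) < 2) .fail("need at least 2 samples")
  if (sum(apply(v, 1, function(r) length(unique(r))) > 1) < 2)
    .fail("need at least 2 variable genes (constant matrix has no variance)")
  p <- prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(n_components %||% ncol(p$x), ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 sdev = p$sdev[seq_len(k)]),
            class = "pav_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pav_pca <- function(x, ...) {
  cat(sprintf("pav_pca: %d components, PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$sdev), 100 * x$explained_variance[1],
              if (length(x$explained_variance) > 1)
                100 * x$explained_variance[2] else NA))
  invisible(x)
}

#' Gene-frequency selection test between two sample groups
#'
#' Per gene, a two-sided Fisher's exact test on the 2x2 presence table,
#' Benjamini-Hochberg correction over all tested genes, and a frequency
#' fold ratio with a half-count continuity correction
#' (eps = 1 / (2 * max(n_a, n_b))) so genes entirely absent in one group
#' still get a finite fold. A gene is selected iff q < `fdr` and
#' fold > `min_fold`. Genes absent in both groups are excluded from
#' testing (count in attribute `n_untested`).
#'
#' @param x a [pav_matrix()] or binary matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param fdr FDR threshold (default 0.001).
#' @param min_fold frequency fold-ratio threshold (default 2).
#' @return `data.frame` with columns `gene_id`, `present_a`, `absent_a`,
#'   `present_b`, `absent_b`, `freq_a`, `freq_b`, `p`, `q`, `fold`,
#'   `higher_in`, `selected`.
#' @export
freq_test <- function(x, group_a, group_b, fdr = 0.001, min_fold = 2) {
  v <- .pav_values(x)
  if (length(intersect(group_a, group_b)))
    .fail("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    .fail("each group needs at least 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(v))
  if (length(missing))
    .fail("samples not in matrix: %s", paste(head(missing, 5), collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  pa <- rowSums(v[, group_a, drop = FALSE])
  pb <- rowSums(v[, group_b, drop = FALSE])
  untested <- pa == 0 & pb == 0
  idx <- which(!untested)
  p <- vapply(idx, function(i) {
    fisher.test(matrix(c(pa[i], na - pa[i], pb[i], nb - pb[i]), 2))$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  fa <- pa[idx] / na; fb <- pb[idx] / nb
  eps <- 1 / (2 * max(na, nb))
  fold <- (pmax(fa, fb) + eps) / (pmin(fa, fb) + eps)
  out <- data.frame(gene_id = rownames(v)[idx],
                    present_a = pa[idx], absent_a = na - pa[idx],
                    present_b = pb[idx], absent_b = nb - pb[idx],
                    freq_a = fa, freq_b = fb, p = p, q = q, fold = fold,
                    higher_in = ifelse(fa >= fb, "a", "b"),
                    selected = q < fdr & fold > min_fold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(untested)
  out
}

#' Breed-specific genes
#'
#' Breeds with fewer than `min_individuals` samples are dropped first. A
#' gene is specific to a breed set iff it is present in at least one
#' retained individual of the set (and in at least `min_inside_fraction` of
#' the set's individuals) and in zero retained individuals outside the
#' set. Genes on `exclusion` (e.g. flagged contaminants) are removed from
#' the result; the number removed is kept in attribute `n_excluded`.
#'
#' @param x a [pav_matrix()] or binary matrix.
#' @param metadata sample metadata with columns `sample_id`, `breed`.
#' @param breed_sets list of character vectors of breed names to test;
#'   default: every retained breed singly.
#' @param min_individuals minimum individuals for a breed to be retained
#'   (default 3).
#' @param exclusion gene ids to drop from the results.
#' @param min_inside_fraction minimum carrier fraction inside the set
#'   (default 0, i.e. one carrier suffices).
#' @return `data.frame` with columns `set`, `gene_id`, `n_carriers`,
#'   `n_in_set`; attributes `n_excluded` and `retained_breeds`.
#' @export
breed_specific <- function(x, metadata, breed_sets = NULL,
                           min_individuals = 3, exclusion = character(),
                           min_inside_fraction = 0) {
  v <- .pav_values(x)
  metadata <- .pav_metadata(x, metadata)
  if (is.null(metadata) || !"breed" %in% names(metadata))
    .fail("metadata with a `breed` column is required")
  metadata <- metadata[metadata$sample_id %in% colnames(v), , drop = FALSE]
  tab <- table(metadata$breed)
  retained <- names(tab)[tab >= min_individuals]
  if (!length(retained)) .fail("no breed retains >= %d individuals",
                               min_individuals)
  meta <- metadata[metadata$breed %in% retained, , drop = FALSE]
  v <- v[, meta$sample_id, drop = FALSE]
  if (is.null(breed_sets)) breed_sets <- as.list(retained)
  rows <- list()
  for (set in breed_sets) {
    unknown <- setdiff(set, retained)
    if (length(unknown))
      .fail("breed set contains non-retained breed(s): %s",
            paste(unknown, collapse = ", "))
    inside <- meta$sample_id[meta$breed %in% set]
    outside <- setdiff(meta$sample_id, inside)
    ci <- rowSums(v[, inside, drop = FALSE])
    co <- if (length(outside)) rowSums(v[, outside, drop = FALSE]) else 0
    hit <- ci >= 1 & co == 0 & ci / length(inside) >= min_inside_fraction
    if (any(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(set = paste(sort(set), collapse = "+"),
                   gene_id = rownames(v)[hit], n_carriers = ci[hit],
                   n_in_set = length(inside), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), gene_id = character(),
                      n_carriers = integer(), n_in_set = integer())
  n_excluded <- sum(out$gene_id %in% exclusion)
  out <- out[!out$gene_id %in% exclusion, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "retained_breeds") <- retained
  out
}

#' Apply a contamination exclusion list to candidate genes
#'
#' @param candidates character vector of candidate gene ids.
#' @param exclusion character vector of gene ids to remove.
#' @return The candidates not on the exclusion list.
#' @export
apply_exclusion <- function(candidates, exclusion) {
  setdiff(candidates, exclusion)
}
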