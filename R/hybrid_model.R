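# Two-haplotype genomic hybridization screen: find individuals that carry
# homozygous copies of population-discriminative genes from BOTH of two
# populations while the other carriers of those genes in their
# high-frequency population are predominantly heterozygous -- the genotype
# pattern expected when a cross-population hybrid inherits one full
# haplotype from each parent population.

#' Infer per-gene copy states from depth ratios
#'
#' For genes called present, the ratio r = gene mean exonic depth / sample
#' baseline depth is compared to a heterozygous band: copy state 2
#' (homozygous present) iff r >= `het_hi`, else 1 (heterozygous). Present
#' genes with r below `het_lo` are still called heterozygous (the presence
#' call dominates); their count is kept in attribute `n_low_ratio`. Absent
#' genes are 0, so collapsing 1,2 -> 1 reproduces the PAV matrix exactly.
#'
#' @param coverage coverage table from [exon_depth()] (needs `gene_id`,
#'   `sample_id`, `mean_depth`).
#' @param pav the [pav_matrix()] for the same genes and samples.
#' @param baseline optional named per-sample baseline depth; default is
#'   each sample's median `mean_depth` over its present genes (must be
#'   > 0).
#' @param het_range length-2 vector `c(het_lo, het_hi)`, default
#'   `c(0.25, 0.75)`.
#' @return A [genotype_matrix()] with provenance `"depth-inferred"`.
#' @export
infer_genotypes <- function(coverage, pav, baseline = NULL,
                            het_range = c(0.25, 0.75)) {
  v <- .pav_values(pav)
  need <- c("gene_id", "sample_id", "mean_depth")
  if (!all(need %in% names(coverage)))
    .fail("coverage needs columns: %s", paste(need, collapse = ", "))
  het_lo <- het_range[1]; het_hi <- het_range[2]
  if (!(het_lo > 0 && het_lo < het_hi && het_hi <= 1.5))
    .fail("invalid het_range")
  dm <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  ok <- coverage$gene_id %in% rownames(v) &
    coverage$sample_id %in% colnames(v)
  cc <- coverage[ok, ]
  dm[cbind(match(cc$gene_id, rownames(v)),
           match(cc$sample_id, colnames(v)))] <- cc$mean_depth
  if (is.null(baseline)) {
    baseline <- vapply(colnames(v), function(s) {
      present <- v[, s] == 1L & !is.na(dm[, s])
      if (!any(present)) return(0)
      median(dm[present, s])
    }, numeric(1))
  }
  if (any(baseline[colnames(v)] <= 0, na.rm = TRUE) ||
      any(is.na(baseline[colnames(v)])))
    .fail("sample baseline depth must be > 0 for every sample")
  r <- sweep(dm, 2, baseline[colnames(v)], "/")
  geno <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  present <- v == 1L
  geno[present] <- ifelse(r[present] >= het_hi, 2L, 1L)
  gm <- genotype_matrix(geno, provenance = "depth-inferred",
                        metadata = .pav_metadata(pav))
  attr(gm, "n_low_ratio") <- sum(present & r < het_lo, na.rm = TRUE)
  attr(gm, "baseline") <- baseline
  gm
}

#' Population-discriminative gene sets from a frequency test
#'
#' @param ft result of [freq_test()] between populations A and B.
#' @return A list `g_a` (selected genes more frequent in A) and `g_b`
#'   (selected genes more frequent in B).
#' @export
discriminative_sets <- function(ft) {
  sel <- ft[ft$selected, , drop = FALSE]
  list(g_a = sel$gene_id[sel$freq_a > sel$freq_b],
       g_b = sel$gene_id[sel$freq_b > sel$freq_a])
}

#' Detect two-haplotype hybridization candidates
#'
#' A sample is a candidate iff there is a gene pair (g_a in `g_a`, g_b in
#' `g_b`) with both genes homozygous-present (copy state 2) in the sample,
#' where among the *other* carriers of g_a in population `pop_a` the
#' heterozygous fraction is at least `het_min`, and likewise for g_b in
#' `pop_b`. The focal sample is excluded from its own carrier background.
#' The score counts all qualifying pairs.
#'
#' @param geno a [genotype_matrix()].
#' @param metadata sample metadata (`sample_id`, `population`); defaults to
#'   the genotype matrix's own metadata.
#' @param g_a,g_b disjoint discriminative gene sets (e.g. from
#'   [discriminative_sets()]).
#' @param pop_a,pop_b population labels whose carriers form the
#'   heterozygosity background for `g_a` and `g_b` respectively.
#' @param het_min minimum carrier-heterozygosity fraction (default 0.5).
#' @return A list: `candidates` (`data.frame`: `sample_id`, `population`,
#'   `score`) and `pairs` (`data.frame`: `sample_id`, `gene_a`, `gene_b`,
#'   `het_frac_a`, `het_frac_b`).
#' @export
detect_hybrids <- function(geno, metadata = NULL, g_a, g_b, pop_a, pop_b,
                           het_min = 0.5) {
  if (!inherits(geno, "genotype_matrix"))
    .fail("`geno` must be a genotype_matrix")
  if (length(intersect(g_a, g_b)))
    .fail("discriminative sets must not overlap")
  metadata <- metadata %||% geno$metadata
  if (is.null(metadata)) .fail("sample metadata is required")
  v <- geno$values
  g_a <- intersect(g_a, rownames(v)); g_b <- intersect(g_b, rownames(v))
  if (!length(g_a) || !length(g_b))
    return(list(candidates = data.frame(sample_id = character(),
                                        population = character(),
                                        score = integer()),
                pairs = data.frame(sample_id = character(),
                                   gene_a = character(),
                                   gene_b = character(),
                                   het_frac_a = numeric(),
                                   het_frac_b = numeric())))
  pop <- setNames(metadata$population, metadata$sample_id)
  unlabeled <- setdiff(colnames(v), names(pop))
  if (length(unlabeled))
    .warnf("%d sample(s) without population label skipped",
           length(unlabeled))
  samples <- setdiff(colnames(v), unlabeled)

  # carrier/het counts per gene within each background population
  bg_counts <- function(genes, p) {
    sub <- v[genes, names(pop)[pop == p & names(pop) %in% colnames(v)],
             drop = FALSE]
    list(car = rowSums(sub >= 1L), het = rowSums(sub == 1L), cols = colnames(sub))
  }
  bga <- bg_counts(g_a, pop_a)
  bgb <- bg_counts(g_b, pop_b)

  het_frac_excl <- function(bg, gene, sample) {
    car <- bg$car[gene]; het <- bg$het[gene]
    if (sample %in% bg$cols) {
      gval <- v[gene, sample]
      if (gval >= 1L) car <- car - 1L
      if (gval == 1L) het <- het - 1L
    }
    if (car == 0) return(NA_real_)
    het / car
  }

  pair_rows <- list(); cand_rows <- list()
  for (s in samples) {
    hom_a <- g_a[v[g_a, s] == 2L]
    hom_b <- g_b[v[g_b, s] == 2L]
    if (!length(hom_a) || !length(hom_b)) next
    fa <- vapply(hom_a, het_frac_excl, numeric(1), bg = bga, sample = s)
    fb <- vapply(hom_b, het_frac_excl, numeric(1), bg = bgb, sample = s)
    qa <- hom_a[!is.na(fa) & fa >= het_min]
    qb <- hom_b[!is.na(fb) & fb >= het_min]
    if (!length(qa) || !length(qb)) next
    grid <- expand.grid(gene_a = qa, gene_b = qb,
                        stringsAsFactors = FALSE)
    grid$sample_id <- s
    grid$het_frac_a <- fa[grid$gene_a]
    grid$het_frac_b <- fb[grid$gene_b]
    pair_rows[[length(pair_rows) + 1L]] <- grid
    cand_rows[[length(cand_rows) + 1L]] <-
      data.frame(sample_id = s, population = unname(pop[s]),
                 score = nrow(grid), stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(sample_id = character(), gene_a = character(),
               gene_b = character(), het_frac_a = numeric(),
               het_frac_b = numeric())
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(sample_id = character(), population = character(),
               score = integer())
  rownames(pairs) <- NULL; rownames(candidates) <- NULL
  list(candidates = candidates,
       pairs = pairs[, c("sample_id", "gene_a", "gene_b",
                         "het_frac_a", "het_frac_b")])
}
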