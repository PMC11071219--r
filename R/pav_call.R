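# Coverage-based gene presence/absence calling: a gene is present in a
# sample iff the fraction of its exonic bases covered by at least `min_cov`
# reads reaches `lost_cutoff` (the SGSGeneLoss rule, minCov = 2,
# lostCutoff = 0.2). The tool's semantics -- lost iff covered fraction is
# below the cutoff, i.e. present iff >= 0.2 -- are used for the boundary.

#' Configuration for presence/absence calling
#'
#' @param min_cov minimum per-base read depth for a base to count as
#'   covered (default 2).
#' @param lost_cutoff minimum covered fraction of the exonic length for the
#'   gene to be called present (default 0.2; below it the gene is lost).
#' @return A `pav_call_config` list.
#' @export
pav_call_config <- function(min_cov = 2, lost_cutoff = 0.2) {
  .check_count(min_cov, "min_cov")
  if (!(lost_cutoff > 0 && lost_cutoff < 1))
    .fail("`lost_cutoff` must lie in (0, 1)")
  structure(list(min_cov = min_cov, lost_cutoff = lost_cutoff),
            class = "pav_call_config")
}

#' Per-gene exonic coverage summaries
#'
#' Counts, per gene and sample, the exonic bases with depth >= `min_cov`.
#' Overlapping exons of one gene are merged (union) so the covered fraction
#' cannot exceed 1. Positions absent from the depth table count as depth 0.
#'
#' @param depth depth table with columns `sample`, `contig`, `pos`
#'   (1-based), `depth`, e.g. from [simulate_depth()] or [read_depth()].
#' @param models gene-model `data.frame` (`gene_id`, `contig`, `start`,
#'   `end`; 0-based half-open exons).
#' @param min_cov minimum depth for a base to count as covered.
#' @return `data.frame` with columns `gene_id`, `sample_id`,
#'   `exon_length_total`, `covered_bases`, `covered_fraction`, `mean_depth`.
#' @export
exon_depth <- function(depth, models, min_cov = 2) {
  depth <- data.table::as.data.table(depth)
  need <- c("sample", "contig", "pos", "depth")
  if (!all(need %in% names(depth)))
    .fail("depth table needs columns: %s", paste(need, collapse = ", "))
  if (any(models$end <= models$start))
    .fail("gene with zero-length exon in models")
  # union of exon intervals per gene
  exon_pos <- data.table::rbindlist(lapply(split(models, models$gene_id),
                                           function(g) {
    ir <- IRanges::reduce(.ir(g$start, g$end))
    data.table::data.table(gene_id = g$gene_id[1], contig = g$contig[1],
                           pos = unlist(Map(seq, IRanges::start(ir),
                                            IRanges::end(ir))))
  }))
  exon_len <- exon_pos[, list(exon_length_total = .N), by = "gene_id"]
  if (any(exon_len$exon_length_total == 0))
    .fail("gene with zero total exon length")
  samples <- unique(depth$sample)
  if (!length(samples)) .fail("depth table is empty")

  dd <- merge(exon_pos, depth, by = c("contig", "pos"),
              allow.cartesian = TRUE)
  covered <- dd[, list(covered_bases = sum(depth >= min_cov),
                       depth_sum = sum(as.numeric(depth))),
                by = c("gene_id", "sample")]
  grid <- data.table::CJ(gene_id = exon_len$gene_id, sample = samples,
                         unique = TRUE)
  out <- merge(grid, covered, by = c("gene_id", "sample"), all.x = TRUE)
  out[is.na(covered_bases), `:=`(covered_bases = 0L, depth_sum = 0)]
  out <- merge(out, exon_len, by = "gene_id")
  empty <- setdiff(samples, unique(dd$sample))
  if (length(empty))
    .warnf("%d sample(s) have no depth over any exon; coverage set to 0",
           length(empty))
  res <- data.frame(gene_id = out$gene_id, sample_id = out$sample,
                    exon_length_total = out$exon_length_total,
                    covered_bases = out$covered_bases,
                    covered_fraction = out$covered_bases /
                      out$exon_length_total,
                    mean_depth = out$depth_sum / out$exon_length_total,
                    stringsAsFactors = FALSE)
  res[order(res$gene_id, res$sample_id), ]
}

#' Call presence from a coverage summary
#'
#' Present (1) iff `covered_fraction >= lost_cutoff`, else absent (0).
#'
#' @param cov coverage `data.frame` from [exon_depth()] (or any table with
#'   a `covered_fraction` column).
#' @param cfg a [pav_call_config()].
#' @return `cov` with an added integer `present` column.
#' @export
call_presence <- function(cov, cfg = pav_call_config()) {
  if (!"covered_fraction" %in% names(cov))
    .fail("`cov` must have a `covered_fraction` column")
  if (any(cov$covered_fraction < 0 | cov$covered_fraction > 1))
    .fail("covered_fraction out of [0, 1]")
  cov$present <- as.integer(cov$covered_fraction >= cfg$lost_cutoff)
  cov
}

#' Assemble presence calls into a binary PAV matrix
#'
#' Rows (genes) and columns (samples) are ordered lexicographically;
#' uncalled (gene, sample) pairs are filled with 0 and counted in a
#' warning.
#'
#' @param calls `data.frame` with columns `gene_id`, `sample_id`,
#'   `present` (from [call_presence()]).
#' @param metadata optional sample metadata.
#' @return A [pav_matrix()].
#' @export
assemble_matrix <- function(calls, metadata = NULL) {
  need <- c("gene_id", "sample_id", "present")
  if (!all(need %in% names(calls)))
    .fail("calls need columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(calls[c("gene_id", "sample_id")]))
    .fail("duplicate (gene, sample) call")
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(calls$sample_id), metadata$sample_id)
    if (length(unknown))
      .fail("calls reference sample(s) missing from metadata: %s",
            paste(head(unknown, 5), collapse = ", "))
    uncalled <- setdiff(metadata$sample_id, unique(calls$sample_id))
    if (length(uncalled))
      .warnf("%d metadata sample(s) have no calls", length(uncalled))
  }
  genes <- sort(unique(calls$gene_id))
  samples <- sort(unique(calls$sample_id))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(calls$gene_id, genes), match(calls$sample_id, samples))] <-
    as.integer(calls$present)
  n_missing <- length(m) - nrow(calls)
  if (n_missing > 0)
    .warnf("%d uncalled (gene, sample) pairs filled with 0", n_missing)
  pav_matrix(m, metadata = metadata)
}

#' Depth-to-PAV convenience pipeline
#'
#' Chains [exon_depth()], [call_presence()] and [assemble_matrix()].
#'
#' @param depth depth table (`sample`, `contig`, `pos`, `depth`).
#' @param models gene-model `data.frame`.
#' @param metadata optional sample metadata.
#' @param cfg a [pav_call_config()].
#' @return A list with `pav` (the [pav_matrix()]) and `coverage` (the
#'   per-gene coverage table including presence calls).
#' @export
call_pav <- function(depth, models, metadata = NULL,
                     cfg = pav_call_config()) {
  cov <- exon_depth(depth, models, min_cov = cfg$min_cov)
  cov <- call_presence(cov, cfg)
  list(pav = assemble_matrix(cov, metadata = metadata), coverage = cov)
}
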