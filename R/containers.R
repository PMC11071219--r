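#' Binary gene presence/absence matrix
#'
#' The central object of the pipeline: a genes-by-samples matrix of 0/1
#' presence calls plus per-sample metadata (breed, population). Row and
#' column names are mandatory and unique; cells are 0 (absent) or
#' 1 (present).
#'
#' @param values integer or numeric matrix with genes as rows and samples as
#'   columns; all entries must be 0 or 1 and dimnames must be set.
#' @param metadata optional `data.frame` with columns `sample_id`, `breed`,
#'   `population` describing the matrix columns.
#' @return An object of class `pav_matrix`: a list with elements `values`
#'   and `metadata`.
#' @examples
#' m <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' pav_matrix(m)
#' @export
pav_matrix <- function(values, metadata = NULL) {
  if (!is.matrix(values)) .fail("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .fail("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values))) .fail("gene ids must be unique")
  if (anyDuplicated(colnames(values))) .fail("sample ids must be unique")
  if (!all(values %in% c(0, 1))) .fail("PAV values must be 0 or 1")
  storage.mode(values) <- "integer"
  if (!is.null(metadata)) {
    if (!all(c("sample_id", "population") %in% names(metadata)))
      .fail("metadata needs at least columns `sample_id` and `population`")
    missing <- setdiff(colnames(values), metadata$sample_id)
    if (length(missing))
      .warnf("%d samples in matrix without metadata rows", length(missing))
    metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(values = values, metadata = metadata),
            class = "pav_matrix")
}

#' @export
as.matrix.pav_matrix <- function(x, ...) x$values

#' @export
dim.pav_matrix <- function(x) dim(x$values)

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("pav_matrix: %d genes x %d samples (%.1f%% present)%s\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$values),
              if (is.null(x$metadata)) "" else ", with metadata"))
  invisible(x)
}

# accept a pav_matrix or a plain binary matrix
.pav_values <- function(x) {
  if (inherits(x, "pav_matrix")) return(x$values)
  if (is.matrix(x)) return(pav_matrix(x)$values)
  .fail("expected a `pav_matrix` or a binary matrix")
}

.pav_metadata <- function(x, metadata = NULL) {
  if (!is.null(metadata)) return(metadata)
  if (inherits(x, "pav_matrix")) return(x$metadata)
  NULL
}

#' Per-gene copy-state (genotype) matrix
#'
#' Genes-by-samples matrix with values 0 (absent), 1 (heterozygous present,
#' one copy) and 2 (homozygous present, two copies). Collapsing 1 and 2 to 1
#' reproduces the binary PAV matrix.
#'
#' @param values integer matrix in \{0, 1, 2\} with dimnames set.
#' @param provenance `"provided"` for externally supplied genotypes or
#'   `"depth-inferred"` for calls made by [infer_genotypes()].
#' @param metadata optional sample metadata as for [pav_matrix()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, provenance = c("provided", "depth-inferred"),
                            metadata = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values)) .fail("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .fail("`values` must have gene row names and sample column names")
  if (!all(values %in% 0:2)) .fail("genotype values must be 0, 1 or 2")
  storage.mode(values) <- "integer"
  structure(list(values = values, provenance = provenance,
                 metadata = metadata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix (%s): %d genes x %d samples\n",
              x$provenance, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Collapse a genotype matrix to a binary PAV matrix
#'
#' @param x a [genotype_matrix()].
#' @return A [pav_matrix()] with 1 wherever the copy state is 1 or 2.
#' @export
collapse_genotypes <- function(x) {
  if (!inherits(x, "genotype_matrix")) .fail("`x` must be a genotype_matrix")
  pav_matrix((x$values >= 1L) * 1L + 0L * x$values, metadata = x$metadata)
}

#' Expression matrix with sample grouping
#'
#' Genes-by-samples abundance values (counts or FPKM) together with a
#' sample-to-group map (tissue, altitude class, ...) and optional gene
#' lengths used for FPKM normalisation.
#'
#' @param values non-negative numeric matrix, genes x samples, dimnames set.
#' @param groups named character vector mapping every sample (column) to a
#'   group label.
#' @param gene_lengths optional named numeric vector of gene lengths in bp.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, gene_lengths = NULL) {
  if (!is.matrix(values)) .fail("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .fail("`values` must have gene row names and sample column names")
  if (any(values < 0)) .fail("expression values must be non-negative")
  if (is.null(names(groups))) .fail("`groups` must be named by sample id")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    .fail("samples without a group label: %s",
          paste(head(missing, 5), collapse = ", "))
  groups <- groups[colnames(values)]
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) .fail("`gene_lengths` must be named")
    if (any(gene_lengths[rownames(values)] <= 0, na.rm = TRUE))
      .fail("gene lengths must be positive")
  }
  structure(list(values = values, groups = groups,
                 gene_lengths = gene_lengths),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %d groups\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

.expr_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values
  else if (is.matrix(x)) x
  else .fail("expected an `expression_matrix` or a matrix")
}
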