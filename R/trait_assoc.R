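# PAV-GWAS by single-marker linear regression with a Bonferroni threshold,
# and gene-CDS-haplotype trait grouping. The marker encoding (binary gene
# presence/absence) and the alpha/m threshold are the essential choices; a
# plain least-squares model (optionally adjusted by PCA covariates) stands
# in for multi-locus GWAS machinery.

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of markers tested (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 2232)  # 2.24e-5 to 3 significant figures
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  .check_count(m, "m")
  .check_fraction(alpha, "alpha")
  alpha / m
}

# OLS fit returning beta, se and two-sided p for the marker column
.ols_marker <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(c(beta = NA, se = NA, p = NA))
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df <= 0) return(c(beta = NA, se = NA, p = NA))
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- beta[2] / se
  c(beta = unname(beta[2]), se = se, p = 2 * pt(-abs(tval), df))
}

#' PAV-GWAS by single-marker regression
#'
#' Fits, per marker, `trait ~ presence (+ covariates)` by least squares and
#' reports the presence coefficient's two-sided t-test p-value. Markers
#' with occupancy 0 or 1 within the tested samples are dropped (counted in
#' attribute `n_dropped`); the Bonferroni threshold uses the number of
#' markers actually tested. Typically run on the shell-gene PAVs.
#'
#' @param x a [pav_matrix()] or binary matrix (markers x samples).
#' @param trait `data.frame` with columns `sample_id`, `trait`; every
#'   trait sample must be a column of `x`.
#' @param covariates optional numeric matrix (samples x k), e.g. the top
#'   PCA coordinates from [pca_binary()]; collinear columns are dropped
#'   with a warning.
#' @param alpha family-wise error rate (default 0.05).
#' @return `data.frame` with columns `marker`, `beta`, `se`, `p`,
#'   `significant`; attributes `m`, `threshold`, `n_dropped`.
#' @export
gwas_pav <- function(x, trait, covariates = NULL, alpha = 0.05) {
  v <- .pav_values(x)
  need <- c("sample_id", "trait")
  if (!all(need %in% names(trait)))
    .fail("trait needs columns: %s", paste(need, collapse = ", "))
  missing <- setdiff(trait$sample_id, colnames(v))
  if (length(missing))
    .fail("trait sample(s) not in the PAV matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  if (nrow(trait) < 10) .fail("need at least 10 samples with a trait value")
  v <- v[, trait$sample_id, drop = FALSE]
  y <- trait$trait
  covs <- NULL
  if (!is.null(covariates)) {
    covs <- as.matrix(covariates)[trait$sample_id, , drop = FALSE]
    full <- cbind(1, covs)
    r <- qr(full)$rank
    if (r < ncol(full)) {
      keep <- qr(full)$pivot[seq_len(r)][-1] - 1L
      .warnf("dropping %d collinear covariate(s)", ncol(covs) - length(keep))
      covs <- covs[, keep, drop = FALSE]
      if (!ncol(covs)) covs <- NULL
    }
  }
  occ <- rowMeans(v)
  variable <- occ > 0 & occ < 1
  n_dropped <- sum(!variable)
  v <- v[variable, , drop = FALSE]
  m <- nrow(v)
  if (m == 0) .fail("no variable markers to test")
  threshold <- bonferroni_threshold(alpha, m)
  fits <- t(vapply(seq_len(m), function(i) {
    X <- cbind(1, v[i, ])
    if (!is.null(covs)) X <- cbind(X, covs)
    .ols_marker(y, X)
  }, c(beta = 0, se = 0, p = 0)))
  out <- data.frame(marker = rownames(v), beta = fits[, "beta"],
                    se = fits[, "se"], p = fits[, "p"],
                    significant = fits[, "p"] < threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Gene-CDS-haplotype trait grouping
#'
#' Groups samples by exact identity of their per-gene CDS allele string
#' (phased haplotype or collapsed genotype string), reports per-group trait
#' means, suppresses groups smaller than `min_n` from the report (still
#' counted), and optionally runs a Kruskal-Wallis test across the retained
#' groups of each gene. Samples whose string contains a missing-site code
#' (`.` or `N`) are excluded and counted.
#'
#' @param haps `data.frame` with columns `gene`, `sample_id`, `hap`
#'   (allele strings; equal length within a gene).
#' @param trait `data.frame` with columns `sample_id`, `trait`.
#' @param min_n minimum group size reported (default 10).
#' @param test if `TRUE`, run Kruskal-Wallis across retained groups per
#'   gene (needs >= 2 retained groups).
#' @return `data.frame` with columns `gene`, `haplotype` (label `Hap_k` by
#'   decreasing group size), `hap_string`, `n`, `trait_mean`, `retained`;
#'   attributes `n_excluded` (samples with missing sites) and `tests`
#'   (per-gene Kruskal-Wallis p-values, if requested).
#' @export
gchap_group <- function(haps, trait, min_n = 10, test = TRUE) {
  need <- c("gene", "sample_id", "hap")
  if (!all(need %in% names(haps)))
    .fail("haps needs columns: %s", paste(need, collapse = ", "))
  tr <- setNames(trait$trait, trait$sample_id)
  rows <- list(); tests <- list(); n_excluded <- 0L
  for (g in unique(haps$gene)) {
    h <- haps[haps$gene == g, , drop = FALSE]
    if (length(unique(nchar(h$hap))) != 1)
      .fail("unequal haplotype string lengths for gene `%s`", g)
    miss <- grepl("[.N]", h$hap)
    n_excluded <- n_excluded + sum(miss)
    h <- h[!miss, , drop = FALSE]
    if (!nrow(h)) next
    grp <- split(h$sample_id, h$hap)
    sizes <- vapply(grp, length, 1L)
    ord <- order(-sizes, names(grp))
    grp <- grp[ord]; sizes <- sizes[ord]
    df <- data.frame(gene = g,
                     haplotype = sprintf("Hap_%d", seq_along(grp)),
                     hap_string = names(grp), n = sizes,
                     trait_mean = vapply(grp, function(s)
                       mean(tr[s], na.rm = TRUE), numeric(1)),
                     retained = sizes >= min_n,
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- df
    if (test) {
      keep <- df$retained
      if (sum(keep) >= 2) {
        vals <- lapply(grp[keep], function(s) tr[s])
        ok <- !vapply(vals, function(x) all(is.na(x)), logical(1))
        if (sum(ok) >= 2) {
          kw <- kruskal.test(vals[ok])
          tests[[length(tests) + 1L]] <-
            data.frame(gene = g, kw_p = kw$p.value)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), haplotype = character(),
                      hap_string = character(), n = integer(),
                      trait_mean = numeric(), retained = logical())
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  if (test)
    attr(out, "tests") <- if (length(tests)) do.call(rbind, tests) else
      data.frame(gene = character(), kw_p = numeric())
  out
}
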