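# Readers and writers for the plain-text formats the pipeline exchanges.
# Genome sequence goes through Biostrings, gene models through rtracklayer;
# coords/PAF alignment tables and the depth/PAV/metadata tables are simple
# TSV/CSV handled here.

#' Read pairwise alignment blocks from a coords-style TSV
#'
#' Expected columns (header optional, this order without one):
#' `ref_start ref_end qry_start qry_end identity ref_contig qry_contig`.
#' Identities given as percentages (as `show-coords` prints) are rescaled
#' to fractions. Coordinates are interpreted as 1-based inclusive on disk
#' and converted to 0-based half-open.
#'
#' @param path path to the TSV file.
#' @return A normalized alignment-block `data.frame`
#'   (see [alignment_blocks()]).
#' @export
read_coords <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("ref_start", first, fixed = TRUE)
  cols <- c("ref_start", "ref_end", "qry_start", "qry_end",
            "identity", "ref_contig", "qry_contig")
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < length(cols)) .fail("coords file needs %d columns", length(cols))
    names(df)[seq_along(cols)] <- cols
  }
  # disk is 1-based inclusive
  df$ref_start <- df$ref_start - 1L
  df$qry_start <- df$qry_start - 1L
  alignment_blocks(df)
}

#' Write alignment blocks as a coords-style TSV
#'
#' @param blocks normalized alignment-block `data.frame`.
#' @param path output path.
#' @export
write_coords <- function(blocks, path) {
  out <- data.frame(ref_start = blocks$ref_start + 1L,
                    ref_end = blocks$ref_end,
                    qry_start = blocks$qry_start + 1L,
                    qry_end = blocks$qry_end,
                    identity = blocks$identity,
                    ref_contig = blocks$ref_contig,
                    qry_contig = blocks$qry_contig)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignment blocks from a PAF file
#'
#' Parses the 12 mandatory PAF columns; `identity` is the number of matching
#' bases divided by the alignment block length. PAF coordinates are already
#' 0-based half-open. When a record carries a CIGAR (`cg:Z:` tag, as written
#' by `minimap2 -c`) and `split_at` is finite, the alignment is split into
#' separate blocks at insertions/deletions of at least `split_at` bp, the
#' way coords-style whole-genome alignments report indel-free stretches as
#' individual blocks; per-block identity is then recomputed from the CIGAR.
#'
#' @param path path to a PAF file (as written by minimap2).
#' @param split_at minimum indel length (bp) at which to split a record
#'   into blocks; `Inf` disables splitting.
#' @return A normalized alignment-block `data.frame`.
#' @export
read_paf <- function(path, split_at = 100) {
  lines <- readLines(path)
  empty <- data.frame(ref_contig = character(),
                      ref_start = integer(), ref_end = integer(),
                      qry_contig = character(),
                      qry_start = integer(), qry_end = integer(),
                      identity = numeric(), orientation = character())
  if (length(lines) == 0L) return(alignment_blocks(empty))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, 1L) < 12L
  if (any(bad)) .warnf("skipping %d malformed PAF records", sum(bad))
  f <- f[!bad]
  if (!length(f)) return(alignment_blocks(empty))
  rows <- lapply(f, function(x) {
    rec <- data.frame(qry_contig = x[1],
                      qry_start = as.integer(x[3]),
                      qry_end = as.integer(x[4]),
                      orientation = if (x[5] == "-") "reverse" else "forward",
                      ref_contig = x[6],
                      ref_start = as.integer(x[8]),
                      ref_end = as.integer(x[9]),
                      identity = as.numeric(x[10]) /
                        max(1, as.numeric(x[11])),
                      stringsAsFactors = FALSE)
    cg <- grep("^cg:Z:", x[-(1:12)], value = TRUE)
    if (!length(cg) || !is.finite(split_at)) return(rec)
    .split_cigar(rec, substring(cg[1], 6), split_at)
  })
  alignment_blocks(do.call(rbind, rows))
}

# split one PAF record at indels >= split_at, recomputing block identity
# from the CIGAR (M/=/X consume both sequences, I query only, D ref only)
.split_cigar <- function(rec, cigar, split_at) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  q <- 0L; r <- 0L          # offsets in alignment order
  bq0 <- 0L; br0 <- 0L      # current block origin
  match_n <- 0L; tot_n <- 0L
  out <- list()
  flush <- function(q1, r1) {
    if (tot_n > 0L && q1 > bq0 && r1 > br0) {
      qs <- if (rec$orientation == "reverse")
        c(rec$qry_end - q1, rec$qry_end - bq0)
      else c(rec$qry_start + bq0, rec$qry_start + q1)
      out[[length(out) + 1L]] <<- data.frame(
        qry_contig = rec$qry_contig, qry_start = qs[1], qry_end = qs[2],
        orientation = rec$orientation, ref_contig = rec$ref_contig,
        ref_start = rec$ref_start + br0, ref_end = rec$ref_start + r1,
        identity = match_n / tot_n, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(op)) {
    o <- op[i]; l <- len[i]
    if (o %in% c("M", "=", "X")) {
      match_n <- match_n + if (o == "X") 0L else l
      tot_n <- tot_n + l
      q <- q + l; r <- r + l
    } else if (o == "I") {
      if (l >= split_at) {
        flush(q, r); q <- q + l; bq0 <- q; br0 <- r
        match_n <- 0L; tot_n <- 0L
      } else { tot_n <- tot_n + l; q <- q + l }
    } else if (o %in% c("D", "N")) {
      if (l >= split_at) {
        flush(q, r); r <- r + l; bq0 <- q; br0 <- r
        match_n <- 0L; tot_n <- 0L
      } else { tot_n <- tot_n + l; r <- r + l }
    }
    # S/H/P consume nothing within the aligned interval
  }
  flush(q, r)
  if (!length(out)) return(rec[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Write a binary PAV matrix as TSV
#'
#' Genes as rows, samples as columns, first column `gene_id`, cells 0/1.
#'
#' @param x a [pav_matrix()] or binary matrix.
#' @param path output path.
#' @export
write_pav_matrix <- function(x, path) {
  v <- .pav_values(x)
  out <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary PAV matrix from TSV
#'
#' @param path path to a TSV written by [write_pav_matrix()].
#' @param metadata optional sample metadata `data.frame`.
#' @return A [pav_matrix()].
#' @export
read_pav_matrix <- function(path, metadata = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  pav_matrix(m, metadata = metadata)
}

#' Write sample metadata as CSV
#'
#' @param metadata `data.frame` with columns `sample_id`, `breed`,
#'   `population`.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path path to a CSV with columns `sample_id`, `breed`, `population`.
#' @return A `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(df)))
    .fail("metadata must have columns: %s", paste(need, collapse = ", "))
  df
}

#' Write a per-base depth track as TSV
#'
#' Columns `sample`, `contig`, `pos` (1-based), `depth`.
#'
#' @param depth depth `data.frame`/`data.table` as produced by
#'   [simulate_depth()].
#' @param path output path.
#' @export
write_depth <- function(depth, path) {
  data.table::fwrite(as.data.table(depth), path, sep = "\t")
  invisible(path)
}

#' Read a per-base depth track from TSV
#'
#' @param path path to a TSV written by [write_depth()] (or equivalent
#'   `sample contig pos depth` table, positions 1-based).
#' @return A `data.table` with columns `sample`, `contig`, `pos`, `depth`.
#' @export
read_depth <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample", "contig", "pos", "depth")
  if (!all(need %in% names(dt)))
    .fail("depth table must have columns: %s", paste(need, collapse = ", "))
  dt[, need, with = FALSE]
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene plus its `exon` children. Internal
#' coordinates are 0-based half-open and are written 1-based inclusive.
#'
#' @param models gene-model `data.frame` with columns `gene_id`, `contig`,
#'   `start`, `end` (one row per exon, 0-based half-open).
#' @param path output path (`.gff3`).
#' @export
write_gene_models <- function(models, path) {
  spans <- do.call(rbind, lapply(split(models, models$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
               start = min(g$start), end = max(g$end))
  }))
  gene_gr <- GenomicRanges_make(spans$contig, spans$start, spans$end,
                                type = "gene", id = spans$gene_id,
                                parent = NA_character_)
  exon_gr <- GenomicRanges_make(models$contig, models$start, models$end,
                                type = "exon",
                                id = paste0(models$gene_id, ".e",
                                            seq_len(nrow(models))),
                                parent = models$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

# build a GRanges with GFF-ish metadata columns (internal)
GenomicRanges_make <- function(contig, start0, end0, type, id, parent) {
  gr <- methods::as(
    S4Vectors_df_to_ranges(contig, start0, end0), "GRanges")
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- parent
  gr
}

S4Vectors_df_to_ranges <- function(contig, start0, end0) {
  GenomicRanges::GRanges(seqnames = contig, ranges = .ir(start0, end0))
}

#' Read gene models from GFF3
#'
#' Uses exon features grouped by their `Parent` (falling back to `ID` for
#' exon-less gene rows). Returns 0-based half-open exon intervals.
#'
#' @param path path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `contig`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_exon <- mc$type == "exon"
  if (any(is_exon)) {
    sub <- gr[is_exon]
    parent <- as.character(S4Vectors::mcols(sub)$Parent)
    gid <- sub("^.*:", "", parent)
  } else {
    sub <- gr[mc$type == "gene"]
    gid <- as.character(S4Vectors::mcols(sub)$ID)
  }
  data.frame(gene_id = gid,
             contig = as.character(GenomicRanges::seqnames(sub)),
             start = GenomicRanges::start(sub) - 1L,
             end = GenomicRanges::end(sub),
             stringsAsFactors = FALSE)
}

#' Read a numeric genes-by-samples matrix from TSV
#'
#' First column is the gene id; remaining columns are samples.
#'
#' @param path path to the TSV.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a numeric genes-by-samples matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name for the first (gene id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  out <- data.frame(rownames(m), m, check.names = FALSE)
  names(out)[1] <- id_col
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
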