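# Iterative construction of the nonreference sequence set. Each genome is
# aligned to the current pan-reference; one-to-one filtered alignments
# define covered query regions, their complement yields candidate
# nonreference segments, candidates are realigned and deduplicated, and the
# survivors are appended to the pan-reference for the next round. A final
# pass realigns everything to the original reference to remove residual
# redundancy.

#' Configuration for the pangenome-construction loop
#'
#' Defaults follow the standard map-to-pan filtering recipe: alignments are
#' kept at identity >= 0.95 and length >= 100 bp; a candidate nonreference
#' segment is discarded when more than 90% of its length realigns to the
#' pan-reference at a (length-weighted) mean identity exceeding 95%; a gene
#' is called novel when at least 80% of its span lies in nonreference
#' sequence.
#'
#' @param min_identity minimum alignment identity kept (fraction).
#' @param min_aln_length minimum alignment length kept (bp).
#' @param dedupe_coverage aligned-fraction threshold above which a candidate
#'   is considered redundant (strict `>`).
#' @param dedupe_identity mean-identity threshold above which a candidate is
#'   considered redundant (strict `>`).
#' @param novel_overlap minimum fraction of a gene span overlapping
#'   nonreference sequence for the gene to be called novel (`>=`).
#' @param min_segment_length minimum retained nonreference segment length (bp).
#' @return A `pan_build_config` list.
#' @export
pan_build_config <- function(min_identity = 0.95, min_aln_length = 100,
                             dedupe_coverage = 0.90, dedupe_identity = 0.95,
                             novel_overlap = 0.80, min_segment_length = 100) {
  .check_fraction(min_identity, "min_identity")
  .check_fraction(dedupe_coverage, "dedupe_coverage")
  .check_fraction(dedupe_identity, "dedupe_identity")
  .check_fraction(novel_overlap, "novel_overlap")
  .check_count(min_aln_length, "min_aln_length")
  .check_count(min_segment_length, "min_segment_length")
  structure(list(min_identity = min_identity,
                 min_aln_length = min_aln_length,
                 dedupe_coverage = dedupe_coverage,
                 dedupe_identity = dedupe_identity,
                 novel_overlap = novel_overlap,
                 min_segment_length = min_segment_length),
            class = "pan_build_config")
}

#' Normalize a table of pairwise alignment blocks
#'
#' Ensures start < end on both sides (0-based half-open), identity in
#' [0, 1] (percent identities are rescaled), recomputes `length` as the
#' query span, and drops malformed records with a warning (count kept in
#' attribute `n_skipped`).
#'
#' @param df `data.frame` with columns `ref_contig`, `ref_start`, `ref_end`,
#'   `qry_contig`, `qry_start`, `qry_end`, `identity` and optionally
#'   `orientation`.
#' @return The normalized `data.frame` with an added `length` column.
#' @export
alignment_blocks <- function(df) {
  need <- c("ref_contig", "ref_start", "ref_end", "qry_contig",
            "qry_start", "qry_end", "identity")
  if (!all(need %in% names(df)))
    .fail("alignment blocks need columns: %s", paste(need, collapse = ", "))
  if (is.null(df$orientation)) df$orientation <- "forward"
  num <- c("ref_start", "ref_end", "qry_start", "qry_end", "identity")
  for (cc in num) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- !stats::complete.cases(df[num]) |
    df$ref_start == df$ref_end | df$qry_start == df$qry_end |
    df$identity < 0
  if (any(bad)) {
    .warnf("skipping %d malformed alignment records", sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  swap <- df$ref_start > df$ref_end
  tmp <- df$ref_start[swap]; df$ref_start[swap] <- df$ref_end[swap]
  df$ref_end[swap] <- tmp
  swap <- df$qry_start > df$qry_end
  tmp <- df$qry_start[swap]; df$qry_start[swap] <- df$qry_end[swap]
  df$qry_end[swap] <- tmp
  if (any(df$identity > 1)) df$identity <- df$identity / 100
  df$length <- df$qry_end - df$qry_start
  rownames(df) <- NULL
  structure(df, n_skipped = sum(bad))
}

#' Filter alignment blocks to a one-to-one set
#'
#' Drops blocks below the identity/length thresholds, then, per query
#' contig, greedily selects a non-overlapping (in query coordinates) subset
#' by decreasing length, breaking ties by identity and then input order.
#'
#' @param blocks normalized alignment blocks (see [alignment_blocks()]).
#' @param cfg a [pan_build_config()].
#' @return The retained subset of `blocks`.
#' @export
filter_alignments <- function(blocks, cfg = pan_build_config()) {
  blocks <- alignment_blocks(blocks)
  keep <- blocks$identity >= cfg$min_identity &
    blocks$length >= cfg$min_aln_length
  blocks <- blocks[keep, , drop = FALSE]
  if (!nrow(blocks)) return(blocks)
  picked <- logical(nrow(blocks))
  for (ctg in unique(blocks$qry_contig)) {
    idx <- which(blocks$qry_contig == ctg)
    ord <- idx[order(-blocks$length[idx], -blocks$identity[idx], idx)]
    kept_ir <- IRanges::IRanges()
    for (i in ord) {
      ir <- .ir(blocks$qry_start[i], blocks$qry_end[i])
      if (!length(IRanges::findOverlaps(ir, kept_ir))) {
        picked[i] <- TRUE
        kept_ir <- c(kept_ir, ir)
      }
    }
  }
  out <- blocks[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regions of the query genome absent from the reference
#'
#' Per query contig, the set complement of the union of kept alignment
#' intervals, filtered to a minimum segment length.
#'
#' @param qry_lengths named vector of query contig lengths.
#' @param blocks kept alignment blocks (query coordinates used).
#' @param min_segment_length minimum reported interval length (bp).
#' @return `data.frame` with columns `qry_contig`, `start`, `end`, `length`
#'   (0-based half-open).
#' @export
absent_regions <- function(qry_lengths, blocks,
                           min_segment_length = 100) {
  if (is.null(names(qry_lengths))) .fail("`qry_lengths` must be named")
  unknown <- setdiff(unique(blocks$qry_contig), names(qry_lengths))
  if (length(unknown))
    .fail("alignment blocks reference unknown contig(s): %s",
          paste(unknown, collapse = ", "))
  out <- lapply(names(qry_lengths), function(ctg) {
    len <- qry_lengths[[ctg]]
    b <- blocks[blocks$qry_contig == ctg, , drop = FALSE]
    if (nrow(b) && any(b$qry_end > len))
      .fail("alignment block exceeds length of contig `%s`", ctg)
    covered <- if (nrow(b)) IRanges::reduce(.ir(b$qry_start, b$qry_end))
               else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), covered)
    df <- .from_ir(gaps)
    if (!nrow(df)) return(NULL)
    df$qry_contig <- ctg
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(qry_contig = character(), start = integer(),
                      end = integer(), length = integer()))
  out$length <- out$end - out$start
  out <- out[out$length >= min_segment_length,
             c("qry_contig", "start", "end", "length")]
  rownames(out) <- NULL
  out
}

#' Remove candidate segments redundant with the pan-reference
#'
#' A candidate is removed iff the union of its realignments covers a
#' fraction of its length strictly greater than `dedupe_coverage` AND the
#' length-weighted mean identity of those realignments strictly exceeds
#' `dedupe_identity`. Candidates with no realignment record are retained as
#' fully novel.
#'
#' @param candidates `data.frame` with at least columns `segment_id` and
#'   `length`.
#' @param realignments alignment blocks whose `qry_contig` values are
#'   candidate `segment_id`s.
#' @param cfg a [pan_build_config()].
#' @return The retained rows of `candidates`, with added columns
#'   `aligned_fraction` and `mean_identity`.
#' @export
dedupe_nonref <- function(candidates, realignments, cfg = pan_build_config()) {
  if (!nrow(candidates)) return(candidates)
  realignments <- alignment_blocks(realignments)
  af <- numeric(nrow(candidates)); mi <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    b <- realignments[realignments$qry_contig == candidates$segment_id[i], ,
                      drop = FALSE]
    if (!nrow(b)) { af[i] <- 0; mi[i] <- 0; next }
    af[i] <- .union_width(b$qry_start, b$qry_end) / candidates$length[i]
    mi[i] <- sum(b$identity * b$length) / sum(b$length)
  }
  candidates$aligned_fraction <- af
  candidates$mean_identity <- mi
  drop <- af > cfg$dedupe_coverage & mi > cfg$dedupe_identity
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' minimap2-based aligner hook
#'
#' Returns a function `(query, target) -> alignment blocks` that shells out
#' to minimap2 (`-c` for base-level alignment) and parses the PAF output.
#' Both arguments must be `DNAStringSet`s. Deterministic for fixed inputs.
#'
#' @param preset minimap2 preset (`-x`), default `"asm5"` for
#'   closely related assemblies.
#' @param extra_args additional command-line arguments.
#' @param split_at indel length (bp) at which records are split into
#'   separate blocks (see [read_paf()]).
#' @return A function usable as the `aligner` of [iterate_pan()].
#' @export
minimap2_hook <- function(preset = "asm5", extra_args = character(),
                          split_at = 100) {
  if (Sys.which("minimap2") == "")
    .fail("minimap2 not found on PATH")
  function(query, target) {
    qf <- tempfile(fileext = ".fa"); tf <- tempfile(fileext = ".fa")
    pf <- tempfile(fileext = ".paf")
    on.exit(unlink(c(qf, tf, pf)), add = TRUE)
    Biostrings::writeXStringSet(query, qf)
    Biostrings::writeXStringSet(target, tf)
    status <- system2("minimap2",
                      c("-x", preset, "-c", "--eqx", extra_args, tf, qf),
                      stdout = pf, stderr = FALSE)
    if (status != 0) .fail("minimap2 failed with status %d", status)
    read_paf(pf, split_at = split_at)
  }
}

#' Iterative nonreference-sequence extraction
#'
#' For each genome in input order: align to the current pan-reference,
#' filter to one-to-one blocks, extract unaligned (absent) regions as
#' candidate segments, realign candidates to the pan-reference and drop
#' redundant ones, and append the survivors to the pan-reference for the
#' next round. After the last round every retained segment is realigned to
#' the original reference and deduplicated once more.
#'
#' @param genomes named list of `DNAStringSet`s, processed in order.
#' @param reference `DNAStringSet`, the reference genome.
#' @param aligner function `(query, target) -> alignment blocks`; see
#'   [minimap2_hook()].
#' @param cfg a [pan_build_config()].
#' @return A list with `nonref` (`DNAStringSet` of retained segments),
#'   `segments` (`data.frame`: `segment_id`, `source_genome`, `qry_contig`,
#'   `start`, `end`, `length`, `round`) and `report` (per-round counts).
#' @export
iterate_pan <- function(genomes, reference, aligner = minimap2_hook(),
                        cfg = pan_build_config()) {
  if (is.null(names(genomes))) .fail("`genomes` must be a named list")
  pan <- reference
  seqs <- Biostrings::DNAStringSet()
  segs <- list(); report <- list()
  for (k in seq_along(genomes)) {
    gname <- names(genomes)[k]
    genome <- genomes[[k]]
    blocks <- tryCatch(aligner(genome, pan), error = function(e)
      .fail("aligner failed in round %d (%s): %s", k, gname,
            conditionMessage(e)))
    kept <- filter_alignments(blocks, cfg)
    regions <- absent_regions(setNames(Biostrings::width(genome),
                                       names(genome)),
                              kept, cfg$min_segment_length)
    cand_seq <- Biostrings::DNAStringSet()
    if (nrow(regions)) {
      regions$segment_id <- sprintf("nr|%s|%s|%d-%d", gname,
                                    regions$qry_contig, regions$start,
                                    regions$end)
      regions$source_genome <- gname
      regions$round <- k
      cand_seq <- Biostrings::DNAStringSet(vapply(
        seq_len(nrow(regions)),
        function(i) as.character(
          Biostrings::subseq(genome[[regions$qry_contig[i]]],
                             regions$start[i] + 1L, regions$end[i])),
        character(1)))
      names(cand_seq) <- regions$segment_id
      realn <- aligner(cand_seq, pan)
      retained <- dedupe_nonref(regions, realn, cfg)
    } else retained <- regions
    if (nrow(retained)) {
      keep_seq <- cand_seq[retained$segment_id]
      seqs <- c(seqs, keep_seq)
      pan <- c(pan, keep_seq)
      segs[[k]] <- retained
    }
    report[[k]] <- data.frame(round = k, genome = gname,
                              n_blocks = nrow(blocks), n_kept = nrow(kept),
                              n_candidates = nrow(regions),
                              n_retained = nrow(retained),
                              bases_retained = sum(retained$length))
  }
  segments <- do.call(rbind, segs)
  if (is.null(segments))
    segments <- data.frame(qry_contig = character(), start = integer(),
                           end = integer(), length = integer(),
                           segment_id = character(),
                           source_genome = character(), round = integer())
  # final pass: remove residual redundancy against the original reference
  if (length(seqs)) {
    realn <- aligner(seqs, reference)
    segments <- dedupe_nonref(segments, realn, cfg)
    seqs <- seqs[segments$segment_id]
  }
  cols <- c("segment_id", "source_genome", "qry_contig", "start", "end",
            "length", "round")
  segments <- segments[, intersect(cols, names(segments)), drop = FALSE]
  list(nonref = seqs, segments = segments,
       report = do.call(rbind, report))
}

#' Call novel genes from nonreference segments
#'
#' A gene is novel iff the overlap of its span with the union of
#' nonreference segments on its genome, divided by the span length, is at
#' least `cfg$novel_overlap`. Genes from different genomes landing on the
#' same pan segment are collapsed into one record when their pan-coordinate
#' intervals reciprocally overlap by at least `cfg$novel_overlap`.
#'
#' @param gene_models `data.frame` with columns `genome`, `gene_id`,
#'   `contig`, `start`, `end` (gene spans, 0-based half-open, on
#'   assembled-genome coordinates).
#' @param segments segment table from [iterate_pan()].
#' @param cfg a [pan_build_config()].
#' @return `data.frame` of novel genes with columns `gene_id`, `genome`,
#'   `contig`, `start`, `end`, `overlap_fraction`, `pan_segment`,
#'   `pan_start`, `pan_end`, `cluster`, `representative`.
#' @export
call_novel_genes <- function(gene_models, segments,
                             cfg = pan_build_config()) {
  need <- c("genome", "gene_id", "contig", "start", "end")
  if (!all(need %in% names(gene_models)))
    .fail("gene_models needs columns: %s", paste(need, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    segs <- segments[segments$source_genome == g$genome &
                       segments$qry_contig == g$contig, , drop = FALSE]
    if (!nrow(segs)) next   # no nonreference sequence on this contig

    span <- g$end - g$start
    seg_ir <- IRanges::reduce(.ir(segs$start, segs$end))
    ov <- IRanges::intersect(seg_ir, .ir(g$start, g$end))
    frac <- sum(IRanges::width(ov)) / span
    if (frac < cfg$novel_overlap) next
    # locate the gene on the pan segment with the largest overlap
    hits <- IRanges::findOverlaps(.ir(g$start, g$end),
                                  .ir(segs$start, segs$end))
    if (!length(hits)) next
    widths <- IRanges::width(IRanges::overlapsRanges(
      .ir(g$start, g$end), .ir(segs$start, segs$end), hits))
    best <- segs[S4Vectors::subjectHits(hits)[which.max(widths)], ]
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = g$gene_id, genome = g$genome, contig = g$contig,
                 start = g$start, end = g$end, overlap_fraction = frac,
                 pan_segment = best$segment_id,
                 pan_start = max(0L, g$start - best$start),
                 pan_end = min(best$length, g$end - best$start),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), genome = character(),
                      contig = character(), start = integer(),
                      end = integer(), overlap_fraction = numeric(),
                      pan_segment = character(), pan_start = integer(),
                      pan_end = integer(), cluster = integer(),
                      representative = logical()))
  # collapse duplicates across genomes by reciprocal overlap on pan coords
  out$cluster <- NA_integer_
  cl <- 0L
  for (seg in unique(out$pan_segment)) {
    idx <- which(out$pan_segment == seg)
    for (i in idx) {
      if (!is.na(out$cluster[i])) next
      cl <- cl + 1L
      out$cluster[i] <- cl
      for (j in idx[idx > i]) {
        if (!is.na(out$cluster[j])) next
        ov <- min(out$pan_end[i], out$pan_end[j]) -
          max(out$pan_start[i], out$pan_start[j])
        if (ov <= 0) next
        ri <- ov / (out$pan_end[i] - out$pan_start[i])
        rj <- ov / (out$pan_end[j] - out$pan_start[j])
        if (ri >= cfg$novel_overlap && rj >= cfg$novel_overlap)
          out$cluster[j] <- cl
      }
    }
  }
  out$representative <- !duplicated(out$cluster)
  rownames(out) <- NULL
  out
}
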