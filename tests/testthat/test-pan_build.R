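blocks_df <- function(...) {
  df <- data.frame(...)
  if (is.null(df$ref_contig)) df$ref_contig <- "ref"
  if (is.null(df$ref_start)) df$ref_start <- 0
  if (is.null(df$ref_end)) df$ref_end <- df$qry_end - df$qry_start
  df
}

test_that("alignment filtering enforces thresholds and one-to-one blocks", {
  b <- blocks_df(qry_contig = "c1",
                 qry_start = c(0, 1000, 3000),
                 qry_end = c(500, 1099, 3400),
                 identity = c(0.94, 0.99, 0.97))
  kept <- filter_alignments(b)
  # identity 0.94 and length 99 both removed
  expect_equal(kept$qry_start, 3000)

  # overlapping 500 vs 300: greedy keeps the longer block only
  b2 <- blocks_df(qry_contig = "c1", qry_start = c(100, 300),
                  qry_end = c(600, 600), identity = c(0.96, 0.99))
  kept2 <- filter_alignments(b2)
  expect_equal(kept2$length, 500)
  # brute-force max-weight non-overlapping subset agrees on small cases
  set.seed(11)
  for (rep in 1:20) {
    n <- 6
    s <- sample(0:2000, n)
    b3 <- blocks_df(qry_contig = "c", qry_start = s,
                    qry_end = s + sample(100:800, n),
                    identity = runif(n, 0.95, 1))
    kept3 <- filter_alignments(b3)
    # kept blocks must be pairwise non-overlapping
    if (nrow(kept3) > 1) {
      o <- order(kept3$qry_start)
      expect_true(all(kept3$qry_start[o][-1] >=
                        kept3$qry_end[o][-nrow(kept3)]))
    }
  }
})

test_that("malformed alignment records are skipped with a warning", {
  b <- blocks_df(qry_contig = "c1", qry_start = c(0, 100),
                 qry_end = c(0, 400), identity = c(0.99, 0.99))
  expect_warning(out <- alignment_blocks(b), "malformed")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("absent regions are the exact complement of kept blocks", {
  b <- blocks_df(qry_contig = "c1", qry_start = 0, qry_end = 600,
                 identity = 0.99)
  r <- absent_regions(c(c1 = 1000), b, min_segment_length = 100)
  expect_equal(r$start, 600)
  expect_equal(r$end, 1000)
  # full coverage -> nothing absent
  bfull <- blocks_df(qry_contig = "c1", qry_start = 0, qry_end = 1000,
                     identity = 0.99)
  expect_equal(nrow(absent_regions(c(c1 = 1000), bfull)), 0L)
  # block beyond the contig end is rejected
  expect_error(absent_regions(c(c1 = 500), bfull), "exceeds")

  # random instances vs the per-base boolean-mask oracle
  set.seed(21)
  for (rep in 1:100) {
    len <- sample(2000:10000, 1)
    n <- sample(1:50, 1)
    st <- sample(0:(len - 10), n)
    en <- pmin(len, st + sample(10:800, n, replace = TRUE))
    bb <- blocks_df(qry_contig = "c", qry_start = st, qry_end = en,
                    identity = rep(0.99, n))
    got <- absent_regions(c(c = len), bb, min_segment_length = 1)
    want <- oracle_absent_mask(len, st, en)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("candidate dedupe applies both coverage and identity thresholds", {
  cand <- data.frame(segment_id = c("a", "b", "c", "d"),
                     length = c(1000, 1000, 1000, 1000))
  re <- blocks_df(qry_contig = c("a", "b", "c"),
                  qry_start = c(0, 0, 0),
                  qry_end = c(960, 960, 860),
                  identity = c(0.96, 0.90, 0.99))
  out <- dedupe_nonref(cand, re)
  # a: coverage 0.96 & identity 0.96 -> removed
  # b: identity 0.90 fails; c: coverage 0.86 fails; d: no hit -> retained
  expect_setequal(out$segment_id, c("b", "c", "d"))
  expect_equal(out$aligned_fraction[out$segment_id == "d"], 0)
})

test_that("iterative pan construction recovers planted insertions once", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not available")
  syn <- synthetic_genomes(20000, insertions = list(
    gA = data.frame(at = 5000, length = 3000, label = "shared"),
    gB = data.frame(at = 5000, length = 3000, label = "shared"),
    gC = data.frame(at = 12000, length = 2000, label = NA)), seed = 11)
  res <- iterate_pan(syn$genomes, syn$reference)
  # the shared insertion is retained once (round-2 copy deduplicated),
  # the private one once: two segments in total
  expect_equal(nrow(res$segments), 2L)
  expect_setequal(res$segments$source_genome, c("gA", "gC"))
  expect_equal(sort(res$segments$length), c(2000, 3000))
  # segment boundaries within alignment ambiguity of the planted truth
  segA <- res$segments[res$segments$source_genome == "gA", ]
  expect_lt(abs(segA$start - 5000), 20)
  # monotone: per-round retained bases are never negative; genome identical
  # to the pan contributes nothing
  expect_true(all(res$report$n_retained >= 0))
  res2 <- iterate_pan(list(gA2 = syn$genomes$gA),
                      c(syn$reference, res$nonref))
  expect_equal(nrow(res2$segments), 0L)
})

test_that("novel genes require >= 80% overlap and collapse across genomes", {
  segments <- data.frame(segment_id = c("nr1", "nr2"),
                         source_genome = c("gA", "gB"),
                         qry_contig = c("cA", "cB"),
                         start = c(1000, 2000), end = c(4000, 5000),
                         length = c(3000, 3000), round = 1:2)
  genes <- data.frame(
    genome = c("gA", "gA", "gA", "gB"),
    gene_id = c("inside", "at79", "at80", "dup_of_inside"),
    contig = c("cA", "cA", "cA", "cB"),
    start = c(1500, 3210, 3200, 2500),
    end = c(2500, 4210, 4200, 3500))
  # inside: fully contained (overlap 1.0); at79: 790/1000 < 0.8 -> not novel;
  # at80: 800/1000 exactly -> novel; dup lands on the same relative pan
  # interval as `inside` on a different segment, so it is NOT collapsed
  nv <- call_novel_genes(genes, segments)
  expect_setequal(nv$gene_id, c("inside", "at80", "dup_of_inside"))
  expect_equal(nv$overlap_fraction[nv$gene_id == "inside"], 1.0)
  expect_equal(nv$overlap_fraction[nv$gene_id == "at80"], 0.8)
  # same segment, reciprocal overlap >= 0.8 -> collapsed to one cluster
  genes2 <- data.frame(genome = c("gA", "gB"),
                       gene_id = c("n1", "n2"),
                       contig = c("cA", "cB"),
                       start = c(1500, 2520), end = c(2500, 3520))
  segments2 <- segments
  segments2$segment_id <- c("nrS", "nrS")
  nv2 <- call_novel_genes(genes2, segments2)
  expect_equal(length(unique(nv2$cluster)), 1L)
  expect_equal(sum(nv2$representative), 1L)
})

test_that("PAF records split into indel-free blocks with CIGAR identity", {
  paf <- paste("q", 2300, 0, 2300, "+", "ref", 2000, 0, 2000, 1995, 2300,
               60, "cg:Z:995=5X300I1000=", sep = "\t")
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf, f)
  b <- read_paf(f, split_at = 100)
  expect_equal(nrow(b), 2L)
  expect_equal(b$qry_start, c(0, 1300))
  expect_equal(b$qry_end, c(1000, 2300))
  expect_equal(b$ref_start, c(0, 1000))
  expect_equal(b$ref_end, c(1000, 2000))
  expect_equal(b$identity[1], 995 / 1000)
  expect_equal(b$identity[2], 1)
  # without splitting the record stays whole
  expect_equal(nrow(read_paf(f, split_at = Inf)), 1L)
})
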