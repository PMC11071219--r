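test_that("FPKM follows count * 1e9 / (total * length) and is scale-free", {
  counts <- matrix(c(10, 0), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  f <- fpkm(counts, c(gA = 1000, gB = 500), totals = c(s1 = 1e6))
  expect_equal(f["gA", "s1"], 10)
  expect_equal(f["gB", "s1"], 0)
  # doubling all counts and the totals leaves FPKM unchanged
  set.seed(121)
  c2 <- matrix(rpois(20, 50), 4, 5,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  lens <- setNames(c(500, 1500, 2000, 800), rownames(c2))
  tot <- colSums(c2)
  expect_equal(fpkm(c2, lens, tot), fpkm(2 * c2, lens, 2 * tot))
  expect_error(fpkm(counts, c(gA = 1000, gB = 500), totals = c(s1 = 0)),
               "totals")
  expect_error(fpkm(counts, c(gA = -5, gB = 500)), "lengths")
})

test_that("TAU hits its landmark values and bounds", {
  expect_equal(tau(c(8, 0, 0, 0)), 1)
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_equal(tau(c(4, 2, 2, 2)), 0.5)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "2 groups")
  expect_error(tau(c(-1, 2)), "non-negative")
  # bounds and characterisations on random non-negative profiles
  set.seed(131)
  for (rep in 1:200) {
    x <- round(rexp(sample(2:8, 1)) * 10, 3)
    if (max(x) == 0) next
    tv <- tau(x)
    expect_gte(tv, 0)
    expect_lte(tv, 1)
    if (length(unique(x)) == 1) expect_equal(tv, 0)
    if (sum(x > 0) == 1) expect_equal(tv, 1)
  }
})

test_that("per-gene TAU runs on group means, not per-sample values", {
  v <- matrix(c(4, 4, 2, 2,
                6, 6, 6, 6), 2, 4, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  groups <- setNames(c("t1", "t1", "t2", "t2"), paste0("s", 1:4))
  ti <- tau_index(v, groups)
  expect_equal(ti$tau[ti$gene_id == "gA"], tau(c(4, 2)))
  expect_equal(ti$tau[ti$gene_id == "gB"], 0)
  expect_equal(ti$n_groups, c(2L, 2L))
})

test_that("class expression summaries rank core above shell as generated", {
  classes <- setNames(rep(c("core", "shell"), each = 150),
                      sprintf("g%03d", 1:300))
  em <- simulate_expression(classes, class_means = c(core = 100, shell = 10),
                            sdlog = 0.1, seed = 14)
  cs <- class_expression_summary(em, classes)
  for (s in unique(cs$sample_id)) {
    expect_gt(cs$median[cs$sample_id == s & cs$class == "core"],
              cs$median[cs$sample_id == s & cs$class == "shell"])
  }
  # one gene per class: the median is that gene's value
  v1 <- matrix(c(7, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  cs1 <- class_expression_summary(v1, c(a = "core", b = "shell"))
  expect_equal(cs1$median[cs1$class == "core"], 7)
  # permuting gene order leaves summaries unchanged
  perm <- sample(nrow(em$values))
  cs2 <- class_expression_summary(em$values[perm, ], classes)
  expect_equal(cs2[order(cs2$sample_id, cs2$class), ]$median,
               cs[order(cs$sample_id, cs$class), ]$median)
})

test_that("simple DE flags a planted fold change and not identical groups", {
  set.seed(141)
  n <- 10
  base <- matrix(rlnorm(200 * 2 * n, log(50), 0.2), 200, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("s%02d", 1:(2 * n))))
  ga <- colnames(base)[1:n]; gb <- colnames(base)[n + 1:n]
  base["g001", ga] <- base["g001", ga] * 4
  de <- de_simple(base, ga, gb)
  expect_true(de$de[de$gene_id == "g001"])
  expect_equal(de$log2fc[de$gene_id == "g001"], 2, tolerance = 0.4)
  # identical groups: log2FC 0, never DE
  same <- cbind(base[, ga], base[, ga])
  colnames(same) <- sprintf("s%02d", 1:(2 * n))
  de0 <- de_simple(same, colnames(same)[1:n], colnames(same)[n + 1:n])
  expect_true(all(de0$log2fc == 0))
  expect_false(any(de0$de))
  expect_error(de_simple(base, ga, ga), "disjoint")
  expect_error(de_simple(base, ga[1:2], gb), "at least 3")
})

test_that("coexpression pairing reports |r| above threshold only", {
  set.seed(151)
  s <- sprintf("s%02d", 1:50)
  m <- matrix(rnorm(5 * 50), 5, 50, dimnames = list(paste0("mr", 1:5), s))
  l <- rbind(pos = m["mr1", ] * 2 + 1e-9 * rnorm(50),
             neg = -m["mr2", ],
             noise = rnorm(50))
  colnames(l) <- s
  cp <- coexpression_pairs(l, m, min_abs_r = 0.9)
  expect_equal(cp$r[cp$lncrna == "pos" & cp$mrna == "mr1"], 1,
               tolerance = 1e-6)
  expect_equal(cp$r[cp$lncrna == "neg" & cp$mrna == "mr2"], -1)
  # independent noise essentially never reaches |r| >= 0.9 at n = 50
  expect_false("noise" %in% cp$lncrna)
  expect_warning(coexpression_pairs(rbind(l, flat = rep(1, 50)), m),
                 "constant")
})

test_that("burden tables conserve counts across strata", {
  vars <- data.frame(gene = c("g1", "g1", "g1", "g2", "zzz"),
                     sample = c("s1", "s1", "s1", "s2", "s1"),
                     consequence = c("splice_region", "upstream",
                                     "splice_region", "upstream",
                                     "upstream"))
  expect_warning(bt <- burden_table(vars, genes = c("g1", "g2", "g3")),
                 "unassigned")
  expect_equal(bt$totals["g1", "s1"], 3L)
  expect_equal(bt$totals["g3", ], c(s1 = 0L, s2 = 0L))
  expect_equal(bt$totals["unassigned", "s1"], 1L)
  # stratified counts sum to the overall totals
  agg <- tapply(bt$long$count, list(bt$long$gene, bt$long$sample), sum)
  for (g in rownames(bt$totals)) for (s in colnames(bt$totals)) {
    got <- if (g %in% rownames(agg) && s %in% colnames(agg)) agg[g, s]
           else NA
    expect_equal(if (is.na(got)) 0L else as.integer(got),
                 bt$totals[g, s])
  }
  empty <- burden_table(vars[0, ], genes = "g1", samples = "s1")
  expect_true(all(empty$totals == 0L))
})
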