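test_that("occupancy classes follow the core/softcore/shell/cloud bounds", {
  n <- 350
  occ_counts <- c(core = 350L, softcore = 347L, shell = 175L, cloud = 3L,
                  unobserved = 0L)
  m <- do.call(rbind, lapply(names(occ_counts), function(k) {
    v <- integer(n); if (occ_counts[k] > 0) v[seq_len(occ_counts[k])] <- 1L
    v
  }))
  dimnames(m) <- list(names(occ_counts), sprintf("s%03d", 1:n))
  cl <- classify_genes(m)
  got <- setNames(as.character(cl$class), cl$gene_id)
  expect_equal(got[["core"]], "core")
  expect_equal(got[["softcore"]], "softcore")   # 347/350 = 0.9914
  expect_equal(got[["shell"]], "shell")         # 0.5
  expect_equal(got[["cloud"]], "cloud")         # 3/350 = 0.0086
  expect_equal(got[["unobserved"]], "unobserved")
  # observed classes partition the observed genes
  counts <- attr(cl, "counts")
  expect_equal(sum(counts), sum(occ_counts > 0) - 0L)
  expect_error(classify_genes(m[0, , drop = FALSE]), "empty")
})

test_that("class-count summaries reproduce shares and derived totals", {
  s <- pan_size_summary(c(core = 16330, softcore = 2614, shell = 2506,
                          cloud = 125))
  expect_equal(s$total, 21575)
  expect_equal(round(s$core_share, 2), 75.69)
  expect_equal(round(s$variable_share, 1), 24.3)
  expect_equal(s$pav_related, 5120)
  expect_equal(sum(s$shares), 100)
})

test_that("saturation matches exhaustive enumeration and its invariants", {
  set.seed(41)
  v <- matrix(rbinom(100, 1, 0.6), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  sat <- saturation(v, exhaustive = TRUE)
  for (k in c(1, 3, 5, 10)) {
    want <- oracle_saturation_means(v, k)
    expect_equal(sat$pan_mean[sat$k == k], unname(want["pan"]))
    expect_equal(sat$core_mean[sat$k == k], unname(want["core"]))
  }
  # k = n: pan = observed genes, core = core-class count, zero spread
  expect_equal(sat$pan_mean[sat$k == 10], sum(rowSums(v) > 0))
  expect_equal(sat$core_mean[sat$k == 10], sum(rowSums(v) == 10))
  expect_equal(sat$pan_min[sat$k == 10], sat$pan_max[sat$k == 10])
  # all-ones matrix: pan(k) = core(k) = G for every k
  ones <- matrix(1L, 4, 6, dimnames = list(paste0("g", 1:4),
                                           paste0("s", 1:6)))
  sat1 <- saturation(ones, replicates = 5, seed = 1)
  expect_true(all(sat1$pan_mean == 4) && all(sat1$core_mean == 4))
  # nested-subset monotonicity, checked exactly on random nested pairs
  for (rep in 1:20) {
    s_small <- sample(10, 4); s_big <- union(s_small, sample(10, 3))
    pan_s <- sum(rowSums(v[, s_small, drop = FALSE]) > 0)
    pan_t <- sum(rowSums(v[, s_big, drop = FALSE]) > 0)
    core_s <- sum(rowSums(v[, s_small, drop = FALSE]) == length(s_small))
    core_t <- sum(rowSums(v[, s_big, drop = FALSE]) == length(s_big))
    expect_lte(pan_s, pan_t)
    expect_gte(core_s, core_t)
  }
  expect_error(saturation(v, ks = 11), "out of")
})

test_that("binary PCA matches the eigendecomposition oracle up to sign", {
  set.seed(51)
  v <- matrix(rbinom(48, 1, 0.5), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  p <- pca_binary(v)
  want <- oracle_pca_scores(v)
  k <- min(ncol(p$scores), ncol(want))
  expect_equal(abs(unname(p$scores[, 1:k])), abs(unname(want[, 1:k])),
               tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  # two anti-correlated sample groups separate on PC1 with opposite signs
  g <- cbind(matrix(rep(c(1L, 0L), c(5, 5)), 10, 4),
             matrix(rep(c(0L, 1L), c(5, 5)), 10, 4))
  dimnames(g) <- list(paste0("g", 1:10), paste0("s", 1:8))
  pg <- pca_binary(g)
  expect_true(all(pg$scores[1:4, 1] * pg$scores[5:8, 1] < 0))
  const <- matrix(1L, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_error(pca_binary(const), "variable genes")
})

test_that("frequency tests match Fisher enumeration and BH by hand", {
  # 5/5 present vs 0/5 present: two-sided p = 2/252
  m <- matrix(c(rep(1L, 5), rep(0L, 5)), 1, 10,
              dimnames = list("g1", paste0("s", 1:10)))
  m <- rbind(m, g2 = rep(1L, 10))  # identical in both groups -> p = 1
  ft <- freq_test(m, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(ft$p[ft$gene_id == "g1"], 2 / 252, tolerance = 1e-12)
  expect_equal(ft$p[ft$gene_id == "g2"], 1)
  expect_false(ft$selected[ft$gene_id == "g2"])
  # implementation p equals exhaustive enumeration for all small tables
  for (na in c(4, 7)) for (nb in c(5, 12)) {
    for (pa in 0:na) for (pb in seq(0, nb, by = 3)) {
      if (pa + pb == 0) next
      mm <- matrix(c(rep(1L, pa), rep(0L, na - pa),
                     rep(1L, pb), rep(0L, nb - pb)), 1, na + nb,
                   dimnames = list("g", paste0("x", 1:(na + nb))))
      f1 <- freq_test(mm, paste0("x", 1:na), paste0("x", na + 1:nb))
      expect_equal(f1$p, oracle_fisher_p(pa, na - pa, pb, nb - pb),
                   tolerance = 1e-9)
    }
  }
  # BH q-values equal the step-up definition and dominate raw p
  set.seed(61)
  v <- matrix(rbinom(30 * 40, 1, 0.5), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:40)))
  ft2 <- freq_test(v, sprintf("s%02d", 1:20), sprintf("s%02d", 21:40))
  expect_equal(ft2$q, oracle_bh(ft2$p))
  expect_true(all(ft2$q >= ft2$p - 1e-12))
  expect_error(freq_test(v, "s01", c("s01", "s02")), "disjoint")
})

test_that("planted frequency difference is detected reliably", {
  hits <- 0L
  for (rep in 1:20) {
    pl <- planted_pav(freq_a = c(0.9, 0.5), freq_b = c(0.1, 0.5),
                      seed = 300 + rep)
    ft <- freq_test(pl$values, pl$group_a, pl$group_b)
    hits <- hits + as.integer(ft$selected[ft$gene_id == "g001"])
    expect_false(isTRUE(ft$selected[ft$gene_id == "g002"]))
  }
  expect_gte(hits, 19L)  # >= 95% of seeded replicates
})

test_that("breed-specific genes need zero carriers outside the breed set", {
  genes <- c("only_x", "x_plus_out", "pair_mc", "excluded")
  samples <- sprintf("s%02d", 1:12)
  breed <- rep(c("X", "Y", "Maiwa", "Changtai"), each = 3)
  meta <- data.frame(sample_id = samples, breed = breed,
                     population = "domestic")
  m <- matrix(0L, 4, 12, dimnames = list(genes, samples))
  m["only_x", 1:2] <- 1L                 # 2 of 3 X individuals
  m["x_plus_out", c(1, 4)] <- 1L         # X plus one Y sample
  m["pair_mc", c(7, 10)] <- 1L           # one Maiwa + one Changtai
  m["excluded", 7] <- 1L
  bs <- breed_specific(m, meta,
                       breed_sets = list("X", "Y", c("Maiwa", "Changtai")),
                       exclusion = "excluded")
  expect_setequal(bs$gene_id, c("only_x", "pair_mc"))
  expect_equal(bs$set[bs$gene_id == "pair_mc"], "Changtai+Maiwa")
  expect_equal(attr(bs, "n_excluded"), 1L)
  # breeds under the individual floor are dropped before testing
  meta2 <- meta; meta2$breed[1:2] <- "tiny"
  bs2 <- breed_specific(m, meta2, min_individuals = 3)
  expect_false("tiny" %in% attr(bs2, "retained_breeds"))
  expect_error(breed_specific(m, meta, min_individuals = 99), "retains")
})
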