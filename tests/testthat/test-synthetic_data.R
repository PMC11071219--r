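test_that("copy states follow the diploid Bernoulli model", {
  # all-present and all-absent extremes are forced
  t1 <- make_truth(5, populations = "p", n_core = 3, n_accessory = 2,
                   freq_range = c(1, 1), seed = 1)
  expect_true(all(t1$copy == 2L))
  expect_true(all(pav_from_truth(t1)$values == 1L))
  t0 <- make_truth(5, populations = "p", n_core = 0, n_accessory = 2,
                   freq_range = c(0, 0), seed = 1)
  expect_true(all(t0$copy == 0L))

  # presence fraction at allele freq 0.5 converges to 1 - (1 - 0.5)^2
  tb <- make_truth(10000, populations = "p", n_core = 0, n_accessory = 1,
                   freq_range = c(0.5, 0.5), seed = 7)
  p_hat <- mean(tb$copy >= 1L)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("truth generation is seed-deterministic and validates input", {
  a <- make_truth(20, seed = 42)
  b <- make_truth(20, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$copy, make_truth(20, seed = 43)$copy))
  expect_error(make_truth(10, freq_range = c(-0.1, 0.5)), "frequency range")
  expect_error(make_truth(10, freq_range = c(0.9, 0.2)), "frequency range")
})

test_that("simulated depth matches the coverage model by copy state", {
  truth <- make_truth(6, n_core = 4, n_accessory = 4, seed = 3)
  models <- synthetic_gene_models(rownames(truth$copy), exon_length = 50)
  d <- simulate_depth(truth, models, coverage_model(noise = "none"), seed = 1)
  # noiseless: every exonic base carries exactly the state's mean depth
  for (s in colnames(truth$copy)[1:3]) {
    for (g in rownames(truth$copy)[c(1, 5, 8)]) {
      want <- c(0, 10, 20)[truth$copy[g, s] + 1]
      got <- d[d$sample == s & d$contig == g, ]$depth
      expect_true(all(got == want))
    }
  }
  # Poisson depth at one copy: mean within 3 SE of depth_het
  one <- matrix(1L, 1, 1, dimnames = list("gX", "s1"))
  mod <- synthetic_gene_models("gX", exon_length = 5000, n_exons = 2)
  dp <- simulate_depth(one, mod, coverage_model(noise = "poisson"), seed = 5)
  expect_lt(abs(mean(dp$depth) - 10), 3 * sqrt(10 / 10000))
  expect_error(
    simulate_depth(one, data.frame(gene_id = "gX", contig = "gX",
                                   start = 5, end = 5)),
    "zero-length")
})

test_that("depth simulation is reproducible under a fixed seed", {
  truth <- make_truth(4, n_core = 3, n_accessory = 3, seed = 2)
  models <- synthetic_gene_models(rownames(truth$copy))
  d1 <- simulate_depth(truth, models, seed = 9)
  d2 <- simulate_depth(truth, models, seed = 9)
  expect_identical(d1, d2)
})

test_that("simulated expression has the requested group structure", {
  classes <- setNames(rep(c("core", "shell"), each = 200),
                      sprintf("g%03d", 1:400))
  spec <- list(testis = "g001")
  em <- simulate_expression(classes, tissues = c("heart", "lung", "testis"),
                            specific_genes = spec, sdlog = 0.1, seed = 4)
  # the testis-specific gene is zero outside testis -> TAU of group means = 1
  ti <- tau_index(em)
  expect_equal(ti$tau[ti$gene_id == "g001"], 1)
  # core medians dominate shell medians in every sample
  core_g <- names(classes)[classes == "core"][-1]
  shell_g <- names(classes)[classes == "shell"]
  med_core <- apply(em$values[core_g, ], 2, median)
  med_shell <- apply(em$values[shell_g, ], 2, median)
  expect_true(all(med_core > med_shell))
  # uniform means, zero noise -> TAU 0 everywhere
  em0 <- simulate_expression(setNames(rep("core", 5), paste0("u", 1:5)),
                             sdlog = 0, seed = 1)
  expect_true(all(tau_index(em0)$tau == 0))
  expect_error(simulate_expression(c(gA = "mystery")), "unknown class")
})

test_that("simulated trait is baseline + effect x presence (+ noise)", {
  truth <- make_truth(40, n_core = 2, n_accessory = 5, seed = 8)
  pav <- pav_from_truth(truth)
  tr <- simulate_trait(pav, trait_model("acc0001", baseline = 14,
                                        effect = 1, noise_sd = 0), seed = 1)
  carriers <- colnames(pav$values)[pav$values["acc0001", ] == 1]
  expect_true(all(tr$trait[tr$sample_id %in% carriers] == 15))
  expect_true(all(tr$trait[!tr$sample_id %in% carriers] == 14))
  # zero effect: trait carries no marker signal
  tr0 <- simulate_trait(pav, trait_model("acc0001", effect = 0,
                                         noise_sd = 0.5), seed = 2)
  expect_equal(cor(tr0$trait, pav$values["acc0001", ]), 0, tolerance = 0.5)
  expect_error(simulate_trait(pav, trait_model("nope")), "not in the PAV")
})

test_that("scenario writer emits readable standard files", {
  dir <- withr::local_tempdir()
  paths <- simulate_scenario(dir, list(n_samples = 12, n_core = 10,
                                       n_accessory = 6, noise = "none"))
  pav <- read_pav_matrix(paths$truth_pav)
  expect_equal(dim(pav$values), c(16L, 12L))
  depth <- read_depth(paths$depth)
  models <- read_gene_models(paths$genes)
  redo <- suppressWarnings(call_pav(depth, models))
  expect_identical(redo$pav$values,
                   pav$values[rownames(redo$pav$values),
                              colnames(redo$pav$values)])
  meta <- read_metadata(paths$metadata)
  expect_setequal(meta$sample_id, colnames(pav$values))
})
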