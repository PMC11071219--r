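# Shared small synthetic scenarios built in code at test time.

# truth + gene models + depth + PAV calls in one go
make_scenario <- function(n_samples = 30, n_core = 20, n_accessory = 15,
                          noise = "none", seed = 101) {
  truth <- make_truth(n_samples, n_core = n_core, n_accessory = n_accessory,
                      seed = seed)
  models <- synthetic_gene_models(rownames(truth$copy))
  depth <- simulate_depth(truth, models, coverage_model(noise = noise),
                          seed = seed + 1)
  res <- suppressWarnings(call_pav(depth, models, metadata = truth$samples))
  list(truth = truth, models = models, depth = depth,
       pav = res$pav, coverage = res$coverage)
}

# a binary matrix with planted per-group presence frequencies
planted_pav <- function(freq_a, freq_b, n_a = 100, n_b = 100, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_along(freq_a))
  a <- matrix(rbinom(length(freq_a) * n_a, 1, rep(freq_a, n_a)),
              length(freq_a), n_a)
  b <- matrix(rbinom(length(freq_b) * n_b, 1, rep(freq_b, n_b)),
              length(freq_b), n_b)
  m <- cbind(a, b)
  dimnames(m) <- list(genes, sprintf("s%03d", seq_len(n_a + n_b)))
  list(values = m, group_a = colnames(m)[seq_len(n_a)],
       group_b = colnames(m)[n_a + seq_len(n_b)])
}
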