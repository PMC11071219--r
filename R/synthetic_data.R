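# Synthetic-data generator. Emulates the statistical structure the PAV
# pipeline assumes: a reference (core) gene pool carried by everyone plus an
# accessory pool with population-structured presence frequencies, diploid
# coverage proportional to gene copy state, a quantitative trait driven by
# one PAV marker, and class-dependent expression levels.

#' Diploid coverage model for depth simulation
#'
#' Mean per-base exonic depths by copy state, with an optional count-noise
#' model. Defaults (20x / 10x / 0x, Poisson) reflect typical short-read
#' resequencing depth for a diploid genome: two copies at full depth, one
#' copy at half depth, absent genes at background.
#'
#' @param depth_hom mean depth over two-copy (homozygous-present) genes.
#' @param depth_het mean depth over one-copy (heterozygous) genes.
#' @param depth_absent mean background depth over absent genes.
#' @param noise `"poisson"` for Poisson per-base counts, `"none"` for exact
#'   means.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(depth_hom = 20, depth_het = 10, depth_absent = 0,
                           noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (!(depth_hom > depth_het && depth_het > depth_absent && depth_absent >= 0))
    .fail("need depth_hom > depth_het > depth_absent >= 0")
  structure(list(depth_hom = depth_hom, depth_het = depth_het,
                 depth_absent = depth_absent, noise = noise),
            class = "coverage_model")
}

#' Trait model for PAV-trait simulation
#'
#' A quantitative trait (e.g. rib count, baseline 14) shifted by `effect`
#' units when the causal gene is present, with Gaussian noise.
#'
#' @param causal_gene gene id whose presence shifts the trait.
#' @param baseline trait value for non-carriers.
#' @param effect trait shift per presence.
#' @param noise_sd standard deviation of the Gaussian residual (>= 0).
#' @return A `trait_model` list.
#' @export
trait_model <- function(causal_gene, baseline = 14, effect = 1,
                        noise_sd = 0.25) {
  if (noise_sd < 0) .fail("`noise_sd` must be >= 0")
  structure(list(causal_gene = causal_gene, baseline = baseline,
                 effect = effect, noise_sd = noise_sd),
            class = "trait_model")
}

#' Simulate pangenome ground truth with diploid copy states
#'
#' Draws, for every accessory gene and population, a presence allele
#' frequency from `freq_range`, then per sample a copy state as the sum of
#' two independent Bernoulli draws at that frequency (i.e. Binomial(2, f)).
#' Reference (core) genes have allele frequency 1 in every population. A
#' gene is "present" in the binary PAV sense iff its copy state is >= 1, so
#' the expected presence frequency is 1 - (1 - f)^2.
#'
#' @param n_samples number of samples to simulate.
#' @param populations character vector of population labels (samples are
#'   split as evenly as possible) or a named integer vector of per-population
#'   sample counts.
#' @param n_core number of reference (core) genes.
#' @param n_accessory number of accessory genes.
#' @param freq_range length-2 allele-frequency range applied to every
#'   population, or a named list of per-population ranges, or a full
#'   populations-by-accessory-genes matrix of allele frequencies.
#' @param breeds_per_population breeds nested inside each population;
#'   samples are assigned round-robin.
#' @param seed RNG seed; identical seeds give identical output.
#' @return A `pan_truth` list with elements `reference_genes`,
#'   `accessory_genes`, `populations`, `allele_freq` (populations x
#'   accessory genes), `samples` (`sample_id`, `population`, `breed`) and
#'   `copy` (genes x samples matrix in \{0, 1, 2\}).
#' @export
make_truth <- function(n_samples, populations = c("wild", "domestic", "jinchuan"),
                       n_core = 200, n_accessory = 100,
                       freq_range = c(0.05, 0.95),
                       breeds_per_population = 3, seed = 1) {
  .check_count(n_samples, "n_samples")
  .check_count(n_core, "n_core", min = 0L)
  .check_count(n_accessory, "n_accessory", min = 0L)
  if (is.numeric(populations) && !is.null(names(populations))) {
    pop_labels <- names(populations)
    pop_of <- rep(pop_labels, times = populations)
    if (length(pop_of) != n_samples)
      .fail("population counts must sum to n_samples")
  } else {
    pop_labels <- as.character(populations)
    pop_of <- rep_len(pop_labels, n_samples)
  }
  npop <- length(pop_labels)
  core_ids <- if (n_core) sprintf("core%04d", seq_len(n_core)) else character()
  acc_ids <- if (n_accessory) sprintf("acc%04d", seq_len(n_accessory)) else character()
  genes <- c(core_ids, acc_ids)

  with_seed(seed, {
    # per-population allele frequencies for accessory genes
    if (is.matrix(freq_range)) {
      af <- freq_range
      if (!all(dim(af) == c(npop, n_accessory)))
        .fail("frequency matrix must be populations x accessory genes")
    } else {
      ranges <- if (is.list(freq_range)) {
        if (!all(pop_labels %in% names(freq_range)))
          .fail("freq_range list must name every population")
        freq_range[pop_labels]
      } else {
        rep(list(freq_range), npop)
      }
      af <- matrix(0, npop, n_accessory)
      for (i in seq_len(npop)) {
        r <- ranges[[i]]
        if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
          .fail("invalid frequency range for population `%s`", pop_labels[i])
        af[i, ] <- runif(n_accessory, r[1], r[2])
      }
    }
    if (any(af < 0 | af > 1)) .fail("allele frequencies must lie in [0, 1]")
    dimnames(af) <- list(pop_labels, acc_ids)

    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    breed_of <- character(n_samples)
    for (p in pop_labels) {
      idx <- which(pop_of == p)
      breed_of[idx] <- sprintf("%s_b%d", p,
                               rep_len(seq_len(breeds_per_population),
                                       length(idx)))
    }
    samples <- data.frame(sample_id = sample_ids, population = pop_of,
                          breed = breed_of, stringsAsFactors = FALSE)

    copy <- matrix(2L, length(genes), n_samples,
                   dimnames = list(genes, sample_ids))
    if (n_accessory) {
      pop_idx <- match(pop_of, pop_labels)
      # Binomial(2, f) == sum of two Bernoulli(f) draws
      f <- af[pop_idx, , drop = FALSE]            # samples x genes
      draws <- rbinom(length(f), size = 2L, prob = as.vector(f))
      copy[acc_ids, ] <- t(matrix(as.integer(draws), n_samples, n_accessory))
    }
  })

  structure(list(reference_genes = core_ids, accessory_genes = acc_ids,
                 populations = pop_labels, allele_freq = af,
                 samples = samples, copy = copy, seed = seed),
            class = "pan_truth")
}

#' @export
print.pan_truth <- function(x, ...) {
  cat(sprintf("pan_truth: %d core + %d accessory genes, %d samples, %d populations\n",
              length(x$reference_genes), length(x$accessory_genes),
              nrow(x$samples), length(x$populations)))
  invisible(x)
}

#' Binary PAV matrix implied by simulated copy states
#'
#' @param truth a `pan_truth` from [make_truth()].
#' @return A [pav_matrix()]: presence iff copy state >= 1.
#' @export
pav_from_truth <- function(truth) {
  pav_matrix((truth$copy >= 1L) * 1L, metadata = truth$samples)
}

#' Simple synthetic gene models
#'
#' Lays each gene on its own contig (named after the gene) with `n_exons`
#' exons of `exon_length` bp separated by `intron_length` bp introns, in
#' 0-based half-open coordinates.
#'
#' @param gene_ids character vector of gene ids.
#' @param exon_length exon length in bp.
#' @param n_exons exons per gene.
#' @param intron_length intron length in bp.
#' @return Gene-model `data.frame` (`gene_id`, `contig`, `start`, `end`),
#'   one row per exon.
#' @export
synthetic_gene_models <- function(gene_ids, exon_length = 60, n_exons = 2,
                                  intron_length = 30) {
  .check_count(exon_length, "exon_length")
  .check_count(n_exons, "n_exons")
  starts <- (seq_len(n_exons) - 1L) * (exon_length + intron_length)
  data.frame(gene_id = rep(gene_ids, each = n_exons),
             contig = rep(gene_ids, each = n_exons),
             start = rep(starts, times = length(gene_ids)),
             end = rep(starts + exon_length, times = length(gene_ids)),
             stringsAsFactors = FALSE)
}

#' Simulate per-base exonic depth from copy states
#'
#' Every exonic base of a gene gets expected depth `depth_hom`, `depth_het`
#' or `depth_absent` according to the sample's copy state, with optional
#' Poisson noise.
#'
#' @param copy genes x samples copy-state matrix (from [make_truth()], field
#'   `copy`) or a `pan_truth`.
#' @param models gene-model `data.frame` as from [synthetic_gene_models()].
#' @param coverage a [coverage_model()].
#' @param seed RNG seed.
#' @return A `data.table` with columns `sample`, `contig`, `pos` (1-based),
#'   `depth`, covering every exonic base of every gene in `models`.
#' @export
simulate_depth <- function(copy, models, coverage = coverage_model(),
                           seed = 1) {
  if (inherits(copy, "pan_truth")) copy <- copy$copy
  if (!inherits(coverage, "coverage_model"))
    .fail("`coverage` must be a coverage_model()")
  if (any(models$end <= models$start)) .fail("zero-length exon in gene models")
  genes <- intersect(rownames(copy), unique(models$gene_id))
  if (!length(genes)) .fail("no genes shared between copy matrix and models")
  models <- models[models$gene_id %in% genes, , drop = FALSE]

  # union of exon intervals per gene, expanded to per-base positions
  pos_tab <- data.table::rbindlist(lapply(split(models, models$gene_id), function(g) {
    ir <- IRanges::reduce(.ir(g$start, g$end))
    data.table::data.table(gene = g$gene_id[1], contig = g$contig[1],
                           pos = unlist(Map(seq, IRanges::start(ir),
                                            IRanges::end(ir))))
  }))
  mu_by_state <- c(coverage$depth_absent, coverage$depth_het,
                   coverage$depth_hom)
  gi <- match(pos_tab$gene, rownames(copy))
  n_pos <- nrow(pos_tab)

  with_seed(seed, {
    out <- data.table::rbindlist(lapply(colnames(copy), function(s) {
      mu <- mu_by_state[copy[gi, s] + 1L]
      depth <- if (coverage$noise == "poisson") rpois(n_pos, mu) else mu
      data.table::data.table(sample = s, contig = pos_tab$contig,
                             pos = pos_tab$pos, depth = depth)
    }))
  })
  out[]
}

#' Simulate a class-structured expression matrix
#'
#' Genes get a lognormal draw around their occupancy-class mean in every
#' sample; genes declared tissue-specific get `specific_mean` in samples of
#' their own tissue and `specific_off` elsewhere. Emulates an expression
#' atlas where highly conserved (core) genes are the most expressed.
#'
#' @param classes named character vector gene -> class label; labels must
#'   appear in `names(class_means)`.
#' @param tissues tissue labels; each gets `n_per_tissue` samples.
#' @param class_means named vector of class mean expression.
#' @param n_per_tissue replicate samples per tissue.
#' @param specific_genes named list tissue -> gene ids specific to it.
#' @param specific_mean mean for a specific gene in its own tissue.
#' @param specific_off mean for a specific gene outside its tissue.
#' @param sdlog lognormal noise sd on the log scale; 0 for none.
#' @param seed RNG seed.
#' @return An [expression_matrix()] grouped by tissue.
#' @export
simulate_expression <- function(classes,
                                tissues = c("heart", "lung", "testis"),
                                class_means = c(core = 100, softcore = 50,
                                                shell = 10, cloud = 2),
                                n_per_tissue = 3,
                                specific_genes = list(),
                                specific_mean = 100, specific_off = 0,
                                sdlog = 0.1, seed = 1) {
  if (is.null(names(classes))) .fail("`classes` must be named by gene id")
  unknown <- setdiff(unique(classes), names(class_means))
  if (length(unknown))
    .fail("unknown class label(s): %s", paste(unknown, collapse = ", "))
  if (length(bad <- setdiff(names(specific_genes), tissues)))
    .fail("specific_genes names unknown tissue(s): %s",
          paste(bad, collapse = ", "))
  genes <- names(classes)
  samples <- paste0(rep(tissues, each = n_per_tissue), "_r",
                    rep(seq_len(n_per_tissue), times = length(tissues)))
  groups <- setNames(rep(tissues, each = n_per_tissue), samples)

  mu <- matrix(class_means[classes], length(genes), length(samples),
               dimnames = list(genes, samples))
  for (tis in names(specific_genes)) {
    g <- intersect(specific_genes[[tis]], genes)
    mu[g, ] <- specific_off
    mu[g, groups[samples] == tis] <- specific_mean
  }
  with_seed(seed, {
    vals <- if (sdlog > 0) {
      noise <- matrix(rlnorm(length(mu), meanlog = 0, sdlog = sdlog),
                      nrow(mu), ncol(mu))
      mu * noise
    } else mu
  })
  expression_matrix(vals, groups)
}

#' Simulate a PAV-driven quantitative trait
#'
#' trait = baseline + effect * presence(causal gene) + Normal(0, noise_sd).
#'
#' @param pav a [pav_matrix()].
#' @param model a [trait_model()]; its `causal_gene` must be in the matrix.
#' @param seed RNG seed.
#' @return `data.frame` with columns `sample_id`, `trait`.
#' @export
simulate_trait <- function(pav, model, seed = 1) {
  if (!inherits(model, "trait_model")) .fail("`model` must be a trait_model()")
  v <- .pav_values(pav)
  if (!model$causal_gene %in% rownames(v))
    .fail("causal gene `%s` not in the PAV matrix", model$causal_gene)
  presence <- v[model$causal_gene, ]
  with_seed(seed, {
    eps <- if (model$noise_sd > 0)
      rnorm(ncol(v), 0, model$noise_sd) else 0
    trait <- model$baseline + model$effect * presence + eps
  })
  data.frame(sample_id = colnames(v), trait = as.numeric(trait),
             stringsAsFactors = FALSE)
}

#' Synthetic genomes with known insertions relative to a reference
#'
#' Builds a random reference contig and derived genomes that each carry the
#' given novel insertions; used to exercise the pangenome-construction loop
#' with a fully known truth.
#'
#' @param reference_length reference contig length in bp.
#' @param insertions a list, one element per genome; each element is a
#'   `data.frame` with columns `at` (0-based reference position of the
#'   insertion) and `length` (bp), plus optionally `label` naming a shared
#'   insertion sequence so several genomes can carry an identical insertion.
#' @param seed RNG seed.
#' @return A list: `reference` (`DNAStringSet`, one contig `ref`),
#'   `genomes` (named list of `DNAStringSet`s, contigs named after the
#'   genome), `truth` (`data.frame` of genome, qry 0-based half-open
#'   insertion interval, label).
#' @export
synthetic_genomes <- function(reference_length = 20000, insertions,
                              seed = 1) {
  with_seed(seed, {
    alph <- c("A", "C", "G", "T")
    ref_seq <- paste(sample(alph, reference_length, replace = TRUE),
                     collapse = "")
    shared <- new.env(parent = emptyenv())
    get_ins <- function(label, len) {
      if (is.na(label)) {
        paste(sample(alph, len, replace = TRUE), collapse = "")
      } else {
        if (is.null(shared[[label]]))
          shared[[label]] <- paste(sample(alph, len, replace = TRUE),
                                   collapse = "")
        shared[[label]]
      }
    }
    truth <- list(); genomes <- list()
    for (gname in names(insertions)) {
      spec <- insertions[[gname]]
      if (is.null(spec$label)) spec$label <- NA_character_
      spec <- spec[order(spec$at), , drop = FALSE]
      parts <- character(); cur <- 0L; qpos <- 0L
      rows <- list()
      for (i in seq_len(nrow(spec))) {
        seg <- substr(ref_seq, cur + 1L, spec$at[i])
        ins <- get_ins(spec$label[i], spec$length[i])
        parts <- c(parts, seg, ins)
        qstart <- qpos + nchar(seg)
        rows[[i]] <- data.frame(genome = gname, contig = gname,
                                start = qstart, end = qstart + nchar(ins),
                                label = spec$label[i],
                                stringsAsFactors = FALSE)
        qpos <- qstart + nchar(ins)
        cur <- spec$at[i]
      }
      parts <- c(parts, substr(ref_seq, cur + 1L, reference_length))
      gseq <- paste(parts, collapse = "")
      genomes[[gname]] <- Biostrings::DNAStringSet(setNames(gseq, gname))
      truth[[gname]] <- do.call(rbind, rows)
    }
  })
  list(reference = Biostrings::DNAStringSet(c(ref = ref_seq)),
       genomes = genomes,
       truth = do.call(rbind, truth))
}

#' Generate a full synthetic scenario on disk
#'
#' Drives [make_truth()], [simulate_depth()], [simulate_trait()] and
#' [simulate_expression()] from a single YAML config and writes the standard
#' pipeline inputs (depth TSV, metadata CSV, trait CSV, truth PAV TSV,
#' expression TSV, gene-model GFF3) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param config path to a YAML file or a named list; recognised keys:
#'   `n_samples`, `populations`, `n_core`, `n_accessory`, `freq_lo`,
#'   `freq_hi`, `depth_hom`, `depth_het`, `depth_absent`, `noise`,
#'   `causal_gene`, `baseline`, `effect`, `noise_sd`, `seed`.
#' @return Invisibly, a named list of written file paths.
#' @export
simulate_scenario <- function(dir, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n_samples = 60, populations = c("wild", "domestic", "jinchuan"),
    n_core = 150, n_accessory = 80, freq_lo = 0.05, freq_hi = 0.95,
    depth_hom = 20, depth_het = 10, depth_absent = 0, noise = "poisson",
    causal_gene = "acc0001", baseline = 14, effect = 1, noise_sd = 0.25,
    seed = 1), config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_truth(cfg$n_samples, populations = unlist(cfg$populations),
                      n_core = cfg$n_core, n_accessory = cfg$n_accessory,
                      freq_range = c(cfg$freq_lo, cfg$freq_hi),
                      seed = cfg$seed)
  models <- synthetic_gene_models(rownames(truth$copy))
  depth <- simulate_depth(truth, models,
                          coverage_model(cfg$depth_hom, cfg$depth_het,
                                         cfg$depth_absent, cfg$noise),
                          seed = cfg$seed + 1L)
  pav <- pav_from_truth(truth)
  trait <- simulate_trait(pav, trait_model(cfg$causal_gene, cfg$baseline,
                                           cfg$effect, cfg$noise_sd),
                          seed = cfg$seed + 2L)
  classes <- setNames(ifelse(rownames(truth$copy) %in% truth$reference_genes,
                             "core", "shell"), rownames(truth$copy))
  expr <- simulate_expression(classes, seed = cfg$seed + 3L)
  paths <- list(
    depth = write_depth(depth, file.path(dir, "depth.tsv")),
    metadata = write_metadata(truth$samples, file.path(dir, "metadata.csv")),
    trait = {
      p <- file.path(dir, "trait.csv")
      utils::write.csv(trait, p, row.names = FALSE, quote = FALSE); p
    },
    truth_pav = write_pav_matrix(pav, file.path(dir, "truth_pav.tsv")),
    genes = write_gene_models(models, file.path(dir, "genes.gff3")),
    expression = write_matrix_tsv(expr$values, file.path(dir, "expression.tsv")),
    groups = {
      p <- file.path(dir, "expression_groups.csv")
      utils::write.csv(data.frame(sample_id = names(expr$groups),
                                  group = unname(expr$groups)),
                       p, row.names = FALSE, quote = FALSE); p
    })
  invisible(paths)
}
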