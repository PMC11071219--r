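---
title: "Methods behind panpav: pangenome presence/absence-variation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind panpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
```

# The problem

A single reference assembly underrepresents a species' gene content:
individuals carry genes the reference lacks, and lack genes the reference
carries. `panpav` implements the standard map-to-pan answer for a diploid
livestock-scale genome: build a pangenome by harvesting nonreference
sequence from multiple de novo assemblies, call each gene present or absent
in each resequenced individual from exonic read coverage, and analyse the
resulting binary matrix at the population level — occupancy classes,
rarefaction, ordination, selection tests, breed-specific genes,
a hybridization screen, trait association, and expression integration.

This vignette records the model behind each step, the defaults and why they
were chosen, the numerical conventions, and what the synthetic generator
does and does not emulate.

# Pangenome construction

`iterate_pan()` consumes pairwise whole-genome alignment blocks
(coords-style TSV or PAF) and is agnostic to the aligner; `minimap2_hook()`
wraps minimap2 with base-level CIGARs. Alignments that span large indels
are split into indel-free blocks at insertions/deletions of at least
`split_at` bp (default 100), since the extraction logic needs the *covered*
query intervals, not the chained span.

Per round, for one genome against the current pan-reference:

1. **Filter** (`filter_alignments()`): keep blocks with identity ≥ 0.95 and
   length ≥ 100 bp, then select per query contig a non-overlapping subset,
   greedily by decreasing length with ties broken by identity and then
   input order. Greedy selection is used because it is deterministic and
   easy to audit; the exact algorithm used by classical one-to-one
   delta-filtering is not specified anywhere, and on non-pathological
   assemblies the greedy and optimal subsets coincide (the unit tests check
   the pairwise-disjointness invariant and the two-block cases exactly).
2. **Complement** (`absent_regions()`): per query contig, the set
   complement of the union of kept intervals, dropped below
   `min_segment_length` (default 100 bp — unaligned slivers shorter than
   the alignment length floor carry no usable signal; configurable).
3. **Dedupe** (`dedupe_nonref()`): realign candidates to the pan-reference;
   remove a candidate iff its aligned fraction exceeds 0.90 *and* its
   length-weighted mean identity exceeds 0.95, both strictly. Two readings
   of the usual "90% regional similarity / 95% similarity rate" recipe are
   possible (coverage + identity, or two identity thresholds); the
   coverage + identity reading is adopted because the two numbers otherwise
   describe the same quantity. Mean identity is length-weighted across a
   candidate's alignments because an unweighted mean over-counts short
   spurious hits. A candidate with no realignment record is retained as
   fully novel.
4. **Append** the survivors to the pan-reference for the next genome.

After the last round, every retained segment is realigned to the *original*
reference and deduplicated once more. Genome processing order is the input
order; the final pass makes the retained set order-robust on clean data,
and the per-round report records the order actually used.

`call_novel_genes()` marks a gene novel iff ≥ 80% of its span lies in
nonreference sequence (boundary inclusive: "80% or more"), and collapses
duplicate novel genes across genomes when their intervals on the same pan
segment reciprocally overlap by the same fraction.

# PAV calling

`call_pav()` reimplements the coverage rule of the SGSGeneLoss family of
tools: a gene is present in a sample iff the fraction of its exonic bases
covered by at least `min_cov = 2` reads is at least `lost_cutoff = 0.2`.

Two conventions deserve a note:

* **Boundary.** Descriptions of this rule sometimes say coverage
  "exceeding 20%"; the tool semantics, however, are *lost iff the covered
  fraction falls below the cutoff*, i.e. present iff ≥ 0.2. The tool
  semantics are adopted; a gene at exactly 0.20 is present.
* **Exon union.** Overlapping exon annotations are merged before counting,
  so the covered fraction cannot exceed 1 and no base is counted twice.

No mapping-quality or duplicate filtering is applied by default (none is
part of the rule); the depth table is taken at face value. Positions absent
from the depth table count as depth 0, so sparse depth exports are safe.
`assemble_matrix()` orders genes and samples lexicographically and fills
uncalled pairs with 0, with a warning carrying the count.

# Population statistics

**Classes** (`classify_genes()`): core = occupancy exactly 1; softcore =
[0.99, 1); shell = [0.01, 0.99); cloud = (0, 0.01); genes observed nowhere
are reported separately as "unobserved" rather than silently entering
cloud. Published descriptions ("more than 99%", "more than 1% but less than
99%", "fewer than 1%") are ambiguous at the 1%/99% boundaries; this one
consistent convention is exposed in `pav_class_config()` so users can adopt
another. `pan_size_summary()` derives percentage shares and the
softcore + shell ("PAV-related") total from class counts.

**Saturation** (`saturation()`): for each subset size k, random sample
subsets without replacement (default 10,000 replicates, the conventional
figure for published rarefaction curves; `replicates` is exposed for
desk-scale work and `exhaustive = TRUE` enumerates all C(n, k) subsets,
which the tests compare against an independent enumeration oracle).
pan(k) counts genes present in ≥ 1 subset member, core(k) genes present in
all members. For nested subsets pan is monotone non-decreasing and core
non-increasing — an exact property the tests check directly.

**PCA** (`pca_binary()`): samples are observations, genes variables;
mean-centering only (no scaling — columns are already on a common 0/1
scale), singular-value decomposition, and a deterministic sign convention
(largest-magnitude loading of each component is made positive) so results
are reproducible across platforms.

**Frequency selection** (`freq_test()`): per gene a two-sided Fisher exact
test on the 2×2 presence table, BH correction across all tested genes, and
selection at FDR < 0.001 with frequency fold > 2. The fold ratio uses a
half-count continuity correction, eps = 1/(2·max(n_a, n_b)), because genes
entirely absent in one group (frequency 0) are among the most interesting
selections and must not produce an undefined ratio. Genes absent in both
groups are excluded from testing and counted.

**Breed-specific genes** (`breed_specific()`): breeds with fewer than 3
individuals are dropped first (too few carriers to distinguish specificity
from sampling); a gene is specific to a breed set iff it has ≥ 1 carrier
inside and 0 carriers outside among retained samples. The asymmetry —
strict on absence outside, lenient on presence inside — matches how
variety-specific genes are screened in practice; `min_inside_fraction`
tightens the inside requirement when desired. An exclusion list
(e.g. contaminant genes flagged by taxonomic screening, which is outside
this package's scope) is applied to the result, with the removed count
reported.

# The two-haplotype hybridization screen

The screen formalises a genotype pattern: when two populations each carry
(mostly heterozygously) genes the other lacks, a cross-population hybrid
can be *homozygous* for discriminative genes of both sides at once, having
inherited one full haplotype from each parent pool.

* `infer_genotypes()` assigns copy states from depth ratios
  r = gene mean exonic depth / sample baseline depth (baseline = the
  sample's median over present genes). Present genes are homozygous (2) iff
  r ≥ 0.75, else heterozygous (1); absent genes are 0. The het band is
  nominally [0.25, 0.75]; a present gene with r < 0.25 is still called
  heterozygous — the presence call dominates — and the count of such
  low-ratio calls is attached for diagnostics. At exactly r = 0.75 the
  homozygous call wins. Collapsing 1,2 → 1 reproduces the input PAV matrix
  exactly, by construction.
* `detect_hybrids()` reports a sample iff some gene pair (one from each
  discriminative set) is homozygous in it while, among the *other* carriers
  of each gene in its high-frequency population, the heterozygous fraction
  is ≥ `het_min` (default 0.5 — "widespread heterozygosity" read as a
  majority). The focal sample is excluded from its own background so a
  single individual cannot vouch for itself. The score counts qualifying
  pairs; raising `het_min` can only shrink the candidate set (an
  anti-monotonicity the tests check).

Every threshold here is a package formalisation of a pattern that is
usually described by worked example only; all are exposed in the function
signatures.

# Trait association

`gwas_pav()` regresses the trait on each binary marker separately
(optionally with PCA covariates), reporting the coefficient's two-sided
t-test p-value against the Bonferroni threshold α/m, where m counts the
markers actually tested — markers constant within the tested samples are
dropped and never inflate m. Multi-locus GWAS machinery (iterative
bin/pseudo-QTN selection) is deliberately not reproduced: the scientifically
load-bearing choices are the marker encoding and the threshold, and a
single-marker linear model is transparent, exactly calibrated under the
null (verified by simulation in the tests), and adequate for binary
presence markers. Shell genes are the natural marker set, since core genes
are monomorphic and cloud genes nearly so.

`gchap_group()` groups samples by exact identity of the allele string over
a gene's CDS variant sites (phased haplotypes when available, otherwise
site-wise diploid genotype strings), reports per-group trait means, labels
groups `Hap_1, Hap_2, ...` by decreasing size, suppresses groups below
`min_n = 10` from the report while still counting them (the smallest
groups' means are sampling noise, but dropping them silently would break
the partition accounting), and optionally runs a Kruskal–Wallis test across
retained groups — rank-based because group sizes are small and trait
distributions within haplotype groups need not be normal.

# Expression integration

* `fpkm()`: value = count × 10⁹ / (total × length_bp); invariant under
  joint rescaling of counts and totals.
* `tau()`: tau = n/(n−1) − Σx_i/((n−1)·max x_i) over **group means** — the
  index is defined on one value per tissue/group, so per-sample replicates
  are averaged within groups first (`tau_index()`). tau is 0 iff the
  profile is uniform, 1 iff exactly one group is nonzero, and NA for an
  all-zero gene (no defined specificity). No default cutoff for calling a
  gene "specifically expressed" is imposed; that threshold is an explicit
  argument wherever it matters.
* `de_simple()` is a deliberately plain two-group test — Welch t on log2
  values with a half-minimum pseudo-value for zeros, BH correction, DE iff
  q < 0.05 and fold > 2. It exists so the pipeline is self-contained and
  calibrated (its null false-positive rate is checked by simulation); it is
  *not* a count-model DE method, and real count data should go to DESeq2 or
  edgeR.
* `coexpression_pairs()` reports lncRNA–mRNA pairs with |Pearson r| ≥ 0.9;
  the threshold is a package default (commonly used, but no canonical value
  exists) and is exposed.
* `burden_table()` tabulates pre-annotated variant records per gene,
  sample and consequence; consequence prediction itself is out of scope.

# The synthetic generator

`make_truth()` draws, per accessory gene and population, a presence allele
frequency f, then per sample a copy state ~ Binomial(2, f) — two
independent Bernoulli haplotype draws. A gene is present iff copy ≥ 1, so
the expected presence frequency is 1 − (1 − f)², a relationship the tests
verify empirically. Reference (core) genes have f = 1 everywhere.
`simulate_depth()` gives every exonic base expected depth 20/10/0 for copy
states 2/1/0 with Poisson noise by default — the scale of typical ~10–20×
short-read resequencing, and the 2:1:0 ratio is exactly the diploid
assumption the genotype inference inverts. `simulate_trait()` adds
`effect` trait units per presence of one causal gene over a baseline
(default 14, a rib-count-like scale) with Gaussian noise.
`simulate_expression()` draws lognormal noise around occupancy-class means
(core highest by default) with optional tissue-specific genes.
`synthetic_genomes()` plants labelled insertions into a random reference so
the pan-construction loop has an exactly known answer.

Defaults the literature does not fix — three populations, three breeds per
population, accessory allele frequencies uniform on [0.05, 0.95] — are
package choices, made once, and are stated as such.

**What the generator does not emulate:** read-level sequencing error and
mapping ambiguity (depth is drawn directly, so there are no misalignment
artefacts); linkage between genes; population structure beyond
per-population frequencies (no kinship, no admixture gradients); GC or
repeat-driven coverage bias; and SNP haplotypes beyond user-supplied CDS
allele strings. Passing tests therefore demonstrate the *logic* of the
pipeline — thresholds, complements, partitions, calibration — not
robustness to alignment artefacts in real short-read data.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 and coords files are
  written/read 1-based inclusive; PAF is natively 0-based half-open.
  Depth-table positions are 1-based (as `samtools depth` prints).
* Strict vs inclusive boundaries follow the wording of each rule: dedupe
  thresholds are strict (`> 0.90`, `> 0.95`); the novel-gene and presence
  rules are inclusive (`≥ 0.80`, `≥ 0.2`); occupancy classes use the
  convention above.
* Ties in one-to-one filtering break by identity then input order; PCA
  signs are fixed by the largest loading; haplotype groups of equal size
  order lexicographically.
* Degenerate inputs fail loudly: zero-length exons, empty matrices,
  zero baselines, zero sequencing totals, overlapping test groups and
  mismatched haplotype string lengths are errors; malformed alignment
  records, unknown variant genes, metadata gaps and uncalled matrix cells
  are warnings with counts.

# Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated data at
desk scale, chosen to make every check sharp but quick: round trips at
30–60 samples × ~200 genes, noisy recovery at 500 genes × 50 samples,
selection and hybrid scenarios at 100 samples per population, GWAS power
at n = 300 with 100 markers over 100–200 replicates, rarefaction oracles on
10 × 10 matrices with exhaustive subset enumeration, and pan construction
on 20 kb synthetic contigs with 2–3 kb planted insertions. Published
population-scale figures that depend on hundreds of real resequencing runs
(total nonreference megabases, genome-wide class counts, concrete selected
gene lists) are inputs to arithmetic checks, not desk-scale reproduction
targets.

# Known limitations

* The one-to-one alignment filter is greedy, not provably optimal for
  adversarial overlap structures.
* Genotype inference from depth ratios assumes roughly uniform coverage;
  copy-number variation beyond 2 and coverage bias will blur the het/hom
  bands (the low-ratio diagnostic count is the first thing to inspect).
* `de_simple()` ignores count overdispersion; it is a calibrated stand-in,
  not a replacement for count models.
* The hybridization screen is a pattern detector, not an admixture model:
  it assigns no ancestry proportions and no statistical significance to a
  candidate, and its thresholds should be read as screening knobs.
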