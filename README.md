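# protoy

Analysis pipeline for studying how young **proto-Y chromosomes** act as
*trans* regulators of gene expression and male courtship behavior in the
house fly, *Musca domestica*.

House flies carry two common proto-Y chromosomes (Y^M and III^M) that are
nearly identical in gene content to their proto-X homologs, yet III^M
males out-compete Y^M males for mates and mate sooner. A family of odorant
binding protein genes (*Obp56h*, on chromosome V) is expressed higher in
Y^M males, and *Obp56h* expression is negatively associated with courtship
speed — so the question is which chromosome III alleles regulate *Obp56h*
in *trans*. `protoy` implements the full inference chain for this kind of
study, for researchers working on sex chromosome evolution, regulatory
variation, or insect behavior genetics:

- **Differential expression** between male types: CPM filtering,
  median-of-ratios variance-stabilizing normalization,
  surrogate-variable batch adjustment (SVD + permutation parallel
  analysis), empirical-Bayes moderated t statistics, and
  Benjamini–Hochberg FDR. Fold-changes are oriented III^M − Y^M.
- **Weighted co-expression network**: unsigned soft-threshold adjacency
  `a_ij = |r_ij|^β` with scale-free β selection, topological overlap,
  deterministic module detection (static modularity cut, minimum size 30,
  eigengene merging at 0.2), module eigengenes, module–trait association,
  and intramodular connectivity (kWithin) for hub ranking.
- **Connection scores** against the *Obp56h* seed family,

  `C_i = Σ_j a_ij · |F_j|`,

  where `F_j` is seed gene *j*'s log2 fold-change between male types;
  central-gene ranking (top 100) and Fisher's exact chromosome-enrichment
  tests.
- **Allele-specific expression**: diagnostic SNP selection (heterozygous
  in III^M males, homozygous in Y^M males), fragments-per-million depth
  normalization, three Wilcoxon rank-sum comparisons per site
  (III^M–III, III^M–Y^M, III–Y^M), and strict monoallelic-expression
  flags.
- **Behavior statistics**: accumulated degree days `(T_D − T_t) × d`,
  proportion Z-tests, competitive-courtship logistic models with type-II
  likelihood-ratio χ² tests, Cox proportional-hazards models for
  right-censored copulation latency (Efron ties), and nested-model χ²
  comparisons.
- **Cross-species resampling nulls**: mean log2 fold-change of an
  ortholog set against 10,000 random same-size subsets, and per-tissue
  expression normalization for heterogeneous platforms.
- A **synthetic-data generator** reproducing the study designs
  (9 Y^M + 15 III^M head libraries in 3 batches; 4 + 4 strain-by-batch
  allele-depth groups; 4-hour mating assays scored every 10 minutes) with
  planted ground truth for parameter-recovery testing.

Everything is tidyverse-native: functions take data frames or matrices
and return tibbles, fitted objects have `tidy()`/`glance()` methods, and
`plot_volcano()`, `plot_ase()`, `plot_latency_curves()`, and
`autoplot()` give ggplot2 graphics.

## Worked example

Simulate a study with a planted *Obp56h*-like family (9 genes, 8 of them
higher in Y^M) inside a 60-gene co-expression module, run the expression
and network stages, and score the connection of every other transcript to
the family:

```r
library(protoy)

cfg <- sim_config(
  n_genes     = 500,
  module_spec = list(list(size = 60, latent_correlation = 0.7)),
  de_spec     = data.frame(gene = c(1:9, 61), log2fc = c(rep(-1.2, 8), -0.3, 1.33)),
  seed        = 20
)
sim  <- simulate_counts(cfg)
expr <- normalize_vst(filter_low_expression(sim$counts))
sv   <- estimate_surrogate_variables(expr, sim$metadata$genotype)
de   <- fit_de_model(expr, sim$metadata$genotype, sv)
de
#> Moderated differential-expression fit (IIIM - YM)
#> 500 genes; 7 DE at FDR 0.05; 2 surrogate variables; prior df 56.5
```

Negative `log2fc` means higher expression in Y^M males — the fit
recovers the planted family direction (e.g. `gene_0001`: log2fc −1.76,
p_adj 1.2e-6). Now the network stage and the connection-score ranking:

```r
adj    <- adjacency(correlation_matrix(expr), 7)
family <- sprintf("gene_%04d", 1:9)
cs     <- connection_scores(adj, family, de)
head(cs, 3)
#> # A tibble: 3 × 3
#>   gene      score  rank
#>   <chr>     <dbl> <int>
#> 1 gene_0012 1.62      1
#> 2 gene_0051 1.23      2
#> 3 gene_0045 1.09      3

ann <- tibble::tibble(gene = names(sim$truth$module),
                      chromosome = ifelse(sim$truth$module == 1, "III", "V"))
chromosome_enrichment(central_genes(cs, k = 50), ann, "III")
#> Fisher's exact test
#>         focal other
#> in_set     43     7
#> out_set    17   433
#> Sample odds ratio = 156.5, two-sided p = 1.017e-40
```

The top-connected transcripts are overwhelmingly drawn from the planted
module (43 of the top 50, p ≈ 1e-40): this is the construction that, on
the real data, localizes the candidate *trans* regulators of *Obp56h* to
chromosome III. Finally, a censored-latency survival model on simulated
mating trials (planted hazard ratio 2.92, III^M vs Y^M):

```r
trials <- simulate_mating_trials(400, seed = 20)
cox    <- fit_cox_latency(trials$latency, c("genotype", "temperature"))
tidy(cox)
#> # A tibble: 2 × 6
#>   term         estimate    hr conf_low conf_high        p
#> 1 genotypeIIIM    0.943 2.57     1.76      3.75  1.04e- 6
#> 2 temperature    -0.186 0.830    0.784     0.880 2.79e-10
```

A hazard ratio above 1 means III^M males mate faster; the estimate 2.57
(95% CI 1.76–3.75) recovers the planted effect within sampling error.

## Command line

A thin wrapper over the same functions lives at `inst/cli/protoy`:

```sh
Rscript inst/cli/protoy simulate --n-genes 2000 --seed 1 --out-prefix sim
Rscript inst/cli/protoy de --counts sim_counts.tsv --metadata sim_metadata.csv --out de.tsv
Rscript inst/cli/protoy network --counts sim_counts.tsv --metadata sim_metadata.csv
Rscript inst/cli/protoy add --conditions conditions.csv
```

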