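# editscape

RNA-editing landscape analysis from matched DNA and RNA evidence, for
case/control cohorts sampled in two tissues. editscape calls A-to-I
dominated editing sites from site-level RNA pileups, annotates them
strand-aware, tests group-level editing statistics, quantifies and tests
gene expression, and integrates editing with expression — and it ships a
fully ground-truthed synthetic-cohort generator so every stage is
validated by recovery against known implants.

## What it does

**Site calling.** At each pileup position the candidate alternative
allele gets an exact binomial upper-tail p-value against sequencing error
(`Pr[X ≥ k]`, `X ~ Binomial(n, e)`, default `e = 0.01`), Benjamini–
Hochberg adjusted per sample. Calls must pass FDR ≤ 0.05, have an
alternative allele frequency in `[0.01, 1.0)` (fully alternative sites
are genomic, not editing), survive germline subtraction against the same
sample's DNA genotypes (GQ ≥ 30; sites with < 10× DNA coverage are
conservatively dropped as unverifiable), and avoid cataloged SNP
positions. Called sites are flagged against a known-editing catalog.

**Annotation.** Changes are complemented into transcript orientation
(genomic `T>C` in a minus-strand gene is A-to-I), regions assigned with
precedence CDS > UTR > noncoding exon > intron > intergenic, CDS sites
translated for synonymous/nonsynonymous/stop recoding via the standard
genetic code, and repeat class assigned as Alu > repetitive non-Alu >
nonrepetitive.

**Statistics.** Exact Wilcoxon / Kruskal–Wallis comparisons of per-sample
summaries, χ²/Fisher proportion tests, a paired one-sided signed-rank
test for nonsynonymous excess, and an essentiality analysis against the
background gene set.

**Expression.** FPKM (`counts / (length_kb · libsize/1e6)`), a
transparent moments-based negative-binomial Wald test (median-of-ratios
size factors, trend-shrunk MoM dispersions, delta-method SE; significant
at `padj ≤ 0.05` and `|log2FC| ≥ 1`), and NIPALS PLS-DA. The DE test is
deliberately not a re-implementation of any published tool; the test
suite cross-checks it against DESeq2 as an independent reference.

**Integration.** Hypergeometric gene-set over-representation
(`padj < 0.05`), condition-specific edited-gene set algebra, and Spearman
correlations with exact permutation p-values for n ≤ 9 (ADAR expression
vs site counts; per-gene editing level vs own expression).

Results are tibbles throughout; `edit_de` and `edit_plsda` fits support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

`run_pipeline()` simulates a cohort to disk, re-reads every input through
the package's file readers (stages communicate only through files), and
runs the full analysis:

```r
library(editscape)
run <- run_pipeline(sim_params(), edit_config(), seed = 1)
run
#> editscape pipeline run
#>   seed: 1  samples: 16
#>   called sites: 5207 (known-catalog overlap 0.52)
#>   powered sensitivity 0.971, empirical FDR 0.005
#>   report tables: 9 (out_dir: ...)
```

The recovery table scores calls against the implanted truth — with the
default cohort (5 case + 3 control subjects × 2 tissues), 97.1% of
powered implants (true level ≥ 0.05, depth ≥ 30) are recovered at 0.5%
empirical FDR and zero surviving high-confidence SNPs:

```r
run$recovery
#> # A tibble: 1 × 7
#>   sensitivity sensitivity_powered empirical_fdr n_snp_survivors_gq30 n_called
#> 1       0.942               0.971       0.00461                    0     5207
```

Differential expression recovers the implanted fold changes:

```r
head(dplyr::arrange(run$de$case_vs_control_subcutaneous, padj), 3)
#>   gene_id base_mean log2fc    se   wald_p     padj significant
#> 1 g032         167.   2.43 0.203 5.01e-33 4.01e-31 TRUE
#> 2 g057         130.  -1.99 0.183 1.80e-27 7.22e-26 TRUE
#> 3 g067         128.  -2.30 0.233 6.11e-23 1.63e-21 TRUE

counts <- read_count_matrix(run$files$counts)
de <- nb_wald_de(counts, run$samples, c("group", "case", "control"))
glance(de)
#>   n_genes n_significant  n_up n_down contrast
#> 1      80             8     4      4 group:case:control
```

Enrichment flags the planted terms among decoys, and the Alu fraction of
called sites sits at the configured 80% in every condition:

```r
head(run$enrichment, 2)
#>   term_id term_name                 K     k     n     N       p    padj enriched
#> 1 PLANT01 immune-like planted …    16    11    21    80 7.07e-5 0.00184 TRUE
#> 2 PLANT02 immune-like planted …    16    11    21    80 7.07e-5 0.00184 TRUE

run$alu$per_condition
#>   group   tissue       n_sites frac_alu frac_non_alu_repeat frac_nonrepetitive
#> 1 case    abdominal       1902    0.808              0.0258              0.167
#> 2 case    subcutaneous    1865    0.805              0.0268              0.168
#> 3 control abdominal        731    0.814              0.0287              0.157
#> 4 control subcutaneous    709     0.804              0.0310              0.165
```

ADAR expression correlates with per-sample site counts
(`r = 0.70, p = 0.0025` at this seed), and plots come from
`autoplot(de)`, `autoplot(pls_da(run$fpkm, run$samples))`,
`plot_type_distribution()`, `plot_region_distribution()` and
`plot_alu_fraction()`.

See `vignettes/editing-landscape-methods.Rmd` for the statistical model
behind each stage, the rationale for every default, and the generator's
scope and limitations.

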