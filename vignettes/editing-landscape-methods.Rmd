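---
title: "Methods: calling, annotating and integrating an RNA-editing landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, annotating and integrating an RNA-editing landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

editscape analyses the RNA-editing landscape of a case/control cohort in
which every subject contributes samples from two tissues, with matched DNA
genotypes available for germline subtraction. This vignette records the
statistical model behind each stage, the reasoning behind every default,
and what the bundled synthetic-data generator does and does not emulate.

## 1. Site calling

The caller consumes site-level RNA pileups (per sample, per position: the
four base counts against a reference base) and emits editing sites.

**Candidate detection.** At each position the candidate alternative allele
is the non-reference base with the highest count; ties are ambiguous and
yield no candidate. Under the null hypothesis that all mismatches are
sequencing error at per-base rate $e$ (default 0.01), the alternative count
$k$ out of $n = k_{\mathrm{ref}} + k_{\mathrm{alt}}$ informative reads is
binomial, and the candidate p-value is the exact upper tail

$$
p = \Pr[X \ge k], \qquad X \sim \mathrm{Binomial}(n, e),
$$

computed as `pbinom(k - 1, n, e, lower.tail = FALSE)`. Errors are assumed
uniform over the three wrong bases, so $e$ is deliberately conservative for
any single alternative allele.

**Multiple testing.** P-values are Benjamini–Hochberg adjusted *within each
sample* by default (`bh_scope = "per_sample"`). Each sample is its own
family: its candidate list stands alone as that sample's editing call set,
and per-sample adjustment keeps the achieved FDR comparable between samples
with very different candidate counts (cases carry more sites than
controls). Cohort-wide pooling is available as `bh_scope = "pooled"`.

**Filtering.** Three filters are pure per-row predicates, so the call set
is invariant to their order (a property the test suite verifies against a
brute-force predicate intersection):

- FDR: adjusted p-value $\le$ 0.05.
- AAF window: the alternative allele frequency must lie in $[0.01, 1.0)$.
  The lower bound removes levels indistinguishable from error; the open
  upper bound removes fully alternative sites, which are genomic variants,
  not partial editing of a transcript pool.
- Germline subtraction: a candidate is dropped when the *same sample's*
  DNA shows a variant genotype at the position with the same alternative
  allele (genotype quality $\ge$ 30, site QUAL $\ge$ 2), and also —
  conservatively — when the sample's DNA covers the position with fewer
  than 10 reads, because such a site cannot be verified as non-genomic.
- Known-SNP removal is positional and sample-agnostic: a cataloged SNP
  position is removed from every sample, since a polymorphism in any
  subject makes the position untrustworthy cohort-wide.

Finally, calls are flagged against a known-editing catalog and the
fraction of distinct called sites present in the catalog is reported; for
a well-behaved call set on human-like data this overlap is substantial,
and on the synthetic cohort it recovers the configured catalog coverage.

## 2. Strand-aware annotation

Editing chemistry happens on the transcript, so genomic changes are
complemented into transcript orientation before typing: a genomic `T>C`
inside a minus-strand gene is the transcript change `A>G`, i.e. A-to-I.
Sites in overlapping genes on both strands (or outside any gene) are
reported with their genomic change and `strand_resolved = FALSE`.

Region assignment uses precedence CDS > 3'UTR > 5'UTR > noncoding exon >
intron > intergenic within the assigned gene (ties between genes go to the
longer gene, with a message). For CDS sites in recoding-eligible models
(CDS length divisible by three) the codon is rebuilt in transcript
orientation and translated with the standard genetic code; effects are
`synonymous`, `nonsynonymous`, `stop_gain` or `stop_loss`. Repeat class
follows precedence Alu > repetitive non-Alu > nonrepetitive from a BED
interval layout (0-based half-open, as BED is defined).

## 3. Group-level statistics

Per-sample summaries (site counts, edited-gene counts, mean levels) are
compared between two groups by exact Wilcoxon rank-sum whenever the total
sample count is small enough ($\le 10$), otherwise by the normal
approximation; three or more groups dispatch to Kruskal–Wallis. Identical
multisets short-circuit to a degenerate $p = 1$ rather than a misleading
tie-corrected value. Proportion tables use $\chi^2$ without continuity
correction, falling back to Fisher's exact test when any expected cell
drops below 5.

The synonymous/nonsynonymous analysis counts both stop changes as
nonsynonymous and applies a *paired, one-sided* Wilcoxon signed-rank test
per condition (nonsynonymous > synonymous within each sample): counts of
the two classes in the same sample share depth and site-count effects, so
pairing removes them, and the direction is fixed a priori. The
essentiality analysis tests the edited/non-edited by essential/
nonessential 2×2 against the background gene set and compares per-gene
mean editing levels of nonsynonymously edited genes by rank-sum.

## 4. Expression and differential expression

FPKM is computed as
$\mathrm{counts} / (\mathrm{length}_{kb} \cdot \mathrm{libsize}/10^6)$
with exonic-union gene lengths.

Differential expression uses a transparent negative-binomial Wald test
built from first principles — deliberately *not* a re-implementation of
any published tool (the test suite cross-checks fold-change agreement with
DESeq2, which is kept strictly as an independent reference):

1. median-of-ratios size factors over genes nonzero in every sample;
2. per-gene method-of-moments dispersion
   $\hat\alpha = (\hat v - \hat\mu)/\hat\mu^2$ pooled within groups,
   shrunk toward the cohort trend (the median dispersion of the
   upper-expression genes) with prior weight 4 and floored at $10^{-8}$;
3. $\log_2$ fold change of normalised group means with pseudocount 0.5;
4. delta-method standard error from the NB variance function
   $v(\mu) = \mu + \alpha\mu^2$, two-sided normal p-value, BH adjustment.

A gene is significant when $p_{adj} \le 0.05$ *and* $|\log_2 FC| \ge 1$.
The pseudocount bounds the fold change of lowly expressed genes; the
dispersion floor keeps the Wald variance positive for ultra-clean genes;
the shrinkage stabilises 3–5-sample groups without erasing genuine
per-gene signal.

PLS-DA is NIPALS against a mean-centred one-hot class response on
$\log_2(\mathrm{FPKM}+1)$ features, with component count truncated to the
matrix rank. It is used for visual group separation, not inference; the
test suite checks separation against label permutations rather than
against a parametric null.

## 5. Enrichment and integration

Over-representation of a query gene set in a catalog term is the
hypergeometric upper tail $\Pr[X \ge k]$ with the annotated gene universe
as background, BH-adjusted across terms, enriched at $p_{adj} < 0.05$.
Condition-specific edited-gene sets are plain set algebra over
group-by-tissue conditions (sizes of both exclusive sets and the
intersection for every pair, plus the genes behind each exclusive set).

Rank correlations are Spearman with midranks. For $n \le 9$ tie-free
pairs the p-value is computed by *exact permutation enumeration* (all $n!$
rank assignments, cached), which matches the classical exact test;
otherwise the t-approximation is used. Two applications ship: ADAR
expression (summed FPKM over the ADAR gene set) against per-sample called
site counts, and per-gene editing level (mean over the gene's called
sites in a sample) against the gene's own FPKM, requiring at least three
informative samples and BH-adjusting across genes.

## 6. The synthetic cohort generator

Every stage is validated by recovery against a generator whose ground
truth is fully known. The generator builds, per seed:

- a two-chromosome genome (220 kb) tiled with 80 stranded three-exon
  genes (10% noncoding, 20% flagged essential), Alu-like repeats covering
  25% of the genome and other repeats 8%;
- 250 shared editing sites, 70% A-to-I in transcript orientation, 80%
  inside Alu, with Beta(2, 6) true levels clipped to [0.01, 0.95]; cases
  carry 1.6× the expected per-sample site count via additional
  case-specific sites, which are preferentially (70%) placed in a
  reserved 30% of genes so that case-only edited-gene sets are
  non-trivial;
- 150 germline SNPs (half cataloged, half only discoverable from the
  matched DNA genotypes), 400 non-edited background positions, and a
  known-editing catalog covering implanted *and* plausible background
  positions at the configured 50% rate, plus decoys — mimicking a
  genome-wide editing database rather than a list restricted to true
  sites;
- per-sample RNA pileups (Poisson depth, mean 60) with exact multinomial
  base counts at error rate 0.01, and DNA genotype records (mean depth
  30) including explicit homozygous-reference records so DNA coverage is
  observable; 1% of DNA records carry genotype quality below 30,
  reflecting a realistic residual low-confidence rate at ~30× coverage;
- negative-binomial expression counts with 8 implanted DE genes at
  $|\log_2 FC| = 2$, an ADAR-like gene whose expression tracks per-sample
  implanted-site counts, and 8 coupled genes (drawn from Alu-rich coding
  genes, each given three shared sites) whose expression scales with the
  sample's squared editing propensity;
- per-sample editing propensities $m \sim U(0.6, 1.4)$ that multiply all
  of a sample's true levels, creating realistic sample-to-sample
  level variation.

All randomness flows through named RNG substreams derived from the master
seed, so every artefact is bit-reproducible and independent stages do not
perturb each other's draws.

**What the generator does not emulate:** alignment artefacts,
strand-specific library protocols, hyper-edited read clusters,
position-dependent error profiles, isoform structure, GC or mappability
bias. It is a calibration instrument for the statistics, not a sequencing
simulator.

**Known generative confounder.** Because coupled-gene counts scale with a
sample's editing propensity, they contribute propensity-correlated mass
to every sample's library size, so after FPKM normalisation all *other*
genes acquire a slight negative correlation between editing level and
expression (mean $r \approx -0.07$ on defaults). Uncoupled-gene p-values
are therefore uniform within any single cohort to the resolution of a KS
test, but pooling thousands of them across many replicates resolves this
small real effect. This is a property of library normalisation that real
studies share, and it is why the correlation stage reports effect sizes
alongside p-values.

## 7. Pipeline contracts

`run_pipeline()` writes the simulated inputs to disk (FASTA, GTF, BED,
VCF, TSVs), then *re-reads every input through the package's own
readers* before analysis — stages communicate only through files, so each
stage is independently testable and the formats are exercised on every
run. The report directory carries eight analysis tables plus a
truth-vs-called recovery table, and a manifest hash ties the outputs to
the configuration and seed; identical seeds reproduce every byte.

## 8. Worked example

```{r example}
library(editscape)
run <- run_pipeline(sim_params(), edit_config(), seed = 1)
run                  # recovery and overlap summary
run$recovery         # sensitivity / FDR against implanted truth
head(run$de$case_vs_control_subcutaneous)

counts <- read_count_matrix(run$files$counts)
de <- nb_wald_de(counts, run$samples, c("group", "case", "control"))
glance(de)
autoplot(de)
autoplot(pls_da(run$fpkm, run$samples))
```
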