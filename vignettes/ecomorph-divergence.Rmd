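---
title: "Quantifying ecomorph divergence from pooled transcriptomes and landmark shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ecomorph divergence from pooled transcriptomes and landmark shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Within-species ecomorphs — morphological variants tied to a habitat, such as
snail radula morphs foraging on wood versus rock — raise a concrete
quantitative question: are the morphs diverging evolutionary lineages, and if
so, is divergence concentrated in the trait-forming tissue? `ecomorphdiv`
implements a pipeline that answers this from three kinds of evidence:

1. **Pool-seq allele counts** along transcripts (two ecomorphs, three pools
   each): coverage standardization, SNP calling, SNP-wise fixation index
   $F_{st}$, and detection of *alternatively fixed SNPs* (af-SNPs) — sites at
   which every pool of one morph is fixed for one allele and every pool of
   the other morph for the alternative.
2. **Fragment counts** per gene for three tissues (radula, mantle, foot) ×
   two morphs × three pools: tiered differential expression, expression
   (FPKM) gating, and tissue-wise divergence statistics.
3. **2-D landmark configurations** of shells: generalized Procrustes
   analysis, shape PCA, per-PC group tests, and a substrate × morph χ² test.

Because the sequencing data behind such a study cannot be re-analyzed at desk
scale, every stage is driven by a synthetic-data generator with fully known
ground truth (planted ORFs, af-SNPs, fold changes, shape displacement), so
every detector can be scored exactly.

# Models and procedures

## Coverage standardization and SNP calling

Variance in gene expression translates into variance in pool-seq coverage,
which biases SNP detection. Each pool is therefore subsampled **without
replacement** to a uniform target coverage (default 20×): at each retained
site a multivariate-hypergeometric draw of 20 reads is taken from the pool's
(A, T, C, G) counts, and any site where any pool has fewer than 20 reads is
removed entirely. Subsampling streams are derived per (contig, position,
pool), so results do not depend on the order sites are processed.

SNPs are then called on counts combined over all pools: alleles are ranked by
combined count (ties broken A < C < G < T), reads of third-ranked and lower
alleles are discarded, and a site is kept as a biallelic SNP iff its combined
minor-allele frequency is at least the MAF threshold (default 10%, kept as
$\ge$ at the boundary). The MAF gate is global rather than per-comparison so
that one SNP list underlies all downstream statistics.

## $F_{st}$ and af-SNPs

SNP-wise $F_{st}$ uses the classical heterozygosity form. For two units with
major-allele frequencies $p_1, p_2$:

$$\pi_u = 1 - p_u^2 - q_u^2, \qquad
  \pi_{within} = \tfrac{1}{2}(\pi_1 + \pi_2), \qquad
  \pi_{total} = 1 - \bar p^2 - \bar q^2,\ \ \bar p = \tfrac{1}{2}(p_1+p_2),$$

$$F_{st} = \frac{\pi_{total} - \pi_{within}}{\pi_{total}},
  \qquad F_{st} \equiv 0 \text{ when } \pi_{total} = 0 .$$

This estimator was chosen deliberately over finite-coverage-corrected or
variance-component (Weir–Cockerham) variants: it reaches the endpoints
*exactly* — $F_{st}=1$ iff the two units are fixed for different alleles and
$F_{st}=0$ for identical frequencies — which the af-SNP criterion requires
($F_{st}=0$ in all within-morph pool comparisons, $F_{st}=1$ in all
across-morph comparisons). The convention $F_{st}=0$ at $\pi_{total}=0$ makes
within-morph comparisons at jointly fixed sites evaluable. The detector
actually tests the equivalent direct condition (every pool monomorphic, the
morphs fixed for different alleles); the equivalence with the $F_{st}$
formulation is itself a tested invariant.

Three summaries are produced: the median SNP-wise $F_{st}$ for every pool
pair; the combined-morph distribution, where each morph's three pools are
summed (60× vs 60× at 20× per pool) with the MAF gate re-applied; and the
percentile position of the af-SNP class within that distribution.

## ORFs and codon effects

The longest complete ORF (ATG … stop, ≥ 30 nt, stop included, length a
multiple of 3) is found per transcript on the **forward strand only** —
libraries are strand-specific, so reverse-strand ORFs are artifacts here.
Leftmost wins on ties; candidates containing N are skipped; transcripts
without a complete ORF are excluded and counted. The 30 nt floor guards
against spurious micro-ORFs in random flanks and is configurable.

A SNP inside the ORF is classified by building its codon twice — once with
the major and once with the minor allele, the other two positions taken from
the transcript — and comparing translations under the standard genetic code.
Major/minor is used rather than reference/alternative because a pooled
assembly's reference base may carry either allele. Per gene, the density of
non-synonymous af-SNPs per kb of ORF is reported with fold enrichments
against all ORF-bearing transcripts and against af-SNP-bearing ones.

## Differential expression

The DE machinery is self-contained (no external DE package is called):

* **Normalization.** Median-ratio size factors: per sample, the median ratio
  of its counts to the per-gene geometric mean over genes positive in all
  samples, rescaled to library-size units (geometric mean of column totals);
  totals are used verbatim when fewer than 50 such genes exist. A sample
  whose counts are a global multiple of another gets exactly that multiple
  as its size ratio, and a planted asymmetric 5% of DE genes leaves null
  genes' median log-ratio at ≈ 0.
* **Dispersion.** A single common dispersion per contrast:
  $\hat\varphi_g = \max\{0, (s^2-\bar m)/\bar m^2\}$ per gene on
  normalized counts, then a 20%-trimmed mean over genes with mean ≥ 5. The
  trimming keeps planted DE genes and outliers from inflating the estimate.
* **Exact test.** Counts are rescaled to a common library size and rounded.
  Conditional on the grand total $T$, the probability of each split between
  the two group sums is evaluated under per-sample NB($\hat m$,
  $\hat\varphi$) (group sums aggregate the size parameter), and the
  two-sided p doubles the smaller tail, capped at 1. $\log_2$ fold change
  (rock vs wood) uses group means with a 0.5 pseudo-count — the pseudo-count
  affects reporting only, never the test.
* **Tiers.** Benjamini–Hochberg within each tissue contrast (three separate
  families, matching per-contrast calling), then DE requires FDR ≤ $10^{-2}$
  and linear fold change ≥ 4 (i.e. $|\log_2 FC| \ge 2$), highly DE
  additionally FDR ≤ $10^{-10}$. Highly-DE calls are nested within DE calls
  by construction.

Two artifact-level diagnostics accompany the calls. The **mapping-bias
test** asks, by two-sided Fisher's exact test, whether af-SNP-carrying genes
are overrepresented among DE genes (they should not be if mapping bias is
absent). The **allele-collapse check** flags pairs of highly DE genes with
opposite regulation whose sequences share > 95% identity over at least half
of the shorter sequence (local alignment, match +1 / mismatch −1 / gap −2,
11-mer prefilter) — the signature of alleles mis-assembled as two genes.

## Tissue-wise divergence

Genes (highly) DE in **all three** tissues are uninformative for
tissue-specific divergence and are excluded from numerators and
denominators. Per tissue, divergence in expression is the proportion of
expressed genes that are (highly) DE; divergence in coding sequence is the
frequency of af-SNPs among genes with non-universal expression, reported
overall, within ORFs, and for non-synonymous af-SNPs. "Expressed in a
tissue" means mean FPKM over that tissue's pools ≥ 1 in at least one morph
(the both-morph rule is reserved for the SNP-based candidate filter, which
states it explicitly); the mean-over-pools aggregation is the least noisy
deterministic choice. Tissue pairs are compared with two-sided Fisher tests
(sidedness is a convention here; two-sided is the conservative default), and
percent differences $(p_a-p_b)/p_b \times 100$ are reported, defined 0 when
both proportions are equal (including both zero).

The top-quantile composition pools all gene × tissue tests — not genes —
ranks them by p (ties by $|\log_2 FC|$ descending, then gene id), and
reports each tissue's share of the top 1% and 5%; pooling tests makes the
shares sum to one. The overlap statistic counts, per tissue, highly DE genes
carrying ≥ 1 af-SNP, split by codon effect, and how many are exclusive to
that tissue's highly-DE set.

## Candidate genes

Two filters, kept distinct but allowed to overlap (any intersection is
reported, never silently removed):

* **Expression-based:** radula FDR ≤ $10^{-10}$ and $|FC| \ge 4$, while in
  each of mantle and foot FDR ≥ $10^{-5}$ **and** $|FC| \le 4$. The quiet
  gate is read as a conjunction — the source phrasing separates the two
  conditions with a semicolon, and the conjunction is the stricter, more
  defensible reading. A gene untested in a tissue fails the radula criterion
  and passes the quiet criterion, with a logged count.
* **SNP-based:** ≥ 1 non-synonymous af-SNP and expressed (mean FPKM ≥ 1) in
  the radula of **both** morphs.

The report includes the distribution of non-synonymous af-SNP counts per
SNP-based candidate (fraction with exactly one; maximum) and the density
ranking.

## Morphometrics

Generalized Procrustes analysis iterates: center each configuration, scale
to unit centroid size, rotate onto the current mean by 2-D orthogonal
Procrustes (cross-covariance SVD with determinant forced +1 — reflections
are disallowed, the shape-biology convention), update and renormalize the
mean; it stops when the mean changes by < $10^{-8}$ or after 100 iterations.
Semi-landmarks are treated as fixed landmarks — no sliding criterion is
implemented, a logged limitation. PCA is run on the flattened Procrustes
residuals; PCs capturing ≥ 5% of total variance are tested between morphs
with Welch (unequal-variance) two-tailed t-tests, the safer default when
only "t-test" is specified. The habitat association uses Pearson χ² without
continuity correction on the 2×2 substrate × morph table; the uncorrected
statistic is the classical df = 1 test and is cross-checked against the
textbook formula in the suite. Radula ratio meristics (mixed units) are
standardized to unit variance before their PCA.

# The synthetic-data generator

`sim_config()` fixes the study conditions; a single seed is expanded into
named substreams (transcripts / alleles / counts / landmarks / subsampling),
so any stage reproduces in isolation and two identically seeded runs are
byte-identical down to the written files.

| parameter | default | what it encodes |
|---|---|---|
| `n_genes` | 2000 | transcripts/genes per dataset |
| `n_pools_per_morph` | 3 | pools per ecomorph |
| `mean_coverage` | 30 | Poisson depth per site and pool; exercises the < 20× removal path |
| `nb_dispersion` | 0.1 | NB dispersion of counts (0 = Poisson) |
| `baseline_log_expression` | meanlog log 20, sdlog 2.5 | per-gene expression scale; wide so some genes fail the FPKM ≥ 1 gate per tissue |
| `tissue_effect_sd` | 2 | per-gene, per-tissue log shifts; creates non-universal expression |
| `de_fraction_per_tissue` / `universal_de_fraction` | 0.05 / 0.01 | planted tissue-specific and universal DE |
| `planted_log2fc` | 3 | 8-fold planted effect, comfortably above the FC ≥ 4 gate |
| `expression_cap` | 2×10⁴ | caps a sample's expected count; bounds the generator's dynamic range |
| `snp_rate_per_kb` / `af_snp_fraction` | 10 / 0.012 | ≈ 15k SNPs per dataset with ≈ 1.2% alternatively fixed |
| `shared_maf_beta` | (2, 2) | allele frequency of shared variation |
| `monomorphic_rate_per_kb` | 20 | monomorphic filler sites (a full per-base site table would add nothing downstream) |
| `orf_fraction` | 0.6 | planted ORF share of transcript length |
| `landmark_n`, specimens | 12; 19 wood + 18 rock | landmark configurations; 37 specimens |
| `shape_effect` / `shape_noise_sd` | 0.15 / 0.02 | radial morph displacement on a third of landmarks vs isotropic noise |
| `morph_concordance` | 0.9 | P(morph matches substrate) — drives the χ² signal |

Key constructions:

* Each transcript carries exactly **one** planted ORF; flanks are re-drawn
  until it is the unique longest, so the finder's truth is unambiguous (real
  transcripts may contain several ORFs; the finder is still tested on
  multi-ORF fixtures built by concatenation).
* Shared-variation SNPs draw **one** allele frequency per site used by both
  morphs, so within- and across-morph pool pairs face identically
  distributed binomial sampling noise and the combined-morph median
  $F_{st}$ sits near 0; planted af-SNPs are the only systematic
  across-morph signal. (Per-morph frequency draws would plant drift-like
  divergence at every shared site; with a single frequency the median
  $F_{st}$ baseline is clean, which is what the endpoint and recovery
  checks need.) A consequence worth knowing: a 1% af-SNP admixture shifts
  the *mean* pairwise $F_{st}$ across morphs robustly but moves pair
  *medians* by less than their sampling noise at these sizes, so the suite
  asserts strict ordering of means and weak ordering of medians.
* Landmark specimens receive a random similarity nuisance — rotation in
  $[0, 2\pi)$, log-scale in $[-1, 1]$, translation — which GPA must remove;
  any nuisance distribution works since invariance is exact.
* Pool allele frequencies are the sampling unit: individual-level allele
  sampling within a pool (real pools hold 4–5 snails) is not modeled.

What the generator does **not** emulate: read-level artifacts (no FASTQ, no
mapping error, no sequencing-error model in the allele counts), batch
effects, isoform structure, linkage between SNPs, and selection acting on
expression. Passing tests therefore demonstrate that the estimators and
filters are correct and calibrated under the stated models — not that the
models capture every property of real pooled RNA-seq.

# Numerical choices and degenerate inputs

* $F_{st}$ endpoints are exact rational arithmetic on frequencies; tests use
  $10^{-12}$ tolerances only to absorb double rounding.
* Allele-rank ties are broken A < C < G < T — deterministic SNP lists.
* The exact test returns p = 1 and $\log_2 FC = 0$ when both groups are all
  zero; a degenerate Fisher margin returns p = 1 with a warning.
* BH is non-decreasing in p within a family (tested).
* GPA rejects configurations with all landmarks coincident; convergence is
  a handful of iterations for landmark-like data (a shared base shape plus
  noise). For unstructured configurations with shape variation on the order
  of the shape itself the contraction is slow — such data are outside the
  intended domain.
* Percentile reporting of af-SNPs is descriptive only; af-SNPs are defined
  by the fixation criterion, never selected by percentile.

# Problem sizes

Defaults run the full pipeline — ≈ 55k sites, ≈ 15k SNPs, 2000 genes × 18
samples, 37 specimens — in well under a minute. The test suite uses 5000
genes × 10 seeds for the null-calibration study, 20,000 sites with ≈ 100
planted af-SNPs for exact-recovery scoring, 1000 random tables for each of
the Fisher and χ² oracles, and 576 codon substitutions for the exhaustive
effect-classification check; these sizes give the oracles resolving power
while keeping a complete run interactive.

# Known limitations

* The $F_{st}$ estimator carries no finite-coverage bias correction — a
  deliberate trade for exact endpoints; absolute $F_{st}$ levels at 20×
  coverage are upward-biased for intermediate frequencies.
* One common dispersion per contrast (no tagwise/trended shrinkage, no GLM
  designs, no batch correction).
* Longest-ORF-only effect annotation; frameshifts, indels and alternative
  genetic codes are out of scope.
* No sliding semi-landmarks; 2-D landmarks only.
* Filler-site density and pool-frequency sampling are simplifications of
  real pool-seq site tables (see generator notes above).
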