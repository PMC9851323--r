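---
title: "Methods: scanning for young homomorphic sex-linked regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for young homomorphic sex-linked regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The problem and the model

A young sex-determining region leaves no coverage footprint: the Y (or W)
has lost essentially nothing, so male and female read depths match and the
region is invisible to the classic degenerate-Y diagnostics. What remains is
population-genetic structure. If males are XY and the sex-linked region
(SLR) rarely recombines in males, then at any site with a fixed or nearly
fixed X/Y difference every (non-recombinant, non-reversed) male is
heterozygous and every female homozygous. Three consequences follow, and the
scan measures all three:

* sex-association: the allele borne by the Y is present almost exclusively
  in males, so a 2 x 2 allele-count test against phenotypic sex is extreme;
* heterozygote excess confined to males: F~IS~ = 1 - H~o~/H~e~ is strongly
  negative in males across the region;
* between-sex differentiation: treating the sexes as two populations, the
  Weir-Cockerham (1984) F~ST~ estimator is elevated, reflecting the
  X/Y-associated linkage disequilibrium rather than true population
  structure.

The pseudoautosomal region (PAR) continues to recombine in both sexes and
shows none of these signals, so the PAR/SLR boundary appears as a
change-point in the windowed tracks.

### Statistics

Per site, with sample allele frequency $\hat p$: $H_e = 2\hat p(1-\hat p)$
(no small-sample correction; a deliberate choice matching the classical
F~IS~ definition), $F_{IS} = 1 - H_o/H_e$, undefined for monomorphic sites.
F~ST~ uses the full Weir-Cockerham variance components $a, b, c$ with the
sexes as the two populations; window values are the arithmetic mean of
per-site estimates by default (`mode = "mean"`), with the ratio-of-sums
variant (`mode = "weighted"`, the vcftools convention) available for
sensitivity analysis. Negative per-site estimates are retained, as they must
be for the window mean to be unbiased around zero under no differentiation.

The association test is a two-sided Fisher exact test on the allele-count
table by default. Resequencing studies of captive (family-structured)
populations typically run a kinship-corrected mixed model (EMMAX) on
imputed, phased genotypes instead; that machinery is intentionally out of
scope because the simulator generates unrelated individuals and unimputed
genotypes. The substitution matters in two ways, both documented here
because they shaped the pipeline:

1. *Exact tests are conservative.* At n = 30/29 the attained level at
   $\alpha = 0.05$ under label permutation is about 0.035. The
   `chisq_allelic` mode (same table, asymptotic reference) is the calibrated
   variant: its attained level is 0.05 within Monte-Carlo error. The exact
   mode never exceeds $\alpha$, which is the guarantee one wants for the
   Bonferroni scan itself.
2. *Mislabeled individuals cost the exact test dearly.* With ~15% of
   individuals sex-reversed, the best attainable pre-exclusion P is only
   ~5e-6, which can sit above a genome-wide Bonferroni threshold. The
   pipeline therefore (a) infers heterogamety from the **top-100**
   most-associated sites by rank, not from a significance cutoff, and
   (b) **recomputes the association scan after excluding flagged
   reversals**, using the recomputed scan for segmentation. Both are the
   standard devices in this kind of analysis: genotype heatmaps of the 100
   most strongly sex-associated SNPs, and statistics recomputed after the
   exclusion pass.

### Heterogamety and sex reversal

Among the selected sites, a site is male-het class if at least half the
males are heterozygous and at least half the females homozygous (the
"most individuals" reading), and mirror for female-het. XY is called when
the male-het share reaches 0.8 with exact binomial P < 0.01 against 0.5; ZW
mirrored; anything else — e.g. a 59% male-het share — is undetermined, and
downstream steps that need expected genotype patterns refuse to run.

A phenotypic male is flagged sex-reversed when ≥ 90% (`match_frac`) of its
non-missing genotypes at the top-100 sites are homozygous (the female
pattern under XY); females mirror. Detection runs once — a single exclusion
pass, no iteration — and the fraction 0.9 is a package choice where field
practice says only "almost all" sites. Flagged individuals stay in
the cohort for the association-by-rank step that found them but are excluded
from every recomputed statistic.

### Segmentation and region calling

`binseg_meanvar()` implements greedy binary segmentation under a Gaussian
cost in which both mean and variance change at a changepoint:
$\mathrm{cost}(i..j) = m\log\hat\sigma^2_{ij}$ with $\hat\sigma^2$ the MLE
variance floored at `var_floor = 1e-8` (so exactly constant stretches cannot
produce infinite gains). A split is accepted when its likelihood-ratio gain
exceeds the penalty; the default "MBIC" penalty is $4\log n$ (2 changed
parameters + the changepoint location), with "BIC" ($3\log n$) and numeric
overrides, since "binary segmentation on mean and variance" pins down the
algorithm but not the penalty. At most 3 changepoints are accepted per
track. On short series with
`max_cpts = 1` the greedy search is exactly the exhaustive optimal single
split, and the test suite asserts that equivalence.

Candidate boundaries come from three tracks independently — mean F~ST~, max
−log₁₀ P, male-het density — and are merged when within one window step
(`concordance_bp`); concordance merging (rather than inspecting the three
tracks by eye) is this package's decision. Because windows overlap, a
changepoint between window
indices is reported at the midpoint between the two window centers.

A segment is called SLR when it contains at least one Bonferroni-significant
SNP *and* its mean F~ST~ and male-het density both exceed the genome-wide
90th percentile of the corresponding window track. That quantile rule is the
package's operationalization of "higher differentiation than the rest of the
chromosome", and it presupposes a genome-like background: if the tracks you
pass cover only the sex chromosome, most windows are themselves sex-linked
and the quantile saturates. Supply all chromosomes (the simulator makes
autosomal background cheap). Segments abutting an SLR that fail the criteria
are PARs; everything else is undetermined, and a scan with no significant
SNP anywhere returns all-undetermined rather than an error.

The window het-class fraction deserves a note: the stand-alone
`sex_het_site_classes()` defaults to `frac = 0.9` (a site must be het in
≥ 90% of males), while the pipeline uses 0.5. With occasional X-Y exchange,
two or three exchanged males that survive the exclusion pass push the
observed male-het fraction at terminal SLR sites below 0.9 and the strict
track collapses over genuinely sex-linked sequence; counting
majority-pattern sites is robust to this and matches the "most males"
phrasing. `frac = 1` remains the criterion for selecting genes for X-Y
divergence.

### X-Y divergence

Genes wholly inside SLR segments in which *every* variable CDS site is
heterozygous in all included males and homozygous in all included females
are accepted; the female-homozygous allele defines X and the alternate
allele defines Y (strand-aware, per-gene concatenated CDS — per-gene rather
than per-exon or pooled across genes, matching gene-level Ks reporting; the
summary is the unweighted mean of per-gene values). NG86 counts
potential sites by per-position synonymous fractions (each position
contributes exactly one site; changes to stop codons are excluded from the
fractions), averages observed differences in multi-hit codons over
mutational pathways excluding those through stop codons (the common
implementation convention; `count_stop_paths = TRUE` switches to counting
them as nonsynonymous), drops codons containing ambiguous bases, and applies
the Jukes-Cantor correction $-\tfrac34\log(1-\tfrac43 p)$, returning NA
beyond its domain.

### Expression side

TPM, limma quantile normalization (ties averaged), and
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$ on per-tissue means, with genes below
TPM 1 in every tissue pre-filtered. A gene is tissue-specific when
$\tau \ge 0.8$ and the tissue is among its top three by normalized
expression; ties at rank three are all included (the top-three rule is
ambiguous under ties; inclusion is this package's documented choice).
Tissue bias uses an inclusive 2-fold threshold against the mean of the other
tissues at the same stage. Chromosomal enrichment is a one-sided (greater)
Fisher test per chromosome with raw-P marks at 0.05/0.01 — enrichment only,
no multiple-testing correction on the marks, matching the convention of
reporting raw asterisks; a BH column is provided for sensitivity.

### Inversion genotyping

Only the evidence-fraction classifier is in scope (read-pair extraction from
BAM belongs to upstream SV tools). The rule defines f < 0.25 as
reference-homozygous and 0.25 < f < 1 as heterozygous; the boundary
conventions f = 0.25 → homRef and f = 1 → homInv are package choices, chosen
to keep the classification total and monotone in f.

## The simulator: what it emulates, and what it does not

`simulate_sexchrom_population()` draws background SNPs as a Poisson process
and genotypes them in Hardy-Weinberg proportions at allele frequencies
uniform on [0.05, 0.95] — uniform so the MAF > 0.05 filter is exercised
non-trivially. Fixed X/Y differences inside the SLR are a second Poisson
process at rate `xy_divergence` per bp. Sex reversal flips an individual's
genotypic sex wholesale with probability `reversal_rate`; X-Y exchange
("leak") reverts a contiguous *terminal* SLR block of a genotypic male to
X/X, one crossover with a uniform breakpoint. Depth is Poisson per
individual per 50 kb window, halved for genotypic males across an optional
degenerate-Y interval (the coverage-ratio expectation of 0.5 for a fully
degenerate Y).

Defaults describe the cohort design this scan targets: 30 males and 29
females at mean depth 15; a 26.1 Mb chromosome whose first 1.28 Mb are
pseudoautosomal; reversal rate 0.15 and X-Y divergence 0.002 per bp, the
scales reported for recently evolved teleost sex chromosomes of exactly
this kind. Two values have no reported counterpart and are fixed here once:
`theta = 3.65e-4` per-bp background
heterozygosity, chosen because with the uniform frequency model (mean
per-SNP heterozygosity 0.365) it places background SNPs at 1/kb, keeping
50 kb windows populated (~50 SNPs each); and `leak_rate = 0.05`, a small
per-male exchange probability consistent with incomplete sex-linkage being
visible but rare. These were not revisited after testing.

What the simulator does **not** emulate: genealogy (no coalescent — allele
frequencies are drawn i.i.d., so there is no linkage disequilibrium between
background sites and no relatedness structure; real captive cohorts are
families, which is what mixed-model scans correct for);
linked selection; indels and multiallelic sites; genotyping error. A green
recovery test therefore establishes that the statistics and the segmentation
logic do what they claim on data with the assumed structure — it does not
establish robustness to kinship confounding, imputation artifacts, or
reference bias.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; VCF and GFF3 coordinates are
  converted at the I/O boundary. A site at 1-based position p is in window
  [start, end) iff start < p ≤ end.
* Missing genotypes are excluded site-wise from every statistic, never
  imputed (imputation is out of scope); all-missing sites give NA.
* Fisher P-values are memoized over unique tables: with no missing data at
  fixed cohort size there are only a few thousand distinct allele tables
  genome-wide, which is what makes the exact scan fast.
* Top-k site selection sorts by (P, chrom, position) so results are
  deterministic under ties.
* `region_fractions()` is plain length arithmetic; segments always tile
  [0, chrom_length) by construction of the boundary set.
* The scan contains no randomness: identical inputs give identical results;
  the simulator is byte-reproducible given `seed`.

## The pipeline as the interface

The orchestration (`stats → assoc → heterogamety → reversals →
exclusion → recompute → segment → fractions → Ks`) is exposed as the single
function `run_full_scan(pipeline_config(...))`, which also writes tracks,
region BED, reports and a JSON manifest when `out_dir` is set;
`scripts/acceptance.R` is the runnable entry point. A shell-level
multi-command CLI was considered and rejected: the package's users work in
R, every stage is an exported function, and the orchestrator plus the
script cover the non-interactive path.

## Known limitations

* Power at small cohort sizes: with 10 males and 10 females the best
  attainable exact-test P is ~4e-4, so no single site can clear a
  genome-wide Bonferroni threshold; detection at that scale rests on the
  rank-based heterogamety call and the windowed tracks.
* The 90th-percentile SLR rule needs genome-scale background (see above).
* Boundary precision is limited to about one window step by construction;
  the reported boundary is a midpoint convention, not a base-pair estimate.
* NG86 is the appropriate estimator at the divergences involved (Ks ≲ 0.01)
  but saturates early; no ML (GY94-style) estimator is provided.
* The RAD mode tests presence/absence only; it does not model allelic
  dropout or depth-dependent presence probabilities beyond the threshold.
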