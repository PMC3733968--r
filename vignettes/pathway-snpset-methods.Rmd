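---
title: "Methods: pathway SNP-set association with a pedigree mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway SNP-set association with a pedigree mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsnpset)
```

# The model and its assumptions

`pathsnpset` tests whether the SNPs surrounding the genes of a candidate
pathway are collectively associated with a quantitative trait, in a
population with strong family structure (the motivating setting is a
dairy-bull reference population where each bull's phenotype is a daughter
trait deviation, DTD — the mean of his daughters' records pre-corrected
for herd, year and season).

## Per-SNP mixed model

For one trait and each SNP in turn,

$$y = 1_n\mu + x\beta + u + e, \qquad u \sim N(0, A\sigma^2_a), \qquad
  e \sim N(0, I\sigma^2_e),$$

with $x$ the 0/1/2 allele counts and $A$ the numerator relationship
matrix from the pedigree. Fitting the polygenic term against $A$ is what
keeps the per-SNP test honest under population structure: relatives share
both alleles and phenotypes, and without $u$ the null p-values would be
badly anti-conservative. Assumptions worth keeping in mind:

* one record per animal, so the incidence matrix for $u$ is the identity
  (repeated records are out of scope);
* additive allele dosage (no dominance term);
* a single homogeneous residual variance — reasonable for DTDs that are
  already averaged over similar daughter-group sizes, less so for raw
  records.

Writing $\delta = \sigma^2_e/\sigma^2_a$, $V \propto A + \delta I$, so
one spectral decomposition $A = UDU^\top$ per trait turns every REML
evaluation and every SNP test into $O(n)$ weighted operations with
weights $1/(d_i+\delta)$. The restricted likelihood is maximised over
$\log\delta \in [\log 10^{-6}, \log 10^{6}]$ by Brent search (tolerance
$10^{-8}$ in $\log\delta$) with explicit boundary checks; the two ends of
that interval are, for practical purposes, the $\sigma^2_a = 0$ (pure
OLS) and $\sigma^2_e = 0$ limits. The reported `loglik_reml` includes all
constants, so it is directly comparable to a textbook dense-matrix
evaluation — the test suite exploits that by checking the optimum against
a 40-point dense grid.

Two scan modes are provided. `"exact"` re-estimates $\delta$ with the SNP
in the fixed design (per-SNP REML, the default, matching how such scans
are run in dedicated mixed-model software); `"null-reuse"` estimates
$\delta$ once without any SNP and reuses it (the EMMAX approximation),
which makes the genome scan a fully vectorised weighted 2×2 GLS and is
the right choice when the scan feeds a 10,000-replicate permutation test.
On null simulations at 300 animals the two modes agree closely — the
suite checks that both the mean and the median absolute p-value
difference stay below 0.01 — though individual SNPs that tag a
disproportionate share of the polygenic background can shift $\delta$
and differ by a few hundredths, a real property of per-SNP REML rather
than a numerical artefact.

The test statistic is the 1-df Wald $F = (\hat\beta/\mathrm{se})^2$
against an $F(1, n-p)$ reference with $p$ the number of fixed effects
(2: intercept and SNP). Monomorphic SNPs are flagged and excluded from
all counts; missing genotypes trigger per-SNP complete-case analysis with
`n_used` recording the drop.

## Known-QTL phenotype correction

A pathway window can swallow a neighbouring major gene (the classic case:
a large-effect milk-fat QTL such as DGAT1 sitting inside the window of a
pathway gene). `correct_phenotype_for_qtl()` subtracts the estimated
per-allele effect times the allele count from each phenotype,
$y_i' = y_i - g_i\hat\beta$, after which the scan can be re-run to check
whether the set-level signal survives. The correction uses the
*estimated* effect, so re-testing the corrected QTL SNP gives
$|\hat\beta'| \approx 0$ by construction — the tests verify exactly that.

## Set-level inference

The set statistic is deliberately simple: the proportion of set SNPs with
$p \le \alpha$ ($\alpha = 0.05$, threshold inclusive). Its null
distribution cannot be treated as binomial — window SNPs are in LD — so
significance comes from a design-matched permutation: draw the same
number of genes uniformly without replacement from a gene universe, build
the same ±500 kb windows, deduplicate SNPs shared by overlapping windows,
and recount. Sampling *genes* rather than SNPs keeps the null sets
gene-anchored (controlling for genic vs intergenic SNP behaviour) and
with a realistic LD block structure. The experiment-wise P is the
fraction of replicates meeting or exceeding the observed proportion; ties
count as exceeding, the conservative reading (a strict `>` option
exists because "exceeded" can be read either way). Replicates whose
windows happen to contain no SNPs are redrawn and counted; the redraw
count is logged because a high rate signals a mismatched universe or map.

Because a SNP's p-value does not depend on which set it is assigned to,
genome-wide p-values are computed once per trait and reused across
replicates — numerically identical to re-fitting per set, just not
wasteful. Per-gene SNP lists are likewise prebuilt once, so 10,000
replicates cost seconds.

The FDR uses the m·P/S form: expected false positives $m\alpha$ over the
observed significant count $S$, as a percent. Table-style reporting
truncates toward zero — the only convention consistent with the published
tables this statistic is reported in ($211 \times 0.05 / 57 = 18.5\% \to
18$) — and the raw percent is returned alongside. With $S = 0$ the rate
is undefined and reported `NA`.

## Pleiotropy

The extent to which the same variants move several traits is proxied by
the Pearson correlation of per-SNP $\hat\beta$ between trait pairs, for
the pathway SNP set and for the whole genome, compared by a paired t-test
over the unique trait pairs (15 pairs for six traits). The default
selection rule uses *all* SNPs of the set: published N values for both
set sizes equal the full set sizes, implying no significance filter was
applied even where the surrounding text says "significant SNP";
`"significant-any"` and `"significant-both"` implement the literal
readings. No Fisher z transform is applied before the paired t by
default (an option exists): the compared quantities are the correlations
themselves.

# The synthetic-data generator

The generator emulates the statistical structure of a national
dairy-bull reference population; its defaults mirror that setting
(~2,154 genotyped bulls, ~43k SNPs on 29 autosomes, six correlated
traits). Every stage draws from a named substream of one root seed, so
outputs are bit-reproducible and enlarging one stage never perturbs
another.

* **Pedigree** — founders plus a fixed number of later generations;
  sires and dams are drawn from all earlier generations (no selfing),
  with a configurable unknown-parent probability (default 0; real
  completeness is rarely published). Random parent reuse yields
  half/full-sib families and a slowly rising mean inbreeding, verified
  against gene-dropping Monte Carlo.
* **Genotypes** — founder haplotypes come from a first-order "copying"
  chain: each SNP's latent uniform is copied from its neighbour with
  probability `ld_decay_rho` (default 0.9) or drawn fresh, giving
  adjacent-SNP correlation `ld_decay_rho` while preserving each SNP's
  own frequency (drawn from `maf_range`). Gametes recombine with a
  single uniformly placed crossover per chromosome per meiosis — enough
  for LD to decay with distance, with no pretence of a calibrated
  genetic map. Unknown-parent gametes are fresh base-population
  haplotypes.
* **Traits** — $y_t = \mu_t + \sum_j x_j\beta_{jt} + u_t + e_t$ run
  generatively, with the polygenic vectors drawn from the Kronecker
  covariance (genetic correlation matrix scaled by per-trait
  $\sigma_a$) ⊗ $A$. A singular genetic correlation (e.g. two traits
  correlated 1) falls back to an eigenvalue-clipped factor with a
  warning rather than failing.
* **Pathway effects** — `embed_pathway_effects()` puts one causal SNP
  per pathway gene (the window SNP nearest the gene midpoint) and sizes
  equal per-SNP variance contributions $2p(1-p)\beta^2$ so the set
  jointly explains a requested fraction of trait variance.

What the generator does *not* emulate: realistic site-frequency spectra
or demographic history (no coalescent), genotyping error or missingness
patterns, sex chromosomes, selection, or heterogeneous daughter-group
sizes behind the DTDs. Passing tests therefore demonstrate the
*statistical machinery* — calibration, power, reproducibility — not that
any particular real pathway would reach significance.

# Numerical choices and degenerate inputs

* Eigenvalues of $A$ are clipped at zero (they can dip to $-10^{-14}$ in
  floating point); $\delta \ge 10^{-6}$ keeps weights finite even for a
  singular $A$.
* The tabular A-matrix build is $O(n^2)$ per animal with vectorised
  rows; ~2k-animal pedigrees take well under a second, so no sparse
  machinery is used (and the inverse of $A$ is never needed).
* Pedigrees are topologically sorted on load (Kahn's algorithm); cycles
  are reported with the offending animal ids, duplicate ids rejected,
  and `0`/empty/`NA` all accepted as unknown-parent codes.
* Windows clamp at position 1 but not at the chromosome end (lengths are
  often unknown for real assemblies); coordinates are 1-based inclusive
  throughout, with BED converted on read.
* A constant genotype vector is a "monomorphic" result, never an error;
  an empty p-value vector *is* an error (the proportion is undefined).
* The paired t degenerates gracefully: identical matrices give
  $t = 0, p = 1$; zero-variance nonzero differences give $p = 0$ with an
  infinite $t$ rather than NaN.

# Validation design and problem sizes

The suite validates every layer against an independent oracle computed at
test time: Wright's recursive coancestry and gene-dropping (100,000
drops) for $A$; a dense-matrix GLS and a 40-point dense REML grid for the
mixed model; brute-force interval intersection and exhaustive
$\binom{5}{2}$ subset enumeration for windows and the permutation null;
and textbook formulas for the Pearson and paired-t statistics.

Calibration and power are checked at sizes chosen to make the checks
sharp yet quick, stated here as the package's own design:

* **Null calibration**: 300 animals ($h^2 = 0.3$), 1,000 SNPs per seed,
  three seeds, per-SNP REML. For this check LD is switched off
  (`ld_decay_rho = 0`) because the 99% binomial band around $\alpha$
  presumes independent tests; with LD the proportion has super-binomial
  variance and the band would test the LD model, not the mixed model.
  Pooled p-values must also pass Kolmogorov–Smirnov uniformity at 1%.
* **Permutation-test calibration**: one null dataset (300 animals, 2,000
  SNPs, 60 genes), 200 pathway draws of 11 genes each tested against 500
  replicates; the resulting experiment-wise P values must be uniform
  (KS at 1%).
* **Power**: 11-gene pathways jointly explaining 5% of trait variance in
  cohorts of 1,500 animals with ~11 SNPs per window (2,000 SNPs over
  3×60 Mb); at 500 replicates the pathway must reach experiment-wise
  $P \le 0.05$ in at least 7 of 10 seeds. The cohort and map density are
  the free parameters here; they were fixed, once, at values where the
  per-SNP noncentrality ($\approx n \cdot 0.05/11$) gives solid
  single-SNP power and the 11 causal SNPs are not drowned among dozens
  of null window SNPs.
* **Parameter recovery**: $h^2 = 0.3$ recovered within ±0.1 on average
  over 20 seeds at 500 animals.

# Known limitations

* Single-trait model only; pleiotropy is summarised from per-trait scans
  rather than a multivariate REML.
* The F-reference uses $n - p$ denominator degrees of freedom; with
  REML-estimated components this is an approximation (no Kenward–Roger
  style correction), adequate at the hundreds-of-animals scale used
  here.
* The permutation universe is sampled uniformly over genes; no matching
  on gene length or SNP density beyond the shared window construction.
* The m·P/S FDR is the historical form used with this test, not a
  Benjamini–Hochberg procedure, and can exceed 100% by construction when
  $S < m\alpha$.
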