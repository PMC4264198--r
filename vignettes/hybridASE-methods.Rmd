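---
title: "hybridASE: methods, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hybridASE: methods, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridASE)
```

## The reciprocal-cross model

Two inbred parents differ at a set of fixed, biallelic SNPs; at each SNP
the reference carries the parent-1 allele.  In an F1 hybrid, each gene is
heterozygous, and reads overlapping a SNP can be assigned to the allele
they carry.  Writing $f$ for the parent-1 allele fraction among allelic
reads:

* a **biallelic** gene has $f \approx 1/2$ in both hybrids,
* an **ASE** gene has $f$ pushed toward the same side in both hybrids,
* an **imprinted** gene has $f$ pushed toward the *mother's* allele (or
  the father's), which is parent 1 in one cross and parent 2 in the
  reciprocal, so $f$ flips between hybrids.

The SNP classifier applies two joint rules across both hybrids of the
reciprocal pair: an exact two-sided binomial test of $n_1$ against
$p = 1/2$ must give $p < \alpha$ in both, and the favoured-axis fraction
must exceed the threshold in both.  For the ASE axis that fraction is $f$
(or $1-f$); for the imprinting axis it is the maternal fraction, which is
$f$ in the hybrid whose mother carries allele 1 and $1-f$ in the
reciprocal.  With a threshold above $1/2$ the two axes cannot both
succeed — they demand opposite values of $f$ in the reciprocal hybrid —
which is asserted as a property test over simulated SNPs.  A gene is
called ASE (imprinted) if at least one of its SNPs has the pattern;
genes whose SNPs disagree on direction stay called but are flagged
`conflicting`.

Assumptions worth keeping in mind: parents are fully inbred (no residual
heterozygosity), SNP genotypes are correct, and mapping treats the two
alleles symmetrically.  The last one fails in practice (reference bias),
which is why the informative-SNP filter demands near-perfect allelic
concordance in the parental samples, and why a pseudo-genome — the
reference with the alternate allele substituted at every SNP — is built
for alignment workflows.

### Tunable parameters

| parameter | default | unit / meaning |
|---|---|---|
| `alpha` | 0.05 | per-SNP binomial test level, uncorrected |
| `ase_threshold` | 0.8 | favoured-allele fraction rule ("more than 80 %") |
| `min_parent_depth` | 10 | reads per parental sample at a SNP |
| `min_parent_concordance` | 0.9 | own-allele fraction in each parent |
| `min_hybrid_depth` | 10 | allelic reads per hybrid at a SNP |
| `require_exonic` | TRUE | restrict to exonic SNPs |
| `min_fold` | 2 | DE fold-change rule |
| `entropy_min_fpkm` | 1 | FPKM floor for breadth analyses |
| `min_reads` | 1 | detection threshold for detected-gene sets |

Comparisons are strict (`> 0.8`, `< 0.05`), matching the usual "more
than 80 %" phrasing.  No multiple-testing correction is applied at the
SNP level by default (the gene-level consequence is mitigated by the
joint two-hybrid rule, which is far stricter than a single test);
BH-adjusted p-values can be fed to the classifier instead.

## Differential expression without replicates

Counts are normalised by median-of-ratios size factors: for each gene
with a positive geometric mean across libraries, the ratio of a
library's count to that geometric mean; the library's factor is the
median ratio.  The DE test is the conditioned negative-binomial exact
test: under a common expression level $q_0 = k_S/(s_A+s_B)$, condition
totals are NB with mean $s_c q_0$ and variance $s_c q_0 + s_c^2 v(q_0)$,
and the p-value is the total probability of all splits $(a, k_S-a)$ of
the observed sum whose joint probability does not exceed the observed
one.  Accumulation is in log space (log-sum-exp); a variance at or below
the mean degrades gracefully to Poisson.

The raw variance function $v(q)$ must be estimated *blind* — one library
per genotype leaves no replicates — by pooling all libraries as
pseudo-replicates.  Three numerical choices here came out of calibration
failures and deserve a record:

1. **Median, not mean, of per-gene variances.**  With $m$ pooled
   libraries each gene's variance estimate has only $m-1$ df, so $\log w$
   has enormous noise (sd $\approx 2.2$ at 1 df) and a heavy left tail; a
   local least-squares fit of $\log w$ is biased and is dragged around by
   the minority of genuinely changed genes.  The fit therefore smooths a
   narrow running median of $\log w$ along $\log q$ (lowess, span 0.3)
   and corrects it by the exact chi-square median factor
   $\log(\chi^2_{m-1,0.5}/(m-1))$, which makes it median-unbiased for
   $\log \mathrm{Var}$ at every $q$ and insensitive to a modest fraction
   of DE genes.
2. **Pool all libraries, not just the two compared.**  The classic blind
   fallback fits on the whole data set; with four genotypes this triples
   the df of each per-gene variance and halves the noise of the fit.
3. **Trim and extrapolate at constant dispersion.**  Genes with real
   fold changes migrate to the extremes of the pooled-mean range, where
   the shrinking median windows can no longer out-vote them; the fitted
   curve is therefore used only over the central 90 % of the rank range
   and extended beyond it at constant dispersion ($v \propto q^2$), the
   standard NB assumption.  Extending at constant *variance* instead
   starves high-expression genes and inflates their false positives.

With these choices, on simulated data with known dispersion 0.05 the
fitted dispersion is 0.046–0.051 across the expression range, the null
$p<0.05$ rate is about 0.056, and power for 4-fold effects at depth 500
is 0.80–0.85 (all recomputed by the test suite).  The approach remains
conservative by construction: true differences still inflate the fit,
so power numbers are lower bounds relative to a replicated design.

A gene is DE when the BH-adjusted p-value is below `alpha` *and* the
normalised-mean fold change (with a pseudo-count of 1 against zeros) is
at least `min_fold`.  All six pairwise comparisons among the four
genotypes are run from one matrix with shared size factors and one
shared blind fit.

## Expression breadth

FPKM uses the closed formula $10^9 k/(L N)$ on union-exon lengths —
isoform deconvolution is deliberately out of scope since gene-level
FPKM only feeds the entropy.  Breadth is Shannon entropy of the
normalised tissue profile in bits, from 0 (single tissue) to $\log_2 T$
($\approx 3.46$ for 11 tissues); genes whose FPKM never exceeds 1 in any
tissue are excluded as unquantifiable.

## Enrichment

Over/under-representation uses the exact hypergeometric tails (both
sides; the reported direction is the smaller tail) against the all-genes
background, BH-corrected across terms by default with a raw mode
available.  A chi-square approximation was rejected because study sets
here are routinely small.  GO-graph propagation is out of scope: terms
are taken as given by the annotation table (GO-slim style).
Transcription-factor identification is likewise an input (gene → family
table), not an HMM scan.

## What the simulator states — and what a green test means

The generator emulates the statistical structure the inference consumes,
at these stated conditions:

* gene classes drawn independently with configured proportions; biased
  classes use one global `bias_level` (default 0.9 — strong enough to be
  unambiguous at depth 100–200, comfortably past the 0.8 rule);
* per-SNP, per-sample depth is negative binomial with mean
  `mean_snp_depth` (default 100) and dispersion 0.1 (the depth model is
  a package choice; nothing in the study design fixes one);
* hybrid allele-1 counts are Binomial(depth, f) with f from the truth
  table; parental samples carry their own allele apart from a flat 0.5 %
  error, which is what gives the concordance filter non-trivial work;
* expression matrices are NB around log-normal gene means (sdlog 1, a
  realistic dynamic range; `expr_meanlog_sd = 0` collapses it), DE genes
  shifted by `de_log2fc` in parent 2 with hybrids at the additive
  mid-parent, tissue-specific genes concentrating 95 % of their mean in
  one tissue;
* one RNG stream per stage, derived from the config seed by fixed
  offsets, so each stage and the full fixture bundle are byte-identical
  across reruns.

Real data differ in ways the generator does not model: reference/mapping
bias correlated across SNPs, positionally clustered SNP ascertainment,
overdispersion of allelic fractions beyond binomial (e.g. from
extra-Poisson technical noise), isoform structure, and library-prep
artefacts.  A green parameter-recovery test therefore establishes that
the *inference logic* is correct under its own model, not that the
thresholds are optimal for any particular real data set.

One boundary is worth stating explicitly: if every gene sits at exactly
the same depth, the genes at a shifted pooled mean are precisely the DE
genes, and no blind variance estimator that sees only that matrix can
avoid absorbing them — power collapses regardless of implementation.
Blind estimation relies on nulls and non-nulls sharing each expression
stratum, which the default log-normal spread provides.

## Numerical and degenerate-input choices

* Binomial two-sided p-values use the mirrored-tail identity (exact under
  the symmetric null), vectorised; zero-depth SNPs are untestable and
  classified biallelic with a flag.
* The exact-test split enumeration is linear in $k_S$ and accumulated in
  log space; ties on the probability boundary are included (`<=`).
* BH adjustment enforces monotonicity from the largest p down and caps
  at 1; NAs propagate.
* `size_factors` errors when no gene is expressed in all libraries;
  all-zero genes are excluded from the variance fit and receive the
  fitted value at their mean.
* SNPs assigned to several overlapping genes count for each gene
  (documented double-counting; the primary inference is per-SNP).
* Uniquely-mapped reads: either mapping quality ≥ 20 (default) or an
  NH tag equal to 1 — two explicit modes, because a pileup pass cannot
  express "NH when present, else MAPQ" as a single filter.
* Coordinates are 1-based inclusive internally (VCF convention); BED is
  converted on load.

## Known limitations

* No allelic mapping-bias correction beyond the parental concordance
  filter (no WASP-style remapping); no dual-reference count
  reconciliation — counting is against parent-1 coordinates with known
  alleles.
* No phasing, no cis/trans decomposition, no outbred designs.
* The imprinting caller is validated on simulations; in vegetative
  tissue an empty result is the expected biological outcome, and the
  package reproduces that on ASE-only simulations.
* Weighted co-expression networks and pathway-bin enrichment are out of
  scope; module-membership enrichment can be run through the generic
  hypergeometric interface given an external module assignment.
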