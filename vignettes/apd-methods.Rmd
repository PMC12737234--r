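---
title: "Average pairwise dissimilarity: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average pairwise dissimilarity: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apdtools)
```

## The statistic

For a panel of $N$ samples genotyped at $L$ biallelic loci (ALT-dosage
coding $g \in \{0,1,2\}$, `NA` for missing calls), the average pairwise
dissimilarity of sample $i$ is

$$\mathrm{APD}_i = \frac{1}{N-1}\sum_{j \ne i} d_{ij},$$

the mean of its dissimilarities against every other assayed sample,
reported together with the standard deviation of the $N-1$ pair values.
APD is a *relative* quantity: it measures how much of sample $i$'s genome
is not mirrored elsewhere in this particular panel, which is exactly the
question a genebank curator asks when choosing distinct accessions or
flagging redundant ones. It is not an individual-diversity measure like
heterozygosity — a completely inbred line can have a high APD if its
(homozygous) genotype is unlike everyone else's.

### The dissimilarity metric

Two per-pair metrics are provided, both computed over the loci where **both**
samples have calls (pairwise-complete deletion):

- `"smc"` (default): one minus the simple matching coefficient — the
  fraction of compared loci at which the two genotype *calls* differ.
- `"ibs"`: the identity-by-state distance — the mean of $|g_i - g_j|/2$,
  one minus the proportion of shared alleles.

They agree exactly wherever no heterozygote is involved, so on a fully
homozygous panel they are identical, and on highly selfing crop panels they
nearly coincide. They differ in how a heterozygous call is scored against a
homozygous one: a full mismatch under `smc`, half a mismatch under `ibs`.

This difference is not cosmetic. Consider an unstructured panel where
individuals vary in inbreeding $f$ and a locus has ALT frequency $p$,
$q = 1-p$. Differentiating the expected pair dissimilarity with respect to
the focal individual's $f$ gives

$$\frac{\partial\, E[d^{\mathrm{ibs}}]}{\partial f_i} = 2p^2q^2(1-\bar f) \;\ge\; 0,
\qquad
\frac{\partial\, E[d^{\mathrm{smc}}]}{\partial f_i} = \frac{pq}{2}\bigl(6pq(1-\bar f) - 1\bigr),$$

where $\bar f$ is the inbreeding of the partner. Under the allele-sharing
metric, more inbreeding can only *raise* an individual's expected distance
(homozygous extremes are further from everything than heterozygotes), so
APD and the inbreeding coefficient correlate non-negatively. Under simple
matching the derivative is negative whenever $pq(1-\bar f) < 1/6$ — i.e. in
any panel that is predominantly inbred or rare-allele-rich — and there APD
falls with inbreeding, the behaviour expected of a variability measure and
observed in real selfing-crop panels. For this reason `smc` (which is also
the classical definition of the coefficient) is the package default;
`ibs` is retained for sensitivity analyses and for comparability with
allele-sharing-based software.

### Missing data and edge conventions

- Pairs are compared over their commonly observed loci. A pair with *no*
  commonly observed locus is undefined; it is excluded from both samples'
  averages with a warning, and a sample with no defined pair gets `NA` APD.
- The per-sample SD is the sample standard deviation of the $N-1$ pair
  values (denominator $N-2$). With $N = 2$ there is a single pair and the
  SD is reported as 0 rather than undefined.
- The implementation accumulates the pair matrix through genotype-indicator
  cross-products, so results are independent of any internal blocking and
  reproduce a literal double loop to $10^{-12}$ (this is asserted in the
  tests against a brute-force oracle).

## Variant filtering

`filter_spec()` keeps a variant iff

- missing-call rate $\le$ `miss_max` (default 0.05; presence/absence SV
  panels are conventionally allowed up to 0.2),
- minor allele frequency $\ge$ `maf_min` (default 0.01, removing singletons
  and other extreme rarities whose pair contributions are pure noise), and
- it is polymorphic (when `drop_monomorphic`, the default).

Both boundaries are **inclusive keeps** (a variant exactly at MAF 0.01 or
missingness 0.05 survives), and MAF is computed from non-missing calls only
— the standard conventions where published pipelines are ambiguous. Variants
with zero non-missing calls are removed and counted separately. Filtering
is idempotent and never alters surviving dosage values. Multi-allelic VCF
records are skipped (with a count) rather than decomposed: every analysis
here is defined for biallelic dosages.

## Ranking and overlap tables

Top-percentage set sizes use **round-half-up** of $N \cdot pct / 100$ with
a floor of one — the only rounding consistent with the published set sizes
for panels of 1789 and 854 samples (e.g. $854 \times 25\% = 213.5 \to 214$,
$1789 \times 5\% = 89.45 \to 89$); half-even rounding fails these. Ties at
the APD cutoff are broken by ascending sample ID so rankings are
deterministic. Overlap tables report $100\,|A \cap B|/|A|$ rounded half-up
to one decimal.

## Genotype PCA and hull-area percentages

PCA uses the population-genetics normalisation: each variant centred by
$2\hat p$ and scaled by $\sqrt{\hat p(1-\hat p)}$ ($\hat p$ from non-missing
calls; missing cells contribute zero after centring; zero-variance variants
dropped with a warning). Scores are the left singular vectors scaled by the
singular values, and each axis's sign is fixed by making its
largest-magnitude variant loading positive, so coordinates are reproducible
across runs and platforms. An unscaled (centred-only) option is available
for sensitivity checks.

The hull-area percentage (HAP) of a sample subset is
$100 \times \text{area(hull of subset)} / \text{area(hull of all samples)}$
in the PC1–PC2 plane, hull vertices from `chull()` and area by the shoelace
formula; collinear sets have area zero, and a degenerate full hull is a
domain error. HAP is invariant to rotation, translation and uniform scaling
of the PC plane, and monotone under subset nesting — both properties are
tested. Hulls are deliberately 2-D: that is the plane in which such panels
are inspected, and higher-dimensional hull volumes are far less robust at
germplasm-panel sample sizes.

One behaviour of HAP worth knowing: the hull area is driven entirely by a
handful of extreme points, so a top-APD subset whose members are
*centrally* placed in PC space can have a very small HAP even when it is
large. On synthetic panels whose PC1 is dominated by the inbreeding
gradient this is the typical outcome; on real structured panels the most
distinct samples tend to sit at the margins of the PC cloud and HAPs are
large. HAP should therefore be read as a descriptive coverage figure, not a
quality score.

## Individual inbreeding coefficients

`individual_inbreeding()` implements the method-of-moments
(excess-homozygosity) estimator: with dosage $g_{il}$ and ALT frequency
$p_l$ estimated from all non-missing calls,

$$\hat F_i = \frac{1}{L_i} \sum_{l}
\frac{g_{il}^2 - (1+2p_l)\,g_{il} + 2p_l^2}{2 p_l (1-p_l)},$$

summing over the $L_i$ loci non-missing for $i$ with $0 < p_l < 1$. A fully
homozygous sample at $p = 0.5$ loci gives exactly $+1$, a fully
heterozygous one exactly $-1$. Estimates are **not clamped** to $[-1, 1]$:
the moment estimator legitimately exceeds those bounds on finite data, and
clamping would bias panel means. Under $s$ generations of selfing the
expectation is $1 - (1/2)^s$; on synthetic panels of 200 samples and 5000
variants the panel mean recovers this within $\pm 0.05$ for
$s \in \{0,1,2,4\}$ (tested over three seeds each). The maximum-likelihood
variant of the estimator is intentionally out of scope.

A caution for small variant counts: $\hat F_i$ and $\mathrm{APD}_i$ share
per-sample sampling noise (a sample that happens to carry extra rare
homozygotes scores high on both), which attenuates — and below a few
hundred loci can even flip — the observed APD–IBC correlation. This is one
more reason for the several-thousand-variant recommendation below.

## Variant-subsampling stability

How many random variants does a reliable APD estimate need?
`stability_table()` draws $m$ variants uniformly without replacement
(simple random sampling across the genome, no chromosome stratification),
recomputes APD, and correlates it with the full-data APD; this is repeated
(default 10 replicates, replicate $i$ seeded as `base_seed + i`) and
summarised by mean, SD and CV per $m$ over the default ladder
$m \in \{1000, 3000, 5000, 10000, 15000\}$. The full-data APD vector is
computed once and reused across replicates (equivalent in expectation to
redrawing it, and cheaper). The report flags the smallest $m$ whose mean
correlation reaches the reliability threshold (default 0.98). On a
200 × 50,000 synthetic panel the mean correlation increases strictly along
the ladder, the CV at $m \ge 5000$ is below 0.01, and drawing all variants
returns a correlation of exactly 1 — mirroring the published finding that
5000–10,000 genome-wide variants suffice for stable APD estimation.

## The synthetic generator

`generate_panel()` draws, in order: ancestral ALT frequencies from
`Beta(maf_shape)` (default shape 0.3/0.3, giving the L-shaped
rare-variant-dominated spectrum of resequencing panels); optional
per-subpopulation frequencies via a Balding–Nichols Beta around the
ancestral value with divergence `fst`; and per-individual genotypes from
the inbreeding mixture law
$P(2) = p^2 + fpq$, $P(1) = 2pq(1-f)$, $P(0) = q^2 + fpq$ with
$f = 1 - (1/2)^s$ for `selfing_gens` $= s$ — exact control of expected
inbreeding without pedigree simulation, which is what the recovery tests
need. Missing calls are placed uniformly (default rate 0.05, SNP-like).
The default panel spans a selfing gradient $s = 0..8$ (expected $F$ from 0
to 0.996), emulating a selfing-crop collection containing everything from
recent outcrosses to fixed lines.

`derive_sv_channel()` emulates a second, noisier variant type assayed on
the same individuals (as SV presence/absence calls are): an independent
variant set with the same per-individual inbreeding and subpopulation
labels, per-call symmetric genotyping errors (each corrupted call replaced
by one of the other two states), and heavier missingness (default 0.2).
Sharing individuals but not variants makes the two channels' APD vectors
positively but imperfectly correlated, and the correlation degrades
monotonically with the error rate — the qualitative regime of real SNP
versus SV comparisons. Two honest caveats: the generator does not target
any particular cross-channel $R^2$ (real SV data can be far less correlated
with SNP APD than this model produces, because real SVs may carry genuinely
different information, not just noise); and with a wide inbreeding gradient
the strong shared $f$-signal keeps the channels more correlated than a
narrow-gradient real panel would be.

Features of real data the generator does **not** emulate: linkage
disequilibrium and recombination maps, admixed individuals (each simulated
individual belongs to exactly one subpopulation), non-uniform missingness,
and SV length/type structure. Tests passing on these panels therefore
validate the estimators and their contracts, not the population-genetic
realism of any particular rice-panel number.

Determinism throughout: every stochastic function takes an explicit integer
seed and sets the RNG itself; identical seeds give bit-identical outputs
(asserted in the tests), and pipeline TSVs carry a config-hash + seed
provenance header.

## Problem sizes and runtime

The test suite builds all fixtures in code at sizes chosen so the whole
suite runs in well under a minute on one CPU: oracle equivalence on
matrices up to 20 × 500, estimator recovery at 200 × 5000, the
APD–inbreeding direction at 300 × 10,000, and the stability ladder at
200 × 50,000 (the one deliberately large case, a few tens of seconds). The
acceptance script reruns the same analyses from scratch in under a minute.

## Known limitations

- APD is panel-relative; values are not comparable across panels with
  different composition, variant sets or filters.
- The two metrics answer slightly different questions in heterozygous
  material; comparisons across studies should fix the metric.
- The moment IBC estimator assumes well-estimated allele frequencies; in
  very small panels its per-sample noise is large (and correlated with
  APD noise, see above).
- Hull areas use PC1–PC2 only and are sensitive to PCA normalisation
  choices in the same way the underlying PCA is.
- PLINK input is restricted to SNP-major PLINK 1 binary filesets; GDS and
  bgzip/tabix-indexed workflows are out of scope.
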