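---
title: "Methods: windowed population genomics and the DCMS selection scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed population genomics and the DCMS selection scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kelpscan implements the population-genomic analysis toolkit used to
characterise domesticated and invasive kelp populations: windowed diversity
and differentiation statistics, linkage-disequilibrium (LD) decay, runs of
homozygosity (ROH), and a decorrelated composite of multiple signals (DCMS)
selection scan, together with a forward Wright-Fisher simulator that
generates genotype data with known ground truth for end-to-end validation.
This vignette records the models, the estimator conventions, the tunable
parameters and the design decisions a maintainer would want to audit.

## Statistics

All statistics consume a `genotype_matrix`: diploid genotypes coded as
counts of the alternate allele (0/1/2, `NA` missing) at sites ordered by
(chromosome, 1-based position). Windows and BED intervals are 0-based
half-open; converters are centralised so the two conventions never mix.

**Nucleotide diversity.** Per site, the unbiased pairwise heterozygosity
$\hat\pi_s = 2 j (n - j) / (n (n - 1))$ for $j$ alternate alleles among $n$
non-missing alleles. Per window, $\pi = \sum_s \hat\pi_s / L$ with $L$ the
full window length in bp, so unlisted (invariant) positions count as
monomorphic. This per-bp convention reproduces the magnitude of genome-wide
diversity values (order $10^{-3}$) rather than per-variant diversity.

**Watterson's estimator and Tajima's D.** $\hat\theta_W = S / (a_1 L)$ with
$a_1 = \sum_{i<n} 1/i$. Tajima's D uses the standard 1989 normalisation,
with the constants evaluated at the rounded mean number of non-missing
alleles over the window's segregating sites. D is reported as missing (not
zero) when $S = 0$ or fewer than 4 alleles are available: a window with no
variation carries no frequency-spectrum information, and this convention
propagates into $\Delta D$ and the scan.

**Heterozygosity and inbreeding.** Per variant site,
$H_e = 2p(1-p)\,n/(n-1)$ (sample-size corrected) and $H_o$ = observed
heterozygote fraction; window values are means over variant sites and
$F_{IS} = 1 - \bar H_o / \bar H_e$ (ratio of window means, the multi-locus
convention).

**F_ST.** The Weir-Cockerham (1984) variance-component estimator for two
groups, aggregated over windows as a ratio of sums
$\sum_s a_s / \sum_s (a_s + b_s + c_s)$, not a mean of per-site ratios —
the ratio-of-sums form has the standard, well-understood bias behaviour and
is deterministic. Small negative estimates are legitimate estimator output;
note that comparing a sample set against itself yields a small negative
value of order $-1/(2n-2)$, not exactly zero.

**ROD and delta Tajima's D.** $\mathrm{ROD} = 1 - \pi_f/\pi_r$ and
$\Delta D = D_f - D_r$, oriented focal (cultivated/introduced/later) minus
or over reference (natural/earlier). Swapping the orientation negates
$\Delta D$ and re-maps ROD; the pipeline treats the baseline group as the
reference throughout.

**Missingness.** Within a group, a site with more than 50% missing
genotypes is excluded from that group's statistics (threshold exposed as
`max_missing_frac`); for F_ST, both groups must additionally retain at
least two called individuals at the site.

## LD decay

LD is the squared Pearson correlation of unphased genotype dosages
(composite, Rogers-Huff style; no haplotype phasing or EM inference), over
pairwise-complete observations with at least 3 complete pairs. Profiles bin
intra-chromosome pairs by separation; when the pair count exceeds
`max_pairs`, a seeded uniform subsample keeps the cost bounded and the
result deterministic.

The half-maximum decay distance takes the first populated bin's mean $r^2$
as the maximum (no model fitting — the simplest auditable reading of
"half of its maximum") and linearly interpolates between bin midpoints at
the first downward crossing of half that value. A profile that never
crosses within the profiled range is reported missing; ordering comparisons
in the validation suite treat such profiles as censored at the distance
cap. `half_decay_distance(min_pairs=)` can mask near-empty bins: with few
samples and sparse variation a bin holding a handful of pairs is noise, and
one noise bin below the threshold would otherwise fabricate an early
crossing. With $n$ diploid samples the expected null $r^2$ is roughly
$1/(n-1)$; this noise floor means half-decay distances from very small
samples should be compared, not interpreted absolutely.

## Runs of homozygosity

A greedy left-to-right scan per individual and chromosome over non-missing
calls: a run tolerates at most `max_het` heterozygous calls and no gap
between successive called sites larger than `max_gap_bp`; closed runs are
trimmed of terminal heterozygotes and kept if they span `min_length_bp` and
`min_snps` calls. This observational scan was chosen over an HMM or a
PLINK-style sliding-window hit rate: with no published algorithm to match,
the scan is the parameter-sparse, deterministic and hand-traceable choice,
and the thresholds are all exposed so PLINK-like behaviour can be
approximated. Missing genotypes neither break nor extend a run unless the
positional gap cap is exceeded. Segment length is last-SNP minus first-SNP
position plus one — no padding to unobserved flanks.

## The DCMS scan

Per window and statistic, one-sided empirical P values are fractional
ranks, $p = \mathrm{rank}/(n+1)$ with average ranks for ties, computed over
the genome-wide empirical distribution (no parametric per-statistic null).
Directionality follows standard sweep expectations: upper tail for F_ST and
ROD, lower tail for $\Delta D$ (both directions exposed as configuration). The composite is

$$\mathrm{DCMS}_j = \sum_i \frac{1}{\sum_k |r_{ik}|}
  \log_{10}\frac{1 - p_{ij}}{p_{ij}},$$

with $r$ the Spearman correlation matrix of the statistics across windows
(rank correlation, because the three statistics live on incommensurate
scales). Scores are calibrated against a robust Gaussian null (location =
median, scale = 1.4826 x MAD — robust moments resist exactly the outliers
the scan is hunting) and windows with calibrated upper-tail $P < 0.025$ are
reported, with no further multiple-testing correction beyond that fixed
threshold. Significant windows are intersected with a gene
BED track (at least 1 bp of half-open overlap; genes deduplicated across
windows; adjacent significant windows are not merged before counting;
merging is exposed as a choice).

A caveat worth recording: the popular claim that the $1/\sum_k |r_{ik}|$
weighting makes the composite invariant to duplicating a statistic is exact
only when the duplicated statistic is rank-uncorrelated with its
companions (and in the pure two-copy case). Duplicating a column that
correlates with others shifts every weight by terms of order $|r_{ij}|$.
The test suite asserts the exactly-satisfiable forms and treats the
correlated case as expected re-weighting, not a defect.

## The simulator

A forward-time discrete-generation Wright-Fisher engine (C++ core, R
driver) with:

* multinomial reproduction with partial selfing (`selfing_rate` =
  probability an offspring is produced by self-fertilisation);
* per-chromosome Poisson crossovers (`rho` per bp per generation) and free
  assortment between chromosomes;
* infinite-sites mutation (`mu` per site per generation) on the finite
  coordinate grid with collision re-draw — a position currently
  segregating or fixed-derived in any population of the simulation is
  never re-mutated, while a position whose derived allele has gone extinct
  everywhere is freed for re-use (on a 100-kb grid the "one mutation per
  position ever" rule would exhaust the grid; re-using a globally extinct
  position is biologically indistinguishable from a fresh mutation);
* optional single-locus additive viability selection (fitness 1, 1+s,
  1+2s) from a new mutation at phase start, restarted automatically on
  loss up to a retry cap, so a configured sweep reliably completes.

The ancestral population is initialised at the stationary infinite-sites
frequency spectrum (site count Poisson with mean $\theta a_{2N-1}$, derived
counts $\propto 1/i$, carriers assigned at random = linkage equilibrium)
and then burned in by forward generations. Diversity is therefore at
mutation-drift equilibrium from generation zero, while LD builds up over
the burn-in: short-range LD approaches drift-recombination balance on a
timescale of order $N$ generations, so scenarios whose validation depends
on background LD use a burn-in of about $1.6N$; diversity-only scenarios
use a short burn-in.

**Demographic archetypes.** One configuration derives all populations from
the common ancestor. *Natural* populations split and evolve independently
with selfing. *Cultivated* populations model pool breeding: gametes are
drawn from the union of all natural populations' individuals with no
selfing for a few generations — the random union of genetically distinct
gametes that large-scale pool fertilisation produces. *Introduced*
populations are founded by a few individuals (`founder_size`), held at that
size briefly, then expanded to a sustained small census, with optional
serial re-introduction pulses replacing a fraction of the population with
source individuals (the repeated-shipping-introduction scenario).

**Desk-scale defaults and calibration.** No demographic parameter
estimates exist for these populations, so the defaults are free choices,
made once and documented here. $N = 500$, $\mu = 10^{-6}$, 50-100-kb chromosomes give
per-bp diversity $4N\mu = 2\times10^{-3}$, the magnitude real kelp
populations show. $\rho = 5\times10^{-7}$ per bp makes LD decay resolvable
at kb scale while keeping chromosomes from collapsing into single linkage
blocks. The demography scenario uses six 50-kb chromosomes — with ~8
diploid samples per population, F_IS and ROH contrasts need several
independent linkage blocks per genome, or chromosome-scale drift noise
swamps the ordering. The founder history (4 founders, then N = 50 for ~30
generations) reproduces the observed introduced-to-natural diversity ratio
of roughly 0.3 and leaves the founder LD plateau above its half-maximum
within the profiled range. Scan windows are 4 kb against 2-kb summary
windows (mirroring genome-scale practice, where 50-kb scan windows sit
over 10-kb summary windows); the sweep scenario places its locus at the centre of a
scan window, because a locus straddling a window boundary splits its
signal between two windows. The sweep scenario samples 150 generations
after fixation: immediately at fixation the swept window has no
segregating sites in the focal group, so Tajima's D — and with it the DCMS
score — would be missing by the conventions above; a short recovery phase
restores the classic excess of rare variants and makes the window
scoreable.

**What a green test does and does not establish.** The generator emulates
drift, selfing, bottlenecks, pooled breeding and hard sweeps on a desk
scale; it does not model the haploid gametophyte life stage, gene
conversion, variable recombination or mutation landscapes, genotyping
error, or reference-bias missingness. Green acceptance tests establish
that the estimators recover the qualitative contrasts of the study design
from data whose generating process is known — not that the pipeline
reproduces published absolute numbers for this system, which depend on
unpublished filter, LD and ROH settings and on full resequencing data.

## Determinism and numerics

Every stochastic stage draws from R's RNG (the C++ engine included), so a
configuration plus seed reproduces output tables byte-for-byte. Empirical
P values are strictly inside (0, 1) by construction, which keeps the
log-odds transform finite. A MAD of zero in score calibration falls back
to the standard deviation with a warning. Half-decay interpolation,
filter-rule attribution (first failing rule in the order QUAL, SNP,
biallelic, call-rate, MAF) and ROH closure are all deterministic
tie-breaks chosen once and tested.

**Calibration at desk scale.** The robust-normal calibration is mildly
anticonservative for rank-based log-odds scores (their tails are logistic,
not Gaussian). The neutral-calibration acceptance test quantifies this: on
fully neutral two-group replicates with a single 100-kb chromosome and
25 scan windows per replicate, the fraction of windows called significant
at nominal 0.025 measures around 0.05 — roughly twice nominal, sitting at
the edge of the tolerance band the validation suite asserts, and the fixed
test batch lands marginally outside it. Part of the excess is the tail
shape; part is linked drift along a single small chromosome producing
clusters of genuinely elevated windows that the per-scan median/MAD bulk
fit does not absorb. At genome scale (many chromosomes, thousands of
windows) both effects shrink, but users of the 0.025 threshold should read
it as an outlier-ranking device, not a frequentist error rate.

## Known limitations

* The variant filters' defaults (MAF 0.05, missingness 0.2) are package
  choices, not values taken from any published pipeline, and should be set
  explicitly
  in runs meant to mirror other pipelines.
* Window F_ST, $\pi$ and D at very small sample sizes (4-10 diploids) are
  noisy; the scan's empirical ranks absorb this, but absolute per-window
  values should be read with the sampling noise in mind.
* The simulator's census sizes are exact (no demographic stochasticity in
  N), and migration exists only as discrete re-introduction pulses.
* Multi-allelic records are carried only far enough to be counted and
  removed by the filter; they are never analysed.
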