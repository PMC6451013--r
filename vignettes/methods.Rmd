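---
title: "Models and methods behind congenstatus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind congenstatus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

congenstatus assembles a conservation-status assessment for a rare plant
species from microsatellite genotypes and occurrence records. This
vignette explains the statistical machinery, the assumptions each stage
makes, the tunable parameters and their defaults, and the design choices
that were genuinely open — the things a maintainer would want to know
before trusting or changing the code.

## Genotype data model

A dataset is a long tibble of diploid codominant calls (individual,
population, locus, two integer allele codes). Codes are fragment sizes or
repeat counts; the stepwise-mutation-aware statistics (R~ST~, SMM/TPM
bottleneck nulls) interpret differences between codes as repeat-count
differences, so a per-locus `motif_length` converts base-pair codes where
needed (default 1: codes already in repeat units). Missingness is
genotype-level: a half-called genotype carries no usable information under
every estimator here, so half-calls are demoted to missing with a warning
rather than silently kept.

## Diversity statistics

Expected heterozygosity uses the small-sample-unbiased form
$H_E = \frac{m}{m-1}\bigl(1 - \sum_a \hat p_a^2\bigr)$ with $m$ the number
of gene copies; at the sample sizes this package targets (tens of
individuals) the unbiased and plug-in forms differ within rounding, and
the unbiased form matches the common desktop implementations. Allelic
richness is rarefied to a standard number of gene copies
$g$: $A_R = \sum_a [1 - \binom{m - m_a}{g}/\binom{m}{g}]$, with $g$
defaulting to the smallest non-missing gene-copy count over
population-by-locus cells so every cell is comparable; cells below $g$
are dropped from the average with a warning. The multilocus inbreeding
coefficient is Weir–Cockerham's $\hat f$, with the within-individual and
among-individual components summed over loci and alleles before the
ratio; it is reported as `NA` (undefined, not zero) when every locus is
monomorphic, and can be suppressed for pooled groups of isolated
individuals that are not a mating population.

The Hardy–Weinberg test randomizes allele copies among individuals within
each locus and takes the two-sided tail of $|F_{IS}|$; two-sided because a
deficit and an excess of heterozygotes are both departures of interest and
the direction is read from the sign of $\hat f$. All permutation p-values
in the package use the $(h+1)/(R+1)$ convention, so $p \ge 1/(R+1)$ and
the test is exact-valid at any replicate count.

## QC: null alleles and linkage disequilibrium

The null-allele scan compares each cell's homozygote count with a
Monte-Carlo Hardy–Weinberg null (genotypes reassembled from the cell's
allele frequencies) and flags counts above the 97.5th percentile; the
Brookfield-1 estimate $r = (H_E - H_O)/(1 + H_E)$ is reported clamped to
$[0, 1]$. Stutter and large-allele-dropout diagnostics are out of scope.
Pairwise linkage disequilibrium uses a log-likelihood-ratio G statistic on
the two-locus genotype table with p from permuting one locus's genotypes
among individuals; pairs with a monomorphic member carry no information
and are reported with $p = 1$. Sequential Bonferroni is implemented as
Holm's step-down procedure (the variant is not standardized across
packages; Holm is uniformly more powerful than the single-step correction
and never anti-conservative).

## AMOVA

Differentiation is a one-level analysis of molecular variance at the
gene-copy level: with two copies per diploid individual, 62 individuals in
4 groups give the familiar 3/120/123 degrees of freedom. Squared
inter-copy distances are 0/1 under the identity metric (yielding F~ST~)
or squared repeat-count differences (yielding Slatkin's R~ST~). Because
all four between-individual copy pairs enter the sums of squares, the
decomposition is invariant to the arbitrary phase of unphased genotypes.
Variance components come from the standard mean-square equations with the
$n_c$ coefficient for unequal sizes; negative among-population components
are reported as computed, but the percentage column clamps them to zero
(a negative share of variance is not interpretable as a percentage).
Missing data are handled pairwise: a missing call drops that locus from
that pair's distance. Significance permutes whole individuals among
populations, the natural exchangeable unit for genotypic data.

## Admixture model and K selection

The clustering stage is a Gibbs sampler for the admixture model with
independent allele frequencies per cluster: latent origins $z$ of each
allele copy given memberships $q_i$ and cluster frequencies $p_{k,l}$,
conjugate Dirichlet updates for $q_i$ (prior $\alpha$) and $p_{k,l}$
(prior $\lambda = 1$), and a Metropolis step for $\alpha$ under a
Uniform(0, 10) prior with proposal sd 0.05. The correlated-frequency
variant is deliberately not implemented; the surrounding machinery
(likelihood traces, ΔK, label alignment) is model-agnostic, and the
independent-frequency model is the cleaner null for the moderate
divergence this package targets. Desk-scale defaults are 5 000 burn-in /
20 000 sweeps; the calibration and recovery tests use shorter chains
(hundreds to ~2 000 sweeps) on small datasets, where the trace is
stationary well before the burn-in ends (checked by a Geweke-style split
comparison).

Model choice reports both the mean post-burn-in log-likelihood and
Evanno's $\Delta K$, the absolute second difference of the mean
log-likelihood normalized by its across-replicate standard deviation
(zero-sd guarded by $10^{-9}$; undefined at the grid edges). Replicate
runs are aligned by exhaustive search over cluster-label permutations
(feasible to $K = 8$), maximizing the summed row-wise inner product with
the first run. Individuals with modal membership below 0.9 are counted
"admixed"; the threshold is exposed as configuration.

## Bottleneck test

A recently crashed population loses rare alleles faster than gene
diversity, so its $H_E$ transiently exceeds the mutation-drift-equilibrium
expectation *conditional on the observed allele count k*. The null
distribution of $H_{eq}$ is simulated by neutral coalescent genealogies of
the observed gene-copy number with mutations under IAM, SMM, or a
two-phase model; the mutation parameter is calibrated by log-scale
bisection until the mean simulated allele count matches the observed $k$
within 0.05, then replicates are retained only when the realized count
equals $k$ exactly (rejection conditioning), with at least 500 retained
draws. TPM multi-steps occur with probability 0.30 and geometric step
lengths with parameter 1/6 — variance 30 repeat units, the conventional
setting; both are configuration. Per locus the standardized difference
$DH = (H_E - \bar H_{eq})/\mathrm{sd}\,H_{eq}$ feeds a one-tailed Wilcoxon
signed-rank test for excess, exact for up to 25 loci. Populations with
fewer than 4 polymorphic loci are refused (ranks are meaningless) with a
pointer to an exact sign test. The conditional-on-$k$ distribution under
the infinite-allele model is $\theta$-free (Ewens), which provides an
independent enumeration oracle used in the tests at small $n$.

## Effective population size

Contemporary $N_E$ uses group coancestry:
$\Theta = [\sum_i 0.5(1+F_i) + \sum_{i \ne j} \theta_{ij}]/n^2$ and
$N_E = 0.5/\Theta$, with pairwise kinship $\theta_{ij}$ from the Loiselle
estimator (Ritland selectable) and individual inbreeding from
self-kinship, $F_i = 2\theta_{ii} - 1$ clamped to $[-1, 1]$.

One design choice matters greatly here: the reference allele frequencies.
If the analysed sample is its own reference, the estimator's centring
makes the data-dependent parts of Eq.-style group coancestry cancel
exactly — the sum of a sample-centred kinship matrix over all ordered
pairs reduces to its bias-correction term, giving
$\Theta \equiv 1/(2n-1)$ and $N_E \equiv n - 0.5$ whatever the genotypes.
The package therefore defaults to whole-dataset ("global") reference
frequencies, the default of the standard kinship software; the collapsed
"within" behaviour remains selectable and is itself verified by a test.
Even with a global reference, the self terms scale as $0.5/n$, so
comparisons of $N_E$ across samples are only meaningful at matched sample
size; the relatedness-sensitivity test accordingly compares equal-sized
samples with and without a full-sib family. $\Theta \le 0$ (possible on
small samples with noisy estimators) yields `NA` with a warning, never a
negative size.

Historical quantities are plain conversions of user-supplied
mutation-scaled coalescent estimates: $N_E m = M\Theta/4$ and
$N_E = \Theta/(4\mu)$ with default $\mu = 4.76\times10^{-3}$ per locus per
generation, a standard microsatellite rate. Fitting the migration models
that produce $\Theta$ and $M$ is out of scope.

## Geospatial assessment

Extent of occurrence is the area of the minimum convex polygon of the
(deduplicated) records, computed by the shoelace formula in a world
cylindrical equal-area projection on the WGS84 authalic sphere
(R = 6371.0072 km) centred on the records' mean longitude — any
equal-area projection gives the same area, and the implementation is
cross-checked in the tests against an independent geodesic polygon-area
oracle to 1%. Area of occupancy snaps the projected records to a 2-km
grid (cell area 4 km², the red-list reference scale — "2-km grids" in
assessment practice means cell width) anchored at the projection origin;
because AOO depends on that arbitrary origin, an optional 3×3 sub-cell
offset scan reports the min/max over origins. Deduplication keeps the
most recent record per locality, dated beating undated and date ties
broken by smallest id — a deterministic rule, stated so results are
reproducible. Degenerate hulls (fewer than three distinct or collinear
points) get area 0 and the standard adjustment EOO := max(EOO, AOO).
Criterion-B categories follow the threshold table (EOO: CR < 100,
EN < 5 000, VU < 20 000 km²; AOO: CR < 10, EN < 500, VU < 2 000 km²);
the subconditions (severe fragmentation, continuing decline) are
user-declared flags — they come from habitat context, not from these
data — and the final B2-based call applies only when at least two are
met.

## Distribution model

Of the many presence-only algorithms in common use, the package
implements the surface range envelope: a cell is suitable iff every
environmental layer lies within the $[q, 1-q]$ empirical quantiles of the
training presences ($q = 0.025$ default; linear-interpolation quantiles,
stated because the envelope boundary depends on the convention). The
evaluation machinery is algorithm-agnostic: replicated stratified 75/25
presence/background splits (train size rounds down; background defaults
to 10× presences drawn uniformly from non-missing cells excluding
presence cells), tie-corrected rank AUC, TSS maximized over thresholds,
a TSS > 0.7 weighted consensus, and projection by substituting a future
raster stack with suitable-area change summarized in km² under the same
equal-area projection. Variable pre-selection by factor analysis is
replaced by nothing — callers choose layers; an SRE is already robust to
monotone transformations of its layers. Rasters are plain matrices with
an extent, in WGS84; no external raster stack format is required.

## The simulator and what passing tests mean

The forward-time simulator is the package's ground truth: discrete
generations, offspring drawing their parents' deme from a row-stochastic
migration matrix, selfing with probability $s$ (else random union of
gametes, self-fertilization by chance included), and per-transmission
mutation (IAM: fresh code; SMM: ±1 repeat; TPM: geometric multi-steps,
reflecting boundary at 2 repeats). Census trajectories allow
instantaneous crashes. A forward (not coalescent) simulator was chosen so
selfing, crashes and null alleles are mechanistically controllable; the
price is a burn-in, defaulting to 10× the largest census.

The default configuration emulates the sampling regime the package is
designed for — three relict populations plus a pooled group of isolated
trees (four demes of census 50/50/25/40 crashing to 20/22/14/10 five
generations before sampling), 11 loci, TPM with 30% multi-steps,
$\mu = 4.76\times10^{-3}$, selfing 0.25, migration 0.02 among the three
populations and 0.005 with the isolated group, 62 sampled individuals.
Those values were fixed once so that, across replicate simulations, mean
per-population $H_E$ falls in [0.25, 0.60] and global F~ST~ in
[0.10, 0.25] — the diversity and structure regime of a genetically
depleted, moderately differentiated tree.

The simulator emulates drift, migration, selfing, mutation-model effects
and crashes. It does not emulate: genotyping error beyond null alleles,
linked loci, overlapping generations, spatially continuous structure, or
sampling biases of real herbarium collections (the occurrence sampler is
a Thomas-style cluster process with an optional labelled synthetic
outlier, not a digitization model). Passing calibration and recovery
tests therefore shows the estimators are correct under their own
assumptions at realistic parameter values — not that real data meet those
assumptions.

Test and acceptance problem sizes were chosen to make Monte-Carlo error
small relative to the tested effect while keeping a laptop-scale run: 500
equilibrium datasets per type-I calibration (binomial 95% CI around
α = 0.05), 50 replicates for the crash-power and selfing-recovery checks
(crash scenario: census 500 → 50 five generations before sampling 40
individuals at 11 loci), 20 datasets × a K = 1–6 grid × 5 replicate
chains for ΔK recovery, and exact enumeration oracles at $m \le 10$ gene
copies or $n = 12$ copies (Ewens). Equilibrium H~eq~ distributions are
memoised per (copies, alleles, model) within a run so the conditioning
cost is paid once.

## Numerical conventions

- Permutation p-values: $(h+1)/(R+1)$, ties counted as hits
  (conservative-exact).
- Quantiles: R's default linear interpolation (type 7) everywhere.
- Holm decisions via `stats::p.adjust`; Wilcoxon via
  `stats::wilcox.test` (exact for ≤ 25 loci).
- ΔK zero-sd guard $10^{-9}$; Eq.-1 $\Theta \le 0$ → `NA`.
- Allele codes reflect at 2 repeat units in the simulators (no
  zero/negative sizes); IAM codes are drawn from a separate range so they
  never collide with founder codes.
- All stochastic functions take an explicit integer seed and restore the
  caller's RNG state; compiled code uses R's RNG stream, so results are
  platform-independent.

## Known limitations

- The admixture sampler uses independent cluster frequencies; closely
  related clusters (where the correlated-frequency model helps) will need
  more loci to separate.
- The bottleneck test's Wilcoxon stage assumes symmetric $DH$ under the
  null; the conditional $H_{eq}$ distribution is mildly skewed, which the
  calibration test bounds empirically rather than theoretically.
- Contemporary $N_E$ from group coancestry is strongly sample-size-linked
  (see above); treat it as a relative, matched-n quantity.
- AOO is grid-origin dependent by construction; use the offset scan when
  a category sits near a threshold.
- The SRE is a rectangular envelope; it cannot represent interactions
  between climate variables and will over-predict into unobserved corners
  of climate space.
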