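---
title: "Methods: community assembly, keystone screening and yield attribution in the phyllosphere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly, keystone screening and yield attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phyllokbs` implements an inference chain used to ask how a crop genotype
shapes its leaf-surface (phyllosphere) microbiome and how that, in turn,
relates to yield: is community assembly deterministic or stochastic, how
connected is the community to its source pool, which taxa are habitat
specialists, which are network keystones, which of those are plausibly
beneficial, and how do soil, community structure and those keystone
beneficial specialists (KBS) jointly explain yield. Every stage is a plain
function over explicit containers (count tables, trees, metadata), and a
synthetic-data generator with known ground truth makes each stage testable
by parameter recovery.

## Study design emulated by the generator

The design is 10 sorghum cultivars (5 resistant to a fungal pathogen, 5
susceptible) x 2 fertilization treatments x 3 replicates = 60 phyllosphere
samples, with one bacterial and one fungal OTU table, a rooted phylogeny
per kingdom, 7-rank taxonomy, six soil variables (pH, AP, moisture, DOC,
NH4-N, NO3-N) and per-sample yield. Counts are filtered to taxa with total
reads > 20 and rarefied to even depth before all downstream analyses.

Generator defaults are the package's fixed study conditions: 400 taxa per
kingdom at 2,000 reads per sample for assembly and neutral-model work
(enough depth for occupancy-abundance structure while keeping null-model
loops fast on one CPU), and 120 taxa at 20,000 reads for network scenarios
(correlation estimation needs depth more than richness). Where the
emulated study itself fixes a number (60 samples, the 10 x 2 x 3 design,
the > 20 read filter, 999/1,000 permutations, the |rho| > 0.6 & p < 0.01
edge rule, Zi > 2.5 / Pi > 0.62) the package uses that number.

### Neutral counts

The metacommunity is lognormal (mu = 0, sigma = 2 on the log scale; a
realistic rank-abundance skew), normalized to relative abundances `p`.
Each sample's composition is drawn Dirichlet with concentration `N m p`
(`N` reads per sample, `m` the migration rate), then reads are multinomial.
This is the stationary approximation of Sloan's neutral birth-death
dynamics: the marginal composition of taxon *i* is Beta(`N m p_i`,
`N m (1 - p_i)`), exactly the occupancy-abundance relationship the neutral
model fit targets.

### Selection

Habitat optima evolve by Brownian motion along the shared phylogeny, so
selection is phylogenetically autocorrelated — the signal betaNTI is
designed to detect. Resistant and susceptible classes are opposite
habitats (+1/-1) and each class's source pool reweights the metacommunity
by `exp(strength * optimum * habitat)`. At `strength = 0` the code path
reduces bit-for-bit to the neutral generator (the optima use a separate
seed stream). The analysis scripts use `strength = 4` as the
strong-selection scenario: across independent tree draws it reliably
pushes the between-class mean betaNTI above +2 while leaving roughly a
hundred taxa after the read filter; much larger strengths concentrate the
pool so hard that few taxa survive filtering and the null models
degenerate. No effect size is claimed to match the field system — the
regime is chosen for detectability, as a ground truth must be.

### Modules and hubs

Co-occurring groups are planted through a latent factor model on log
abundances: each module has a module factor and three member groups
loading on 120-degree contrast vectors, so ordinary members correlate at
`within_module_corr` (default 0.8) inside their group but only 0.7 x that
across groups, while hubs load almost purely on the module factor and
correlate ~sqrt(0.8 x 0.8) = 0.8 with *every* member. After Spearman
thresholding at 0.6 this gives hubs a robust degree advantage at n = 60
samples — the property the Zi-Pi analysis must recover. The construction
is positive definite by design. Hubs share a fixed, moderately high base
abundance so any recovered subset of them tracks their total abundance;
their genera are always included in the beneficial list, giving the
three-criterion screen a recoverable target.

### Yield

`yield = intercept + b_soil * soilPC1 + b_kbs(class) * KBS + noise`, with
`b_kbs` positive in resistant and negative in susceptible cultivars
(defaults +80/-80 on the relative-abundance scale, b_soil = 0.4, noise sd
0.25, shifted to a positive t/ha-like scale). The defaults make the
within-class correlations strong (|r| ~ 0.8-0.9 for the true KBS taxa),
emulating a study that reports *significant* relationships of opposite
sign in the two classes.

## Assembly partition

Abundance-weighted betaMNTD between two samples averages each community's
nearest-taxon patristic distances into the other, weighted by relative
abundance; shared taxa contribute zero. betaNTI is its z-score against
999 (199 in desk runs) tip-label shuffles of the whole tree — the
Stegen-standard "taxa.labels" null; one shuffle per replicate is applied
to all pairs, and running Welford moments bound memory. betaNTI is
scale-free in branch lengths (the z-score cancels a global factor), which
is tested. Pairs with zero null spread (e.g. star trees) are reported
missing with a warning rather than fabricated.

RC-Bray assembles null communities that preserve each sample's observed
richness (taxa drawn proportional to metacommunity occupancy) and read
total (multinomial over metacommunity relative abundances), computes
Bray-Curtis for every pair in each replicate, and rescales the rank of the
observed distance to [-1, 1].

The partition follows the cited two-step framework: betaNTI < -2
homogeneous selection, > +2 heterogeneous selection; otherwise RC > 0.95
dispersal limitation, RC < -0.95 homogenizing dispersal, else drift. Pairs
are formed within cultivar classes, matching how the study contrasts the
two distributions; the reported group t-test on pair values ignores pair
non-independence, a caveat inherited from the source procedure. Note that
under strong *within-class* selection toward a shared optimum the
partition attributes pairs mostly to homogenizing dispersal rather than
selection — samples drawn from one reweighted pool are more similar than
richness-preserving nulls, which is a known reading ambiguity of the
framework, not a code artifact; the drift fraction still collapses, which
is the recoverable signal.

## Sloan neutral model

`fit_ncm()` estimates the migration rate `m` by bounded one-dimensional
least squares (coarse log-grid bracket, then golden-section refinement) of
observed occurrence frequencies against the neutral prediction, with
N = mean reads per sample and a one-read detection limit. Two forms of
that limit are offered. The classical continuous approximation treats
detection as a hard threshold at d = 1/N on the Beta composition,
`1 - pbeta(1/N; Nmp, Nm(1-p))`. For read-count data the exact form of
"detected means at least one read" is the beta-binomial survival
probability `1 - B(Nmp, Nm(1-p) + N) / B(Nmp, Nm(1-p))`; the threshold
approximation smooths through it and, on Dirichlet-multinomial data at
N = 2000, inflates the fitted m by roughly a quarter. The exact form is
therefore the default (`detection = "exact"`), with the threshold form
retained for comparability with the convention (`detection =
"threshold"`). R² is computed on observed frequencies and may be negative
for poor fits; per-taxon 95% envelopes are Wilson intervals around the
predicted frequency at the sample count, and taxa are flagged
above/within/below.

## Niche breadth

Levins B = 1 / sum(p_j²) over a taxon's share of reads per sample, ranging
from 1 (one sample) to the number of samples (perfectly even). The null
holds all row and column sums fixed ("quasiswap count" randomization, the
default of the cited procedure); labels come from the empirical two-sided
95% band (type-7 quantiles) at 1,000 permutations. Single-sample taxa are
classifiable (B = 1) but flagged, since their null is near-degenerate;
matrices with no checkerboard structure (where the fixed-fixed null space
collapses) classify everything neutral with a warning. Fixed-fixed nulls
are narrow: strongly aggregated taxa — such as the module-structured
synthetic communities — are mostly labelled specialists, which is the
expected behaviour of the procedure rather than a defect. Breadth is
computed per cultivar-class table, matching the network stratification;
an all-sample run feeds the CS/CR/FS/FR comparison.

## Co-occurrence networks and keystones

Per cultivar class, both kingdoms are converted to per-kingdom relative
abundances, merged over shared samples, prefiltered to >= 20% prevalence
(all-pairs Spearman on rare taxa yields spurious tied-rank correlations),
and correlated with mid-rank Spearman; p-values use the t approximation.
Edges require |rho| > 0.6 and raw p < 0.01 — raw because that is how the
thresholding is defined; a BH option exists. Modules come from seeded
Louvain on the unweighted simple graph, with modules under 3 nodes pooled
and excluded from Zi standardization. Zi is the within-module degree
z-score (0 where the module has no spread), Pi the participation
coefficient 1 - sum((k_is/k_i)²); module hubs Zi > 2.5, connectors
Pi > 0.62, network hubs both, and all three are keystones. The keystone
score sqrt((Zi/2.5)² + (Pi/0.62)²) is a threshold-normalized proxy
combining both axes — the quantity the screened outputs label a proxy,
since no formal definition accompanies the plotted scores it emulates —
and is regressed (log scale) on betweenness and degree over keystone
nodes, overall and for specialist keystones.

## The KBS screen

KBS = keystones ∩ specialists ∩ beneficial, computed on the same
cultivar-class sample set, bacteria-only by default (the screened
keystone specialists are predominantly bacterial). Beneficial matching is
case-insensitive exact string match at genus rank, the granularity of the
beneficial-bacteria databases this list stands in for; the package ships
no database and treats the list as user input, since such databases are
root/soil-derived and their "beneficial" labels are functional inferences.
The screen is an exact set intersection: tightening any single criterion
can only shrink it, which is tested. Downstream: per-sample summed
relative abundance on the rarefied table, class-level taxonomic
composition normalized within the KBS set, and per-resistance-class
Pearson correlation and slope of yield on KBS abundance.

## Path analysis

The SEM is an observed-variable recursive path model over soil PC1
(PCoA axis 1 of Euclidean distances on z-scored soil variables, sign
anchored to correlate positively with DOC), community PCoA1, keystone
relative abundance, KBS relative abundance and yield. The default
topology is soil -> community -> keystone -> KBS with all four into
yield, and is user-overridable; no latent variables are modelled. Fitting
minimizes the ML discrepancy F = log|Sigma(theta)| + tr(S Sigma^-1) -
log|S| - p. Starting values are per-equation OLS — exact ML for recursive
models with uncorrelated errors — polished by L-BFGS-B with variances
bounded below (Heywood cases warn at the boundary) and ten seeded jittered
restarts. Variables are z-scored internally for conditioning (every fit
index is invariant to affine rescaling, which is tested) and estimates are
rescaled back. chi² = (n-1)F, GFI = 1 - tr[(Sigma^-1 S - I)²] /
tr[(Sigma^-1 S)²], RMSEA = sqrt(max((chi² - df)/(df (n-1)), 0)) and 0 for
saturated models; standard errors come from the numerical Hessian of F
(acov = 2/(n-1) H^-1) with z-based p-values, the convention of the
commercial tool the procedure emulates. Total effects are
(I - B_std)^-1 - I, verified against a path-enumeration oracle. Constant
or collinear inputs (an empty KBS set, or a KBS set identical to the
keystone set) are dropped with their paths and logged, rather than
producing a singular covariance.

## Diversity utilities

Richness is the per-sample count of present taxa; Bray-Curtis comes from
`vegan::vegdist` on rarefied counts (relative-abundance mode available);
PCoA is classical metric scaling with negative eigenvalues dropped and
their mass logged (no Cailliez/Lingoes correction — the simplest
treatment, recorded in output). PERMANOVA wraps `vegan::adonis2` with free
permutations (999 by default); the block design could justify restricted
permutation, so a strata option exists but is off, matching the
single-factor usage emulated. Group comparisons are Welch/Student t for
two groups and one-way ANOVA with unadjusted pairwise pooled-variance t
("LSD", as named) plus a compact letter display for CS/CR/FS/FR.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; the pipeline derives
per-stage seeds from one master seed by a deterministic hash, so a single
integer reproduces the whole chain bit-for-bit (tested by running it
twice). Null-model counts default to the emulated study's values (999
permutations for betaNTI/RC/PERMANOVA, 1,000 for niche breadth); the
analysis scripts and acceptance checks run at 199 nulls and the pipeline
demonstrations at 29-199, with sizes stated where used — z-scores and
empirical quantiles are stable at these counts for the effect sizes the
generator plants. Typical desk-scale runtimes on one CPU: the neutral
model fit in under a second, the full 60-sample assembly partition at 199
nulls in ~10 s, niche classification at 1,000 permutations in ~6 s, and
the end-to-end pipeline in well under a minute.

## What the synthetic tests do and do not show

The generator emulates count structure (Dirichlet-multinomial),
phylogenetically autocorrelated selection, planted correlation modules
with hubs, and genotype-dependent yield coupling. It does not emulate
compositional artifacts of relative-abundance correlation (no SparCC-style
correction is implemented or tested), sequencing error or chimeras,
realistic taxonomies, habitat gradients within a class, or temporal
dynamics. Passing recovery tests therefore shows the estimators detect
the signals they are defined to detect at study-like sample sizes — not
that real phyllosphere data satisfy those models. Printed results from
the emulated study (node/edge counts, KBS percentages) depend on the
deposited reads, upstream read processing and an external database, and
are not reproduction targets at desk scale; the package's claims are
property-based.
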