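---
title: "Rareness, core selection and the bulked-genotyping model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rareness, core selection and the bulked-genotyping model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareset)
```

## The data model

A landrace collection is genotyped as DNA bulks: each accession contributes
B bulks (default 3) of n pooled plants (default 10, diploid), and each SSR
marker/allele combination is scored 1 in a bulk if it is detected there at
all. Pooling means presence, not frequency: detecting an allele in a bulk of
10 diploid plants says only that at least one of the 20 pooled haplotypes
carried it. The chance of detecting an allele at within-accession frequency
p is

$$P(\text{detect}) = 1 - (1 - p)^{n \cdot \text{ploidy}},$$

`detection_probability()` in the package. At p = 0.1 a 10-plant diploid bulk
detects the allele with probability `r round(detection_probability(0.1), 4)`;
above p ≈ 0.2 detection is almost certain. Two consequences shape everything
downstream: (i) allele frequencies are not estimable from the scores, and
(ii) only low-frequency alleles produce variation between bulks of the same
accession.

Collapsing the B bulks of accession $i$ gives the z-score
$z_{ij} \in \{0,\dots,B\}$, the number of bulks presenting combination $j$.
All accession-level analyses run on z; bulk-level analyses run on the
binary scores.

## The rareness coefficient

For M columns with collection-wide means $\bar z_j$ (focal accession
included),

$$R_i = \frac{1}{M}\sum_{j=1}^{M} (z_{ij} - \bar z_j)^2 .$$

$R_i$ is a mean squared deviation, so it responds to the *aggregate* allele
content of an accession: every common allele it lacks and every uncommon
allele it carries adds to it. A single private allele contributes at most
$(B - B/N)^2 / M$ — about 0.03 on a 14-locus, ~270-column collection —
which is below the typical between-accession spread of R. An accession
becomes "rare" by deviating at many columns, not by one needle; the needle
is instead guaranteed to be captured by the core selection (below). Tests
and the acceptance script therefore plant divergent accessions (a private
allele at half the loci) when they require top-class recovery.

Leaving the focal accession out of $\bar z_j$ is available
(`exclude_self = TRUE`) but not the default: the conventional definition
uses the whole collection, and the difference is $O(1/N)$.

Class labels cut the empirical distribution of R at four quantile levels
(default 0.40, 0.60, 0.77, 0.97) into *very common*, *common*, *average*,
*rare*, *very rare*. The defaults put roughly 77% of a collection in the
three common classes, 20% in *rare* and 3% in *very rare*, matching the
shares such collections typically show; they are fully configurable because
no canonical break points exist. A value tying a boundary goes to the rarer
class, so a degenerate distribution (all R equal) collapses deterministically
to *very rare* rather than splitting arbitrarily.

## AMA core selection

AMA ("All Marker Alleles") is a greedy set cover with a rarity objective:

1. Seed with the accession of maximal $R_i$.
2. Repeatedly add the accession covering the most not-yet-covered columns;
   break gain ties by higher $R_i$.
3. Stop when every coverable column (present in at least one accession,
   $z \ge 1$) is covered.

The conventional tie-breaks end at rareness; we add a final lexicographic
tie-break on accession id so the algorithm is a pure function of its input.
Determinism, guaranteed full coverage, and the rarity bias are the points of
contrast with stochastic core selectors. Columns present in no accession
(possible after subsetting) are excluded from the target with a warning
rather than looping forever.

Greedy set cover has the classical $(1 + \ln M)$ approximation guarantee;
`brute_force_min_cover()` provides the exact optimum by enumerating subsets
in increasing size (first hit is optimal and lexicographically smallest),
guarded to ≤ 20 accessions. On 200 random instances (N ≤ 15, M ≤ 30) the
test suite verifies $|\text{opt}| \le |\text{AMA}| \le
\lceil (1+\ln M)\,|\text{opt}| \rceil + 1$; empirically the mean size ratio
sits near 1.1.

A presence threshold of $z \ge 1$ defines coverage: one bulk suffices to
witness an allele, consistent with the detection semantics above.

## Distances, trees, sensitivity

Euclidean distance on binary bulk profiles (bulk level) or z profiles
(accession level) feeds average-linkage (UPGMA) clustering. UPGMA is
implemented in-package because we fix a deterministic tie-break — among
minimal-distance pairs, merge the one with the lexicographically smallest
pair of representative labels — which `stats::hclust` does not expose; on
tie-free inputs the two agree to 1e-9 (tested), and output goes through
`ape` as Newick. Merge heights are half the merged distance, so cophenetic
distances reproduce merge distances and the tree is ultrametric by
construction (verified to 1e-9 on random inputs).

Within/between statistics split bulk-pair distances by whether the two
bulks share an accession and compare the populations with a Welch t-test.
Pair distances sharing a bulk are not independent, so the t-test p-value is
an approximation — reported as is, with an optional permutation test
(accession labels shuffled over bulks) behind the `permutations` argument
for a calibrated alternative. For N accessions of B bulks there are exactly
$N\binom{B}{2}$ within and $B^2\binom{N}{2}$ between pairs; the tests assert
these counts.

Jackknife sensitivity rebuilds the tree with each column excluded;
sensitivity is $1 - r$ between full and reduced cophenetic vectors.
Excluding a constant or duplicated column leaves distances bit-identical and
scores exactly 0 — a useful self-check of the pipeline.

Geographic distance uses the haversine great-circle formula with Earth
radius 6371 km (via `geosphere`), an excellent approximation to planar
projected distances at intra-state scale. Correlation with genetic distance
is Pearson's r on the condensed vectors with a Mantel permutation p-value
(`vegan::mantel`), since distance entries are not independent.

## Association analyses

Per group (race, kernel colour) and column, a Welch t-test compares z
in-group vs all others; a G-statistic contingency test
($G = 2\sum O \ln(O/E)$, chi-square reference) compares presence
($z \ge 1$) by membership. G equals $2N$ times the mutual information of
the empirical joint — asserted in tests as an independent identity. Groups
below 10 members are excluded by default (small races carry no power);
columns constant over all accessions are reported untested. The q-values are
Benjamini–Hochberg over the whole group × column family of one run, with
significance defaulting to FDR ≤ 0.1%. Dichotomizing z at ≥ 1 is the
default contingency (the bulk-detection reading); a multi-level z table is
available via `levels = "z"`.

Altitude association is a forward-selection OLS of MASL on z columns:
starting from the intercept, add the candidate most improving BIC (AIC
optional) until no improvement or `max_terms`. BIC is the default because
the candidate set is wide relative to N and the selection should stay
sparse; under pure noise it selects zero terms in most replicates (tested).
Collinear candidates (rank-deficient fits) are skipped and recorded. The
returned object carries the full selection path; coefficients are meters
per z unit.

## The simulator

`simulate_collection()` emulates the data-generating design: per marker a
collection-wide base allele-frequency vector (Dirichlet, concentration 0.8
per allele, so some alleles are rare); per race a Dirichlet perturbation
with total concentration 10 (race-level divergence around $F_{ST} \approx
0.09$); per accession a perturbation of its race with total concentration
150 — chosen so that between-accession bulk distances exceed
within-accession ones by the 20–40% real landrace collections show. Bulks
draw $n \cdot \text{ploidy}$ haplotypes per marker independently
(multinomial; loci unlinked, as SSR panels spread over chromosomes are) and
score presence, with an optional per-call false-negative rate (default
0.5%, the order of null-allele rates seen in practice). Altitude and
coordinates are race-clustered in a Puebla-like bounding box so geography
and MASL carry real signal. Matrix columns span the full configured allele
universe, so shapes are deterministic; alleles that happen never to be
drawn surface as uncoverable columns downstream.

Planted rare accessions override the focal accession's frequency vector
with a private allele at a chosen frequency; planted altitude effects put
the allele's *per-bulk detection probability* on a logistic curve in
standardized altitude (the frequency is recovered by inverting the
detection formula). The logistic acts on the detection scale deliberately:
the bulk design saturates for frequencies above ~0.2, so a
frequency-scale logistic would produce a nearly constant column with no
recoverable signal.

What the simulator does *not* emulate: mutation processes (no stepwise
mutation or homoplasy), linkage, fragment-size artefacts, or real
geography. Passing recovery tests therefore demonstrates that the
estimators behave correctly under the stated sampling design — not that
any particular real collection will show the same rates.

## Problem sizes and numerical choices

The test suite and acceptance script use: 100 random matrices up to 50 × 100
for the rareness oracle (agreement to 1e-12); 200 random cover instances
with N ≤ 15, M ≤ 30 against the exhaustive optimum; 50 seeded replicates of
100 accessions for planted-rare recovery (observed rate 0.92–0.98 against a
0.90 requirement); 20 random trees for ultrametricity (1e-9); 2001
simulated bulks for the Monte-Carlo detection check (3 binomial SEs); and a
240 × 3 × 278 full-shape study for the pipeline summary. These sizes keep
the full suite under a minute per module while leaving the property checks
statistically meaningful.

Ties are broken lexicographically everywhere (AMA seed and steps, UPGMA
merges, brute-force enumeration order) so every result is a pure function
of the input. Quantile classification uses R's default type-7 quantiles.
Degenerate inputs — constant columns, all-equal distances, single pairs,
zero-variance t-tests — are reported as missing with notes rather than
silently dropped or crashed, and each such path is exercised by a test.

## Known limitations

- R_i is insensitive to single private alleles by construction (see above);
  use the core selection, which captures them by coverage, or inspect
  per-column redundancy from `core_metrics()`.
- The within/between t-test inherits the dependence of pair distances; use
  the permutation option when calibrated inference matters.
- `brute_force_min_cover()` is exponential and refuses N > 20; it is an
  oracle, not a production selector.
- The G-test's chi-square reference is asymptotic; very sparse tables (cell
  expectations below ~5) deserve caution at extreme significance levels.
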