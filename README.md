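# rareset

Rareness coefficients and minimal core collections from bulked SSR
genotyping of landrace germplasm.

## The problem

Genotyping every plant of a large landrace collection is expensive, so
collections are often scored as **DNA bulks**: each accession is sampled as a
few bulks of pooled plants (here, 3 bulks of 10 diploid plants), and each SSR
(microsatellite) marker allele is scored 1 if it is detected in the bulk and
0 otherwise. The result is a binary accessions × bulks × marker/allele
matrix. Two questions follow for conservation genetics:

1. **Which accessions carry unusual allele content?** Rare germplasm is the
   priority for in situ conservation.
2. **What is the smallest subset of accessions that still contains every
   marker/allele combination observed in the whole collection?** That subset
   is a candidate core collection.

`rareset` implements the two estimators at the heart of this workflow plus
the supporting diversity and association analyses.

## The statistics

Collapsing the B bulks of accession *i* gives the z-score
`z_ij ∈ {0, …, B}`, the number of bulks presenting marker/allele
combination *j*. With column means `z̄_j` taken over the whole collection,
the **coefficient of rareness** of accession *i* over M columns is

    R_i = (1/M) · Σ_j (z_ij − z̄_j)²

Accessions whose allele content deviates from the collection average score
high; the empirical distribution of R is cut at four quantiles into five
ordered classes (very common … very rare).

The **AMA ("All Marker Alleles") algorithm** selects a covering core set
deterministically: seed with the accession of highest R_i, then repeatedly
add the accession contributing the most not-yet-covered combinations,
breaking ties by higher R_i and then by accession id, until every coverable
combination is included. Unlike stochastic core selectors, two runs on the
same input always return the same set, full coverage is guaranteed, and the
rareness objective biases the core toward unusual germplasm. An exhaustive
minimum-cover oracle (`brute_force_min_cover()`, ≤ 20 accessions) quantifies
how close the greedy set is to optimal.

Around these sit: Euclidean distances at bulk and accession level, Welch
t-tests of within- vs between-accession bulk distances, UPGMA trees with
Newick export and jackknife column-exclusion sensitivity, great-circle
geographic vs genetic Mantel correlation, per-race Welch t and G-statistic
association tests with Benjamini–Hochberg FDR control, forward-selection
regression of altitude (MASL) on z-scores, and a seeded simulator of the
whole bulked-genotyping design (including the closed-form bulk detection
probability `1 − (1 − p)^(n·ploidy)`).

## Worked example

```r
library(rareset)

fx <- make_fixture("F1")     # 3 accessions, 3 marker/allele columns, B = 1
r  <- rareness_coefficients(fx$accessions)
r$R
#> [1] 0.3333333 0.1111111 0.2222222

core <- ama_select(fx$accessions, r)
core$selected
#> [1] "A" "C"
```

Accession A is the rarest (R = 1/3) and seeds the core; B and C tie on gain
for the last uncovered column and C wins on rareness (2/9 > 1/9). The
exhaustive oracle confirms the optimum size is also 2.

A full-scale run on simulated data:

```r
sim <- make_fixture("study_shape")        # 240 accessions x 3 bulks, 278 columns
a   <- collapse_bulks(sim$bulks)
r   <- classify_rareness(rareness_coefficients(a))
core <- ama_select(a, r)
#> Warning: 7 column(s) present in no accession excluded from the coverage
#> target: SSR03_151, SSR05_062, ...
core
#> Core set (ama): 20 accessions, coverage 1.000
#>   mean rareness of selected: 0.9868
#>   7 uncoverable column(s) excluded
#>   selected: A045, A094, A091, A007, A210, A106, A240, A035, A219, A085 ...
within_between_stats(sim$bulks)
#> Within/between-accession bulk distances
#>   all pairs:  mean 9.26, median 9.33, range 4.69-10.91
#>   within:  mean 6.60 (median 6.63, n = 720)
#>   between: mean 9.27 (median 9.33, n = 258120)
#>   between/within ratio: 1.406
#>   Welch t = 164.329, p = 0
```

Twenty of 240 accessions suffice to retain every observed marker/allele
combination (seven configured alleles happened never to be drawn and are
excluded from the target with a warning), the selected set is rarer on
average than the collection (0.987 vs 0.921), and bulks of the same
accession are substantially closer to each other than to bulks of other
accessions — the structure a sound bulk design should show.

A thin command-line front end over the same functions is installed at
`inst/cli/rareset.R` (`Rscript rareset.R <command> --help`).

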