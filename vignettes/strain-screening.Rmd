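---
title: "Screening entomopathogenic fungal strains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening entomopathogenic fungal strains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epfscreen)
```

## The screening problem

Entomopathogenic fungi such as *Beauveria bassiana* vary enormously from
strain to strain in how fast they grow, how many conidia they produce,
and how lethal they are to a target pest. Picking a strain for
biopesticide development on any single trait is misleading: a highly
virulent strain that barely sporulates cannot be mass-produced, and a
fast grower may kill nothing. `epfscreen` implements the screening
workflow used for large strain panels assayed against whitefly
(*Bemisia tabaci*) nymphs: replicate-level bioassay counts are turned
into control-corrected mortalities, combined with culture traits into a
single weighted bioefficacy index, and the panel is then explored with
standardized PCA, Ward clustering of the index, and an ITS-sequence
phylogeny to ask whether bioefficacy tracks host or geographic origin.

## Corrected mortality and its analysis

Observed treatment mortality confounds fungus-induced death with
background death, so every replicate is corrected against the untreated
control (Schneider-Orelli):

$$CM = \frac{T - C}{100 - C} \times 100$$

with $T$ the replicate's raw mortality (%) and $C$ the mean control
mortality of the same observation day. The correction uses the
day-matched *mean* control rather than pairing replicates to controls:
bioassay controls are not physically paired with treatment replicates,
and the mean is the lower-variance estimate of background mortality.
Negative corrected values (control above treatment) are clamped to zero
and flagged; mortality cannot be negative, and silent negative values
would propagate into the index.

Percentages are arcsine-square-root transformed
($\theta = \arcsin\sqrt{p/100}$, in degrees) before ANOVA, the standard
variance-stabilization for binomial-type percentages. The design is a
completely randomized one (CRD), analysed as a one-way fixed-effects
ANOVA; test dates are not modelled as blocks. Mean separation uses the
least significant difference at $\alpha = 0.05$,

$$LSD = t_{1-\alpha/2,\,df_e}\sqrt{2\,MS_e/r},$$

with a compact letter display assigned by insertion grouping on the
descending means: means closer than the LSD share a letter, means
further apart never do. Shapiro-Wilk and Brown-Forsythe diagnostics are
advisory only -- the pipeline warns but proceeds, because screening
decisions rest on the index ranking, not on exact p-values.

## The bioefficacy index

The index aggregates the three deployment-relevant traits:

$$BI = 0.37\,MG + 0.13\,SP + 0.50\,MO$$

where $MG$ is the mean colony diameter (mm), $SP$ the conidial
concentration ($\times 10^8$/ml) and $MO$ the corrected nymphal
mortality (%) at 7 days post spray. Half the weight is virulence; the
remainder is split between the culture traits that determine whether a
strain can be produced and persist in the field. The literature also
describes a 15/35/50 weighting in prose; the 0.37/0.13/0.50 weights are
the package default because they exactly reproduce the published
per-strain index values from their printed inputs (the packaged
`table1_fixture()` verifies this to within 0.06, attributable to the
one-decimal rounding of the inputs). Alternative weights are accepted
through `bi_weights()` and must sum to one.

Note on units: the reference table's growth column is headed cm² while
the index formula is stated over mm diameters. The numeric values are
consumed exactly as printed -- which the recomputability of the BI
column confirms is what the index uses -- so the package treats growth
throughout as a colony diameter in mm. The formula text also dates
growth at 10 days while the growth assay's final reading is at 7 days;
`build_strain_summaries()` therefore summarizes growth at the latest
day present unless `mg_day` says otherwise.

Virulence categories partition the BI axis into six half-open bins:
HV $[60,\infty)$, GV $[50,60)$, V $[40,50)$, MV $[30,40)$, LV
$[20,30)$, PV $[0,20)$. The printed category bounds leave integer gaps
(nothing between 49 and 50); since the index is continuous the bins are
closed on the left and open on the right, so every value receives
exactly one label.

## Multivariate selection

PCA runs on the standardized (mean 0, variance 1, denominator $n-1$)
six-variable matrix -- MG, SP, MO3, MO5, MO7, BI -- i.e. on the
correlation matrix, because the variables live on incommensurate
scales. Variance-explained figures are reported from the unrotated
solution; varimax rotation (Kaiser-normalized, preserving per-variable
communalities) is reported separately for interpreting which variables
define which component. Components are retained until their cumulative
variance reaches 70%. Variables are attached to components by Pearson
correlation between variable and component scores, with the
t-approximation on $n-2$ degrees of freedom and a deliberately liberal
$P \le 0.15$ screen -- the goal is biplot interpretation, not formal
inference. Component signs are fixed so the largest-magnitude loading
is positive, and `select_strains()` additionally orients PC1 so the
mortality/index block loads positively; rankings and biplot quadrants
are then reproducible across platforms.

## Clustering

The strain dendrogram is built from the BI scalar by default (a flag
accepts the full feature matrix), using squared Euclidean distances
under Ward's minimum-variance criterion. "Ward" is implemented in
mutually incompatible dialects across software; this package pins the
classical Lance-Williams update applied to squared distances
(`hclust(method = "ward.D")` on squared input), under which merge
heights equal twice the within-cluster sum-of-squares increase and the
merge sequence coincides with the exhaustive greedy minimum-variance
agglomeration -- the test suite checks this equivalence directly for
small panels. UPGMA (average linkage) is provided as the cross-check
method; it inverts ultrametric distances exactly. The tree is cut at
$k = 6$, and because the cut's cluster numbers are arbitrary, clusters
are reported in descending mean-BI order and labelled HV through PV in
that order. This labelling describes cluster composition -- the
fixed-threshold `categorize_bi()` labels remain available and need not
coincide at the cluster boundaries.

## Phylogeny

ITS sequences arrive pre-aligned; the package never aligns. For each
sequence pair, columns with a gap or IUPAC ambiguity code in either
sequence are dropped (pairwise deletion) before counting the two
transition types and transversions. Distances are Tamura-Nei (1993),
by default with base frequencies pooled over the whole alignment --
the composite flavor that borrows frequency information across pairs,
chosen as a close, transparent stand-in for composite-likelihood
distances at the low divergences typical of intraspecific ITS data; a
`pair` mode uses pair-only frequencies. Saturated pairs, whose
logarithm arguments are non-positive, return a configurable ceiling
(default 5 substitutions/site) with a warning rather than `NaN`, so a
single saturated pair cannot poison a bootstrap replicate.

Trees are neighbor-joining with deterministic lowest-index
tie-breaking. Negative branch-length estimates are clamped to zero with
the deficit moved to the adjacent branch of the join
(Kuhner-Felsenstein), preserving path lengths through the new node.
Bootstrap support resamples alignment columns with replacement,
rebuilds distances and tree per replicate, and reports the percentage
of replicates containing each internal bipartition of the reference
tree; replicates whose distances are uncomputable are skipped with the
denominator adjusted. The seed is an explicit argument and the run is
bit-reproducible for a fixed seed. `annotate_tree()` decorates leaves
with host order, state and virulence category and tabulates clade
composition, which is how the absence of host/location structure is
made visible.

## The synthetic panel generator

`generate_panel()` emulates the study conditions: 102 strains, three
replicates, 45 marked nymphs per replicate, growth 8.4-69.5 mm,
sporulation 0.3-55.7 ($\times 10^8$/ml), day-7 corrected mortality
4.7-98.1%, and 5% mean control mortality (the study never prints its
control levels; 5% is a typical background for caged nymph assays and
is a stated assumption of the generator). A latent virulence
$v_i \sim U(0,1)$ drives the day-7 mortality propensity through a
monotone map of $\lambda v_i + (1-\lambda)u_i$; day-5 and day-3 values
are shrunken fractions, so the time-kill curve rises in expectation.
Mortality noise is binomial at the count level, not Gaussian on
percentages -- that is how the data arise. Growth and sporulation are
drawn independently of $v_i$ by default, mirroring the real panel's
lack of a growth-virulence correlation; `mg_sp_coupling` couples them
for sensitivity work. All generators take explicit seeds and touch no
global state beyond R's RNG.

What the generator does *not* emulate: spatial/leaf-level correlation
within replicates, date-block effects, dose-response (a single
concentration is assumed), and strain-specific control interference.
Passing tests therefore demonstrate the correctness of the computations
and the recoverability of planted structure, not field predictivity.

One property deserves honesty: because the index deliberately mixes
mortality with independently varying culture traits, its ranking can
only partially recover a latent factor that drives mortality alone.
With the default trait ranges, roughly a third of the index's standard
deviation comes from growth and sporulation, which bounds the rank
correlation between a mortality-side latent virulence and BI in the
mid-0.8s even at $\lambda = 1$ -- the simulations in the test suite
show exactly this. That is a property of any mixed-weight index, not a
defect of the estimator: BI is designed to demote unproducible
killers.

The sequence simulator (`generate_alignment()`) evolves columns under
TN93 along a supplied or random coalescent tree (defaults: 590 columns,
mild transition bias with the pyrimidine rate above the purine rate,
2% gaps, 0.5% ambiguity codes) and returns the true tree so topology
recovery and bootstrap behaviour can be scored.

## Numerical choices and degenerate inputs

* Corrected mortality at 100% control is an error, not infinity.
* A zero error mean square in the ANOVA yields a flagged large finite
  F (and LSD 0) instead of a crash; Shapiro-Wilk on constant residuals
  reports `NA` with a flag.
* PCA on rank-deficient input proceeds with zero eigenvalues; constant
  columns are an error naming the variable, since a correlation with a
  constant is undefined.
* Ties in agglomeration and NJ break toward the lowest index pair.
* The reference-table fixture is stored verbatim; one printed
  transformed value (strain MTCC-4575's transformed BI) is
  inconsistent with its own BI and is excluded from the transform
  cross-check.

## Problem sizes used in the checks

The shipped tests run generated panels at the study scale (102 strains)
for the pipeline, PCA and recovery properties; exhaustive oracles
(greedy Ward, path-length NJ, textbook UPGMA) at $n \le 8$ where
enumeration is exact; a $10^5$-column pair for distance consistency;
and bootstraps of 20-100 replicates on 6-taxon alignments. These sizes
were chosen so every oracle is exact or tight at desk scale; the
production defaults (500 bootstrap replicates, arbitrary panel sizes)
are plain arguments.

## Known limitations

* The published 102-sequence tree (total branch length 24.52394125)
  is not reproducible here: the underlying GenBank accessions are not
  listed in the source, so the phylogeny stage is validated purely by
  simulation and property tests.
* Composite-likelihood distances are approximated by pooled-frequency
  TN93; at ITS-level divergence the difference is second-order, but it
  is an approximation.
* The LSD letter display assumes a balanced design; unbalanced panels
  get the classical ANOVA on available cells, with the LSD computed
  from the nominal replicate count.
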