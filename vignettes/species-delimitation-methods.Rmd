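---
title: "Methods: the molecular evidence chain behind felidelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the molecular evidence chain behind felidelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felidelim)
```

felidelim implements the chain of molecular analyses used to ask whether a
single specimen — here, a small spotted cat (genus *Leopardus*) from the
southern Colombian Andes, the "Nariño cat" — represents a lineage distinct
from every recognised congener. Four lines of evidence are computed from
two marker classes: corrected mitochondrial distances with species-band
flagging, haplotype-network divergence dating, multivariate clustering of
nuclear microsatellites, and fixed diagnostic sites. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
choices, in enough detail that a maintainer could re-derive every formula.

## 1. Kimura 2-parameter distances

For each sequence pair, sites carrying anything other than a determined
`A/C/G/T` in either sequence are excluded (pairwise deletion — the
barcoding default, and it keeps the per-pair site count `n` explicit).
With transition proportion $P$ and transversion proportion $Q$ over the
$n$ compared sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

and the delta-method variance uses $c_1 = 1/(1-2P-Q)$,
$c_3 = \tfrac12\,[1/(1-2P-Q) + 1/(1-2Q)]$:

$$\mathrm{var}(d) = \frac{c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2}{n}.$$

When $1-2P-Q \le 0$ or $1-2Q \le 0$ the estimator has left its domain;
the pair is recorded in `undefined_pairs` rather than dropped, because
whole-mitogenome outgroup comparisons (jaguarundi and domestic cat sit
near 21–33% from the ingroup) approach exactly this edge. The test suite
checks the closed form against high-precision evaluation, the SE against
a multinomial site bootstrap, and both against an independent
implementation (`ape::dist.dna`, model K80), which is used only as an
oracle.

Species-band flagging renders distances in percent (one decimal, matching
how such tables are printed) and classifies each comparison against a
band: 6–11% is the conventional distinct-species range for whole
mitogenomes, and a degenerate band at 2.5% models the single-threshold
rule used for mammalian Cyt-b. A distance below the band is evidence
against separate status at that marker, not proof of conspecificity; the
package reports counts per category and leaves the inference to the
analyst.

## 2. Haplotype networks and rho dating

`collapse_haplotypes()` keeps the columns with at least two observed
determined bases and merges identical restricted sequences; multiplicity
is preserved because rho weights by sample counts. Merging is by exact
string equality, so two sequences differing only in where their missing
data fall stay distinct — a conservative choice that never invents
identity.

`build_mjn()` follows the published median-joining scheme: iterate
(i) the minimum spanning network (all links whose weight is within
$\varepsilon$ of the smallest weight connecting their endpoints;
$\varepsilon = 0$, the default and most parsimonious setting, yields the
union of all minimum spanning trees), (ii) per-column majority median
vectors of connected triplets, (iii) admission of median vectors that
strictly reduce the total minimum-spanning weight, repeated to a fixed
point, then deletion of median vectors left with fewer than two links.
Two deliberate deviations from the reference software are documented
here: medians are admitted greedily (each candidate is evaluated against
the current node set, which makes the total weight monotonically
decreasing and guarantees termination) rather than in batches, and the
final maximum-parsimony pruning pass is not implemented. Majority ties in
a triplet go to the state of the first member in node order, making the
construction deterministic. On homoplasy-free data the network provably
reduces to the generating tree, and on small instances the suite checks
it reaches brute-force minimal Steiner configurations.

The rho statistic is the multiplicity-weighted mean number of mutations
along network shortest paths from a designated ancestral node to the
sampled haplotypes; the ancestor must be designated by the analyst
(nothing in the data roots the network). Its error follows the standard
genealogy-weighted estimator: on the shortest-path tree from the
ancestor, every mutation on an edge subtends a fraction $f$ of the
sample, and $\sigma^2 = \sum f^2$ over mutational events.

Calendars convert a per-position rate $r$ (% per My) and a sequence
length $L$ into `round(1 / (L r / 100 / 10^6))` years per mutation: 315
bp at 1.22%/My gives 260,213 years. For the whole mitogenome the same
arithmetic on 16,756 bp at 1.15%/My gives 5,190 years, not the round
5,500 sometimes quoted for that marker; the package always computes from
$(L, r)$ and accepts a published round figure only as an explicit
override (`mutation_rate_spec(..., years_per_mutation = )`). Dated splits
are the plain product $\rho \times$ years-per-mutation, displayed in My
at two decimals; independent estimates of the same split can be averaged
with `combine_split_estimates()`.

At mitogenome-scale divergence (hundreds of mutations per lineage) the
median step adds many unsampled intermediates without changing any
ancestor-to-tip shortest-path length — every admitted median lies on such
a path. `build_msn()` therefore exposes the spanning phase alone, and the
dating recovery study uses it; a test verifies the rho-invariance claim
by comparing both constructions at moderate divergence. Because repeated
hits at a site are invisible to a mismatch count, rho dating carries a
small downward bias that grows with divergence (about 1% at 0.014
substitutions/site); the recovery study shows it stays within the
estimator's own error at the scales used here.

## 3. Microsatellite statistics

Allele sizes are interpreted as repeat units; every called diploid
genotype contributes two observations. Three distances are implemented:

* **delta-mu-squared** between groups: the squared difference of
  per-locus mean allele sizes, *averaged* over loci with data in both
  groups (averaging, not summing, keeps values comparable across the
  locus subsets drawn during bootstrap). Under stepwise mutation its
  expectation after $\tau$ generations at rate $\beta$ is $2\beta\tau$.
* **squared Euclidean** between individuals, on 0/1/2 allele-count
  vectors over the union of (locus, allele) keys. The encoding is the
  standard one that makes "squared Euclidean distance among specimens"
  well-defined; a missing call is imputed with the individual's group
  mean counts at that locus, because Ward clustering needs complete
  vectors and pairwise deletion would break the Euclidean embedding.
* **Euclidean** between group allele-frequency vectors, for the
  species-level unrooted NJ tree.

Ward trees use the Lance–Williams `ward.D` update on the squared
Euclidean matrix — exactly the greedy minimum-SSE-increase agglomeration,
as the suite verifies against a brute-force oracle. Bootstrap support
resamples **loci** (the unit of independent information here), default
B = 500, the bootstrap count conventionally used for tree support in
this literature. NJ trees clamp negative branch lengths to zero and move
the deficit to the sister branch, preserving path lengths. PCoA is the
Gower construction (double-centering of $-d^2/2$); axes with negative
eigenvalues — expected for non-Euclidean inputs like delta-mu-squared —
are dropped from the coordinates but their mass is reported. The MST
overlaid on the ordination is computed on the *original* distances, not
the projected ones, so it exposes distortions of the 2-D view; Prim's
algorithm with first-label tie-breaking makes it deterministic.

## 4. Diagnostic sites

A column is diagnostic for a focal set when all focal sequences share one
determined base that no background sequence carries. Background missing
data are ignored (an `N` cannot vouch either way), but a single
background match rejects the site, and a missing base in any focal
sequence disqualifies the column — both choices keep false positives at
zero by construction, which the planted-fixture study confirms.
Positions are reported in the coordinate system of a designated reference
sequence (successive numbering of its non-gap columns), since published
diagnoses cite positions in a reference mitogenome; gene intervals, when
provided as 1-based inclusive reference coordinates, restrict and
annotate the report.

## 5. What the simulators emulate — and what they do not

`simulate_sequences()` evolves a uniform root along a tree with branch
lengths in years, events Poisson at $rL t$, each a transition with
probability $\kappa/(\kappa+2)$. This is the two-class process the K2P
estimator inverts exactly, so estimator recovery is a clean oracle. It
deliberately omits rate heterogeneity among sites, base-composition
bias, and selection — features of real mitogenomes under which K2P is
known to be downwardly biased. Passing recovery tests therefore
demonstrates correctness of the implementation, not robustness of K2P to
model violation.

`simulate_msat()` is a Wright–Fisher stepwise-mutation simulation: each
generation every allele copies a uniformly chosen parent and mutates with
probability $\beta$ by $\pm 1$ (reflecting at size 1, negligible for
ancestral sizes $\ge 30$). The population is the $n_{ind}$ sampled
diploids. A burn-in of $10\,n_{ind}$ generations brings the ancestral
pool to mutation–drift equilibrium before the split; without shared
within-population drift (i.e. with independent lineage walks) the
expected delta-mu-squared would collapse toward zero instead of
$2\beta\tau$, which is why a genealogy-free walk generator would not
exercise the statistic. Omitted: unequal population sizes, range
constraints on allele size, multi-step mutations, and migration.

Every simulator is a pure function of its argument list including the
seed (default 20230615 throughout).

## 6. Problem sizes, defaults and numerical tolerances

The study conditions baked into the recovery studies are: rho dating on
stars of 50 tips, 16 kb at 1.15%/My, true age 1.2 My, 200 replicates,
judged against twice the mean per-replicate rho error; K2P at true
distance 0.05 on 10 kb, 100 replicates, judged against twice the SEM;
delta-mu-squared on 500 loci, 30 diploids per population, $\beta =
5\times10^{-3}$, $\tau \in \{200, 400, 600, 800\}$, slope within 15% of
$2\beta$. Oracle-equivalence checks run at the sizes where brute force is
exact: Steiner configurations to 5 haplotypes, Ward and MST enumeration
to 7 points, NJ additivity to 8 taxa. Symmetry tolerance for matrix
input is 1e-9; PCoA axes are kept when their eigenvalue exceeds 1e-9 of
the largest magnitude; distances render at 6 significant digits on disk.

## 7. Known limitations

* Median-joining here lacks the maximum-parsimony post-processing pass of
  the reference software, so on data with heavy homoplasy the network can
  retain links that pass would remove.
* Tree inference beyond distance methods (likelihood or Bayesian dated
  trees) is out of scope; published dated-tree estimates enter only as
  numbers to be averaged with network estimates.
* The gap filter `filter_columns()` is a per-column missingness rule, a
  declared simplification of block-based alignment cleaning; it makes no
  attempt to reproduce any particular block-selection heuristic.
* The 113-specimen genotype panel behind the published microsatellite
  figures is not redistributable; the microsatellite stage is exercised
  on simulated panels with the same locus count, and the package reads
  user-supplied genotype CSVs for real analyses.
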