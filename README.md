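# felidelim

Molecular species-delimitation toolkit for neotropical cats (genus
*Leopardus*), written for systematists weighing whether a candidate
specimen — the motivating case is the "Nariño cat", a single skin from
the Galeras Volcano in southern Colombia — represents a lineage distinct
from all recognised congeners. The package implements the four
quantitative stages such a case rests on, each usable on its own or
through a one-call pipeline, plus simulators that generate data with the
statistical structure every stage assumes, so the whole chain is testable
offline.

## The methods

**Corrected mitochondrial distances.** Kimura 2-parameter distances with
pairwise deletion,

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

with delta-method standard errors, nearest-taxon ranking for a focal
lineage, and flagging against species bands (6–11% for whole mitogenomes;
a 2.5% single cut-off for Cyt-b). Saturated pairs are reported as
undefined, never dropped.

**Haplotype networks and ρ dating.** Median-joining network construction
(minimum spanning networks plus majority median vectors of connected
triplets, ε-tolerance, deterministic tie-breaks), and the ρ statistic —
the multiplicity-weighted mean mutational distance from a designated
ancestral node — converted to years through a mutation-rate calendar:
315 bp of ND5 at 1.22%/My gives one mutation per 260,213 years.

**Microsatellite multivariate clustering.** δμ² distances (squared
difference of mean allele sizes averaged over loci; expectation 2βτ under
stepwise mutation), squared-Euclidean distances between individuals on
0/1/2 allele-count vectors, Ward minimum-variance trees with locus
bootstrap, unrooted neighbour-joining on group frequencies, and Gower
PCoA with a minimum spanning tree overlaid on the ordination.

**Molecular diagnosis.** Fixed diagnostic sites (synapomorphies): columns
where the focal taxon carries a determined base absent from every
comparison sequence, reported in reference coordinates and optionally
restricted to gene intervals.

## Worked example

The package ships the published 14-taxon whole-mitogenome K2P table as a
plain-text fixture. Ranking all *Leopardus* taxa by distance from the
Nariño cat:

```r
library(felidelim)
m  <- table1_fixture()
nt <- nearest_taxa(m, "Narino_cat", exclude = c("F_catus", "H_yagouaroundi"))
head(nt, 3)
#>                    label distance percent
#> 1 CA_transAndean_tigrina    0.056     5.6
#> 2            L_geoffroyi    0.058     5.8
#> 3              L_emiliae    0.061     6.1

threshold_report(m, "Narino_cat", threshold_band(6, 11, "mitogenome"),
                 exclude = c("F_catus", "H_yagouaroundi"))
#> Threshold report for Narino_cat (band 6-11% mitogenome)
#>     below    within     above undefined
#>         2         7         2         0
```

The closest taxon sits at 5.6% (the Central American/trans-Andean
tigrina), then 5.8% (*L. geoffroyi*) — larger than the distances
separating several accepted species pairs in the same table (*L. guigna*
vs *L. geoffroyi* 2.0%, *L. pardalis* vs *L. wiedii* 4.4%), though below
the 6–11% band itself. Converting the ND5 rate calendar and dating a
simulated 1.2-My star radiation:

```r
years_per_mutation(315, 1.22)
#> [1] 260213

r <- rho_recovery_study(n_rep = 50, seed = 20230615)
round(c(mean = r$mean_age_my, sigma_bar = r$mean_sigma_my), 3)
#>      mean sigma_bar
#>     1.189     0.011
```

The numbered scripts under `analysis/` run the full workflow — distance
evidence, estimator calibration, network dating, microsatellite
clustering, molecular diagnosis — writing their tables under `results/`:

```sh
Rscript analysis/01_distance_evidence.R
Rscript analysis/02_k2p_calibration.R
# ... through 05
```

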