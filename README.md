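# photoidnet

Social-structure analysis of photo-identification sighting data.

Field studies of cetaceans (and other individually identifiable animals)
accumulate a *sighting database*: repeated group encounters in which
individuals are identified from natural markings. photoidnet turns such a
database into an association network and the standard downstream analyses
used to delineate social communities:

* **Half-weight association index (HWI).** Under the gambit of the group
  (individuals identified together are associated), each dyad gets
  `HWI = X / (X + 0.5 (Ya + Yb))`, where `X` counts encounters containing
  both individuals and `Ya`, `Yb` those containing only one. The encounter
  is the sampling unit.
* **Community partitioning.** The sociogram (edges where HWI exceeds a
  threshold, default 0) over permanently marked individuals is split into
  connected components, labelled `A`, `B`, ... by decreasing size.
  Temporarily/superficially marked individuals are assigned to a community
  only if *all* their permanently marked associates belong to it, else
  `UNASSIGNED`.
* **Composition statistics.** Pearson chi-square (no continuity correction)
  comparisons of mark-severity and fin-damage proportions between
  communities, with Bonferroni-corrected pairwise 2×2 tests.
* **Spatial segregation.** Distance from shore per encounter (recorded, or
  computed from a coastline polyline), summarized per community grouping
  and compared with an exact two-sided Mann-Whitney U test.
* **Synthetic data.** A fission-fusion generator with ground truth — one
  cohesive inshore community plus transient offshore groups — so the whole
  pipeline is testable without field data.

## Worked example

```r
library(photoidnet)

sim <- generate_sightings(default_config(), seed = 1)
sim$db
#> <sighting_db> 267 individuals, 60 encounters, 699 identifications

m <- association_matrix(sim$db, grade_filter = "PERMANENT")
g <- build_sociogram(m, threshold = 0, db = sim$db)
part <- assign_unmarked(sim$db, detect_communities(g))
part
#> <community_partition> 267 individuals in 5 group(s): A=187, B=33, C=30, D=9, E=8

pearson_chi_square(rbind(A = c(72, 120), B = c(33, 9)))
#> Pearson chi-square: chi2 = 23.5, df = 1, N = 234, p = 1.249e-06

compare_group_distances(sim$db, part)$summary[, c("group", "n_encounters", "mean")]
#>   group n_encounters       mean
#> 1     A           56  0.7686487
#> 2   B-E            4 14.4855047
```

The five groups are the one large inshore community (`A`, 187 individuals
after secondary assignment, most of them resighted) and four offshore
groups whose members were each seen exactly once; `A`'s encounters average
under 1 km from shore against 14.5 km for the rest. The chi-square call
shows the composition machinery on a published-style 2×2 permanent/other
table.

Or from a shell:

```sh
Rscript inst/cli/photoidnet.R simulate --defaults --seed 1 --out sim/
Rscript inst/cli/photoidnet.R analyze --sightings sim/sightings.csv --out report/
```

`report/` then holds the catalogue summary (JSON), association matrix
(long + square CSV), sociogram (GraphML + edge list), partition CSV,
mark-severity table, pairwise test tables, distance comparison and a
manifest.

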