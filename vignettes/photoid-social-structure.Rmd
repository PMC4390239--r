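---
title: "Methods: photo-ID social structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photo-ID social structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoidnet)
```

photoidnet analyses the social structure of photo-identified animal
populations — built with coastal bottlenose dolphin studies in mind — from a
sighting database: one row per individual identified within a group
encounter. This vignette explains the model behind each stage, the
parameters that matter, and the design decisions where more than one
reasonable choice existed.

## The data model

A `sighting_database` has three tables: individuals (id, mark severity
grade, dorsal-fin tip-damage flag), encounters (id, date, area label,
optional coordinates and distance from shore), and identifications linking
the two. Mark severity takes three grades — `PERMANENT` (deep cuts and
scars, stable over years), `TEMPORARY` (small cuts and rakes that may heal
within a year), `SUPERFICIAL` (shallow rakes and lesions only) — and
controls which individuals can be matched reliably across years, hence which
enter the network analysis. Conflicting metadata for the same individual or
encounter across CSV rows is a hard error, not a last-one-wins merge: a
photo-ID catalogue must be internally consistent, and silently repairing it
would mask matching mistakes upstream. Photo quality is carried as an opaque
integer (1 = best) with a pass-through filter; the package deliberately does
not operationalize quality grading.

## Association: the half-weight index

Association follows the gambit of the group: individuals identified in the
same encounter are taken to be associated. For a dyad $(a, b)$, with $X$ the
number of encounters containing both, and $Y_a$, $Y_b$ the numbers
containing only one of them,

$$\mathrm{HWI} = \frac{X}{X + \tfrac{1}{2}(Y_a + Y_b)} \in [0, 1],$$

the half-weight association index, preferred in cetacean work because
incomplete photographic coverage of a group biases it less than the simple
ratio. The sampling unit is the encounter: each encounter contributes at
most one count to any tally, and no temporal pooling of encounters is done.
The matrix is computed over a grade subset (default: permanently marked
individuals only), including every such individual regardless of sighting
frequency, since the target of inference is community structure, not dyadic
preference. A dyad with all three counts zero cannot arise when ids come
from the catalogue; the convention (HWI 0, flagged `undefined`) exists for
defensive completeness. HWI values are kept at full precision; rounding is
left to reports.

## Communities

The sociogram has an edge wherever HWI exceeds a threshold (default 0, so
any shared group membership connects two individuals). A community is a
connected component of this graph. No modularity-style algorithm is applied:
in the data this package models, the clusters of interest are fully
separated components (offshore groups share no members with the inshore
community or each other), and a clustering heuristic would add tuning
parameters without changing the answer. Components are labelled `A`, `B`,
... by decreasing size, ties broken by smallest member id, so the largest
community is reproducibly `A` and reruns are deterministic.

Temporarily and superficially marked individuals are then assigned by the
secondary rule: an individual joins a community if **all** of its
permanently marked associates (co-occurrence in any encounter, i.e. $X \ge
1$, not HWI magnitude — the literal reading of "all its associates") belong
to that community; otherwise it is `UNASSIGNED`, an explicit category that
summaries count rather than drop.

## Contingency statistics

Composition differences between communities (proportion permanently marked;
proportion with tip damage) use the Pearson chi-square with **no continuity
correction** — recomputing published comparison tables of this kind confirms
the uncorrected statistic is the convention (e.g. counts (72,120) vs (33,9)
give 23.48, printed 23.5; the Yates-corrected value would differ) — with
Yates available behind an off-by-default flag. Pairwise 2×2 tests across $k$
communities are Bonferroni-corrected with denominator equal to the number of
pairs actually tested ($\binom{5}{2} = 10$ for five); an explicit
`n_comparisons` override reproduces analyses that used another denominator
(a published table of this kind used 0.05/9; with ten testable pairs the 9
is unexplained, so it is an override, not the default). A pair with a zero
margin is reported untestable rather than dropped. Upper-tail p-values come
from `pchisq(lower.tail = FALSE)` — the regularized incomplete gamma — and
are verified against a numerical-integration oracle to 1e-10 in the tests.
One published cell of this kind prints "P = 0.201" beside a df-1 statistic
of 5.4, whose upper tail is 0.020; the package always reports the computed
p.

## Spatial comparison

Distance from shore is the encounter's recorded value when supplied;
otherwise it is computed from coordinates and a coastline polyline as the
minimum point-to-segment distance in a local equirectangular projection
centred on the point (exact at vertices, sub-0.5% error at the coastal
scales involved; sphere radius fixed at the IUGG mean, 6371.0088 km).
Supplied distances are never overwritten.

The inshore/offshore comparison uses the **encounter** as the sampling unit
(a published N of 60 for this test equals the encounter count, not the
individual count). Each encounter is attributed to a grouping side by
majority community membership of its identified individuals; exact ties are
excluded with a warning. The two-sided Mann-Whitney test is exact (full
permutation distribution by dynamic programming) for tie-free samples with
$n_1 n_2 \le 400$, otherwise a normal approximation with tie and continuity
corrections; both routes are property-tested against brute-force
enumeration and each other.

## The synthetic generator

No sighting-level data accompany the study this package models, so the
generator is the test bed: it emulates one cohesive inshore fission-fusion
community plus several transient offshore groups, with known ground truth.

Default study conditions (chosen once, from the published descriptive
statistics, and not revisited):

* Inshore: pool of 192 individuals, 56 encounters; group sizes lognormal
  with observed-scale mean 10.4 and SD 11.1, rounded and truncated to
  [1, 192]; mark-grade probabilities 72/192, 74/192, 46/192; tip-damage
  probability 0.07; distances folded-normal(0.61, 0.61) km clipped to
  [0.05, 3] (the published mean ± SD with a 50 m shore clearance);
  encounters split 47:9 between two coastal areas.
* Offshore: pool of 94, 4 transient encounters of sizes 8, 9, 30, 33 (fresh
  individuals each time, so nobody is ever resighted); grade probabilities
  80/94, 8/94, 6/94; tip-damage probability 0.48; distances uniform on
  [4.6, 40.5] km.

Two structural choices deserve explanation. First, the catalogue contains
only individuals actually identified in at least one encounter: the pool is
the latent population, and a photo-ID catalogue records identified animals
only — so the default offshore catalogue holds the 80 animals its four
groups contain, not the full pool of 94. Second, *cohesion is guaranteed by
construction, not by luck*: under purely uniform membership a once-sighted
permanently marked individual whose single group happens to contain no
other permanent member would form its own component, so exact recovery of
the generating partition would fail with small probability per replicate.
Because the generator's purpose is to emulate a cohesive community (the
kind whose members nearly all get resighted and form one cluster), the
fluid model enforces that every encounter contains at least one permanently
marked member and, after the first, at least one *previously sighted*
permanently marked member, swapping one uniformly chosen member when
needed; transient groups similarly promote one member to permanent if the
grade draw left none. This perturbs the uniform null only in rare draws and
makes the recovery invariant (connected-component detection returns exactly
the generating partition whenever cross-community mixing is zero) a theorem
about the generator rather than a high-probability event. Each transient
encounter-group is its own true social unit in the ground truth, since by
construction its members associate with nobody outside it.

Optional knobs: per-individual gregariousness weights (heterogeneous HWI
distributions), per-member capture probability below 1 (incomplete
photographic coverage; at least one member is always identified), and a
cross-community co-membership probability that, per encounter, adds one
visitor from another community — at 0 communities never mix; raising it
degrades partition recovery, which `sweep_recovery()` quantifies.

Randomness: one seed governs a run; each community consumes a
deterministically derived sub-stream, so editing one community's
specification leaves the other's draws unchanged, and equal seeds give
byte-identical CSV exports.

What the generator does *not* emulate: real fission-fusion preference
structure (membership is exchangeable within a community, so the HWI
distribution is flatter than in real data), mark-grade transitions over
time, spatially explicit movement, and survey-effort heterogeneity. Passing
recovery tests therefore demonstrates the pipeline's correctness on data
satisfying its assumptions, not robustness to preference structure or
observation error beyond the capture-probability model.

## Numerical and scale choices

Tests and the acceptance script run the generator at the full default sizes
(286-individual pool, 60 encounters) — small enough that a complete pipeline
run takes well under a second — with 20-replicate recovery sweeps and
100-fixture association-matrix oracle comparisons at 4-20 individuals.
Chi-square oracle agreement is required to 1e-10; HWI oracle agreement to
1e-12; the exact Mann-Whitney p must equal brute-force enumeration to
1e-12 for all tie-free sample splits with $n_1 + n_2 \le 10$.

## Known limitations

* Community = connected component is the right operationalization only when
  clusters are truly disjoint; densely connected populations would need a
  modularity or stochastic-block approach (the sociogram builder is the
  natural extension point).
* The secondary-assignment rule is order-free and deterministic but
  all-or-nothing; a single stray association with another community sends
  an individual to `UNASSIGNED`.
* The equirectangular coastline distance degrades for points hundreds of
  kilometres offshore or near the poles; it is intended for coastal survey
  scales.
* Percentages in summaries are rounded to integers to match field reporting
  conventions; the raw fractions are always carried alongside for testing.
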