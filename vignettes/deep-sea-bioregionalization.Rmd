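---
title: "Delimiting deep-sea biogeographical units from benthic occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting deep-sea biogeographical units from benthic occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepbioreg)
```

## The problem

Deep-sea biogeographical classifications for the South Atlantic disagree:
depth-province schemes, coastal ecoregion systems extended downslope, and
water-mass stratifications all partition the Brazilian continental margin
differently. `deepbioreg` turns the comparison of such schemes into a
reproducible computation: curated benthic occurrence records are assigned
to the units of each candidate scheme, between-unit faunal turnover is
measured, and the resulting cluster structure is tested for robustness
against both the order-sensitivity of tied dissimilarities and sampling
noise in the species pool.

The pipeline is: curation → unit assignment → presence/absence →
Simpson turnover → order-randomized UPGMA consensus → species bootstrap →
multiscale bootstrap → node classification.

## Occurrence curation

Records are retained when they fall inside the study-area predicate
(default: a 6°N–36°S, 55°W–25°W box standing in for the exclusive economic
zone; any polygon predicate can be substituted), inside the deep-water
window 200–5,000 m, and when their name is species-rank. Species rank is a
lexical test — at least two epithets, no trailing "sp."/"spp."/"cf." — because
an offline pipeline cannot consult a taxonomic registry; a local synonym
map (applied before all filters, chains rejected) covers the commonest
revisions, e.g. *Lophelia pertusa* → *Desmophyllum pertusum*. Every removal
is tallied by rule and the report always balances.

Two choices deserve emphasis. Depth given as a minimum/maximum pair
becomes the midpoint (a single bound is used as-is): deterministic and
symmetric, but records with very wide depth ranges inherit a fictitious
point depth. And the tropical/subtropical summary split defaults to 21°S,
the Vitória–Trindade Ridge, which is the natural divide of the margin.

## Classification schemes

All packaged schemes are latitude-band × depth-stratum grids with two
boundary conventions chosen once and used everywhere:

* depth strata are half-open `(lower, upper]`, with the scheme's global
  floor (200 m) included in the shallowest stratum — this reproduces
  printed bands of the "200–800 / 801–3,500" style with no gap at integer
  boundaries and puts a 3,501 m record in the abyssal stratum;
* latitude bands are half-open `(south, north]`, with the southernmost
  limit included.

Four constructors are provided: the seven-unit depth-province scheme
(upper/lower bathyal split at 5°S, three abyssal provinces), the ten-unit
hybrid scheme (five ecoregion bands at upper-bathyal depth over the same
lower-bathyal/abyssal provinces), the water-mass scheme (SACW, AAIW, NADW
in each of three regions, plus UCPW in the South only — ten bathyal units —
and Antarctic Bottom Water below 3,500 m), and the consolidated proposal
(four upper-bathyal ecoregions to 1,000 m, three lower-bathyal regions,
three abyssal provinces).

Where the source classifications are polygon-based (ecoregions, abyssal
province boundaries) the packaged defaults are latitude bands that
preserve the ordering and the 21°S boundary; they are stand-ins, and every
boundary is a constructor argument. Water-mass depth envelopes are
likewise configurable stand-ins (SACW to 600 m; AAIW to 1,200 m in the
tropical column, 1,000 m in the subtropical; UCPW 1,000–1,300 m in the
South; NADW below, to 3,500 m), consistent with the permanent pycnocline
at 1,000–1,300 m. Envelope sets must tile each region's bathyal column
exactly; UCPW outside the South region is a configuration error.
Constructors are pure, and assignment is a partial function — a point
matching two units is a configuration bug and raises, a point matching
none yields `NA` and is counted.

## Turnover, and why ties matter

Between two assemblages with `a` shared species and `b`, `c` exclusives,
the Simpson turnover is

> βsim = min(b, c) / (min(b, c) + a)

It is 0 whenever one assemblage is nested in the other and 1 for disjoint
assemblages, and — unlike Sørensen — does not grow merely because one unit
was sampled harder. That matters here because sampling effort across the
margin is grossly uneven. The flip side is degeneracy: incidence data
produce many exactly tied values (every nested pair sits at exactly 0),
and under ties the UPGMA agglomeration order decides the topology.
`tie_report()` quantifies the problem per matrix.

## Order-randomized consensus

`upgma()` makes the order-dependence explicit instead of hiding it: among
tied minimal pairs (values compared after rounding to 12 decimals, so
re-associated floating-point arithmetic cannot split a mathematical tie)
the pair earliest in the supplied label order merges first. The consensus
stage draws many random label orders (default 1,000), runs UPGMA under
each, and keeps the clusters appearing in a strict majority — the standard
majority rule, which also guarantees the retained clusters are mutually
compatible. A tie-free matrix yields its unique topology with every node
at 100; three equidistant units collapse to a star, since each resolved
pair appears in only a third of the orders.

Node identity throughout is the exact leaf-label set; there is no partial
cluster matching. Consensus node heights are the mean merge height over
the runs containing the node; in the Newick export, branch lengths derived
from those means are clamped at zero, because means over different run
subsets can invert slightly.

## Bootstrap and multiscale support

Units are the objects being classified, so rows are never resampled. Each
bootstrap replicate draws species columns with replacement (same count),
recomputes the turnover matrix, builds its own consensus from 100
order-randomized trees (that inner consensus is this package's reading of
"consensus trees each made up of reordered trees"; resampling a hundred
*sites* is not meaningful when the site count is ~10), and scores a node
as recovered when the replicate consensus contains its exact leaf set. A
unit that loses every species in a replicate drops out of that replicate,
so nodes containing it cannot be recovered there — with realistic
assemblage sizes this is rare, but it is why a group whose cohesion hangs
on a handful of shared species can sit fractionally below 100% support
without anything being wrong.

The multiscale extension repeats this at resample sizes k × S for scales
k = 1…10: larger resamples give rare species a better chance of entering
the replicate, so genuinely supported nodes gain support with scale.
Scale 1 shares the plain bootstrap's random substream, so a one-scale run
reproduces `bootstrap_support()` exactly. A node is labelled *supported*
when its least-squares support-vs-scale slope is strictly positive and
the top-scale support exceeds the scale-1 support; anything flat or
decreasing is *unsupported*. The threshold is strict — a constant 100%
profile is already saturated and carries no trend information, which is
the honest reading of "support increases with scale".

All randomness flows from one mandatory master seed through
counter-indexed substreams (one per stage and replicate), so results are
bit-identical for a given configuration regardless of execution order,
and pipeline outputs contain no wall-clock state — identical runs produce
byte-identical files.

## What the synthetic generator does and does not emulate

`generate_assemblages()` plants a known partition: each unit's species
set is the union of `u` unit-unique, `w` group-shared and `g`
cosmopolitan species, giving analytic expectations
βsim = u/(u+w+g) within groups and (u+w)/(u+w+g) across. Records then
emulate field sampling — uniform species picks, uniform coordinates/depth
inside each unit's geometry, per-unit record counts free to vary. This
captures exactly the statistical structure the analysis assumes
(incidence data with turnover and unequal effort) and nothing more: no
spatial autocorrelation, no abundance structure, no detection bias, no
taxonomic error. Passing recovery tests therefore demonstrate that the
machinery is correct, not that real margins decompose this cleanly.

Completeness (every planted species seen at least once) is reported, not
assumed; end-to-end equality with the analytic truth matrix is asserted
only when completeness holds, and effort invariance (doubling records
changes nothing) likewise.

## Problem sizes used in the packaged checks

The packaged test fixtures mirror the study's scale — 6–13 units, tens of
species — with resampling scaled to desk size: 200 consensus trees and 200
bootstrap replicates of 100 reordered trees for the planted-recovery
check (6 units, 40 species: 3 unique per unit, 11 shared per group), and
five scales at 400 replicates of 50 trees for the multiscale trend check
(deliberately weak signal: one shared species per group, so low scales
under-sample it and the trend has room to rise). These sizes give
stable-to-the-digit results under fixed seeds while the full defaults
(1,000/1,000/100/10) remain the package defaults.

## Known limitations

* Band geometry: packaged ecoregion and abyssal boundaries are latitude
  intervals, not the published polygons; longitude enters only through
  user-supplied polygon predicates.
* The depth-midpoint rule invents a point depth for ranged records.
* Species-rank detection is lexical; no registry validation is attempted.
* Bootstrap support of small shared pools saturates below 100% by
  construction (column dropout), and the node trend rule deliberately
  refuses to call a saturated flat profile "supported".
* The multiscale trend rule is an operationalization of "support
  increases with scale"; no calibrated p-value (AU-test style) is
  computed.
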