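---
title: "Pericentromeric panels and sSMC characterization: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pericentromeric panels and sSMC characterization: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericore)
```

## Scope and model

`pericore` computes the two in-silico halves of a FISH-first workflow for
small supernumerary marker chromosomes (sSMCs): designing junction-bridging
BAC probe panels per chromosome arm, and turning per-probe signal patterns
on a marker into a structured characterization (class, breakpoints, dosage,
content, mosaicism, risk). Wet-lab steps — probe labeling, hybridization,
image analysis — are out of scope: signal classes are inputs. Array-CGH
segmentation is likewise consumed, never recomputed.

## Coordinates and arithmetic

Intervals are half-open `[start, end)` tibbles, so width is the plain
difference of the bounds. Locus strings (`chrN:A-B`, any dash flavour,
optional thousands separators) parse verbatim and format back identically;
reported sizes are therefore differences of printed coordinates, which is
the convention that makes published duplication sizes and probe-window
widths come out exactly (e.g. 45,754,992 to 61,126,608 is 15.4 Mb).
Megabase/kilobase rounding is half-away-from-zero at the requested decimal
(`round_half_up()`), not banker's rounding: 13.364286 must print as 13.4.

Arm orientation matters because "distal" on a p arm means *smaller*
coordinates. All panel and breakpoint logic works in signed arm
coordinates: `arm_distance()` multiplies coordinate differences by a
per-arm `distal_sign` (-1 for p, +1 for q).

## Junctions and arm structure

The heterochromatin/euchromatin junction anchors everything. From a
BED-like het track, the p/q split of a chromosome is placed at the midpoint
of the largest gap between merged het blocks — assemblies leave a
centromeric gap between the two arm-root blocks — or at the midpoint of a
single contiguous complex. The p junction is the start of the het block
nearest the centromere on the p side; the q junction the corresponding
block end. An arm with no het block at its root has no junction: that is a
value (`no_junction`), not an error, and its panel is reported
`incomplete_no_junction`, mirroring reference assemblies in which several
arms lack an annotated boundary.

## Clone screening

A probe is usable only if its FISH signal is unambiguous. Screening applies
three reproducible rules per clone, in order: any alternate placement on a
different chromosome excludes it outright; same-chromosome alternates above
`max_alternate_placements` (default 0) or a segmental-duplication overlap
fraction above `max_segdup_fraction` (default 0.5) make it
cross-hybridizing; otherwise it is specific. The defaults are deliberate
policy choices, exposed as parameters: published screens report *that*
pericentromeric segdups blocked certain arms but not a numeric threshold.
Only `specific` clones enter panels by default. Labels depend on each
clone's own record, so library order never changes a call (tested by
permutation).

## Panel selection

Given a junction and a screened library, `select_core_panel()` anchors on
the eligible clone whose proximal edge lies nearest the junction (distance
floored at zero for straddling clones — the common case in practice, which
is why junction distances of 0 dominate coverage tables) and then greedily
extends: among clones whose proximal edge falls within `max_gap_bp`
(default 50 kb) of the current frontier, take the one reaching farthest
distally; stop at `target_span_bp` (default 700 kb, the proximal ~0.7 Mb of
euchromatin) or `max_clones` (default 7). Farthest-reach greedy selection
is the optimal strategy for interval cover; the test suite asserts, rather
than assumes, equality with an exhaustive minimum-cover search on random
libraries (both searches share the anchor clone, without which the
optimality claim would not be well-posed). Panel statistics use outer clone
edges: the junction-to-proximal-clone distance and the
proximal-edge-to-distal-edge span, both half-up at 2 decimals. The
published per-arm coverage table ships as a data file and summarizes to 43
panels, 35 complete, mean core span 0.73 Mb over the 42 arms with both core
clones; the mean is taken over all arms with a span rather than only
completed ones, because that is the convention under which the printed
average reproduces.

A designed panel can also end `incomplete_coverage` when eligible clones
exist but stall before the target span — a state the published status
vocabulary does not separate from its segdup/no-junction causes; it is kept
distinct here with the stall distance in `status_note`.

## Breakpoint inference

Calls on one arm are ordered proximal to distal by clone edge distance
(ties by name, for determinism). The inference is deliberately
conservative:

* present probe P followed distally by absent probe A brackets the
  breakpoint; the reported interval is the convex hull of both clones'
  outer edges, which cannot under-cover sub-probe partial overlaps;
* a `diminished` probe places the breakpoint inside that clone
  (`within_diminished_probe`);
* no absent probe distally leaves the interval open (`open_distal`), and
  content is reported as "> X Mb";
* absent probes proximal to present ones split the arm into blocks, one
  interval per block, flagged `internal_deletion`.

Dosage maps `double`/`single`/`diminished`/`absent` to 2/1/partial/0 marker
copies and collapses equal consecutive calls into segments; total dosage
adds the constitutive two copies (trisomy, tetrasomy). Copies must be
non-increasing along the arm — an isodicentric with asymmetric breakpoints
legitimately steps 2 to 1 to 0 — unless an internal deletion was flagged;
an unflagged increase is a data inconsistency and errors. The "equal
signal = one copy, enlarged signal = two copies" reading is the mapping
under which an asymmetric isodicentric yields the expected
tetrasomy-then-trisomy segment pair.

Euchromatic content per arm is bounded by the junction-to-breakpoint arm
distances of the interval's two ends (clamped at zero; infinite when
open-ended) and summed over arms. A marker is heterochromatic-only exactly
when every euchromatic probe is absent, which is equivalent to a maximal
content of zero — an equivalence the simulation suite checks on every
generated case.

## Mosaicism

The mosaic fraction is the binomial proportion of marker-positive
metaphases with the exact Clopper–Pearson interval computed from the
beta-quantile closed form (`alpha = 0.05` two-sided by default); tests
require agreement with the independently implemented interval of
`binom.test()` to 1e-9. `required_metaphases()` gives the smallest n with
detection probability c at mosaic level m, `ceil(log(1-c)/log(1-m))`,
floored at the diagnostic minimum of 16 (disable with `floor = 0`). The
floor reflects practice — at least 16 metaphases scored per case — while
the closed form is exposed because labs scale the count with the suspected
mosaic level; the package does not claim to reproduce any particular lab's
policy.

## Array-CGH integration

Segments arrive as a TSV with mean log2 ratios; gain/loss calls use a
configurable threshold (|log2| >= 0.3 by default — segmentation software
reports ratios, not calls). Breakpoint refinement intersects the FISH hull
with an explicit boundary-uncertainty interval (the printed
last-normal-probe to first-aberrant-probe pair); re-deriving those pairs
from raw probe data is out of scope because raw probe tables are not part
of the input contract. Refinement is a strict intersection: the result is
contained in both inputs, refining an interval with itself is a no-op, and
disjoint intervals either raise an error (`refine_breakpoint()`) or flag
the case `acgh_conflict` while keeping the FISH interval
(`refine_characterization()`, used by the pipeline — an assay conflict is
data, not a crash). Arms whose panel probes are all proximal to the gain
can take an aCGH-only breakpoint from the segment's distal boundary pair.

## Phenotype risk

Critical/noncritical region boundaries are curated knowledge that the
package consumes as a TSV and never ships; the bundled map is synthetic and
named accordingly. The label logic: heterochromatic-only markers are
likely benign; any dosage segment touching a critical region (from
`critical_start` toward the telomere) is likely pathogenic; unknown
boundaries on an involved arm, or segments confined to the annotated gap
between noncritical and critical regions, yield uncertain — gaps are
deliberately *not* benign, because gap-region dosage has accompanied mild
phenotypes. A mosaic fraction below 0.30 (configurable) appends an advisory
attenuation note without ever changing the label; how mosaicism modulates
risk is not formalized anywhere we would trust, so it stays advisory.

## The simulator

`sim_genome()` emulates the landscape the panels assume: per chromosome a
centromere, a het block at each arm root separated by a 150 kb assembly
gap, euchromatin beyond, and a BAC-like library (150–200 kb inserts,
5–30 kb overlaps) tiling the proximal 1.2 Mb of every designable arm, with
the first clone straddling the junction. Decoy clones carrying
cross-hybridization signatures are placed distal to the tiled span so the
clean tiling path is unaffected. Acrocentric p arms get no clones;
optionally trailing chromosomes get no het annotation at all, exercising
the no-junction path. Defaults (6 chromosomes of 60–120 Mb, 2–4 Mb het
blocks, one acrocentric) keep a genome small enough that a full
simulate-and-characterize round trip runs in tens of milliseconds.

`simulate_case()` plants a marker with per-arm breakpoints 50 kb–1 Mb
beyond the junction (isodicentrics get a second, nested breakpoint at
30–90% of the first, giving the 2/1/0 copy ladder) and derives calls from
an explicit observation model: overlap with marker content below 10 kb is
undetectable (`absent`); overlap fraction above 0.8 reads as a full signal
(`double` if the probe also sits 80% inside the two-copy zone, else
`single`); anything between is `diminished`. Heterochromatic-only markers
place the breakpoint inside the het block, so every euchromatic probe is
absent. Array segments reflect the content with boundary pairs jittered at
the 43 kb oligo spacing; metaphase counts are binomial at the planted
mosaic level. Optional per-probe false-negative/false-positive flips model
call noise.

What passing simulations do and do not show: at noise 0 the pipeline
recovers 100% of planted breakpoints (inside the inferred hulls) and dosage
ladders over 500 cases, and stays above 90% containment at a 5% call-flip
rate — but the generator draws clean, arm-structured genomes with honest
probe placements. It does not model mislocalized clones beyond the
screening decoys, cross-hybridization *signals* on the marker itself,
segmental-duplication-mediated complex rearrangements, or raw image
artefacts; real-world performance on such cases is not demonstrated by
these tests.

## Numerical and degenerate-input choices

* Zero-width intervals are legal points; intersection of disjoint intervals
  returns an empty tibble, and cross-chromosome intersection errors.
* Ties in probe ordering (identical junction distance) break by name.
* `required_metaphases()` subtracts 1e-12 before `ceiling()` so exact
  integer quotients do not round up spuriously.
* Empty call tables classify as `undetermined`; risk classification
  refuses undetermined input.
* JSON reports are canonical: write, read, re-write is byte-identical;
  unbounded content serializes as a null upper bound plus an `open` flag.

## Problem sizes in the checks

The default test run uses 6-chromosome toy genomes, 40–120 simulated cases
per property, 200 random libraries for the greedy-vs-exhaustive
comparison, and a 35-point (k, n) grid for the exact interval; the
acceptance script scales the end-to-end recovery to 500 cases. These sizes
were chosen as the smallest at which each property is meaningfully
exercised across structures (ring, minute, isodicentric) and both arms.

## Known limitations

* Clone placements are taken as given; whether published clone intervals
  are outer coordinates or trimmed unique-sequence extents is not
  modelled.
* The hull convention makes intervals conservative; sub-probe breakpoint
  positions inside a present clone are invisible to FISH and only
  recoverable via array boundaries.
* Content bounds for internally deleted markers use the outermost
  breakpoint, so they over-state the maximum for those (flagged) cases.
* The simulator's mean-log2 model for mosaic gains is idealized
  (`log2((2 + c·m)/2)`) and exists to drive boundary logic, not to
  benchmark segmentation.
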