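---
title: "Simulating trap saturation: the model behind trapsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating trap saturation: the model behind trapsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapsim)
```

## The question the simulator answers

Maintenance control of invasive vertebrates — brushtail possums, stoats and
ship rats in New Zealand forests — leaves traps in the field for weeks
between checks. A single-capture trap is out of service from its first
capture until someone resets it; a self-resetting multiple-capture trap
keeps working until a design capacity is exhausted, but costs several times
as much. The operational question is how many captures a trap *site* can
realistically accumulate at a given pest density over an unchecked period,
because that determines whether one expensive multiple-capture trap or a
handful of cheap single-capture traps is the better buy.

trapsim answers this with an individual-based, spatially explicit removal
simulation: it predicts the distribution of capture counts per trap site
and the proportion of the population removed, and prices the competing
deployment strategies.

## The model

### Detection

Each animal occupies a circular home range whose centre is fixed for the
whole trapping period. The probability that animal $i$ is taken by trap
$j$ on a single night follows the half-normal detection function

$$P_{ij} = g_0 \, e^{-d_{ij}^2 / 2\sigma^2},$$

where $d_{ij}$ is the distance from the animal's home-range centre to the
trap, $g_0$ is the nightly capture probability for a trap at the centre,
and $\sigma$ scales the home range ($2.45\sigma$ is the radius containing
about 95% of the animal's activity). The shipped presets use field
estimates: possum $g_0 = 0.05$, $\sigma = 63$ m; stoat $g_0 = 0.045$,
$\sigma = 641$ m; ship rat $g_0 = 0.03$, $\sigma = 32$ m.

### Landscape, traps and animals

Traps sit on a rectangular grid (possum 50 m along lines 100 m apart,
2106 sites; stoat 200 × 800 m, 84 sites; rat 25 × 100 m, 4200 sites),
surrounded by an untrapped buffer (100 m for possums and rats, 300 m for
stoats) so edge animals hold complete home ranges. Animal numbers are
`round(density × buffered_area)` using the preset's *nominal* buffered
area (1140, 1472 and 1148 ha respectively), which converts the planning
densities to exact whole-animal counts (e.g. 0.5 possums/ha → 570 animals;
11 rats/ha → 12,628). The nominal areas differ from the geometric span of
the grid-plus-buffer rectangle by a few percent — a deliberate choice in
favour of the planning arithmetic, since the grid's exact factorisation
into lines is not part of the published layout. Home-range centres are
uniform over the buffered rectangle.

### The nightly removal process

The simulation runs (by default) 30 nights. Traps are never re-set within
the period: each site has a capacity (1 for single-capture traps; 2, 3, 6,
12 for multiple-capture traps), and a trap is retired the moment its
capacity is reached. Captured animals are removed from the population.

The published description leaves the within-night rule open — what happens
when several traps "want" the same animal, or several animals the same
nearly-full trap, on the same night. trapsim's default is a
**competing-hazards** resolution, the standard formulation for multi-catch
traps in spatial capture–recapture: each pair probability becomes a hazard
$h = -\log(1 - P)$; an at-large animal is captured that night with
probability $1 - \exp(-\sum h)$ over the currently active traps, and,
conditional on capture, the trap is drawn proportional to its hazard.
Animals are processed in uniformly random order each night, so a trap that
saturates mid-night is unavailable to animals processed later. For one
animal and one trap this degenerates exactly to a Bernoulli trial with
probability $P$, which is what the engine's analytic tests exploit. An
alternative rule — independent Bernoulli trials per pair, the capturing
trap drawn uniformly among that night's successes — is available via
`competition = "bernoulli"` for sensitivity analysis; at the scales of the
shipped scenarios the two rules differ by well under the Monte-Carlo
spread.

### Immigration (rats)

Rats reinvade on the timescale of a trapping round, so the rat preset
carries an immigration block: over the period a number of immigrants equal
to the initial population arrives (density/30 per night), spread across
nights deterministically with the fractional remainder carried forward, so
nightly counts differ by at most one and sum exactly. Arrivals are placed
with a perimeter-to-centre gradient: the buffered rectangle is partitioned
into three nested frames of equal step width (one third of the half-width
of the narrower dimension), receiving 60%, 30% and 10% of immigrants from
the outside in, uniformly within each frame. Immigrants join the at-large
pool at the start of their night, before captures are resolved, and the
removal proportion is reported against residents *plus* all immigrants
introduced — that denominator is what makes the with-immigration kill
fractions directly comparable to the closed-population ones. Whether
immigrants should be restricted to the trapped block rather than the whole
buffered rectangle is not determined by the published description; trapsim
places them over the full buffered rectangle, consistent with resident
placement.

## Numerical choices

* **Truncation.** Animal–trap pairs beyond $5\sigma$ are dropped from the
  encounter table; their nightly probability is below
  $4 \times 10^{-6} g_0$. A matched-stream comparison against a $10\sigma$
  table (same replicate seeds; ample capacity so the streams stay aligned)
  changes the mean kill proportion by well under 0.1 percentage point
  while shrinking the table several-fold. The minimum allowed truncation
  is $2.45\sigma$, the 95% home-range radius.
* **Hazard capping.** $P$ is capped at $1 - 10^{-12}$ before the
  $-\log(1-P)$ transform so a literal $g_0 = 1$ at distance zero cannot
  produce an infinite hazard.
* **Seeding.** Replicate $r$ of a scenario runs on an integer stream
  derived from (base seed, $r$) by a Lehmer-style mix kept below $2^{31}$;
  sweep cells hash (base seed, density index, capacity index). Any
  replicate or cell is reproducible in isolation, and adding cells to a
  sweep never perturbs existing ones.
* **Degenerate inputs.** Zero density yields an empty population and an
  all-zero summary; a population with nobody exposed makes the capture
  proportion an error (in the summary functions) or `NA` (in the file
  runner). Ties in trap assignment are impossible almost surely; the
  hazard-selection scan guards the floating-point tail by falling back to
  the last active pair.
* **Pair ordering.** Within an animal's row the pairs are sorted by trap
  index, so conditional trap assignment does not depend on the spatial
  binning used to find the pairs (binning follows the truncation radius).

## What the generator emulates — and what it does not

The synthetic landscape reproduces the *design* of an orchestrated control
operation: regular grids, uniform residents, fixed home ranges, a single
$g_0$ and $\sigma$ per species, and (for rats) a smooth perimeter-weighted
immigration stream. Real operations violate most of these in detail:
animals differ individually in trappability, home ranges drift, terrain
and habitat make both density and trap performance patchy, traps misfire,
and lures decay. Passing the shipped checks therefore shows that the
removal arithmetic, saturation bookkeeping and immigration accounting are
right — not that a field operation will hit the same percentages. The
published comparisons these simulations are checked against share all of
the same idealisations.

## Problem sizes and runtime

The shipped scenarios are modest: the largest (11 rats/ha with
immigration) tracks 25,256 animals against 4200 traps for 30 nights, about
0.2 s per replicate with the compiled engine. The package defaults to 100
replicates per scenario, which puts the Monte-Carlo standard error of the
reported means well under one percentage point on every headline
statistic; the test suite uses smaller grids (typically 60 traps) and
20–150 replicates per check.

## Known limitations and honest discrepancies

* The cost model is deliberately a *parameterised formula* — hardware
  `price × traps × sites / area` plus labour
  `(setup + n_checks × check) minutes` at a daily rate, with an explicit
  exchange-rate knob — because the published cost curves cannot be
  reproduced from the printed prices and times under any obvious
  arithmetic (the number of checks, travel time and currency conversion
  are unstated). The qualitative result survives: with the default labour
  settings, five Sentinel single-capture traps per site cost about the
  same per hectare as one Goodnature A12.
* The published stoat percentages are mutually inconsistent with their own
  animal and trap counts: 84 capacity-1 traps cannot remove 60% of 177
  stoats (the ceiling is 84/177 ≈ 47.5%), a ">99%" removal at capacity 2
  exceeds the 168-slot ceiling, and "~100% removed" at 0.02 stoats/ha (29
  animals) implies 34.5% of the 84 traps catching, not the printed 29%.
  trapsim reports the saturation-limited values (≈34.5%, ≈93%, ≈47.5%) and
  its acceptance checks keep the printed references, so those three
  comparisons fail by design rather than being tuned away.
* No trap-specific $g_0$ (the same detection parameters serve single- and
  multiple-capture traps), no behavioural response, trap-shyness, lure
  decay or misfires, no non-rectangular landscapes, and no immigration for
  possums or stoats.

## Reproducing the headline numbers

`scripts/acceptance.R` in the source repository reruns every preset
scenario from scratch at 100 replicates and writes the resulting
percentages to JSON; see the README for the exact invocation and a worked
example with the numbers it prints.
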