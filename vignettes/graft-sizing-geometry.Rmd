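---
title: "Geometry of donor graft sizing in deep anterior lamellar keratoplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of donor graft sizing in deep anterior lamellar keratoplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalksizer)
```

## The clinical problem

Deep anterior lamellar keratoplasty (DALK) replaces the corneal stroma
while preserving the recipient's Descemet's membrane (DM) and endothelium.
In advanced keratoconus the recipient cornea is very steep: keratometry
above 60 D corresponds to a radius of curvature below 5.6 mm. When a
trephine of diameter $a$ cuts into such a cornea, the tissue removed is a
curved cap, and the DM left on the bed spans a circular **arc** whose
length exceeds $a$. The donor button, punched from a cornea flattened
under suction, has a diameter essentially equal to the punch. A graft
sized to the trephine is therefore shorter than the membrane it is sutured
over; the excess membrane buckles into DM folds, which degrade vision when
they cross the visual axis. The remedy is geometric: size the donor button
to the **arc length** of the retained membrane, not to the trephine.

## The model and its assumptions

The recipient cornea is modelled as a sphere of a single radius of
curvature $r$. Keratometers report power $K$ in diopters; the two are
related through the keratometric refractive index $n = 1.3375$:

$$ r\,[\mathrm{mm}] = \frac{(n - 1) \times 1000}{K} = \frac{337.5}{K}. $$

The trephine diameter $a$ is a chord of this sphere. Connecting the
chord's endpoints to the centre of curvature forms an isosceles triangle
with two sides equal to $r$; the cosine rule gives the apex (central)
angle

$$ \cos\alpha = \frac{r^2 + r^2 - a^2}{2r^2} = 1 - \frac{a^2}{2r^2}, $$

and the membrane arc length is $x = r\alpha$ (with $\alpha$ in radians;
the degree form $2\pi r\,\alpha/360$ is the same quantity, not a separate
code path). Because the donor flattens during punching, the donor
diameter equals the punch size, so the recommended punch is simply $x$.

Assumptions worth keeping in mind:

* **Single spherical curvature.** Real keratoconic corneas are aspheric
  and astigmatic; the model takes whatever single $K$ it is given. The
  package deliberately does not choose among K1 (flat meridian), K2
  (steep) or their mean Km — clinical summaries report all three and no
  canonical choice exists for this calculation. The CLI's `--k-choice`
  flag records which one the user supplied, as metadata only.
* **Flat donor.** The donor diameter is taken exactly equal to the punch
  size; residual donor curvature under suction is ignored.
* **No pachymetry.** Corneal thickness and trephination depth do not
  enter the arc computation.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `kindex` | D·mm | 337.5 | diopter-to-radius constant $(n-1)\times 1000$; configurable for non-standard keratometer indices |
| `step` | mm | 0.25 | punch/trephine availability granularity |
| `snap_policy` | — | `nearest-up-on-tie` | how a computed size maps onto the step grid |
| `threshold` | mm | 0 | mismatch above which fold risk is flagged |

The default `kindex` was fixed by regenerating all 234 cells of the
packaged reference grid under candidate constants (337.5, 336.0, 334.375,
334.0, 333.0): only 337.5 reproduces every cell within 0.01 mm (in fact
within 0.005 mm unrounded and exactly at two decimals), so the standard
keratometric index is the one the reference table was computed with.

```{r constant-fit}
validate_size_table(generate_size_table(kindex = 337.5),
                    reference_size_table(), tolerance = 0.005)$n_mismatched
validate_size_table(generate_size_table(kindex = 336.0),
                    reference_size_table(), tolerance = 0.005)$n_mismatched
```

## Snapping and rounding

Punches come in 0.25-mm steps, so the computed arc is snapped to the
nearest available size. Three policies are provided. The default,
`nearest-up-on-tie`, rounds an exact midpoint (e.g. 6.125 mm with 0.25-mm
steps) to the **larger** punch: the clinically dangerous direction is
undersizing, which causes the folds the model exists to prevent, whereas
a slightly oversteep graft is well tolerated. `always-up` never
recommends a punch below the computed arc; `nearest-down-on-tie` is the
symmetric alternative. Ties are detected with a $10^{-9}$ relative
tolerance so snapping is idempotent.

Table values are rounded **half away from zero** to two decimals
(`round_half_up()`), not banker's rounding. On the default grid the two
conventions happen to agree in every cell, so the choice is not
observable there; it is stated and tested so the convention is fixed for
finer grids.

## Numerical choices and degenerate inputs

* The arccosine argument is clamped to $[-1, 1]$ so a chord exactly equal
  to the diameter ($a = 2r$, a semicircle) is valid and returns
  $\alpha = \pi$ despite floating-point rounding.
* A chord exceeding $2r$ is a geometry error (the trephine cannot span
  the sphere); non-positive or non-finite scalars are domain errors.
  These are the only hard failures.
* Inputs outside the tabulated envelope (45–70 D, 6.00–8.00 mm) compute
  normally but raise a warning: the geometry is exact there, but the
  recommendation grid — and the clinical experience behind it — covers
  only the envelope. `warn = FALSE` suppresses this for programmatic use.
* In the flat-cornea limit ($K \to 0$, $r \to \infty$) the arc collapses
  onto the chord. Near that limit $\cos\alpha$ approaches 1 and the
  arccosine loses relative precision; at $K = 0.001$ D the computed arc
  still agrees with the chord to better than $10^{-6}$ mm, which bounds
  the numerical error of the cosine-rule path across any clinically
  conceivable input.
* The inverse problem, the trephine whose arc equals a target punch, has
  the closed form $a = 2r\sin\!\big(x/(2r)\big)$, valid up to the
  semicircular arc $x = \pi r$; beyond it no chord reproduces the arc and
  the function errors. Forward and inverse compose to the identity to
  $10^{-9}$ mm across the grid.

## The recommendation grid and its validation

`generate_size_table()` evaluates the pipeline over curvatures 45–70 D in
1-D steps and trephines 6.00–8.00 mm in 0.25-mm steps — 234 cells, the
clinically validated envelope. The package ships a verbatim transcription
of the published grid (`reference_size_table()`); two cells printed at one
decimal in the source ("7.6", "7.8") are read as trailing-zero-trimmed
two-decimal values. `validate_size_table()` compares grids at two tiers:
0.005 mm (strict agreement at two printed decimals) and 0.01 mm (relaxed;
tolerates cells sitting on a rounding boundary where half-up and
half-even conventions could differ by one unit of the last decimal). The
regenerated grid matches the transcription at the strict tier in all 234
cells.

```{r grid}
tab <- generate_size_table()
tab$cells["60", "7.50"]
validate_size_table(tab, reference_size_table())
```

Both monotonicities visible in the grid are structural: the arc
$x(K, a) = \tfrac{337.5}{K}\,\arccos\!\big(1 - \tfrac{a^2K^2}{2\cdot 337.5^2}\big)$
is strictly increasing in $K$ at fixed $a$ (steeper cornea, longer arc)
and in $a$ at fixed $K$ (wider trephine, longer arc); rounding can only
flatten a strict increase into a tie, so the printed grid is
non-decreasing along every row and column.

## Verification strategy

The test suite checks the angle computation against an independent closed
form — the half-angle relation $\alpha = 2\arcsin\!\big(a/(2r)\big)$ —
over $10^4$ random valid (radius, chord) pairs at $10^{-10}$ rad; the two
derivations share no code. Grid-level tests compare the full regenerated
table against the packaged transcription, and property-style tests cover
arc-dominates-chord, the flat limit, monotonicity, snapping idempotence
and the forward/inverse round-trip. All checks are exact recomputations;
nothing in the package is stochastic, and the problem sizes above (234
cells, $10^4$ sampled pairs) run in well under a second.

What passing these tests shows — and does not show: they establish that
the implementation agrees with the stated geometry and with the published
grid. They say nothing about how well a single-sphere model fits a real
keratoconic cornea, which K value best represents an astigmatic eye, or
the clinical tolerance of the membrane to small positive mismatch; the
fold-risk flag is a strict geometric criterion (any positive mismatch),
with a configurable threshold for users who accept a tolerance band.

## Limitations

* No aspheric or conic corneal model; a single curvature stands in for
  the whole bed.
* No modelling of suture tension, wound apposition, or postoperative
  refraction (equal-size grafts are sometimes chosen deliberately to
  flatten the cornea; that trade-off is outside the model).
* The reference grid covers 45–70 D only; outside it the package
  extrapolates geometrically and warns.
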