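# dalksizer

Donor graft punch sizing for deep anterior lamellar keratoplasty (DALK).

## The problem

In DALK the surgeon removes the recipient's corneal stroma but leaves the
Descemet's membrane (DM) and endothelium on the bed. In steep corneas —
advanced keratoconus, with keratometry well above 60 D — the trephine cuts
a strongly curved cap out of the recipient cornea, so the DM left behind
spans an **arc** longer than the trephine's diameter. The donor button, by
contrast, is punched from a cornea flattened under suction: its diameter
equals the punch size. Suturing a graft the same size as the trephine over
a longer membrane arc leaves excess membrane that wrinkles into DM folds,
degrading vision when the folds cross the visual axis.

## The model

Treat the recipient cornea as a sphere. Keratometric power *K* (diopters)
converts to radius of curvature *r* (mm) through the standard keratometric
index 1.3375:

&nbsp;&nbsp;&nbsp;&nbsp;*r* = 337.5 / *K*

The trephine diameter *a* is a chord of this sphere. Joining its endpoints
to the centre of curvature forms an isosceles triangle with equal sides
*r*, so the cosine rule gives the central (apex) angle:

&nbsp;&nbsp;&nbsp;&nbsp;cos α = (r² + r² − a²) / (2r²) = 1 − a²/(2r²)

and the DM arc length — the diameter the donor button must match — is

&nbsp;&nbsp;&nbsp;&nbsp;*x* = *r* · α  (α in radians; equivalently 2π*r* · α/360 in degrees).

`dalksizer` computes *x*, rounds it to the 2-decimal table convention,
snaps it to the 0.25-mm punch steps actually available (ties resolved
upward, because the failure mode comes from undersizing), flags fold risk
when a chosen punch is smaller than the membrane arc, solves the inverse
problem (which trephine yields a target arc), and generates/validates the
full 26 × 9 recommendation grid (curvatures 45–70 D, trephines
6.00–8.00 mm).

## Worked example

```r
library(dalksizer)

recommend_punch(60, 7.50)
#> Donor punch recommendation (K = 60 D, trephine 7.50 mm)
#>   DM arc length : 8.2094 mm (table value 8.21 mm)
#>   snapped punch : 8.25 mm (step 0.25 mm, policy nearest-up-on-tie)
```

At 60 D the cornea's radius is 337.5/60 = 5.625 mm; a 7.50-mm trephine
subtends an apex angle of 1.4595 rad, so the membrane arc is 8.2094 mm —
0.71 mm longer than the trephine. The nearest available punch is 8.25 mm.
Using a same-size punch instead would leave the membrane 0.87 mm too long:

```r
assess_mismatch(62, 7.75, punch = 7.75)
#> Mismatch report (K = 62 D, trephine 7.75 mm, punch 7.75 mm)
#>   DM arc 8.6240 mm, mismatch +0.8740 mm -> fold risk: YES
```

The full grid and its check against the packaged reference transcription:

```r
tab <- generate_size_table()          # 26 x 9, punch sizes in mm
validate_size_table(tab, reference_size_table())
#> Table validation: 234/234 cells within 0.005 mm
#>   max |deviation| = 0.0000 mm at (K = 45 D, trephine = 6.00 mm)
```

A command-line front end is installed with the package
(`system.file("exec", "dalksizer", package = "dalksizer")`) with
subcommands `calc`, `mismatch`, `inverse`, `table` and `validate`; see
`?dalk_cli`.

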