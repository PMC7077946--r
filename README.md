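# smilecurves

Objective aesthetic analysis of the anterior smile for dentists,
orthodontists and dental researchers. The package turns a set of widely
used aesthetic references — maxillary central-incisor dominance, the
regressive diagonal-of-a-square width proportion, the six horizontal smile
lines (upper lip, cervical, papillary, contact-point, incisal, lower lip)
and the 50-40-30 rule of connector spaces — into three tools:

1. **A parametric template generator.** From a single central-incisor width
   $W_1$ (default 8.0 mm) it constructs the ideal six-tooth geometry:
   crown height $H_1 = W_1 / 0.80$, widths decreasing by
   $r = 1/\sqrt{2}$ per tooth ($W_2 = rW_1$, $W_3 = r^2 W_1$; the
   1:1.414 regressive proportion, ≈71% per step), central and canine
   zeniths level with the lateral zenith 0.6 mm below, a 0.8 mm incisal
   step giving the "soup plate" incisal outline, and connector-zone heights
   of 50/40/30% of $H_1$ from the midline outward.
2. **A metric suite** that computes, from named 2D landmarks annotated on a
   frontal smile or intraoral photograph, the apparent widths and
   regressive ratios, cervical-line class (convex/flat/concave), incisal
   outline (soup plate / flat plate / inverted), connector percentages,
   smile-arc class (consonant/flat/reverse, by quadratic fits of incisal
   edge and lower lip), lip line (high/medium/low with gingival display), a
   bilateral symmetry score, and the deviation of each quantity from its
   template ideal. Metrics are invariant to photograph rotation,
   translation and scale.
3. **An overlay renderer** that registers the template onto a photograph
   with a two-point similarity transform (the central-incisor widths
   coincide; default anchors are the distal incisal corners of teeth 11
   and 21) and writes a semi-transparent SVG or PNG overlay.

A synthetic-fixture generator (`make_smile()`) produces ideal and
deliberately deformed landmark sets (gummy smile, deep bite, reverse arc,
asymmetry, flat plate) so the entire pipeline is testable with no clinical
photographs.

## Worked example

```r
library(smilecurves)

p <- sct_params(central_width = 8)   # the ideal parameter set
geom <- build_template(p)
geom
#> Anterior-tooth template (sct_template)
#>   central incisor: 8.00 x 10.00 mm (W/H 80%)
#>   total width    : 35.314 mm across six teeth
#>   connectors     : 50-40-30% of central height

# a synthetic gummy smile, annotated with 0.1 mm landmark noise
ls <- make_smile("gummy", noise_sd = 0.1, seed = 7)
rep <- full_report(ls)
rep
#> Smile report
#>   cervical line : convex
#>   incisal line  : soup_plate
#>   smile arc     : consonant
#>   lip line      : high
#>   connectors    : 49.4 / 39.4 / 29.7 % of central height
#>   dominance     : ok
#>   symmetry      : 0.2078 mm mean mirrored discrepancy
#>   max |deviation from ideal| : 0.128
```

Reading the report: the tooth geometry is still the ideal template (convex
cervical line, soup-plate incisal outline, connectors within noise of
50-40-30, widths dominant and regressive), but the raised upper lip makes
the lip line **high** — `rep$gingival_display_mm` reports the 3 mm of
gingiva on display, the quantity a clinician would target with intrusion or
crown lengthening. The symmetry score and the 0.128 maximum deviation are
what 0.1 mm annotation noise alone contributes.

To register the template on a photograph and write the overlay:

```r
ls  <- read_landmarks("patient_smile.json")      # pixel-frame annotations
tr  <- fit_transform(default_anchors(geom),
                     rbind(lm_point(ls, "11_distal_incisal"),
                           lm_point(ls, "21_distal_incisal")))
render_overlay(geom, tr, image = "patient_smile.png",
               out = "overlay.png", style = overlay_style(opacity = 0.5))
```

## Command line

```sh
Rscript inst/cli/smilecurves.R template --central-width 8.0 --out template.svg --json template.json
Rscript inst/cli/smilecurves.R simulate --preset gummy --noise-sd 0.1 --seed 7 --out lm.json
Rscript inst/cli/smilecurves.R analyze  --landmarks lm.json --out report.json
Rscript inst/cli/smilecurves.R overlay  --image smile.png --landmarks lm.json --opacity 0.5 --out overlay.png
```

Exit status 0 on success, 2 on validation errors (the message names the
offending field). A YAML `--config` file supplies defaults; flags override.

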