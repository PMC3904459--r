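# rangemod

A one-dimensional water-phantom simulator of proton spread-out Bragg peaks
(SOBPs), built to study **range modulation**: splitting a beam's planned
dose across two or three identical copies whose ranges differ by a few
millimetres, so that the distal falloff is smeared and the elevated
relative biological effectiveness (RBE) at the end of range is diluted.

It is intended for medical physicists and planners who want a transparent,
scriptable sandbox for the dose/RBE trade at the distal edge — not a
clinical dose engine.

## The model

* **Pristine peaks.** Bragg–Kleeman stopping-power kernel
  `d0(z; R) = (R − z)^(1/p − 1)` (p = 1.77) integrated against a Gaussian
  distribution of residual range, `σ(R) = sqrt((0.012 R^0.935)² + σ_E²)`
  (range straggling plus delivery-system energy spread, σ_E = 2.4 mm by
  default). Curves are max-normalized; absolute dose lives in the weights.
* **SOBP.** `sobp()` stacks equally spaced pristine peaks (default: 4
  peaks, deepest range 150 mm, 6 mm pull-back per peak) and fits
  non-negative weights by NNLS so the plateau sits at the prescription
  (100 AU, so doses read as percentages).
* **Distal-edge RBE.** Per pristine peak k,
  `RBE_k(z) = 1.1 · [1 + 0.35 · (1 + tanh((z − z_k)/2 mm))/2]`,
  centered on the straggled peak's dose maximum z_k: uniform 1.1
  proximally, saturating 35% above baseline distally. RBE-weighted dose is
  `Σ_k w_k D_k(z) RBE_k(z)`.
* **Range modulation.** `two_way_scheme()` delivers half the dose as
  planned and half with the range pulled back 3 mm;
  `three_way_scheme()` splits into thirds at 0 / −2 / −4 mm.
* **Metrics.** Plateau flatness, distal R90/R80, biologically effective
  range extension, distal hotspot ratio, terminal-window mean RBE, and
  paired before/after comparisons (`beam_metrics()`, `compare_metrics()`).

## Worked example

```r
library(rangemod)

beam <- sobp()          # canonical 4-peak, 150 mm, 6 mm-spacing SOBP
beam
#> Spread-out Bragg peak fit: 4 peaks, distal range 150 mm, spacing 6 mm
#>   plateau [130.6, 146.6] mm, prescription 100 AU
#>   weights:
#> R150mm R144mm R138mm R132mm
#> 88.782 35.397 26.948 22.590

beam_metrics(beam)
#> Dose metrics (none delivery):
#>   plateau flatness     physical  1.583 %   RBE-weighted  5.943 %
#>   R90                  physical  148.52 mm  biological  150.32 mm
#>   range extension      1.800 mm
#>   distal hotspot ratio 1.1453
#>   terminal mean RBE    1.3223  (window +/- 5 mm)
#>   dose beyond R90 / +2 / +5 mm: 301.48 / 144.98 / 25.56 AU.mm
```

The physical plateau is flat to 1.6%, but the per-peak RBE ramps make the
RBE-weighted plateau ripple (5.9%), push the biologically effective range
1.8 mm beyond the physical R90, and leave a 15% biological hotspot at the
distal edge. Now split the beam three ways:

```r
compare_metrics(beam_metrics(beam),
                beam_metrics(beam, scheme = three_way_scheme()))
#>                 metric unmodulated  modulated       delta     flag
#> 1    flatness_physical    1.582644  15.600189 14.01754513 worsened
#> 2  flatness_biological    5.943296   7.506931  1.56363546 worsened
#> 3         r90_physical  148.523025 145.806326 -2.71669921  changed
#> 4       r90_biological  150.322896 147.842707 -2.48018886  changed
#> 5      range_extension    1.799871   2.036381  0.23651035 worsened
#> 6 distal_hotspot_ratio    1.145264   1.028256 -0.11700793 improved
#> 7    terminal_mean_rbe    1.322303   1.304607 -0.01769611 improved
```

The trade is explicit: the distal hotspot essentially disappears (ratio
1.15 → 1.03) and the terminal mean RBE drops, at the price of a smeared
distal shoulder (the "worsened" physical flatness is the falloff of the
pulled-back copies entering the unmodulated plateau interval).

A thin command-line front end over the same functions lives at
`inst/cli/rangemod.R` (subcommands `build-sobp`, `apply-rbe`, `rangemod`,
`report`, `demo`; YAML configs; exit codes 0/2/3 for
success/validation/computation errors):

```sh
Rscript inst/cli/rangemod.R demo --out demo_out
```

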