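# microcrackct

3D segmentation and morphometry of bone microcracks in micrometre-scale
micro-CT volumes of human trabecular bone.

Microcracks — planar voids ~1–7 µm thick and 50–500 µm across — are a key
bone-quality factor, but in reconstructed micro-CT volumes at 1.4 µm voxels
they are barely one voxel thick, weakly contrasted (partial volume), and
buried in noise and ring artifacts. This package implements a complete,
automatic analysis chain for researchers quantifying microdamage in 3D:

* **pre-processing** — polar-median ring-artifact removal and polynomial
  intensity normalisation;
* **crack enhancement** — Hessian eigen-analysis selecting thin dark
  sheets (`|h1| ≥ |h2| ≥ |h3|`, high score for large positive `h1` with
  small `|h2|, |h3|`), followed by a planarity-guided bilateral filter;
* **segmentation** — hysteresis thresholding of the porosity response and
  3D connected-component labelling within the trabecular envelope;
* **morphometry** — per porosity: volume `Cr.V = N·v³`; length and width
  from the centered second-order moment matrix
  `M = (1/N) Σ (x−x̄)(x−x̄)ᵀ` via the solid-ellipsoid closure
  `aᵢ = √(5λᵢ)`, `Cr.Le = 2a₁`, `Cr.W = 2a₂`; mean direct thickness
  `Cr.Th` from the maximal-inscribed-sphere map; surface
  `Cr.S = Cr.V / Cr.Th`;
* **classification** — microcrack iff `Cr.V > 500 µm³` and
  `Cr.Th/Cr.W < 1/3`, else lacuna (above the volume cut) or other;
* **specimen metrics** — BV/TV, SMI (`6·BV·S′/S²`; 0 plates, 3 rods,
  4 spheres), crack and lacunar densities `Cr.Dn = Cr.N/BV`,
  `La.Dn = La.N/BV`, local trabecular thickness `Tb.Th.lo` and shape at
  each crack site;
* **virtual 2D sections** — thick-section simulation (5-slice averages
  every 128 slices by default) with automated 2D counting, exposing the
  over/under-counting of section-based histomorphometry;
* **synthetic phantoms** — trabecular architecture, lacunae, cracks
  (linear / twisted / crossed / parallel), mineralisation bands, noise and
  ring artifacts with voxel-level ground truth, so every stage is
  benchmarked end to end.

## Worked example

```r
library(microcrackct)

cfg <- phantom_config(dim = c(128, 128, 128), n_cracks = 8, n_lacunae = 10,
                      crack_length_um = c(60, 140),
                      crack_width_um = c(30, 80), seed = 42)
res <- run_pipeline(cfg)   # phantom in, full analysis + truth scoring out
res
#> pipeline_result
#> specimen report
#>   BV/TV 0.197 (BV 0.00113 mm^3, TV 0.00575 mm^3), SMI 2.59
#>   Cr.N 10 (Cr.Dn 8810.61 /mm^3), La.N 7 (La.Dn 6167.4 /mm^3), other 1
#>   Cr.Le 60.3 +/- 29.8 um, Cr.W 30.5 +/- 9.5 um, Cr.Th 3.09 um
#>   detection: recall 1.00, precision 1.00

head(format_record_table(subset(res$records, class == "microcrack")))
#>   label      class Cr.Le Cr.W Cr.Th  Cr.V Cr.S Tb.Th.lo    shape
#> 1     1 microcrack   119   35  3.09 10.00 3.23       29 junction
#> 2     3 microcrack    96   36  3.20  7.36 2.30       24 junction
#> 3     5 microcrack    22   14  4.62  1.10 0.23       52    plate
#> 4     7 microcrack    51   37  2.83  4.34 1.53       53 junction
#> 5     8 microcrack    50   29  2.34  3.00 1.28       44    plate
#> 6    10 microcrack    83   38  2.82  5.30 1.87       31    plate
```

The report reads: the synthetic specimen has a bone volume fraction of
0.197 and an SMI of 2.59 (rod-leaning mixed architecture); 10 segmented
porosities classify as microcracks and 7 as lacunae, every ground-truth
crack was detected (recall 1.00) and every predicted crack overlaps a true
object (precision 1.00). Per-crack rows mirror the field's table
conventions: lengths/widths/thickness in µm, `Cr.V` in 10⁻⁶ mm³, `Cr.S`
in 10⁻³ mm², plus the local trabecular thickness (µm) and shape. (The
crack densities are that high only because the desk-scale phantom packs 8
cracks into a 0.006 mm³ volume; physiological specimens carry a few
cracks per mm³.)

Real volumes enter through `read_volume()` (TIFF slice stacks or
MHD/raw) and the same `run_pipeline()`; `inst/cli/microcrackct.R` wraps
the stages (`phantom`, `preprocess`, `segment`, `quantify`, `sections2d`,
`score`, `all`) for shell use with a YAML configuration.

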