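# glomorph

Quantitative morphometry of the glomerular mesangium from serial histology
sections. Mesangial expansion — growth of the supporting matrix compartment
inside the glomerular capillary tuft — is a structural hallmark of diabetic
kidney disease, and its canonical metrics are the mesangial volume (µm³) and
the mesangial fractional volume Vv(mes/glom), the fraction of tuft volume
occupied by mesangium. `glomorph` implements, in one tested toolkit, the
three ways these metrics are measured and the statistics used to compare
them:

- **3D reconstruction** — traced compartment contours on aligned serial
  sections are extruded into watertight prism meshes; volume is exactly
  `sum over sections of (contour area × section thickness t)`, the Cavalieri
  identity `V = t · Σ Aᵢ` made geometric.
- **Cavalieri / PSI point counting** — a systematic uniform random (SUR)
  grid of pitch `s` gives the unbiased estimator `V̂ = t · s² · ΣP`, with
  `P` the grid hits per section; the PSI fractional volume is
  `Vv = ΣP_mes / ΣP_tuft` (boundary hits count ½, the Gundersen rule).
- **Planimetry** — direct areas of traced profiles (the TEM-style
  comparator), converted to volume by extrusion or by the Weibel–Gomez
  shape model `V = (β/k)·Ā^{3/2}` with β = 1.38, k = 1.1.

Around these sit the supporting pipeline: colour-deconvolution segmentation
of PAS-stained RGB sections (optical density `OD = −log₁₀((I+1)/256)`,
least-squares unmixing, Otsu thresholding, morphological cleanup, sub-pixel
contour extraction), landmark-based rigid registration of successive
sections (2D orthogonal Procrustes on matched fiducial points, composed
into a stack-wide alignment chain), a within-subject repeated-measures
ANOVA harness with post-hoc paired contrasts and correlations, and a
synthetic glomerulus **phantom generator** whose voxel ground truth is
exact by construction — the oracle against which every estimator is tested.

## Worked example

```r
library(glomorph)

# a phantom with known ground truth: ellipsoidal tuft, blob mesangium at
# a target fractional volume of 0.5, ten 1-µm sections, PAS-like rendering
# with noise and per-section misalignment
spec  <- phantom_spec(tuft_radii_um = c(9, 8, 4.5), target_vv = 0.5,
                      n_sections = 10, seed = 42)
truth <- generate_phantom(spec)
imgs  <- render_sections(truth)

# segment every rendered section, align via the embedded fiducials,
# reconstruct, and summarise
contours <- segment_stack(imgs$images, spec$pixel_size_um)
chain    <- build_alignment_chain(imgs$fiducial_pairs)
rec      <- compute_morphometrics(align_contours(contours, chain),
                                  thickness_um = spec$section_thickness_um)
rec[, c("mesangial_volume_um3", "tuft_volume_um3", "mes_to_total_ratio")]
#> # A tibble: 1 × 3
#>   mesangial_volume_um3 tuft_volume_um3 mes_to_total_ratio
#>                  <dbl>           <dbl>              <dbl>
#> 1                 672.           1418.              0.474

truth$true_vv
#> [1] 0.4986077
```

The reconstructed mesangial-to-total area ratio (0.474) recovers the voxel
ground truth (0.499) to within the sectioning and segmentation error; the
mesangial volume is the prism-mesh volume in µm³. The PSI estimate of the
same stack:

```r
psi_fractional_volume(align_contours(contours, chain),
                      spacing_um = 1, seed = 1)$vv
#> [1] 0.47435
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/glomorph.R` (subcommands `phantom`, `segment`, `align`,
`reconstruct`, `cavalieri`, `psi`, `planimetry`, `compare`); every run
writes its effective configuration and seed next to its outputs.

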