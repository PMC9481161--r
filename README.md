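# polarquant

Quantitative analysis of front–rear polarity in rod-shaped bacteria.

In *Myxococcus xanthus* and related gliding bacteria, directed movement is
controlled by a polarity module built around a small Ras-like GTPase (MglA)
whose GTP-bound form marks the leading cell pole, a GTPase-activating
protein (MglB) concentrated at the lagging pole, and accessory regulators
that localize asymmetrically between the two poles. Studying such systems
routinely requires four kinds of quantification, which this package
implements as one tested pipeline:

1. **Snapshot localization** (`quantify_snapshot()` and friends): per-cell
   polar cluster detection in segmented fluorescence images, partitioning of
   total cell fluorescence into pole 1 / pole 2 / cytoplasm, the asymmetry
   index
   ω = (F<sub>pole1</sub> − F<sub>pole2</sub>) / (F<sub>pole1</sub> + F<sub>pole2</sub>)
   (pole 1 = brighter pole), and binning into unipolar (ω > 0.9), bipolar
   asymmetric (0.2 < ω ≤ 0.9), bipolar symmetric (ω ≤ 0.2) and diffuse (no
   polar signal) classes.
2. **Motility tracking** (`link_tracks()`, `detect_reversals()`,
   `dynamic_omega()` …): linking cells across time-lapse frames, per-interval
   speeds, gated reversal detection, leading/lagging pole assignment, and the
   signed dynamic asymmetry index
   ω<sub>dyn</sub> = (F<sub>leading</sub> − F<sub>lagging</sub>) / (F<sub>leading</sub> + F<sub>lagging</sub>)
   (−1 = unipolar at the lagging pole, +1 at the leading pole), with the
   standard frame-inclusion rules (runs of ≥ 3 frames without a reversal,
   first frame after and last frame before each reversal excluded). Includes
   Welch's unequal-variance t-test for the usual strain comparisons.
3. **GTPase assay kinetics** (`fit_linear_rate()`, `trace_to_turnover()`,
   `malachite_standard_fit()`, `endpoint_to_turnover()`,
   `fold_stimulation()`, `titration_analysis()`): NADH-coupled regenerative
   assay traces (ΔA340, 1 NADH per GTP) and malachite-green phosphate
   endpoints converted into specific activities in GTP hydrolyzed per enzyme
   per hour, with background subtraction, replicate averaging,
   fold-stimulation ratios and hyperbolic titration fits.
4. **Gene co-occurrence profiling** (`profile_similarity()`,
   `cooccurrence_table()`): Jaccard (or phi) similarity of genomic
   presence/absence profiles against a reference gene across large genome
   panels — the screening logic that flags candidate members of a polarity
   module.

Because raw images and plate files from such studies are rarely deposited,
the package ships a first-class synthetic-data module
(`gen_snapshot_scene()`, `gen_timelapse()`, `gen_coupled_trace()`,
`gen_malachite_plate()`, `gen_presence_absence()`): seeded, ground-truth
annotated generators that emulate the statistical structure each stage
assumes, so every stage is testable end to end.

## Worked example

```r
library(polarquant)

## a 200-cell synthetic field: 81% of cells unipolar or bipolar asymmetric
spec <- snapshot_population_spec(
  n_cells = 200,
  pattern_mixture = c(unipolar = 0.40, bipolar_asymmetric = 0.41,
                      bipolar_symmetric = 0.09, diffuse = 0.10),
  noise_sd = 4, seed = 8)
scene <- gen_snapshot_scene(spec)
res <- quantify_snapshot(scene$label_image, scene$fluorescence_image)
res$summary
#> population of 200 cells
#>   unipolar              40.0 %
#>   bipolar_asymmetric    41.5 %
#>   bipolar_symmetric      9.0 %
#>   diffuse                9.5 %
#>   mean cytoplasmic fluorescence (cells with clusters): 88.1 %

## a GAP-stimulated GTPase: 12 GTP/enzyme/hr at 3 uM enzyme
trace <- gen_coupled_trace(coupled_assay_spec(enzyme_conc = 3,
                                              true_turnover = 12,
                                              noise_sd = 0))
est <- trace_to_turnover(fit_linear_rate(trace)$slope,
                         assay_context(enzyme_conc = 3))
est
#> specific GTPase activity: 12 GTP/enzyme/hr
fold_stimulation(est, 2)
#> [1] 6
```

The summary shows the classifier recovering the generator's intended class
mixture (81.5% unipolar + bipolar asymmetric against 81% ground truth), and
the kinetics branch converting a noise-free absorbance trace back to its
generating turnover exactly; the six-fold ratio is the stimulation of a
12 GTP/enzyme/hr GAP-activated rate over a 2 GTP/enzyme/hr intrinsic rate.

A command-line interface wrapping the same functions is installed at
`system.file("exec", "polarquant.R", package = "polarquant")` with
subcommands `simulate`, `snapshot`, `timelapse`, `kinetics` and `cooccur`;
every run writes a provenance record (`run_info.json`) beside its outputs.

## Documentation

The methods vignette (`vignettes/polarquant-methods.Rmd`) describes the
models and assumptions of each stage, the tunable parameters with their
defaults and units, what the synthetic generators do and do not emulate,
and the numerical design choices. Function-level documentation is in the
roxygen comments in `R/`.
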