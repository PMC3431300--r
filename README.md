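# nucfish

Quantification of interphase chromosome organization from multi-channel 3D
FISH confocal stacks of large polyploid *Drosophila* nuclei (nurse cells,
salivary glands), with a ground-truthed synthetic-nucleus simulator so every
measurement stage can be validated by parameter recovery.

## The problem

In polyploid nurse cells, Condensin II activity determines whether
chromosomes form discrete globular chromosome territories or remain as
pole-anchored polytene fibers in the Rabl configuration, and it axially
compacts chromosome arms more than tenfold. Testing such hypotheses from
3D FISH images requires a reproducible quantification chain:

1. **Object detection** — per-channel absolute intensity thresholding
   (voxel kept iff intensity ≥ threshold; defaults DAPI 25,
   Alexa488/Alexa647 35, Alexa546 55 on the 8-bit scale), 3D
   connected-component labeling (6/18/26 connectivity, default 26), and
   removal of objects smaller than 10 voxels.
2. **Per-object features** — voxel count, volume, total fluorescence, and
   the intensity-weighted centroid
   `c = Σᵥ Iᵥ xᵥ / Σᵥ Iᵥ` over member voxels, in µm.
3. **Nuclear geometry** — the nuclear center is the center of DAPI
   fluorescence intensity; the nuclear radius is estimated two ways:
   sphere-equivalent `R = (3V/4π)^{1/3}` from the thresholded DAPI volume
   `V`, and a least-squares circle fit to the boundary of the widest
   z-slice. Locus positions are reported as radial fractions
   `|x − c| / R` (0 = center, 1 = periphery).
4. **Territory metrics** — probe-set centroids (weights = object total
   intensities), inter-probe and inter-chromosome centroid distances,
   axial compaction folds, spot counts with telomere normalization (÷5),
   intensity-weighted PCA shape descriptors, traced-path arc lengths, and
   the mean distance between two random points in a ball (`36R/35`) as the
   unlinked-locus reference.
5. **Group statistics** — per-group mean ± SEM with n, two-sided Welch
   comparisons (permutation test available), stars at p < .05/.01/.001,
   no multiple-testing correction (per-pair reporting).

Because no real stacks ship with the package, a simulator
(`synthetic_spec()`, `simulate_nucleus()`, `preset_scenarios()`) renders
calibrated 8-bit TIFF stacks of spherical nuclei with chromosome backbones
in Rabl/polytene or territorial configuration, probe spots with an
anisotropic Gaussian PSF, background and noise — together with an exact
ground-truth table, so recovered distances can be compared with programmed
truth.

## Worked example

Simulate 15 wild-type-like stage-4 nuclei (two X-chromosome probes 2 Mb
apart, programmed 1.18 µm separation), run the pipeline, and summarize:

```r
library(nucfish)

sim_dir <- tempfile(); res_dir <- tempfile()
manifest <- simulate_nuclei("wt_stage4", n = 15, out_dir = sim_dir, seed = 1)
tabs <- run_pipeline(manifest, file.path(sim_dir, "probes.yaml"), res_dir)
tabs$summary[tabs$summary$metric == "distance_um", ]
#>                                       group      metric  n     mean         sem
#> 1 territorial:simulated:X_probe_A-X_probe_B distance_um 15 1.179918 0.002897325
```

The measured mean separation (1.180 ± 0.003 µm over 15 nuclei) recovers
the programmed 1.18 µm truth to within a fraction of a voxel: the
segmentation + centroid + distance chain is unbiased at this noise level.
`res_dir` now holds `objects.csv`, `nuclei.csv`, `distances.csv`,
`radial.csv`, `spots.csv`, `shapes.csv`, `summary.csv` and a log.

Worked compaction arithmetic on published distances:

```r
compaction_fold(9.88, 0.80)   # nurse cells, mutant vs wt stage 10 -> 12.35
compaction_fold(144.3, 12.0)  # salivary arm vs compacted arm     -> 12.025
```

A shell entry point wrapping the same functions is at
`inst/cli/nucfish.R` (`simulate` and `run-all` subcommands).

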