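# FociQuant

Quantitative image analysis for experiments that perturb chromatin at
defined intranuclear foci — e.g. pericentromeric heterochromatin targeted
by a programmable TALE–effector fusion — and read out the consequences by
fluorescence microscopy. FociQuant covers the three measurement arms such
studies rely on, plus a synthetic-data module that makes every stage
testable with known ground truth:

* **3D foci quantification** — nucleus segmentation in calibrated
  Z-stacks by a gradient-watershed edge detector (borders at intensity
  gradient maxima), adaptive spot segmentation, and the normalized
  density statistic

  ```
  D = (Signal_foci / Volume_foci) / (Signal_nucleus / Volume_nucleus)
  ```

  pooled per nucleus, with per-spot volume-normalized intensities,
  largest-overlap partner selection, Wilcoxon–Mann–Whitney group
  comparison and 1.5 × IQR boxplot summaries.
* **Single-molecule localization microscopy (PALM/STORM)** — Gaussian
  PSF fitting of raw frames with Thompson-style localization
  uncertainties, fiducial-based drift correction, merging of consecutive
  detections, super-resolution rendering (unit-amplitude Gaussians, σ =
  localization uncertainty, tenfold canvas upsampling) and max-normalized
  cluster-area measurement above a relative threshold.
* **Chromosome instability scoring** — per-nucleus FISH copy counts with
  S/G2 (8-copy) and nucleus-volume exclusion rules, instability rates
  (% of usable nuclei deviating from the tetraploid count), Pearson
  chi-squared 2×2 contingency tests and percent-change reporting.
* **Synthetic microscopy data** — ellipsoidal nuclei with Gaussian foci,
  PSF blur and Poisson/Gaussian camera noise; blinking emitters in
  disc-shaped clusters with linear drift and fiducial beads; ploidy
  populations with an instability fraction, an S/G2 subpopulation and
  log-normal volumes. All generators return index-aligned ground truth
  and are bit-reproducible from config + seed.

The central data containers are S4 classes: `VoxelGrid` (calibrated
multichannel Z-stack, µm voxels) and `SuperResImage` (rendered canvas,
nm pixels). Stacks are read/written as TIFF with a JSON calibration
sidecar; localization tables as CSV in a `simple` or `thunderstorm`
dialect; measurements as byte-reproducible CSV.

## Worked example

Simulate a stack, segment it, and quantify marker density at the foci:

```r
library(FociQuant)

cfg <- stackSimConfig(dim = c(28L, 192L, 192L), nNuclei = 4L, seed = 7L)
sim <- simulateIfStack(cfg)
sim$grid
#> VoxelGrid: 28 x 192 x 192 voxels, 2 channels
#>   voxel size (dz, dy, dx): 0.23 x 0.10 x 0.10 um
#>   channels: dna, marker1
#>   intensity range: [0, 183.167]

seg  <- segmentNuclei(sim$grid)
foci <- segmentFoci(sim$grid, "marker1", seg)
dens <- nucleusDensities(foci$records, seg$records, group = "control")
dens
#>   nucleus channel density   group
#> 1       1 marker1   2.485 control
#> 2       2 marker1   2.523 control
#> 3       3 marker1   2.442 control
#> 4       4 marker1   2.466 control
```

Each of the four simulated nuclei yields one pooled density ≈ 2.5:
the marker is two-and-a-half-fold enriched inside the foci relative to
the nuclear mean (a density of 1 would mean no enrichment). Group
comparisons then go through `rankSumTest()` /`summarizeGroup()`, and a
20 % simulated marker loss is recovered from two such groups with
`densityEffectSize()`.

Instability scoring works directly on count tables. With the summary
counts of a two-condition FISH experiment (aberrant = copy number ≠ 4
after exclusions):

```r
tab <- matrix(c(45L, 1109L, 76L, 1130L), 2,
              dimnames = list(c("aberrant", "normal"),
                              c("uninduced", "induced")))
chi2Test2x2(tab)
#> $statistic
#> [1] 6.99675
#> $p
#> [1] 0.00817

percentChange(100 * 45 / 1154, 100 * 76 / 1206)
#> [1] 61.5
```

i.e. a ~62 % increase of instability, significant at p < 0.01. The same
numbers come out of the full pipeline (`applyExclusions` →
`instabilityRate` → `contingencyTable` → `chi2Test2x2`), wrapped in
`instabilityReport()`.

## Documentation

The methods vignette (`vignettes/foci-quantification.Rmd`) explains the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic data do and do not emulate, the numerical
conventions, and known limitations.
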