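# nucleogradient

Quantitative analysis of how ribosome biogenesis is organized in space
inside intact nucleoli imaged by cryo-electron tomography (cryo-ET).

## The scientific problem

The nucleolus is a membraneless organelle in which ribosomal subunits are
assembled. In cryo-electron tomograms of intact cells, pre-ribosomal
particles (SSU processomes and pre-60S intermediates) decorate the outer,
granular component of the nucleolus. The central quantitative questions
this package addresses are:

* Where is the nucleolar surface? Pre-ribosome positions are fit with a
  sphere, robustly, so each particle gets a **normalized distance**
  r = |x − c| / R (1.0 = the surface).
* How is particle **mass** distributed radially? Tomograms are
  standardized, Gaussian-filtered, binarized at a threshold calibrated so
  that reference pre-ribosomes measure ~4.5 MDa, segmented into
  26-connected components, and converted to Dalton masses via the protein
  density ρ = 1.3 g/cm³:
  mass = voxels × (voxel size in cm)³ × ρ / 1.66054·10⁻²⁴ g.
* Are particle **positions** found without reference bias? Template
  matching uses a featureless (rotationally averaged) sphere, and a
  dual-reference strategy: two copies of a reference with different
  regions computationally erased are matched independently, and only hits
  present in both lists within ±4 voxels survive.
* Are structural **classes** reproducible? Subvolumes are classified by
  simulated-annealing multireference alignment (temperature 10 → 0 over
  10 iterations, then hill climbing until < 1 % of subvolumes change
  class), replicated six times, and a particle keeps a class only if 5 of
  6 replicates agree.
* Are radial differences **significant**? Fisher–Pitman permutation tests
  (exhaustive where enumerable, Monte-Carlo with p = (b+1)/(m+1)
  otherwise) compare means and variances of normalized distances between
  classes; kernel density estimates localize each class's radial peak.

Because the raw tomograms behind such studies are rarely deposited, the
package ships a first-class synthetic-data generator that emulates the
relevant structure — radial particle shells around a ~600 nm sphere,
lamella-slab truncation, a background mass spectrum up to ~2.5 MDa with a
3–5.5 MDa surface spike, and class-structured subvolume sets — with full
ground truth, so every stage of the pipeline is validated end to end.

## Worked example

The bundled demo simulates one synthetic nucleolar tomogram (three
particle classes in shells at 0.85 / 0.95 / 1.00 of a 120-voxel radius),
fits the nucleolar sphere, and tests the radial gradients:

```r
library(nucleogradient)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "nucleogradient"))
run_pipeline(cfg, "demo_run")
read.delim("demo_run/sphere_fits.tsv")
#>   tomogram_id       cx       cy       cz radius_voxels radius_nm n_inliers n_iterations
#> 1      tomo_1 159.0436 159.7646 159.6471       112.982  154.5594       378           12
read.delim("demo_run/permutation_tests.tsv")
#>   class_a class_b statistic    observed      p_value stars
#> 1       1       2 mean_diff -0.10378575 0.0004997501    **
#> 2       1       3 mean_diff -0.15836877 0.0004997501    **
#> 3       2       3 mean_diff -0.05458303 0.0004997501    **
```

The fitted center sits at the configured (160, 160, 160) within a
voxel, and the fitted radius (113 voxels) lands inside the pooled shell
band (0.85–1.00 × 120). All three pairwise mean-distance contrasts are
significant at the Monte-Carlo floor of the demo's 2000 permutations
(p = (0+1)/(2000+1) ≈ 5·10⁻⁴); the classes sit at increasing radii, the
signature of a maturation gradient. `radial_pdfs.tsv` holds the
per-class kernel density estimates.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/nucleogradient run --config inst/extdata/demo_config.yaml \
    --out demo_run --seed 1
```

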