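# pctomo

Synchrotron inline (propagation-based) phase-contrast tomography of
air-filled vasculature, end to end and fully synthetic: phantom
simulation, flat/dark correction, fringe-visibility distance optimization,
single-distance Paganin phase retrieval, parallel-beam filtered back
projection, multiscale ridge segmentation, and branch-point morphometry.

## The problem

Brain microvasculature can be imaged without any contrast agent by drying a
perfused, fixed brain so that air fills the intact vessel lumina: the
refractive-index step at each air--tissue interface produces strong
propagation fringes on a detector placed behind the sample, making
micrometre-scale vessels visible at ~3.7 um pixels. After reconstruction
and segmentation, each bifurcation is summarized by the **branching radius
ratio**

    K = mean(daughter radii) / parent radius,

computed per junction, restricted to small vessels (parent radius < 20 um)
and binned at 7.4 um (twice the effective pixel). Active angiogenesis adds
newborn small branches and lowers K among sub-7.4 um vessels, so comparing
per-animal mean K between cohorts (two-sample Student's t-test) detects
post-stroke vascular rebuilding.

Because no raw beamline data of this kind are public, `pctomo` ships a
first-class synthetic acquisition model — bifurcating vessel trees with
controlled K, attenuation and phase-decrement maps, transport-of-intensity
edge enhancement, vignetted flat fields, dark offsets and Poisson noise —
so the entire chain is testable against exact ground truth.

## Worked example

```r
library(pctomo)

cfg <- pipeline_config(
  tree     = tree_spec(root_radius = 8, max_depth = 4, min_radius = 3.8,
                       radius_ratio_mean = 0.794, radius_ratio_sd = 0.02,
                       asymmetry = 0, length_per_radius = 6,
                       branch_angle_deg = 40),
  grid     = grid_spec(c(128, 128, 128), 2),
  geometry = acquisition_geometry(n_angles = 180, distance_mm = 0),
  noise    = noise_off(),
  scales_um = c(4, 6, 8, 12),
  tissue_mu = 1e-3,
  seed     = 5)

res <- run_pipeline(cfg, keep_volumes = FALSE)
res
#> pipeline_result (config 00dce38c )
#>   true junctions: 6 | measured junctions: 6
#>   mean measured K (radius < 20 um): 0.7676
res$binned[, c("junction_id", "pre_radius_um", "post_radius_um", "K", "bin")]
#>   junction_id pre_radius_um post_radius_um      K     bin
#> 1           1         7.000          5.317 0.7595 [0,7.4)
#> 2           3         5.633          4.064 0.7215 [0,7.4)
#> 3           4         5.000          4.828 0.9657 [0,7.4)
#> 4           6         5.000          3.000 0.6000 [0,7.4)
#> 5           8         3.472          3.000 0.8640 [0,7.4)
#> 6           9         4.657          3.236 0.6949 [0,7.4)
```

(The run takes a bit over a minute and is deterministic given `seed`.) All
six true bifurcations of the generated tree are recovered; each row reports
the parent radius, the mean daughter radius and their ratio K, already
filtered to the sub-20 um band and binned at 7.4 um. The per-junction K
scatters around the generating ratio 0.794 (mean 0.768 here): radii carry
about a voxel of quantization error, which averages out across junctions
and animals in the cohort studies.

Cohorts are compared with

```r
cmp <- group_compare(list_of_binned_tables_sham, list_of_binned_tables_injury)
```

which reduces every animal to its mean K per radius bin and runs the
equal-variance t-test per bin.

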