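# linkfuse

Multi-atlas segmentation with **linked (composed) deformable registrations**
and signed-distance label fusion, for 3D medical images.

## The problem

Atlas-based segmentation transfers expert contours from pre-segmented
reference images ("atlases") to a new patient image via deformable
registration; fusing the proposals of several atlases beats any single one.
The catch is runtime: every atlas needs its own deformable registration.
An alternative is to *link* registrations — pre-compute all atlas-to-atlas
transforms offline, register only a single intermediate (hub) atlas to the
patient at runtime, and reach every other atlas by composing transforms:

    T_M←I(l)←F = T_M←I ∘ ... ∘ T_I1←F

where `F` is the fixed (patient) image, `M` a moving atlas and `l` the
number of intermediate transformations. Composition is cheap (one trilinear
interpolation per link), so the whole atlas set costs one runtime
registration — but each link adds registration error. This package
implements the machinery and quantifies the quality loss as a function of
`l`.

## What is inside

* **Transforms** — cubic B-spline free-form deformations and dense
  displacement fields (pull-back convention `R(x) = M(T(x))`), composition,
  chain collapse, image warping (trilinear or prefiltered cubic B-spline)
  and nearest-neighbor label warping.
* **Label fusion** — per-structure signed Euclidean distance maps
  `D_j` (exact, anisotropic mm; negative inside, zero on the 6-connected
  border), fused as the weighted mean
  `D_fus = Σ w_j D_j / Σ w_j`, with the consensus segmentation given by the
  iso-level-zero region `D_fus ≤ 0`. Probabilistic weights
  `w_i = ½ (1 − erf((k/s)(SIM_best − SIM_i) / √2))`
  map each atlas's similarity deficit (NCC over a structure-local band
  `D ≤ r`) to a fusion weight; `k/s` can be set from a regression-angle
  sweep (`calibrate_weights`). Majority voting is included as a baseline.
* **Metrics** — Dice similarity coefficient
  `DSC(B1, B2) = 2|B1 ∩ B2| / (|B1| + |B2|)` and the cumulative fraction of
  surface voxels within a distance of a reference surface (fMAD).
* **Evaluation engine** — leave-one-out enumeration of direct
  (`n(n−1)`) and one-link (`n(n−1)(n−2)`) cases, seeded random sampling of
  longer chains, matched relative-change tables, quartile summaries,
  Wilcoxon rank-sum tests, and the ordinary-least-squares trend of median
  DSC versus link count (whose intercept extrapolates to zero links).
* **Synthetic study generator** — a CT-like head-and-neck phantom
  (paired gland ellipsoids, a mandible-like arc, a cord-like tube, nodal
  slabs), a population of subjects deformed from it by random smooth
  B-spline fields, and pairwise "registrations" equal to the ground-truth
  maps corrupted by independent smooth error fields of controllable RMS
  magnitude (mm).

## Worked example

```r
library(linkfuse)

g <- image_grid(c(24, 24, 18), spacing = c(2, 2, 3))
organs <- list(
  list(name = "gland_l", shape = "ellipsoid", center = c(14, 16, 18),
       radii = c(7, 8, 9), intensity = 70),
  list(name = "gland_r", shape = "ellipsoid", center = c(32, 16, 18),
       radii = c(7, 8, 9), intensity = 70),
  list(name = "cord", shape = "tube", center = c(23, 33, 25),
       radii = c(5, 5, 18), intensity = 40))
template <- make_template(phantom_spec(g, organs), seed = 7)

pop <- make_population(template,
                       population_spec(n_atlases = 4, deform_amplitude = 1.2,
                                       error_amplitude = 2, seed = 7))
provider <- population_transform_provider(pop)
tab <- run_experiment(pop$atlases, provider, links = 0:2,
                      n_samples = 24, seed = 7)
summ <- summarize_experiment(tab)
print(summ$per_links, row.names = FALSE)
cat(sprintf("trend: %.4f DSC per link, zero-link intercept %.3f\n",
            summ$trend$slope, summ$trend$intercept))
fus <- subset(tab, mode == "fused_linked")
ind <- subset(tab, mode == "linked" & links == 1)
cat(sprintf("median relative DSC change at one link: %.1f%% (individual), %.1f%% (fused)\n",
            median(ind$rel_change), median(fus$rel_change)))
```

Output:

```
 links median_dsc       p25       p75  n
     0  0.7726631 0.7326412 0.7915110 36
     1  0.7045621 0.6500987 0.7485694 72
     2  0.6388698 0.5768872 0.6978762 72
trend: -0.0669 DSC per link, zero-link intercept 0.772
median relative DSC change at one link: -7.6% (individual), -5.9% (fused)
```

Reading it: direct registrations (0 links) score a median DSC of 0.77
against the left-out subject's own labels; every composed link costs about
0.07 DSC on this small, strongly deformed population, and the linear trend
extrapolated to zero links recovers the direct quality. Fusing all atlases
damps the per-case spread relative to individual proposals.

## Command-line use

A thin CLI wraps the same functions (also installed under `exec/`):

```sh
Rscript -e 'quit(status = linkfuse::cli_main(commandArgs(TRUE)))' \
    simulate --n-atlases 6 --seed 1 --out pop/
Rscript -e 'quit(status = linkfuse::cli_main(commandArgs(TRUE)))' \
    evaluate --atlases pop/ --links 0,1,2 --samples 30 --seed 1 --out results/
```

`simulate` writes the phantom population (NIfTI images and labels, B-spline
transform JSON, displacement fields, a YAML manifest); `compose`, `warp`,
`fuse`, `evaluate` and `calibrate` consume such directories or individual
NIfTI/MetaImage/JSON files. Every stage writes a log with its seed and
input checksums.

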