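---
title: "Feature-based nonrigid registration of thermal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based nonrigid registration of thermal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(thermreg)
```

Infrared (thermal) images of soft tissue are hard to register: most of the
frame is flat and low-contrast, intensity is not preserved between
acquisitions, and displacements can be large. `thermreg` implements a
pipeline built for exactly this regime:

1. **Detect** feature points in both the bright, vessel-like *hot pattern*
   and the dark, flat *cold pattern*.
2. **Describe** each point with a per-class shape-context histogram.
3. **Match** descriptors, then prune and extend the matches with an
   iterative thin-plate-spline coherence filter.
4. **Flow**: estimate a dense displacement field with a variational
   large-displacement optical flow solver whose energy is anchored by the
   sparse matches.

A synthetic phantom generator with exact ground-truth fields supports all
of the quantitative claims below.

## A worked example

Phantoms pair a vessel network (bright ridges) with cold blobs carrying a
faint interior grid, deformed by a known smooth field:

```{r phantom}
preset <- phantom_preset("II", height = 128, width = 160, seed = 5)
case <- make_case(preset$spec, preset$deform)
op <- par(mfrow = c(1, 2), mar = c(0.5, 0.5, 1.5, 0.5))
image(t(unclass(case$source))[, nrow(case$source):1], axes = FALSE,
      col = gray.colors(256), main = "source")
image(t(unclass(case$target))[, nrow(case$target):1], axes = FALSE,
      col = gray.colors(256), main = "target")
par(op)
```

The whole pipeline is one call:

```{r register}
run <- run_register(case$source, case$target, truth = case)
run
```

`run_register` returns a run record with the per-stage outputs: feature
sets, the control-point set, the dense field, the warped source, and a
metrics report. Against the phantom's ground truth:

```{r score}
c(mean_endpoint_error_px = run$report$mean_epe,
  match_precision = run$report$precision,
  mi_gain_nats = run$report$mi_after - run$report$mi_before)
```

## Detection: hot and cold patterns

The image is split by the sign of the dominant eigenvalue of the
Gaussian-smoothed Hessian (scale `sigma = 2`): bright ridges and blobs have
a strongly negative dominant eigenvalue, dark flat regions a positive one.

```{r detect}
eig <- hessian_eigen(case$source)
masks <- binarize_patterns(eig)
feats <- detect_features(case$source)
table(feats$points$klass)
```

Three point classes result: **W** — branch points of the skeletonized hot
pattern (vascular intersections); **B** — branch points of the skeletonized
cold pattern (grid intersections in flat regions); **C** — Harris corners
restricted to the hot pattern. Adding B points is what gives the detector
coverage inside flat regions; `feature_quality()` quantifies this with the
nearest-neighbor uniformity score `h_uni`.

```{r uniformity}
full <- feature_quality(feats)
corners <- feats
corners$points <- feats$points[feats$points$klass == "C", , drop = FALSE]
c(full = full$h_uni, corners_only = feature_quality(corners)$h_uni)
```

## Description and matching

Each point gets a log-polar shape-context histogram (5 radial × 12 angular
bins, radii scaled by the mean pairwise distance), compared only within its
class using a χ² cost. Initial matches are mutual minima of the cost
matrix. Two stages then alternate until the pair set is stable:

* **Mismatch removal**: a thin-plate spline is fit to the current pairs
  with a strong smoothing penalty that anneals geometrically; pairs whose
  residual exceeds an adaptive threshold are removed one at a time, worst
  first, with a refit after each removal so that gross outliers cannot
  drag their coherent neighbors over the threshold.
* **Pair addition**: unmatched points are re-admitted when their
  displacement length matches the inlier mean and the fitted spline maps
  them near their candidate partner; removed pairs are never re-admitted.

```{r matches}
run$matches$n_iterations
nrow(run$matches$inliers)
```

## Dense flow

The displacement field minimizes a robustified energy with four terms:
intensity constancy, gradient constancy (weight `gamma`), smoothness
(weight `alpha`), and a quadratic penalty tying the field to the sparse
matches (weight `beta`). Minimization is coarse-to-fine over a Gaussian
pyramid (factor `eta = 0.8`); each level runs fixed-point iterations with
frozen robust weights, and each linearized system is solved by
point-coupled successive over-relaxation. Two solver details matter in the
flat-image regime:

* the relaxation sweeps are followed by a constant-mode correction — a
  2×2 Galerkin solve on the globally constant component of the increment,
  which the smoothness operator cannot see and plain relaxation moves
  extremely slowly; and
* every fixed-point step is accepted only if the energy does not increase
  (step halving otherwise), so the per-pass energy trace is monotone.

```{r flow-trace}
lev <- attr(run$field, "levels")
round(lev[[length(lev)]]$energy_trace, 2)
```

The `beta` anchor term is what carries large displacements that the data
terms alone cannot reach; setting `beta = 0` on a large-deformation case
degrades the endpoint error (see the package tests for the paired
ablation).

## Evaluation

`mutual_information()` (nats, 64-bin joint histogram) compares the warped
source with the target; `canny_overlay()` renders edge agreement (green
where edges coincide); `feature_quality()` scores detector coverage; and
for phantoms, `mean_endpoint_error()` and `match_precision()` score against
the exact ground truth.

```{r metrics}
c(mi_before = run$report$mi_before, mi_after = run$report$mi_after,
  edge_agreement = run$report$edge_agreement)
```

## Command line

A thin CLI wraps the same functions (`inst/cli/thermreg`): `config init`,
`phantom`, `register`, `batch`, and `metrics` subcommands, with per-flag
overrides for the flow solver (`--alpha`, `--beta`, `--gamma`, `--eta`,
`--epsilon`, `--levels-min-size`, `--max-sor`, `--omega`) and `--swap` to
exchange the source/target roles.
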