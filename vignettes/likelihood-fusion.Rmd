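---
title: "Multi-atlas segmentation by likelihood fusion: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas segmentation by likelihood fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`likefuse` segments subcortical and ventricular structures in a T1-weighted
MR volume using several expert-labeled atlases at once. The generative view
is the random diffeomorphic orbit model: the observed image $I$ on the voxel
lattice $\Omega$ is a noisy observation of some atlas deformed by an unknown
diffeomorphism $\varphi$, and the atlas that generated any particular voxel
is itself unknown. Each atlas is a collection of local *charts* — one per
structure, plus generic white-matter / gray-matter / CSF charts — and each
chart $k$ of atlas $a$ carries its own empirical intensity mean
$\mu_{a,k}$ and variance $\sigma^2_{a,k}$. Conditioned on the segmentation
label $W(x)$ and the chart, the intensity is Gaussian:

$$\log p_a(I(x) \mid W(x)=k) = \log\mathcal N(I(x);\,\mu_{a,k},\,\sigma^2_{a,k})
  + \log \pi_a(k \mid x),$$

where $\pi_a(k\mid x)$ is the label prior obtained by carrying atlas $a$'s
labels through its optimized deformation: an indicator deep inside a
structure, linearly interpolated mass at boundaries
(`warp_labels(..., mode = "prob")`).

Because the generating atlas is latent, the posterior over segmentations is
a mixture across atlases. The EM algorithm makes this tractable: the E-step
computes the conditional mean of the per-voxel atlas indicator — a convex
weight $q(x,a)$ — and the M-step maximizes the *fused* score

$$S(x,k) = \sum_a \bar q(x,a)\,\big[\log\mathcal N(I(x);\mu_{a,k},\sigma^2_{a,k})
  + \log \pi_a(k\mid x)\big],$$

a convex combination of per-atlas log-likelihoods (likelihood fusion, as
opposed to fusing per-atlas label decisions). Registration enters twice:
once through the label priors, and once through a transformation prior
$\exp(-\lambda\,E_{\mathrm{geo}})$ on each atlas's geodesic energy, which
down-weights atlases that had to deform far to reach the target.

## Registration

Each atlas image is matched to the target by LDDMM image matching: gradient
descent on

$$E(v) = \frac1T\sum_t \|L v_t\|^2 + \frac{1}{\sigma_d^2}\,
  \|I_0\circ\varphi_1^{-1} - I_1\|^2,
  \qquad L = (-\alpha\nabla^2 + \gamma)^p,$$

with the velocity field discretized at $T$ timesteps, the kernel
$K=(L^\dagger L)^{-1}$ applied per component in the Fourier domain (7-point
discrete Laplacian symbol, periodic boundary, 4-voxel zero padding against
wrap-around), and Beg-style gradients. The $\gamma/\alpha$ ratio is cascaded
downward across stages (default $\{1, 0.1, 0.01\}$), each stage warm-started
from the last; a halving line search guarantees the energy trace never
increases within a stage. A center-of-mass translation initializes the
field. The inverse map is integrated from $-v$ backward rather than by
fixed-point inversion (the fixed-point iteration is kept as a test oracle).

The optimization runs once per atlas (the *mode approximation*): the single
optimized deformation stands in for the integral over deformations and is
reused across EM iterations. Re-registering inside the EM loop is possible
in principle but is deliberately not the default: it is costly, and its
stopping behaviour is much harder to reason about.

## Why the M-step smooths the selector weights

The E-step aggregates each atlas's per-voxel log-likelihood over a box
window of radius $r$ (default 2 voxels) before the softmax — atlas evidence
is chart-local, not voxel-local. With that window, the textbook pairing
"softmax weights at $x$, argmax at $x$" is *not* an exact alternating
maximization of any single objective, and the monitored objective could in
principle decrease. `likefuse` therefore treats the windowed model honestly
as a composite likelihood: each voxel's latent atlas indicator explains its
whole window, giving the incomplete-data objective

$$\mathcal L(W) = \sum_x \log \sum_a \exp\Big(\log\pi(a) - \lambda E_a +
 \sum_{y \in B_r(x)} \ell_a(y; W)\Big).$$

The exact E-step is the windowed softmax above; the exact M-step maximizes
per voxel under the *box-mean smoothed* weights $\bar q(x,a)$ (windows are
symmetric, so the double sum regroups exactly). With this pairing
$\mathcal L$ provably never decreases, and the implementation enforces that
as a hard invariant (a decrease beyond $10^{-6}$ relative is an error, not a
warning). With $r=0$, one atlas, or spatially constant weights,
$\bar q = q$ and everything reduces to the plain per-voxel EM.

## Outliers, initialization, stopping

The segmentation is initialized by majority vote over the propagated hard
labels. Before fusing, each atlas is scored by its mean Dice overlap with
that initialization across structure labels; atlases below
$\text{mean} - 1.5\,\text{sd}$ are removed, always retaining at least half
(best scores kept). This is the robust metric-distance screen that keeps a
badly registered or mislabeled atlas from polluting the mixture. Iteration
stops when fewer than $\varepsilon = 10^{-4}$ of ROI voxels change label, or
after 100 iterations.

All computation happens inside a cuboid ROI enclosing every warped
structure with a 4-voxel margin. ROI voxels outside the structures of
interest must still be explained — otherwise the argmax over structure
labels alone *over-assigns* structures into background tissue. Two
mechanisms cover this: atlases can carry generic WM/GM/CSF charts
(preferred; they compete in the fusion exactly like structure charts), and a
3-class Gaussian mixture (`fit_tissue_gmm`; deterministic Lloyd k-means
initialization from range-spread seeds, so a minority tissue cannot be
missed when one class dominates the sample; components reported
CSF < GM < WM by ascending mean) can label tissue from the target itself
when atlases lack tissue charts.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `kernel_params`: $\alpha$, $\gamma$, $p$ | 1, 1, 2 | — | operator stiffness; $p=2$ gives a smooth, stable kernel; per-stage $\gamma=\alpha\cdot$ratio |
| `registration_config`: $T$ | 5 | timesteps | time discretization of the flow |
| cascade | $\{1, 0.1, 0.01\}$ | $\gamma/\alpha$ | decreasing ratio: stability first, flexibility later |
| `step` | 0.4 | voxels | line-search cap on the per-iteration velocity update |
| $\sigma_d$ (data weight $1/\sigma_d^2$) | $2\times$ MAD noise | intensity | see below |
| `fusion_config`: window $r$ | 2 | voxels | chart-local selector evidence |
| $\varepsilon$ | $10^{-4}$ | fraction | stop when almost no voxel changes |
| `outlier_c` | 1.5 | sd | robust cut; retention floored at half |
| $\lambda$ | 0 | — | transformation prior off by default, mechanism wired and tested |
| `prior_floor` | $-30$ | nats | keeps zero-probability labels finite |
| ROI margin | 4 | voxels | room for chart overlap at boundaries |

On the data weight: $\sigma_d$ is estimated from the target as the median
absolute deviation of first differences (divided by $\sqrt 2$), then
doubled. With $\sigma_d$ set exactly to the voxel noise, the summed SSD term
overwhelms the geodesic prior at desk scale and the optimizer chases noise,
which measurably *worsens* the overlap of well-aligned structures while
improving the misaligned ones. Doubling $\sigma_d$ restored uniform
improvement across all structures on deformed-phantom pairs and is the
package's declared default; pass `sigma` explicitly to override.

## The synthetic world

`generate_phantom` builds ellipsoidal structures (closed-form membership,
so exhaustive voxel-scan oracles are possible) with T1-like means —
thalamus 95, putamen 88, caudate 85, hippocampus 75, ventricle 32 —
embedded in a concentric WM (110) / GM-shell (80) / CSF-exterior (30)
background with additive Gaussian noise (sd 4) on a $48^3$ grid at
$0.9375 \times 0.9375 \times 1.2$ mm spacing. The ventricle is placed
adjacent to the hippocampus on purpose: that CSF/gray boundary is where
generic tissue labels earn their keep. `generate_population` warps the
phantom with independent random diffeomorphisms (smoothed white noise,
max displacement 2 voxels, smoothness 6 voxels, integrated as a stationary
flow with guaranteed positive Jacobian) and adds a per-atlas global
intensity offset (sd 2) emulating scanner gain differences.

What the phantom does *not* emulate: bias fields, partial-volume mixtures
beyond linear boundary interpolation, cortical folding, multi-modal
contrasts, and true inter-subject anatomical variability. A green test on
this world establishes the algorithm's internal correctness (monotonicity,
convexity, reductions, recovery) and qualitative behaviours (multi-atlas
benefit, tissue-chart benefit, outlier rejection) — not clinical accuracy.
The deformation generator is stationary-velocity for invertibility; the
registration module still optimizes the full time-indexed field.

## Numerical choices and degenerate inputs

* Chart variances are floored at $\max(10^{-6}, 0.01\cdot\mathrm{var}(I))$;
  noise-free synthetic charts would otherwise produce degenerate
  likelihoods.
* Softmax across atlases subtracts the per-voxel maximum before
  exponentiation.
* Argmax ties in the M-step go to the label with larger summed prior mass,
  then the lowest id; initialization ties go to the lowest id; tissue-GMM
  responsibility ties go to the lower component. All tie-breaks are
  deterministic, which is what makes the pipeline invariant to atlas order.
* Dice of two empty sets is defined as 1 and flagged (`both_empty`).
* The randomization test uses the Welch statistic (safe for unequal group
  sizes), the two-sided $|t|$ convention, and add-one smoothing
  $p=(\#\{|t^\ast|\ge|t|\}+1)/(n_{\mathrm{perm}}+1)$; an exact enumeration
  mode exists for small groups.
* The permutation test and all generators derive their randomness from
  explicit seeds and restore the caller's RNG state; registration and
  fusion are deterministic throughout.

## Known limitations

Single-compartment Gaussian charts (no within-structure mixtures);
intensity-only matching (no multi-channel support); no surface/mesh
matching; greedy time-discretized descent rather than geodesic shooting;
the selector's window radius is a fixed model choice, not estimated from
data. At desk scale the registration uses few iterations — the acceptance
fixtures run a scaled-down configuration ($T=2$, two cascade stages, 4
iterations per stage) and the tests state so explicitly.
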