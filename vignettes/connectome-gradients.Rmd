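---
title: "Connectome gradients, group comparison, and transcriptomic association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradients, group comparison, and transcriptomic association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientscope)
```

# Overview

`gradientscope` implements a complete case–control analysis of cortical
connectivity gradients. The pipeline is:

1. **Connectomes.** Per subject, a region × region Pearson correlation
   matrix — either functional connectivity (FC) from region time series, or
   a morphometric similarity network (MSN) from five structural features
   (gray-matter volume, cortical thickness, surface area, intrinsic and mean
   curvature), each feature z-scored across regions before correlating
   region profiles.
2. **Gradients.** Each connectivity matrix is row-thresholded to its top
   10% of connections, converted to a nonnegative cosine-similarity
   affinity, and embedded by diffusion map embedding. Per-subject embeddings
   are aligned to a group template by iterative Procrustes rotation.
3. **Group statistics.** Gradient scores are averaged within seven canonical
   resting-state networks; groups are compared per network with pooled
   two-sample t-tests, BH-FDR correction, Cohen's d, and analytic
   noncentral-t power. Region-wise t statistics are standardized into a
   z-map.
4. **Transcriptomic association.** Single-response PLS regresses the z-map
   on region × gene expression; component significance uses a
   spatial-autocorrelation-preserving permutation test; gene contributions
   are stabilized by bootstrap (weight / bootstrap SE) and summarized by
   VIP, with hypergeometric over-representation of the VIP > 1 genes in
   gene sets.

A synthetic-cohort generator supplies every input with known ground truth,
so each claim the pipeline makes is testable without any imaging or
transcriptome data.

# The synthetic cohort model

Regions carry a latent coordinate $g_i$ evenly spaced on $[-1, 1]$,
representing the unimodal-to-transmodal axis; the seven networks occupy
contiguous blocks along it. The population region-pair correlation is

$$\mathrm{corr}(i, j) = c_0\, e^{-|g_i - g_j|/\ell} + c_1\,
\mathbf{1}[\text{same network}],$$

with unit diagonal. Because the exponential kernel is positive definite and
the block indicator is positive semidefinite, $c_0 + c_1 < 1$ makes the
matrix positive definite by construction; a nearest-PSD projection
(eigenvalue clipping plus rescaling to unit diagonal) backs up
parameterisations outside that region. Subject time series are multivariate
Gaussian draws from $(R + \sigma^2 I)/(1 + \sigma^2)$, so $\sigma \to 0$
recovers the population law exactly; no temporal autocorrelation is
modelled, since the downstream gradients depend only on the correlation
structure. The patient group's latent axis is
$g_i \cdot \kappa + s_{\mathrm{net}(i)}$ with compression factor
$\kappa \in (0, 1]$ and optional per-network shifts $s$.

## Why the defaults are what they are

* `n_regions = 400`, `n_networks = 7`, `n_timepoints = 140`,
  `n_controls = 74`, `n_patients = 72`: a standard 400-parcel cortical
  parcellation with the seven-network partition, a 150-volume resting-state
  run with the first 10 volumes discarded, and typical case–control group
  sizes for a single-site schizophrenia cohort.
* `corr_length = 0.8` (latent-axis units): connectivity profiles in cortex
  decay slowly along the hierarchy — neighbouring parcels share most of
  their connectivity. This choice also matters mechanistically. The
  embedding stage is invariant to uniform rescaling of the latent axis
  (top-k selection is rank-based and cosine similarity is scale-free), so a
  compressed axis is equivalent to a longer kernel length. With a long
  correlation length, compression pushes the patient group's profiles
  toward de-differentiation: affinity contrast between neighbours shrinks,
  sampling noise erodes the spectral gap of the diffusion operator, and the
  aligned principal gradient contracts — which is exactly the phenomenon of
  compressed hierarchical organization the generator is meant to emulate.
  With a short correlation length this de-differentiation route is absent
  and axis compression is nearly invisible to the pipeline.
* `corr_network = 0.05`: a small within-network elevation on top of the
  axis kernel. Values much larger make the top-10% neighbourhoods of a
  400-region cohort purely within-network, disconnecting the affinity graph
  into network blocks; 0.05 preserves a single connected graph at full
  scale while still marking network structure.
* `noise_sd = 0.8`: measurement noise comparable to the signal, typical of
  single-subject resting-state correlations; shared by the morphometry and
  expression generators.
* `n_genes = 200`, `n_signal_genes = 20`, `signal_beta = 2`: a planted
  association twice the SD of the spatially autocorrelated expression noise
  — strong enough that a working pipeline should recover most planted
  genes, weak enough that a broken ranking will not.
* `sa_length_scale = 20` with regions on an arc of radius 50 (arbitrary
  units): expression maps are smooth over roughly a fifth of the cortical
  extent, so map-to-map association tests genuinely need a
  spatial-autocorrelation-aware null.

Morphometry uses a fixed 5 × 2 loading matrix on the latent axis and a
second smooth axis ($\sin \pi g$) plus Gaussian noise, so nearby regions
have similar feature vectors and the MSN inherits the latent geometry.
Expression columns are the planted signal (`signal_beta` × standardized
difference map) plus a Gaussian field with covariance
$\exp(-d/\texttt{sa\_length\_scale})$ over the region coordinates, scaled by
`noise_sd`, then z-scored; column order is shuffled so signal genes are not
positionally identifiable.

What the generator does **not** emulate: hemodynamics, head motion, scanner
drift, parcellation error, subject-level anatomical variability, donor
effects in expression. Passing tests therefore demonstrate that the
statistical machinery behaves as claimed under its own assumptions, not
that those assumptions hold in any particular dataset.

# Numerical and design choices

* **Sparsification** keeps the $k = \lceil 0.10 (N-1) \rceil$ largest
  signed off-diagonal values per row; ties break toward the lower region
  index, for determinism. Negative correlations are not excluded first —
  top-k by signed value drops strong negatives naturally. The diagonal is
  stored as 0 so thresholding never selects self-connections.
* **Affinity** is cosine similarity of sparsified rows clipped below at 0.
* **Diffusion embedding** uses anisotropic normalization with
  $\alpha = 0.5$ and eigendecomposes the symmetric conjugate
  $D'^{-1/2} W' D'^{-1/2}$ of the Markov operator (real spectrum, stable),
  back-transforming eigenvectors. The trivial $\lambda = 1$ eigenvector is
  dropped; gradient $k$ is the unit-norm eigenvector scaled by
  $\lambda_k/(1-\lambda_k)$ (diffusion time 0). The variance fraction is
  defined as $\lambda_k / \sum_{\text{retained}} \lambda$ — an internal
  convention, asserted only for internal consistency.
* **Procrustes alignment** rotates centered embeddings (orthogonal, no
  scaling) onto the reference, updates the reference to the aligned mean,
  and iterates to a $10^{-8}$ mean-squared change; column signs are fixed
  to correlate positively with the reference. The template is built from
  the mean matrix over **all** subjects, treating groups symmetrically.
* **Group tests** are pooled-variance Student t (not Welch): the published
  per-network power values are reproduced exactly by pooled-df
  noncentral-t power at two-sided $\alpha = 0.05$, which pins down the
  convention, including the $\alpha$ itself. FDR is applied within each
  gradient's family of seven networks. The z-map uses the sample-SD
  convention.
* **PLS** is single-response deflation PLS (NIPALS-equivalent); with one
  response the component-1 weight has the closed form $X^\top y / \lVert
  X^\top y \rVert$, which doubles as an independent test oracle. Both the
  gene columns and the response are z-scored before fitting.
* **Surrogate maps** implement a variogram-matched permutation null: each
  surrogate is the source map's value multiset re-ordered by rank-matching
  against a Gaussian field (exponential kernel over region coordinates).
  The field's length scale is selected from a grid (plus one refinement
  pass) to minimize the relative error between surrogate and source binned
  semivariograms (10 bins), weighting short-distance bins more heavily
  (weights proportional to 1/bin), and each surrogate is redrawn (up to 40
  candidate fields) until its own variogram is within 10% weighted relative
  error of the source's, keeping the best candidate otherwise. Both details
  matter: short-range smoothness is what drives spurious map-to-map
  association, and without the redraw step surrogates are systematically
  rougher than the source at short distances — in either case the
  permutation test becomes anticonservative. For an unstructured source the selected scale collapses
  and surrogates reduce to plain permutations. Permutation p-values use the
  add-one rule and can never be 0.
* **Bootstrap gene weights** resample regions with replacement, refit, and
  sign-align each replicate's weights to the original fit by dot product
  (PLS weights are sign-indeterminate across refits). Degenerate resamples
  (zero-variance columns, rank collapse) are dropped; more than 10%
  dropped, or a zero bootstrap SE, is an error.
* **Enrichment** is threshold-based over-representation of the VIP > 1
  genes (hypergeometric upper tail, BH-FDR across sets) — matching an
  explicit selection threshold rather than a ranked-list statistic.

# Simulation scales used by the test suite

Replicate-ensemble checks (compression recovery, null calibration, gene
recovery) run at 100 regions, 12 + 12 subjects, 140 timepoints, 150 genes
(15 planted), with row density 0.15 — at 100 regions a 10% threshold
retains too few edges to keep the cosine affinity graph reliably connected,
so the reduced-scale runs use the next denser setting. Single-run checks
use the full 400-region, 74 + 72-subject default, which completes in
seconds. The test suite asserts, among others: exact agreement of the
embedding with a dense eigensolver oracle on small graphs; recovery of
random orthogonal rotations by the alignment; type-I calibration of the
per-network q-values and of the SA-corrected permutation test under the
null; recovery of the compressed principal-gradient range, of the planted
signal genes, and of the planted pathway.

# Known limitations

* The variance-explained convention ($\lambda$-ratio) is one of several in
  use; absolute percentages are not comparable across conventions.
* The surrogate null preserves the source map's empirical variogram, not
  its full spatial covariance; strongly anisotropic autocorrelation would
  need a richer null.
* Network-level inference uses subject-level network means; region-level
  pooling would weight networks by size.
* A focal group perturbation propagates through the embedding (alignment
  and eigenvector structure redistribute it), so secondary networks can
  show genuine, if smaller, group differences — selectivity of the
  per-network test is best judged by effect ranking, not by an empty
  complement set.
* Covariate adjustment (age, sex, motion) is out of scope.
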