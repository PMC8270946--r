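---
title: "Intrinsic manifolds of brain-state dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic manifolds of brain-state dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During sleep, the brain moves through discrete global states (wakefulness,
NREM stages N1–N3) that electrophysiologists score from EEG. The question this
package addresses is whether those states are recoverable from fMRI alone:
does the high-dimensional BOLD signal live, at any moment, on a
low-dimensional *intrinsic manifold* on which brain states occupy separable
regions? `imanifold` implements the full analysis chain that answers this:
phase-coherence dynamics, nonlinear spectral embedding, cross-subject
alignment, linear decoding, and surrogate-based inference — plus a synthetic
generator that makes every stage testable without clinical data.

# The pipeline, stage by stage

## Band-pass filtering and instantaneous phase

Regional BOLD series are filtered to the ultraslow band 0.04–0.07 Hz with a
sixth-order Butterworth filter applied forward and backward
(`signal::filtfilt`), so the filter has zero phase response and cannot bias
the phase estimates that follow. `filter_order = 6` is the *overall* band-pass
order (the design doubles the prototype order, so the prototype has 3 pole
pairs); the order must therefore be even. Each region is mean-centered and
its instantaneous phase $\theta_i(t)$ taken as the argument of the analytic
signal, built by the standard frequency-domain construction (positive
frequencies doubled, negative zeroed).

Two practical notes. First, zero-phase filtering at these very low normalized
frequencies is numerically benign here (passband gain verified to $<10^{-5}$
relative error); a second-order-section implementation was considered and not
needed. Second, no samples are dropped by default: edge TRs and TRs near
stage transitions carry filter/Hilbert artifacts (the impulse response spans
roughly $1/\Delta f \approx 33$ s $\approx 16$ TRs), and the decoding results
must be read with that smear in mind. A `trim_trs` option exists for callers
who prefer to discard edges.

## Coherence states and the CCD matrix

At each TR the phase-coherence matrix has entries
$\cos(\theta_i(t) - \theta_j(t))$; its strict upper triangle in row-major
order is the coherence vector $V(t)$, the brain's synchrony state at time
$t$ (the constant unit diagonal is excluded — it would only rescale norms).
The coherence connectivity dynamics matrix is the cosine similarity between
states for every pair of timepoints:

$$\mathrm{CCD}(t_i, t_j) = \frac{V(t_i) \cdot V(t_j)}{|V(t_i)|\,|V(t_j)|}.$$

No temporal windowing is involved; each column of the CCD is a feature vector
describing how one instant relates to every other instant.

## Graph construction: the relaxed minimum spanning tree

Similarities become distances, $d(t_i,t_j) = 1 - \mathrm{CCD}(t_i,t_j)$, and
the T timepoints are connected into a sparse graph. A minimum spanning tree
guarantees connectivity with minimal total weight but is too sparse to
represent the data's local geometry; k-nearest-neighbor graphs are sensitive
to sampling inhomogeneity. The relaxed MST interpolates: starting from the
MST (deterministic Kruskal; ties broken lexicographically on
(weight, i, j)), a non-tree pair $(i,j)$ is added as an edge when

$$mw_{ij} + \gamma\,(d_i^{k} + d_j^{k}) > d_{ij},$$

where $mw_{ij}$ is the largest edge weight on the tree path between $i$ and
$j$ and $d_i^{k}$ is node $i$'s distance to its $k$-th nearest neighbor
(default $k_{\text{local}} = 1$, the nearest neighbor — the concrete reading
of the rule as usually stated; the parameter is exposed because the defining
inequality is stated for a general $k$). $\gamma = 3$ relaxes the admission
threshold; $\gamma = 0$ recovers exactly the MST by the cycle property.
Candidates are examined in ascending distance and each node accepts at most
$k_n = 5$ relaxation edges; mandatory MST edges do not count against the cap,
since connectivity cannot be budgeted away. The candidate ordering is this
package's tie-break choice; the construction leaves it open.

$mw_{ij}$ for all pairs is computed from the Kruskal merge order (when an
edge of weight $w$ joins two components, $w$ is the path maximum for every
cross pair), which is $O(T^2)$ overall and avoids per-pair path searches.

## Laplacian eigenmaps and the PCA baseline

With binary adjacency $A$ on the RMST edge set (the default — the procedure prunes and then forms the graph Laplacian, with no
canonical weighting; a similarity-weighted option `laplacian_weighting = "similarity"`
is provided), the combinatorial Laplacian is $L = D - A$. The embedding
coordinates are the eigenvectors of $L$ for the $d$ smallest non-trivial
eigenvalues (the constant eigenvector at $\lambda_0 = 0$ is dropped; a second
near-zero eigenvalue is an error, the graph being disconnected). Eigenvector
sign is fixed by making each column's largest-magnitude entry positive, so
runs are reproducible. A dense symmetric eigensolver is used at all sizes:
the study scale ($T \approx 1500$) is comfortably dense, and no iterative
sparse symmetric eigensolver for smallest eigenvalues is among this package's
dependencies.

The linear baseline is PCA on the filtered region-by-time matrix with
timepoints as observations (`pca_embedding`), exactly the comparison the
manifold method is meant to beat: if stage structure were linearly embedded
in BOLD amplitudes, PCA would find it.

The headline embedding dimension is $d = 7$. `estimate_intrinsic_dimension()`
reproduces the estimation logic: sweep $d$, collect decoding-accuracy samples
per dimension, and report the smallest $d^\ast$ such that every larger
dimension is statistically indistinguishable from it (two-sided Wilcoxon
rank-sum, Benjamini–Hochberg FDR at $\alpha = 0.05$).

## Cross-subject alignment

Per-subject embeddings are aligned by full Procrustes analysis on landmarks:
for each stage, the two timepoints with minimal and maximal Euclidean norm
(ties broken by earliest TR). The transform (orthogonal matrix with
reflections allowed, isotropic scale, translation) minimizing the Frobenius
misfit on corresponded landmarks is the closed-form SVD solution; it is
fitted on landmarks only and applied to the whole point cloud. Reflections
are permitted deliberately: eigenvector sign flips make them physically
meaningless differences between subjects. The default reference is subject 1;
a generalized-Procrustes mode (`method = "gpa"`, iterate to the landmark
mean) is provided as the better-conditioned alternative.

One identification caveat the tests make explicit: $2S$ landmarks ($S$
stages) span at most $2S - 1$ dimensions after centering, so the rotation is
only fully determined when $d \le 2S - 1$. With two stages and $d = 4$ the
landmark fit can be perfect while the cloud alignment is arbitrary on the
unexplored subspace.

## Decoding

All classifiers are linear soft-margin SVMs (`e1071::svm`, `C = 1`, no
internal feature scaling — scaling would break rotation invariance of the
embedding space). Nonlinearity is the manifold's job, not the classifier's.

* **1-vs-1**: 10-fold cross-validation per stage pair, folds stratified
  within stage. Fold assignment is random by default with a fixed seed;
  `fold_scheme = "contiguous"` is available because filtering-induced
  autocorrelation makes interleaved folds optimistic (see the surrogate
  section below, where this matters).
* **1-vs-all multi-class**: per fold, one binary SVM per stage plus a
  monotone logistic (Platt-style) map from decision values to posteriors,
  fitted on training scores only (a deterministic `glm` fit; the libsvm
  internal posterior fit has uncontrolled randomness); prediction is the
  argmax posterior. Accuracy is trace(confusion)/total.
* **Leave-one-subject-out**: per round, the 1-vs-all ensemble trains on all
  other subjects' aligned coordinates and tests on the held-out subject; a
  test stage absent from training counts as errors.
* Averaged pairwise accuracies carry the combined uncertainty
  $e = \frac{1}{m}\sqrt{\sum_i e_i^2}$.

## Surrogate significance and ROC

The null model is the phase-randomized surrogate: one uniform phase shift per
positive frequency bin added to *every* region's spectrum (conjugate symmetry
enforced, DC untouched, Nyquist sign-flipped for even lengths), inverse
transformed to a real series. Each surrogate is pushed through the full
pipeline — filter, phase, CCD, RMST, eigenmaps, SVM — and the Monte-Carlo
p-value is

$$p = \frac{\#\{i: a < a^i_{\mathrm{perm}}\} + 1}{N_{\mathrm{perm}} + 1},$$

with ties favoring the observed value. A cheaper mode that reuses parts of
the observed-data embedding was considered and rejected: it answers a
different question, and no unambiguous definition of "partial re-use" exists.

What should one expect of the null? The common shift preserves each region's
amplitude spectrum *and all cross-spectral relations*; the surrogate is the
original multivariate series passed through one random all-pass filter. Its
coherence trajectory is therefore still a smooth, narrowband trajectory — by
design, since this null exists to capture exactly the clustering that
filtering alone induces. Under within-stage k-fold cross-validation a linear
SVM decodes *any* such smooth trajectory well above naive chance (temporal
neighbors of each test point sit in the training set); in our synthetic
experiments surrogate accuracies concentrate around 0.6–0.8, matching what
structure-free noise manifolds score, not 0.5. The inference is valid because
the observed accuracy is ranked against this *matched* null, not against
0.5. Two practical consequences, verified in the tests: the observed-vs-null
margin is largest when recordings are realistically noisy (in-band SNR near
1; nearly noiseless trajectories are perfectly memorizable and the null
saturates), and a naive "surrogates decode at 50%" expectation is wrong for
this construction.

ROC analysis sweeps a decision threshold along one embedding dimension over
all midpoints between consecutive sorted scores, integrates TPR over FPR by
trapezoid, auto-orients so AUC ≥ 0.5, and `best_dimension_roc()` scans the
leading dimensions (default 3) reporting the best, ties to the lowest index.

# The synthetic generator

The study's clinical recordings are not redistributable, so the generator
plants the *property the method measures* — stage-dependent pairwise phase
locking — in a Kuramoto phase model:

$$d\theta_i = 2\pi f_i\,dt
  + K \sum_j A^{s(t)}_{ij} \sin(\theta_j - \theta_i)\,dt
  + \sigma_\theta\,dW,$$

observed as $\cos\theta_i(t)$ plus Gaussian noise. The coupling matrix
$A^{s(t)}$ switches between per-stage templates according to a hypnogram-like
label track. Defaults, chosen once for realism:

| parameter | default | rationale |
|---|---|---|
| regions $N$ | 20 | desk-scale stand-in for a 90-area parcellation |
| TR | 2.08 s | the study's sampling interval |
| $f_i$ | Uniform(0.04, 0.07) Hz | the analysis band |
| templates | block-diagonal, blocks of 5, stage-specific permutation | distinct synchrony pattern per stage |
| $K$ | 1 | well above the within-block locking threshold, stable under Euler steps of TR/10 |
| dwell | 150 TRs (~5 min) | consolidated NREM bouts; see below |
| $\sigma_\theta$ | 0.05 rad/$\sqrt{s}$ | mild within-stage variability |
| observation noise | 0.1 | low-noise default; 1.0 gives in-band SNR ≈ 1, typical of real BOLD |
| Euler substeps | 10 per TR | adequate at these frequencies; raise for $K \gtrsim 5$ |

Hypnograms are geometric-dwell runs (memoryless, contiguous, no immediate
repeats) with deterministic, bounded regeneration when coverage or a
requested per-stage minimum is not met. The dwell default matters more than
it may seem: every stage transition contaminates roughly 16 TRs of phase
estimates (the filter's impulse-response width), so short-bout tracks put
most timepoints inside transition smear and cap decodability — with 150-TR
bouts, transitions cost under 10% of samples, which is also the realistic
regime for consolidated sleep.

What the generator does **not** emulate: hemodynamic response convolution,
scanner drift and physiological artifacts, REM, inter-regional conduction
delays, and — important for interpreting the group analysis — the strong
cross-subject stereotypy of real functional anatomy. Passing tests on this
generator show the pipeline recovers planted phase-coupling structure; they
do not show the pipeline works on any particular scanner's data.

# Design choices on genuinely open points

* **Diagonal excluded from $V(t)$** — constant ones only rescale norms.
* **Vectorization order** fixed to row-major upper triangle; cosine
  similarity is order-invariant but reproducibility demands one order.
* **$k_{\text{local}} = 1$** in the RMST relaxation term (the explicit
  nearest-neighbor statement), exposed as a parameter.
* **$k_n$ caps relaxation edges only**; MST edges are mandatory.
* **Binary Laplacian adjacency** by default; similarity weighting optional.
* **Eigenvector sign convention**: largest-magnitude entry positive.
* **Procrustes with reflections**, reference subject 1, GPA optional.
* **Random stratified folds** with fixed seed by default; contiguous
  alternative exposed.
* **Platt calibration as logistic GLM** on training decision values.
* **No class reweighting** by default.
* **Hypnogram retry seeds** advance by a fixed stride so that near-identical
  base seeds cannot collapse onto the same accepted track.

# Known limitations

* TRs near stage transitions are systematically mislabeled by the smooth
  phase estimates; accuracy is a property of the (data, hypnogram) pair, not
  the classifier alone.
* Cross-subject alignment by 2-per-stage landmarks assumes the per-subject
  eigenmap modes correspond geometrically. For independently simulated
  subjects that assumption fails (each subject's manifold is shaped by its
  own bout sequence) and leave-one-subject-out decoding sits near chance
  even under shared coupling templates; the alignment machinery is verified
  instead on rotated/scaled copies of one embedding, where the ground-truth
  transform is known. Real recordings may or may not provide the stereotypy
  the group analysis needs — that is an empirical question outside the
  synthetic model.
* The rotation is unidentified when $d > 2S - 1$ (landmark rank).
* The dense eigensolver is $O(T^3)$; beyond $T \sim$ a few thousand an
  iterative solver would be needed.
* Test and example problem sizes (T = 120–800, N = 10–20, 99 surrogates,
  4–5 subjects or seeds) are chosen to exercise every claim at desk scale;
  they are smaller than the study scale (T ≈ 1505, N = 90, 18 subjects,
  1000 surrogates), which the same code handles in proportionally longer
  runs.
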