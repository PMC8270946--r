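# imanifold

Brain activity measured with fMRI is high-dimensional — one time series per
brain region — yet global brain states such as wakefulness and the NREM sleep
stages N1–N3 are few and discrete. `imanifold` implements an analysis
framework built on the hypothesis that the momentary state of the brain lives
on a low-dimensional *intrinsic manifold*: a nonlinear embedding of
instantaneous synchrony patterns on which those states become linearly
separable, decodable with nothing more than a linear SVM.

The package is written for computational neuroscientists and methods
developers who want the full chain as composable, deterministic, tested R
functions — and for anyone who wants to study the method's behavior under
controlled conditions using the built-in synthetic generator, since clinical
sleep-fMRI recordings are rarely redistributable.

## The method

For one subject with parcellated BOLD series (N regions × T timepoints,
repetition time TR):

1. **Band-pass** each region to the ultraslow band 0.04–0.07 Hz
   (sixth-order Butterworth, zero-phase forward–backward application) and
   take the **instantaneous phase** θᵢ(t) of the analytic signal.
2. **Coherence states.** At each TR, the phase-coherence matrix
   cos(θᵢ − θⱼ) is vectorized (upper triangle) into the coherence vector
   V(t). The **coherence connectivity dynamics** matrix is the cosine
   similarity between all state pairs:
   CCD(tᵢ, tⱼ) = V(tᵢ)·V(tⱼ) / (|V(tᵢ)||V(tⱼ)|).
3. **Graph.** Distances d = 1 − CCD are pruned with the **relaxed minimum
   spanning tree**: all MST edges, plus any pair (i, j) satisfying
   mwᵢⱼ + γ(dᵢᵏ + dⱼᵏ) > dᵢⱼ
   (mwᵢⱼ = max edge weight on the MST path, dᵢᵏ = distance to the nearest
   neighbor; γ = 3, at most kₙ = 5 additions per node).
4. **Embedding.** The eigenvectors of the graph Laplacian L = D − A for the
   d smallest non-trivial eigenvalues give the **Laplacian-eigenmap**
   coordinates (d = 7 headline; PCA on the filtered series is the linear
   baseline).
5. **Group alignment.** Per-stage extreme-norm landmarks, full Procrustes
   (rotation + reflection, scale, translation) onto a reference subject.
6. **Decoding & inference.** Linear SVMs under stratified 10-fold CV
   (1-vs-1 and multi-class 1-vs-all with Platt-style posteriors),
   leave-one-subject-out for group analysis, phase-randomized surrogates
   (common spectral phase shift across regions, full pipeline re-run per
   surrogate) for Monte-Carlo p-values, Benjamini–Hochberg FDR, Wilcoxon
   rank-sum comparisons, and single-dimension ROC/AUC.

A Kuramoto-oscillator generator (`simulate_subject`) plants stage-dependent
phase coupling with hypnogram-like label tracks, providing ground truth for
every stage of the pipeline.

## Worked example

```r
library(imanifold)

# one subject: 20 regions, 800 TRs, four planted coupling regimes
sim <- simulate_subject(n_trs = 800, n_regions = 20, seed = 1)
print(sim$labels)
#> Stage labels: 800 TRs
#> Awake    N1    N2    N3
#>   309   173   179   139

config <- pipeline_config(seed = 1)     # band 0.04-0.07 Hz, gamma 3, d = 7
emb <- embed_timeseries(sim$ts, config)
print(emb$graph)
#> State graph: 800 nodes, 1652 edges ( 799 MST + 853 relaxed ), gamma = 3 , k_n = 5

dec <- crossval_1vall_multiclass(emb$le, sim$labels, seed = 1)
print(dec)
#> Decoding result (tenfold_1vall): accuracy = 91.0% over 10 folds/rounds
print(dec$confusion)
#>        pred
#> true    Awake  N1  N2  N3
#>   Awake   306   3   0   0
#>   N1       17 130  25   1
#>   N2       15  10 154   0
#>   N3        0   1   0 138

crossval_1vall_multiclass(emb$pca, sim$labels, seed = 1)
#> Decoding result (tenfold_1vall): accuracy = 38.6% over 10 folds/rounds

best_dimension_roc(emb$le, sim$labels, "Awake", "N3")
#> ROC: AUC = 1 (direction < ), best dimension = 2
```

The planted four-regime structure decodes at 91% on the 7-dimensional
manifold versus 39% for the PCA baseline (chance is ~25–39% depending on
stage balance), and wakefulness and deep sleep are perfectly separable along
a single manifold dimension (AUC = 1). Most residual confusions sit between
N1 and its neighbors — timepoints near stage transitions, where narrowband
phase estimates necessarily smear across the boundary.

`run_pipeline()` chains everything (multi-subject alignment, LOSO,
significance, serialized reports), and `inst/cli/imanifold.R` exposes
`simulate` and `run` subcommands for shell use:

```sh
Rscript inst/cli/imanifold.R simulate --out demo --subjects 2 --n-trs 400 --seed 1
Rscript inst/cli/imanifold.R run --ts demo/subject1.tsv,demo/subject2.tsv \
    --labels demo/subject1_labels.tsv,demo/subject2_labels.tsv \
    --tr 2.08 --out demo_report --seed 1
```

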