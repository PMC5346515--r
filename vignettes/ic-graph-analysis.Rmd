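---
title: "Building and comparing graphs from independent component networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing graphs from independent component networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icga)
```

## The problem

Independent component analysis (ICA) decomposes a resting-state BOLD fMRI
run into spatial maps and associated time-courses, and the resulting
intrinsic connectivity networks (default mode, auditory, salience, ...) are
usually compared voxel-wise on their z-maps. `icga` instead turns each
component into a *weighted graph* over an anatomical parcellation, so the
within-network organization can be quantified with standard graph measures
(edges, degree, triangles, small-worldness) and compared — per network —
against the "classical" whole-brain connectivity graph built from the full
artifact-cleaned signal.

## The model

Let $X$ be the $N \times P$ matrix of neuronal component time-courses and
$Y$ the $R \times P$ matrix of region-averaged BOLD signal over $R$
parcellation regions. For every region we solve the ordinary least-squares
regression

$$Y = X\beta + \varepsilon$$

with the component courses as predictors plus an intercept, and convert each
coefficient $\beta_{ij}$ into a t-statistic using the contrast vector that
selects component $i$:

$$t_{ij} = \frac{c_i^\top \beta_j}
  {\sqrt{\widehat{\sigma}_j^2 \; c_i^\top (D^\top D)^{-1} c_i}},
  \qquad \widehat{\sigma}_j^2 = \frac{\lVert \varepsilon_j \rVert^2}{\mathrm{DOF}},
  \qquad \mathrm{DOF} = P - N - 1 .$$

The intercept column is included in the design $D$ but not counted in $N$;
the $-1$ in the DOF rule is exactly that intercept. This is standard GLM
accounting and matches the printed DOF formula; whether the original
procedure demeaned instead of fitting an intercept is not stated, and the
two choices give identical t-values for the component contrasts.

### Edge weights

For one component with regional t-values $t_a$, the correlation-flavor edge
weight between regions $a$ and $b$ is

$$W_{a,b} = |t_a| + |t_b| - |t_a - t_b|,$$

which is $2\min(|t_a|,|t_b|)$ when the t-values share a sign and $0$
otherwise: an edge is strong when both regions load strongly, and with
similar sign, on the component. The complementary anti-correlation weight
$W^{AC}_{a,b} = |t_a| + |t_b| - |t_a + t_b|$ is nonzero exactly on
opposite-sign pairs, and $W + W^{AC} = 2\min(|t_a|,|t_b|)$ everywhere —
a decomposition the test suite checks on a dense sign grid.

### Thresholding

Edges are kept only when both endpoints are individually significant:
with $t_{thr} = t^{-1}(1-p,\ \mathrm{DOF})$ (default $p = .001$), an edge
survives iff $W_{a,b} \ge 2\,t_{thr}$, which is equivalent to
$\min(|t_a|,|t_b|) \ge t_{thr}$ plus the sign condition. Two remarks on
choices that were genuinely open:

* The source description of the rule ("discard edges above $2 t_{thr}$,
  $2 t_{thr}$ being the maximum value for $W$") is internally inconsistent,
  because $2 t_{thr}$ is the *minimum* weight an edge with two significant
  endpoints can have. We keep edges with $W \ge 2 t_{thr}$ — the only
  reading consistent with removing non-significant t-values. Ties at
  exactly the threshold are kept.
* The stated significance level ($p < .001$) and the stated "99th
  percentile" imply different cutoffs (0.001 vs 0.01). We honor the p-value
  and expose it in `pipeline_config(significance_p = ...)` so either can be
  requested.

### Group aggregation

Subject graphs are thresholded individually; a group edge is retained when
it is present in at least 25% of the subjects
(`presence_fraction = 0.25`; 4 of 15 subjects qualifies, 3 of 15 does not).
Group edge weights are not part of the method's definition, so the group
graph stores the canonical presence counts plus mean weights as a
convenience; all metric comparisons are computed per subject, so this
choice never affects the statistics.

### The classical network

The whole-brain reference network reconstructs the voxel signal as the
linear combination of the neuronal components weighted by their calibrated
spatial maps, region-averages it, and connects regions by the significance
of their pairwise Pearson correlation. The connectivity measure for this
network is not prescribed by the per-component weighting (which needs a
single component's t-values), so we use the standard $r \to t$ conversion
$t = r\sqrt{\mathrm{DOF}/(1-r^2)}$, threshold at the same $t_{thr}$, and
scale the weight as $2t$ to live on the same scale as the component-graph
weights. This is a documented stand-in, flagged as such.

### Template matching and neuronality

Components are assigned to named network templates by goodness-of-fit —
mean map value inside the binary template minus mean value outside (the
standard Greicius-style score) — and the assignment over all templates is
solved *simultaneously* as a maximum-weight one-to-one assignment (exact
dynamic programming over template subsets, feasible because template counts
are small). A template whose attainable scores are all non-positive is
reported absent. This optimal-assignment rule is our explicit stand-in for
the multiple-template procedure whose details live outside the method
description; greedy matching is provably never better, and the test suite
compares the solver against exhaustive search.

Neuronal/non-neuronal discrimination was originally a trained SVM on
component fingerprints; its training data is not available, so the
classifier is a pluggable interface. The built-in default labels a
component neuronal when more than half of its time-course spectral power
(DC excluded) lies in 0.01–0.1 Hz — the band-limited character of
resting-state signal — and is clearly non-canonical: any
`function(timecourse, tr_seconds) -> logical` can be supplied.

## Graph metrics

All metrics are computed on the binarized post-threshold graph after
removing isolated nodes (degree and triangle counts are integers by
nature; weights stay available in the outputs). The battery is: number of
edges $E$, average degree $k = 2E/n$, triangle count, average local
clustering coefficient $C$ (degree-0/1 nodes contribute 0), characteristic
path length $L$, and small-worldness

$$\sigma = \frac{C/C_{rand}}{L/L_{rand}},$$

with null values averaged over an Erdős–Rényi $G(n, m)$ ensemble matched on
node and edge counts (the Humphries–Gurney convention; the null family and
ensemble size are not prescribed by the source, so ER matched on $n$ and
$E$ with `n_random_nulls = 20` and an explicit seed is our documented
default; a degree-preserving rewiring null is a possible alternative we do
not implement). Triangle counts are likewise normalized by the ensemble
mean. On disconnected graphs $L$ is averaged over reachable pairs only and
the unreachable fraction is reported rather than returning an infinite
length.

Per-network comparisons against the classical network restrict both graphs
to the non-isolated node set of the network's group graph (network size
strongly affects topology), then compare the per-subject metric
distributions by one-way ANOVA followed by Tukey HSD (Tukey–Kramer for the
unbalanced group sizes that arise when a network is not detected in every
subject), flagging pairs at the 0.05 and 0.01 tiers. Whether subjects
should enter as a blocking factor (repeated measures) is unstated in the
source; one-way ANOVA is the literal reading and our default.

## Synthetic data: what it emulates, and what it does not

Because no test data ships with the method, `synthetic_config()` +
`simulate_cohort()` generate cohorts with known ground truth:

* component courses are band-limited Gaussian noise (Fourier-filtered to
  0.01–0.1 Hz at the configured TR), orthogonalized over the sample and
  scaled to unit variance — so sample correlations are exactly zero;
* regions mix the components through a known signed loading matrix plus
  white noise at a configured SNR (var(signal)/var(noise) per loaded
  region);
* optionally, the region courses are painted into a box-parcellated volume
  (geometry is irrelevant to every formula; only label bookkeeping
  matters), with spatial maps equal to the loadings.

The defaults are the validation cohort used throughout the tests: 15
subjects, 297 volumes at TR = 2 s (emulating a 300-volume acquisition with
3 discarded), 3 components over 60 regions in signed blocks of 20
(component $i$: +1 on block $i$, −1 on the next block), SNR 10. At these
settings each component's correlation graph should be exactly the two
planted block cliques and its anti-correlation graph the complete bipartite
graph between them — the end-to-end test asserts Jaccard 1.0 against this
truth at the group level.

The generator deliberately omits hemodynamic response convolution, motion
and physiological artifacts, and spatial autocorrelation: the graph-building
method consumes only the second-order structure of the signal, so passing
these tests validates the pipeline's arithmetic and logic, not its
robustness to realistic noise. Sizes were chosen so the whole suite runs in
well under a minute of simulation per cohort: 60 regions keep the $R \times
R$ matrices readable while preserving the block combinatorics; nothing in
the code restricts $R$ (a 1,015-region label fixture is exercised in the
I/O tests).

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7)          # 15 subjects, 3 components
thr <- compute_t_threshold(cfg$n_timepoints - cfg$n_components - 1, 0.001)

graphs <- lapply(seq_len(cfg$n_subjects), function(s) {
  sub <- simulate_subject(cfg, s)
  tv <- fit_glm(sub$series, sub$ic)
  build_subject_graph(tv, "IC01", "correlation", t_threshold = thr)
})
gg <- aggregate_group(graphs, presence_fraction_min = 0.25)
compute_metrics(gg, "IC01", n_random = 20, seed = 7)
```

## Numerical choices and degenerate inputs

* Exact fits (zero residual variance) produce infinite t-values; they are
  flagged, excluded from graph construction with a warning, and never
  silently clipped. Constant regions are dropped with a warning.
* Rank-deficient designs (collinear components) are a hard error naming the
  offending columns.
* Label volumes must already sit on the image's voxel grid; mismatched
  grids are a hard error because silent resampling would hide
  misalignment that is supposed to be fixed upstream by coregistration.
* All dense matrices: at $R \approx 1000$ an $R \times R$ double matrix is
  ~8 MB, which needs no sparsity machinery.
* Determinism: every stochastic step (synthetic draws, null ensembles)
  takes an explicit seed, and rerunning a pipeline with the same config and
  seed produces byte-identical outputs.

## Limitations

* The neuronality classifier and the template-assignment rule are
  documented stand-ins for procedures whose exact definitions are external
  to the method description; both are pluggable.
* The classical network's connectivity measure is our correlation-to-t
  construction, not a verified replication.
* Graph metrics are computed on binarized graphs; weighted variants are
  not offered.
* The synthetic cohort validates logic, not biophysics (see above).
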