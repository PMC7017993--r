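---
title: "Fractal dimension of functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal dimension of functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Resting-state fMRI yields, for each subject, a table of BOLD time-series —
one per cortical region of interest (ROI). A standard summary of such data
is the functional connectivity graph: nodes are ROIs, edges join pairs whose
signals are strongly correlated. `fdconn` quantifies the *multi-scale
structure* of that graph (and of the underlying signals) with three fractal
dimension estimators, and compares them across clinical groups with
nonparametric statistics. Higher fractal dimension means that coarse-graining
the system removes detail quickly — a signature of heterogeneous,
multi-scale organization; lower values arise for fragmented or structureless
systems. In disorders-of-consciousness cohorts these measures order
clinical severity, which is the analysis this package operationalizes
end-to-end on data you supply or synthesizes for validation.

# From time-series to a binary graph

`correlation_matrix()` computes all pairwise Pearson correlations
\(M_{ij} = \rho(F_i(t), F_j(t))\) and zeroes the diagonal so the matrix can
be read as the adjacency matrix of a simple graph (no self-loops).
Zero-variance ROIs (regions with no detectable signal) make the Pearson
correlation undefined and must be removed first by `drop_dead_rois()`; the
criterion is zero variance, not all-zero signal, since any constant series is
equally degenerate.

`threshold_binarize()` keeps the strongest pairs: with \(R\) ROIs and
\(E = R(R-1)/2\) candidate pairs, the top
\(\lfloor (1 - q/100)\,E \rfloor\) correlations become edges (default
\(q = 95\), i.e. the strongest 5%). Three deliberate choices:

* **Exact rank selection, not an interpolated quantile.** The edge count is
  then deterministic and identical to percentile thresholding except exactly
  at ties, which rank selection resolves by stable row/column order — a
  reproducibility requirement.
* **Signed ranking, negatives discarded after selection.** Correlations are
  ranked signed (no absolute value); any *retained* negative value is then
  dropped. With a 95% threshold this rarely matters — the top 5% of a
  correlation distribution is almost always positive — but the order of
  operations is part of the contract.
* **Per-subject thresholds.** Each subject's matrix is thresholded on its own
  distribution. This is an assumption (a pooled threshold is also
  conceivable); per-subject thresholding keeps subjects exchangeable and
  edge counts fixed, which the null models rely on.

# Network fractal dimension: Compact Box Burning

The box-counting dimension of a graph comes from covering it with *boxes* —
node sets with pairwise hop distance \(< l_B\) — and watching how the minimum
box count \(N_B\) scales: \(N_B(l_B) \propto l_B^{-d_B}\). Finding the true
minimum covering is NP-hard, so `cbb_cover()` implements the stochastic
Compact Box Burning heuristic: grow each box by uniform random draws from the
shrinking set of nodes compatible with every current member, and
`covering_number()` takes the minimum over `restarts` independent coverings
(default 10 — the box-covering literature stabilizes the heuristic with
minima; on all graphs small enough for the exhaustive
`exact_covering_number()` oracle, 50 restarts recover the true optimum in
our tests).

`network_fd()` sweeps integer \(l_B\) from 1 to 10 (the resolution a
1000-node graph supports), enforces monotone \(N_B\) by a running minimum —
covering numbers are mathematically non-increasing in \(l_B\), but
independent stochastic runs can jitter — and fits \(\ln N_B\) on
\(\ln l_B\) by ordinary least squares; \(d_B\) is the negated slope. Two
conscious choices:

* The regression spans the full range 1..10 *including* the \(N_B = 1\)
  plateau once the box size exceeds the diameter. This matches the standard
  protocol at this graph scale; `drop_plateau = TRUE` exposes the
  sensitivity of the estimate to that choice.
* Distances are unweighted hop counts (BFS); nodes in different components
  are infinitely distant and never share a box, so \(N_B\) plateaus at the
  component count rather than 1 in fragmented graphs — this is exactly why
  fragmentation lowers \(d_B\).

This estimator is *not* a rigorous power-law inference: ten scale points
cannot support maximum-likelihood power-law fitting, and no claim of true
scale-freeness is attached to the fitted exponent. The number is a
descriptive multi-scale summary that is nonetheless sensitive enough to
order experimental groups. Note also that dense unstructured graphs collapse
to \(N_B = 1\) within two or three steps and therefore get *steep* log-log
slopes (a 1000-node complete graph gives \(d_B \approx 2.16\) by closed-form
OLS; dense \(G(n,m)\) graphs give \(\approx 3.4\)): a high \(d_B\) alone is
not evidence of fractal organization — the fit diagnostics (`r.squared`,
the \(N_B\) profile) must be read alongside it.

# Adjacency-matrix (image) dimension

`matrix_fd()` treats the adjacency matrix as a binary image (one pixel per
entry, `adjacency_image()`) and runs classic 2-D grid box counting: for each
grid origin and box side \(\epsilon\), count occupied cells; instantaneous
slopes \(-\Delta\ln N / \Delta\ln\epsilon\) between consecutive sizes give a
lower and upper bound (their min and max across origins and sizes), and the
reported dimension is the mean of the two bounds — the convention of batch
image fractal analysis tools. Defaults are frozen in code: box sides are
powers of two from 2 up to a quarter of the image side, with the four image
corners as grid origins. Images are written losslessly (PNG) — a lossy
format would corrupt the 0/1 field that is being counted. On exactly
self-similar images with divisor-aligned grids the bounds collapse onto the
analytic dimension (the level-5 Sierpinski carpet returns
\(\ln 8/\ln 3\) to machine precision with sizes \(3^k\)).

# Higuchi temporal dimension

`higuchi_fd()` implements the Higuchi curve-length estimator: for each
coarse-graining interval \(k\) and offset \(m \le k\), the decimated series
\(x_m, x_{m+k}, \ldots\) has length
\[
L_m(k) = \Big(\sum_i |x_{m+ik} - x_{m+(i-1)k}|\Big)
\frac{N-1}{\lfloor (N-m)/k \rfloor\, k}\cdot\frac{1}{k},
\]
and \(\langle L(k)\rangle \propto k^{-D}\) defines \(D\), again via OLS on
the log-log points. The \(k\) grid is *all* integers 1..`k_max` (default
64), the convention of the widely used reference implementations, rather
than Higuchi's original log-spaced subsampling. Intervals where some offset
leaves an empty decimated series (\(N < 2k\)) are dropped with a warning.
The estimate is affine-invariant by construction and recovers the analytic
values on test signals: exactly 1 for a linear ramp, \(2 - H\) for
fractional Brownian motion, 2 for white noise.

No upper clamp at 2 or lower clamp at 1 is applied: short, strongly
low-pass-filtered series can legitimately produce estimates below 1, and
truncation effects can push them above 2. `truncate_series()` supports
equalizing scan lengths between conditions before comparison, since \(D\)
estimates are length-sensitive.

A Hilbert-envelope preprocessing path (`hilbert_envelope()`, or
`higuchi_fd(..., hilbert = TRUE)`) is provided but **off by default**: BOLD
pipelines sometimes analyse the analytic-signal magnitude rather than the
raw series, and the two choices give systematically different dimensions.
Both paths are exposed; neither is asserted as canonical. Per-subject
reduction is the mean over ROI-level dimensions (`higuchi_subject()`), with
the full per-ROI table always returned so other reductions remain possible.

# Null models

`ring_lattice()` (node degree \(2D\), circulant) and `random_gnm()`
(uniform simple graph with an edge count matched to the thresholded
empirical graphs) bracket the order/disorder spectrum;
`null_fd()` batch-runs the network estimator over replicates with derived
substreams and reports the replicate distribution. "D-dimensional lattice"
is ambiguous between a ring with \(2D\) neighbours and a hypercubic grid;
the ring is the default reading and `grid_lattice()` provides the other.
The battery reproduces the *procedure* of null-model comparison; since the
estimator conventions behind historical printed null values cannot always be
recovered, replicate distributions from this package should be compared
within-package, not against external absolute numbers.

# Nonparametric statistics

`compare_groups()` composes the statistics stage: medians with interpolated
quartiles, the tie-corrected Kruskal-Wallis omnibus test (chi-squared
p-value), pairwise Mann-Whitney U tests and Benjamini-Hochberg FDR control
at \(q = 0.05\) across the pairwise family — the narrowest defensible
family, applied within one measure. The U statistic is reported in the
\(\min(U_{ab}, U_{ba})\) convention with ties counted half, exact p-values
for small tie-free samples and the tie-corrected normal approximation
otherwise. Computations delegate to R's `stats` machinery
(`kruskal.test`, `wilcox.test`, `p.adjust`, `cor.test`); the tests validate
them against direct rank-formula evaluation and exhaustive permutation
enumeration at small N. `ingest_supplementary()` maps externally deposited
per-subject tables (arbitrary column headers, via a schema map) into this
stage without code changes.

# The synthetic cohort generator

No raw clinical fMRI ships with (or is downloadable by) this package, so
`simulate_cohort()` provides the study bed. It emulates what the analysis
actually relies on: multi-subject groups of ROI time-series with
hierarchical-modular correlation structure and a single group-level knob
that monotonically degrades between-module integration.

ROIs are leaves of a balanced tree (default branching 4, depth 4, so 256
ROIs); two ROIs separated by \(u\) tree levels correlate at
\(w^{1 + (u-1)/s}\) with \(w = 0.9\) and group effect \(s \in (0,1]\).
The division by \(s\) is the essential design choice: at \(s = 1\) the
correlation bands of successive hierarchy levels lie close together, so
finite-sample noise (150 time points) mixes levels and the thresholded
graph keeps integrative between-module edges — small effective diameter,
fast covering decay, high \(d_B\). As \(s\) shrinks the bands separate, the
top-5% edges retreat inside modules, the graph fragments, \(N_B\) plateaus
at the component count, and \(d_B\) falls. One scalar thus yields the
monotone structure degradation the group comparison is validated against.
Defaults — groups of 15/10/8 subjects, effects 1.0/0.6/0.3, 256 ROIs, 150
time points, AR(1) smoothing 0.3 — were calibrated once so that the median
\(d_B\) ordering follows the effect ordering in at least 90% of seeded
replicates, then frozen.

What the generator does *not* emulate: haemodynamics, scanner noise
spectra, head motion, atlas geometry, or the empirical magnitudes of
clinical fractal dimensions. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline detects monotone connectivity degradation at
realistic sample sizes — not that it reproduces any particular clinical
value. Analytic validation (flower graphs, fBm, the carpet) is what pins
the estimators themselves.

`uv_flower()` supplies graphs of known dimension \(\ln(u+v)/\ln u\)
(generation 0 is a single edge, making the edge count \((u+v)^g\) exact);
`fbm()` supplies exact fractional Brownian paths via circulant embedding of
the fractional Gaussian noise covariance — exact, not approximate, because
the Higuchi tolerances assume the true covariance. If the embedding is ever
numerically non-PSD, negative eigenvalues are clipped with a warning.

# Reproducibility and numerics

Every stochastic routine accepts a `seed` and restores the caller's RNG
state; batch routines derive per-(unit, box size, restart) substreams from
the master seed by a counter scheme, so results are independent of
evaluation order and bit-reproducible (`run_pipeline()` writes the seed and
a config fingerprint into every output's metadata). Degenerate inputs fail
fast with classed conditions (`fdconn_degenerate`, `fdconn_parse_error`,
...) rather than propagating NaNs: constant signals, empty foregrounds,
all-dead ROI sets and single-group comparisons are errors, while an empty
post-threshold edge set is a warning plus an edgeless graph (dimension 0).

Problem sizes in the test-suite were chosen to keep the full suite within a
couple of minutes on one core while preserving the properties under test:
the flower oracle uses generation 6 (2732 nodes, estimate within 25% of the
analytic 2 — box counting converges slowly, so finite-size bias of this
order is expected and calibrated once against the exact construction);
null-model concentration uses 200-node graphs in tests and the full
1000-node, 50-replicate battery in the acceptance script; Higuchi asymptotic
checks use \(2^{14}\)-sample signals averaged over 20 seeds.

# Known limitations

* CBB is a heuristic; the reported \(N_B\) is an upper bound on the true
  covering number. Restarts tighten it, with diminishing returns.
* Ten box sizes cannot certify power-law scaling; \(d_B\) is comparative,
  not an absolute fractal claim, and is meaningful only alongside its fit
  diagnostics.
* The adjacency-image dimension depends on node order (it is not a graph
  invariant), inherits the ROI ordering of the input table, and is the less
  discriminative of the two graph measures — it is kept as a cross-check.
* Higuchi estimates on short (~150-sample), low-frequency series are biased;
  only within-study comparisons at equal length are supported
  (`truncate_series()`).
* The group-effect knob is a one-parameter abstraction of connectivity
  degradation; it makes no claim of biophysical realism.
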