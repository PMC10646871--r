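---
title: "Euler characteristic curves and profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euler characteristic curves and profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EulerProfiles)
```

## The invariant

A filtered cell complex assigns to every cell $\sigma$ an entry value
$f(\sigma)$, monotone on faces, so that the sublevel sets
$K_t = f^{-1}(-\infty, t]$ are nested subcomplexes. The Euler
characteristic curve is $ECC(K, t) = \chi(K_t)$ with
$\chi = \sum_d (-1)^d |K^d|$; for a filtration indexed by
$p \in \mathbb{R}^n$ the Euler characteristic profile is
$ECP(K, p) = \chi(K_p)$. Because $\chi$ is an alternating count, the
whole function is determined by the multiset of *contributions*
$(f(\sigma), (-1)^{\dim \sigma})$: the value at $t$ (or $p$) is the sum
of the deltas at locations $\le t$ (coordinate-wise $\le p$).

Everything in this package flows through such contribution lists,
stored as plain data frames with columns `f1..fn, delta` and
canonicalized by `aggregateContributions()`: exact-duplicate locations
are merged, cancelled locations dropped, and the result sorted
lexicographically. Grouping uses **exact floating-point equality** — a
deliberate choice. Duplicate filtration values arise from identical
arithmetic (the same pairwise distance, the same voxel minimum); a
numerical tolerance would make aggregation dependent on the encounter
order and break the determinism contract (identical input and seed give
byte-identical output regardless of worker scheduling).

Curves are right-continuous: a cell with $f(\sigma) = t$ belongs to
$K_t$, so `ecAt()` returns the value at the largest jump $\le t$
(binary search via `findInterval`) and 0 before the first jump, where
the sublevel complex is empty.

## Vietoris–Rips engine

For a pointcloud $X$ and a scale bound, the Vietoris–Rips complex
contains every vertex subset whose *diameter* (longest pairwise
distance) is within the bound, filtered by diameter. The user-facing
`threshold` bounds the diameter directly and the filtration value *is*
the diameter, with vertices entering at 0. The literature sometimes
parameterizes the same complex by a radius $\epsilon$ with diameter
$\le 2\epsilon$; exposing the diameter avoids that factor-of-two
ambiguity, and the CLI help states the convention.

The engine never materializes the complex. Given a vertex ordering,
vertex $i$ owns exactly the simplices whose minimal vertex is $i$. Its
*local graph* holds the subsequent neighbors ($j > i$, within the
threshold) and their pairwise distances; the owned simplices are
enumerated breadth-first, one dimension per level: every simplex keeps
its vertex set, its filtration (diameter so far) and its *extendables*
(common subsequent neighbors of all its vertices), and is extended by
each extendable vertex in turn, updating the filtration with the
longest new edge and intersecting the extendables with the new vertex's
subsequent neighbors. Each simplex appears exactly once, in sorted
vertex order; breadth-first (rather than depth-first) expansion keeps
the per-level memory bounded by the widest layer of the local simplex
tree. The per-vertex tasks share no mutable state, so any scheduler may
run them (`workers` uses `parallel::mclapply`); the aggregated result
is invariant to the worker count and to the ordering.

The `ascending_degree` ordering sorts vertices by their number of
in-threshold neighbors (ties by original index). Since each vertex only
looks *forward*, putting hubs last removes them from most local graphs
and equalizes the local tree sizes — the total number of simplices is
unchanged, but the largest per-vertex task shrinks, which matters when
the tasks run in parallel. The test suite checks both effects.

Multiparameter filtrations (`vrMultiparameter`) attach $m$ extra
per-vertex values, extended to simplices by a user rule applied
incrementally along the generation path; the default is the
coordinate-wise maximum, the natural monotone extension. The rule must
be monotone — each extension is checked against the parent simplex and
the added vertex, and a violation raises an error rather than silently
producing a non-filtration. `codensity()` (mean distance to the $k$
nearest neighbors, default use $k = 10$) is the standard density-aware
companion filtration for this bifiltered construction.

## Cubical engine

Images become cubical complexes by the T-construction: each voxel is a
top-dimensional cell, and every face gets the minimum of the voxel
values over the top cells containing it (coordinate-wise, i.e.
per-channel, for multi-channel images; the propagation rule sits behind
a single internal function so a V-construction could be added). The
complex is the full closed one — all faces of all top cells — so a
constant image is contractible ($\chi = 1$ at its value, in any
dimension) and an image of shape $(m_1, \dots, m_d)$ has
$\prod_i (2 m_i + 1)$ cells.

Ownership partitions the cells so each is emitted once: along every
axis a cell is, for its owner voxel, either the voxel's own interval,
the shared face toward the $+1$ neighbor (owned by the lower voxel, and
still owned by it on the image's high edge where it is unshared), or —
only for the first voxel of an axis — the unshared low-boundary face.
A generic interior voxel therefore owns $2^d$ cells (the top cell plus
its high faces). `eccCubical`/`ecpCubical` stream over the last array
axis with a two-slab window, computing each slab's owned cells with
vectorized per-axis minima; the tests verify bit-for-bit equality with
an explicit all-in-memory per-voxel traversal
(`upperClosureContributions`) and with the independent brute-force
complex (`bruteCubical`). Integer voxel values pass through exactly;
floating-point values are equally valid since nothing in the pipeline
requires sorting by value ahead of time.

## Multicritical cells

In a general multifiltration a cell may enter at several pairwise
incomparable points $p_1, \dots, p_k$. Its contribution must equal
$(-1)^{\dim}$ on the union of the upward cones above the $p_i$, without
double counting the overlaps. `multicriticalContributions()` seeds the
candidate support with the entry points, closes it under pairwise joins
$p \vee q = \max(p, q)$ (coordinate-wise), scans the candidates in a
linear extension of the product order (coordinate sum, then
lexicographic — any point follows everything strictly below it), and at
each candidate adds whatever delta restores the target indicator. The
procedure terminates because the candidate set is finite and each
correction fixes its own point permanently. Inclusion–exclusion over
subset joins serves as the reference construction in the tests, and the
contract — accumulated delta $= (-1)^{\dim} [\exists i: x \ge p_i]$ on
the full grid of coordinate combinations, one step beyond included — is
verified directly. Comparable entry points are rejected rather than
minimized: a comparable pair in a caller's entry set is almost always a
bug in the upstream filtration, and silently repairing it would hide
that.

## Distances

`distanceCurves` computes $\int |ECC_1 - ECC_2|\,dt$ by merging the two
contribution lists with the second list's signs flipped and summing
segment width times $|$running sum$|$. The absolute value matters: the
signed sum telescopes to the difference of terminal values, not the L1
norm. If the terminal values differ, the integrand is eventually a
nonzero constant and the integral diverges; the function then requires
an explicit `upper` bound and errors otherwise, rather than returning
an arbitrary number.

`distanceProfiles` builds the irregular grid whose per-axis breakpoints
are the distinct merged contribution coordinates. Inside each cuboid
the difference is constant and equal to its value at the lower corner,
obtained with cumulative sums of the binned deltas along every axis;
the distance is $\sum |EC| \cdot \text{volume}$ up to the truncation
$f_\infty$ per axis. Truncation is mandatory and has no default: a
single shifted vertex already makes the untruncated distance infinite,
and distances computed under different silent truncations would be
incomparable. For 8-bit images $f_\infty = 256$ (strictly above the
largest value) is the natural choice. Integration starts at the
smallest merged breakpoint per axis — below it the difference is
identically 0, so the choice only documents where the grid begins; the
contributions with any coordinate at or beyond the truncation affect
only the excluded region and are dropped up front. The cost is linear
in the grid size, at worst $(N+1)^n$ cuboids for $N$ merged
contributions, but far smaller when coordinates repeat (integer-valued
images especially).

## Vectorization

`vectorizeCurve` samples the curve at $N$ evenly spaced points from 0
to $f_{max}$ inclusive, resolution $\Delta = f_{max}/(N-1)$. The L1
error of the induced step function is bounded by
$\Delta(|K|/2 + F)$ where $F$ is the total variation of the sample
vector: crossings visible in the samples cost at most their
$\Delta$-wide rectangle, and invisible excursions need paired cells,
at most $|K|/2$ of them. `vectorizationBound` evaluates the bound and
the test suite confirms it on random Vietoris–Rips curves. Two
standard counterexamples, both constructed in the tests, document that
vectorization does **not** preserve distances: excursions strictly
between sample points make far-apart curves indistinguishable, and a
sliver straddling one sample point makes near-identical curves differ.
For profiles (`vectorizeProfile`, one cumulative pass over the sample
grid instead of per-point evaluation) no analogous bound exists — paired
contributions invisible on the grid can affect an arbitrarily large
area — so none is asserted.

## Stability bench

`bettiCurve` turns a persistence diagram into
$\beta(t) = \sum I_{[b, d)}(t)$ (half-open bars; infinite deaths never
switch off). `wasserstein1` is an exact matcher for small diagrams: a
dynamic program over subsets of one diagram that considers every
injection of points with the remainder projected to the nearest
diagonal point $((b+d)/2, (b+d)/2)$, cost = sum of $l_\infty$
displacements. It is exhaustive-equivalent, restricted to at most 8
off-diagonal points, and cross-checked in the tests against a separate
naive recursive enumeration. `checkBettiStability` returns both sides
of $\|\beta(C) - \beta(D)\|_1 \le 2 W_1(C, D)$;
`checkEcpPerturbation` perturbs every contribution by at most
$\epsilon$ per coordinate (clamped to $[0, f_\infty]$) and compares the
truncated L1 distance against $|K| \cdot n \cdot \epsilon^{n-1} \cdot
f_\infty$, $n$ being the number of filtration parameters. Random
diagram generators exclude points at infinity so all distances in the
sweeps are finite; the infinite cases exist only as error paths.

## Synthetic data: what it does and does not show

The generators make every claim testable without downloads.
`sampleSphere` draws uniform points on a unit $d$-sphere (normalized
Gaussians) with optional coordinate noise. `textureImage` produces
8-bit RGB images: a binary 0/255 stripe or checkerboard pattern in one
named channel, i.i.d. Gaussian pixel noise in all channels, clamped to
$[0, 255]$ and rounded. The pattern period defaults to 1/8 of the side
and the noise standard deviation to 10 on the 0–255 scale — values a
texture of this kind would plausibly have; the class-ordering result
below is not sensitive to reasonable alternatives, which is the point
of a qualitative check. The texture study (10 samples of each
style/color pair, 64×64 pixels, 3-parameter profiles truncated at 256,
all $\binom{60}{2}$ pairwise distances) reproduces the intuitive
ordering of mean inter-class distances: same style and color < same
style, different color < different style, same color < different style
and color.

These generators emulate geometry and sensor-like noise, nothing more:
no spatial noise correlation, no illumination gradients, no anisotropy,
no class imbalance. Passing tests show the *machinery* is correct and
the summaries separate controlled classes; they do not show that ECPs
discriminate any particular real-world imagery.

## Problem sizes and numerical choices

The routine test suite runs in about two minutes on one CPU: 50 random
pointclouds (up to 12 points, dimensions 2–4) against exhaustive subset
enumeration, 50 random images (up to 6×6×3 voxels, 1–3 channels)
against the materialized complex, 500 diagram pairs for the stability
sweep, 100 perturbation and 100 vectorization sweeps, 30 multicritical
antichains verified on full grids, and the 60-texture study. Oracles
are deliberately naive and share no code with the engines.

Remaining numerical conventions, in one place: ties in the curve-merge
are harmless because zero-width segments contribute nothing; the
Riemann-sum cross-checks use tolerance $10^{-3}$ at step $10^{-4}$;
bound checks allow $10^{-9}$ for accumulated rounding; the
`ascending_degree` tie-break is the original index, making the
permutation (not just the result) deterministic.

## Limitations

* Profile distances cost $O(N^{n+1})$ in the worst case; no faster
  algorithm is attempted.
* No homology or persistence-diagram computation: the Euler
  characteristic cannot separate classes whose Betti numbers cancel.
* The Vietoris–Rips engine computes exact complexes only — no
  sparsification, Čech or Alpha constructions.
* `wasserstein1` is exponential by design and refuses diagrams beyond 8
  points; it is a verification tool, not a transport solver.
* Cubical streaming holds two slabs in memory but assumes the image
  array itself is addressable; out-of-core file chunking is not
  implemented.
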