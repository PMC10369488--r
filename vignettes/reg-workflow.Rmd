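---
title: "Segment-wise relative energy gradient analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise relative energy gradient analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regpes)
```

## The problem

Additive energy decompositions such as interacting quantum atoms (IQA)
partition the total wave-function energy of a molecular system into
intra-atomic self energies and pairwise classical-electrostatic and
exchange-correlation interaction energies. For a system of $n$ atoms this
yields $n^2$ terms ($n$ intra-atomic plus two sets of $n(n-1)/2$ pair
terms) at *every* geometry of a reaction path — 17,689 terms for a
133-atom enzyme cluster model. The analysis question is: out of thousands
of terms, which few actually drive the energy profile?

`regpes` implements the downstream analysis layer that answers this. It
takes partitioned energies along a one-dimensional control coordinate $s$
(an IRC arc length or a scanned internal coordinate) as input; computing
those energies is the job of quantum-chemistry and atomic-integration
codes and is out of scope here.

## The REG model

Let $E_\mathrm{tot}(s_j)$ be the total energy at the $M$ grid points and
$E_i(s_j)$ the $i$-th partitioned term. Within a **segment** — the part of
the profile between two subsequent stationary points (reactant, transition
state, product) — each term is modelled as linear in the total energy,

$$E_i(s) \approx m_i\,E_\mathrm{tot}(s) + c_i,$$

fitted by ordinary least squares after translating both series over their
segment means. The translation makes the intercept identically zero, so
the package computes the slope directly as the covariance ratio

$$m_i \;=\; \frac{\operatorname{cov}(E_i, E_\mathrm{tot})}
                 {\operatorname{var}(E_\mathrm{tot})},$$

which is numerically transparent and avoids a general least-squares solve
(`lm()` is used only as an independent cross-check in the test suite).
The slope $m_i$ — the REG coefficient — is dimensionless, invariant under
any strictly monotone reparameterisation of $s$ (only the energies enter),
invariant under adding a constant to any series (so a systematic recovery
error is harmless), and equivariant under scaling a term. For a complete
decomposition $\sum_i E_i = E_\mathrm{tot}$ the slopes obey the exact
linear-algebra identity $\sum_i m_i = 1$ on every segment; `regpes`
reports this sum as a completeness diagnostic.

Each slope is paired with the Pearson correlation $R_i$ of the term with
the total energy over the segment. Terms with low $|R_i|$ have no linear
relationship with the profile, so their slope is not interpretable; they
are *flagged*, never silently dropped, and the ranking (most positive to
most negative REG) is reported with and without them. The threshold
default is $|R| \ge 0.7$: the literature discards "low" correlations
without fixing a cutoff, so the package makes the choice explicit and
configurable, and keeps flagged rows in the output so either convention
can be reproduced exactly.

Segmentation acts on the discrete series only: stationary points are
sign changes of the finite differences, plus both endpoints. No spline or
interpolation is involved because the analysis selects among *computed*
geometries. Exact zero differences (plateaus) inherit the preceding trend
— floating-point profiles essentially never tie, and splitting on ties
would create degenerate one-point segments — and a tied extremum is
reported at its first index. Segments need at least 3 points to be
regressed: two points always give $|R| = 1$, which carries no
information.

## Geometry selection by polyline simplification

Every retained geometry costs an expensive set of atomic integrations, so
the package calibrates a minimal geometry subset with the
Ramer–Douglas–Peucker (RDP) algorithm. RDP keeps the point farthest
(perpendicular distance) from the chord between the current endpoints
whenever that distance exceeds a tolerance $\varepsilon$, recursing on the
two halves. Implementation choices:

* **strict inequality** $d_\mathrm{max} > \varepsilon$ for keeping a
  point, and farthest-point ties broken toward the lowest index, so the
  retained set is deterministic;
* $\varepsilon$ has no physical meaning, so it is converted to an energy
  through a **tolerance scan**: $\varepsilon$ runs from 0 to the largest
  chord deviation $\varepsilon_\mathrm{max}$ in steps of 0.01, and each
  simplification is scored by the RMSE between the original profile and
  the simplified polyline interpolated vertically back onto the original
  abscissae. The user then asks for a target RMSE in kJ/mol rather than a
  geometric tolerance;
* the RMSE averages over **all** $M$ original points (retained points
  contribute zero). Averaging over eliminated points only would differ by
  a constant factor per retained set; the all-points convention is
  recorded in the selection output;
* abscissae are normalised to $[0,1]$ by default before distances are
  measured (configurable off). The control coordinate's unit is arbitrary
  relative to the energy unit, and normalising makes the perpendicular
  distance — and hence the default step of 0.01 — meaningful regardless
  of how $s$ is parameterised. Note that because the perpendicular
  distance mixes the two axes, it does not scale exactly with the energy
  axis; the RMSE, being vertical, does;
* a selection is never allowed to collapse to the straight chord: at
  least 3 points are kept, adding back the farthest interior point if
  necessary (flagged in the output), because a two-point "profile" cannot
  represent the sigmoidal shape of a reaction path;
* in the pipeline, RDP runs **within each segment** by default so a
  stationary point can never be eliminated; a global mode exists behind a
  flag.

## Truncation diagnostics

Two ways of shrinking the atom set are supported. The *biased* route
keeps the full-system wave-function and simply restricts the term
bookkeeping to a sphere of chosen radius around a center atom
(`sphere_select()`, closed ball so boundary atoms are included
deterministically, then `filter_terms()`); the total-energy reference is
unchanged, only $k^2$ of the $n^2$ terms remain. The *unbiased* route
compares the energy profile of a systematically truncated (hydrogen-
capped) system against the full profile via three values that all equal 1
for a perfect truncation: the OLS slope $m$ of the mean-translated lite
profile on the full one, the coefficient of determination $R^2$
(preferred over $R$ because it is more sensitive to systematic
deviations), and the ratio of endpoint energy differences
$\Delta E_\mathrm{lite}/\Delta E_\mathrm{full}$ (the activation-energy
ratio when the segment runs reactant to transition state). The third
value is essential: a candidate can match $m$ and $R^2$ while its
gradients are systematically compressed, which only the $\Delta E$ ratio
exposes. `assess_truncations()` aggregates the triple as the maximum
absolute deviation from unity ($L_\infty$) and ranks ascending — a
deliberate package choice; visual inspection of the three values is the
traditional alternative. Generating capped geometries and their energies
requires quantum-chemistry software and is out of scope; the module
consumes the resulting profiles.

## The synthetic generator

Real IQA term tables for large systems are not deposited anywhere, so the
package ships a generator that produces the *statistical structure* the
method assumes — additivity and near-linear term/total relations — with
every parameter controlled:

* `lj_decomposition()` — the Lennard-Jones 12-6 potential split into its
  repulsive $A/r^{12}$ and attractive $-B/r^6$ parts, the canonical
  two-term example: two segments meet at the well minimum
  $r = (2A/B)^{1/6}$, the repulsive term drives the falling wall
  (REG $> 1$, attraction $< 0$) and the roles reverse on the rising tail.
* `weighted_decomposition()` — terms that are known fractions $w_i$ of a
  base curve plus i.i.d. Gaussian noise, emulating small unstructured
  numerical-integration error. With `exact_total = TRUE` the last term
  absorbs the negated noise sum, so the decomposition is exactly additive
  while individual terms stay noisy. The seeded stream is part of the
  public contract: identical parameters and seed reproduce the dataset
  bit for bit.
* `base_curve()` — a sigmoid of height 66 kJ/mol by default (a typical
  enzymatic activation energy, and the scale against which the default
  noise levels are meaningful), or a double-well quartic. The double-well
  grid is mapped onto $t \in [-1.2\,w,\; +w]$ so the profile enters above
  the reactant well, crosses the barrier and ends exactly at the product
  minimum, giving the three-segment falling/rising/falling shape of a
  scanned reaction profile; a domain symmetric about the barrier would
  add a fourth segment beyond the product well, which is not the shape
  the analysis targets. Analytic extremum locations are attached so
  segmentation can be checked against closed-form positions.

What the generator does **not** emulate: realistic magnitude
distributions of enzyme IQA terms, correlated integration errors, or
long-range electrostatic tails. Passing tests therefore demonstrate the
correctness of the analysis machinery, not the chemical behaviour of any
particular system.

## Numerical and interface choices

* Indices are 1-based inside R (idiomatic); the on-disk long-format table
  and the CLI `segment` output use a 0-based `point_index`, which is
  stated in the file-format documentation.
* Energies default to kJ/mol; hartree input is converted with
  2625.4996394799 kJ/mol per hartree.
* Atom labels are case-insensitive on input and stored lowercase
  (geometry files capitalise element symbols; term tables do not), and
  pair labels are stored in locale-independent lexicographic order so
  $V(a,b)$ and $V(b,a)$ are one identity.
* Missing (term, point) values are an error, never implicit zeros —
  zero-filling would silently corrupt the $\sum m_i = 1$ diagnostic.
* Tables are written with 17 significant digits and a fixed row order, so
  write–read round trips are exact and re-writing is byte-stable; the
  pipeline's human-readable reports use 6 significant digits with a
  full-precision JSON alongside.
* Zero-variance cases raise explicit errors (degenerate segment, constant
  term in a direct `reg_pearson()` call, zero $\Delta E_\mathrm{full}$);
  inside a bulk `analyze_segment()` a constant term is reported with
  `R = NA` and flagged rather than aborting the remaining terms.

## Problem sizes and verification

The test suite verifies the implementation against independent routes:
`lm()`/`cor()` for slopes and correlations on 100 seeded random
complete decompositions (agreement to $10^{-10}$ relative), a separately
written stack-based RDP on full tolerance scans of 50-point fixtures
(identical retained sets), brute-force scans for stationary points and
sphere membership, and closed-form cases (affine truncation candidates,
collinear polylines, the LJ minimum). Parameter recovery uses 200
replicates of a two-term decomposition with noise at 1% of the curve
height, checking recovered slopes against generating weights within three
standard errors. These sizes keep the whole battery fast while leaving
the statistical checks well-powered.

## Limitations

* The package analyses energies it is given; it cannot detect an
  incorrectly computed profile, and the RDP selection assumes the input
  PES is trustworthy.
* Segmentation is strictly one-dimensional; multi-dimensional saddle
  detection is out of scope.
* Exchange-correlation terms are treated as atomic units of bookkeeping;
  splitting them further (exchange vs correlation) is not supported.
* The chemical interpretation of a ranking — covalency for
  exchange-correlation terms, ionicity for classical terms — is the
  user's, not the package's.
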