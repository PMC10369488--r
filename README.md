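# regpes

Segment-wise **relative energy gradient (REG)** analysis of additively
partitioned potential energy surfaces.

Additive energy decompositions — interacting quantum atoms (IQA) being the
prototype — split the total wave-function energy of a molecular system
into intra-atomic terms and pairwise classical-electrostatic /
exchange-correlation terms: `n²` terms for `n` atoms (17,689 for a
133-atom enzyme cluster model), at every geometry of a reaction path. REG
answers the question such studies actually pose: *which few of those
thousands of terms drive the energy profile?*

`regpes` is for computational chemists who already have partitioned
energies along a one-dimensional control coordinate `s` (an IRC or an
internal-coordinate scan) and need the analysis layer on top of them:

* **Segmentation** of the discrete profile at its stationary points
  (reactant, TS, product) — the unit on which REG is defined.
* **REG ranking**: for each segment, every term's ordinary least-squares
  slope against the total energy after mean-translation,
  `m_i = cov(E_i, E_tot) / var(E_tot)`, paired with the Pearson
  correlation `R_i` that validates the linear model. Terms rank from most
  positive (working with the profile) to most negative (working against
  it); for a complete decomposition the slopes sum to exactly 1, which is
  reported as a diagnostic.
* **Recovery error**: residuals of `Σᵢ Eᵢ − E_tot`, the standard quality
  measure of the numerical atomic integrations.
* **Geometry selection**: Ramer–Douglas–Peucker polyline simplification
  with a tolerance scan that converts the geometric `ε` into an
  energy-unit RMSE, so the user asks for "a profile faithful to
  0.5 kJ/mol with the fewest geometries".
* **Atom-subset tools**: sphere-based "lite system" selection and term
  filtering; truncation assessment via the `(m, R², ΔE_lite/ΔE_full)`
  triple that all approach 1 for a faithful truncation.
* A **seeded synthetic generator** (Lennard-Jones 12-6 split and weighted
  decompositions with controlled noise) so the whole machinery is testable
  without any quantum-chemistry software, plus a **pipeline runner** and a
  `regpes` command-line interface.

Computing the partitioned energies themselves (wave-functions, basin
integrations) is out of scope: those come from quantum-chemistry and
atomic-integration codes, and this package consumes their output.

## Worked example

The Lennard-Jones 12-6 potential `E(r) = A/r¹² − B/r⁶` is the canonical
two-term decomposition: repulsion and attraction meet at the well minimum
`r = (2A/B)^(1/6)`.

```r
library(regpes)

ds <- lj_decomposition(A = 1, B = 1, r_grid = seq(0.9, 2.5, length.out = 40))
split_segments(ds)
#> 2 PES segment(s):
#>  segment start end direction n_points too_short
#>        1     1   6   falling        6     FALSE
#>        2     6  40    rising       35     FALSE

out <- reg_analyze(ds, r_threshold = 0.7)
out[[1]]
#> REG analysis of segment [1, 6] falling  (|R| threshold 0.70)
#>   sum of REG over all 2 terms: 1.000000 (kept terms: 1.000000)
#>  rank     label kind     reg pearson discarded
#>     1 xc(a1,a2)   xc  1.6544  0.9943     FALSE
#>     2 xc(b1,b2)   xc -0.6544 -0.9651     FALSE
```

On the falling repulsive wall the repulsive term "calls the shots"
(REG 1.65 > 1: its gradient exceeds the total's) while attraction works
against the trend (negative REG); the two slopes sum to exactly 1 because
the decomposition is complete. On the rising segment the roles reverse
(`out[[2]]`: attraction 1.6838, repulsion −0.6838).

Selecting the fewest geometries that keep the profile faithful to
0.05 energy units:

```r
select_points(ds$s, ds$e_total, rmse_tolerance = 0.05)
#> RDP selection: 6 of 40 points at epsilon 0.03 (RMSE 0.0450639)
#>   retained indices: 1, 3, 5, 7, 20, 40
```

Note the well minimum (index 6) was eliminated — which is why the
pipeline runs the selection *within* each segment by default, so
stationary points can never be dropped. The same workflow end-to-end,
from a YAML config:

```r
reg_run("run.yaml")   # or: regpes run --config run.yaml
```

writes the segment table, the tolerance scan and selection, per-segment
REG rankings restricted to the selected geometries, the recovery report,
and a run log — byte-identical across reruns with the same config.

The long-format term-table interchange format, the CLI subcommands
(`validate`, `recover`, `segment`, `analyze`, `rdp`, `sphere`, `filter`,
`truncate`, `simulate`, `run`) and all analysis choices are documented in
the function reference and the methods vignette
(`vignettes/reg-workflow.Rmd`).

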