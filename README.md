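# tidesr

Protein signaling networks rewire while cells change state: an edge that
transmits information early in a transition can fall silent later, and a
static network inferred from a pooled snapshot misses this entirely.
`tidesr` learns **time-varying edge strength** between pairs of proteins
from a *single* static single-cell snapshot (e.g. mass cytometry of cells
undergoing the epithelial–mesenchymal transition), by exploiting the
asynchrony of the cells: each cell carries a pseudotime value `T ∈ [0, 1]`
from any external trajectory tool, and the package turns the per-cell
triples `(T, X, Y)` into a continuous curve of dependency strength of
target `Y` on regulator `X` along `T`.

## What it computes

- **Heat-diffusion KDE (1–3D).** The joint density `p(T, X, Y)` is
  estimated by evolving the data histogram under the heat equation with
  reflecting (Neumann) boundaries, solved spectrally: DCT of the
  histogram, attenuation of coefficient `k` by `exp(-k²π²t/2)` per axis
  (diffusion time `t = h²`, with Silverman's rule
  `h_j = (4/(5n))^{1/7} σ_j`), inverse DCT. Cost `O(nB + B³ log B)` for
  `B` bins per axis — seconds at `B = 128`, versus hours for a direct
  Gaussian sum on the same mesh (kept in the package as the oracle).
- **DREVI / DREMI.** The conditional `p(Y | T, X)` is rescaled per
  conditioning column and denoised; the conditional-mean surface
  (3D-DREVI) visualizes the response's typical level across the
  regulator's range and pseudotime, and DREMI
  `I_c = H_c(Y) − H_c(Y | T, X)` scores the dependency in bits on a
  resampled joint that weights the regulator's full dynamic range equally.
- **TIDES** (Trajectory Interpolated DREMI Scores): the rescaled 3D
  conditional is sliced at 256 fixed pseudotimes by linear interpolation,
  each slice is denoised (ε = 0.9) and scored with 2D-DREMI, and the curve
  is Gaussian-smoothed — edge strength as a function of trajectory
  position, able to catch transient couplings that DREMI in discrete
  pseudotime bins dilutes away.
- **Driver-edge ranking** by `3D-DREMI((T,X)→Y) + 2D-DREMI(X→Y) +
  2D-DREMI(T→Y)`, averaged over replicates.
- **Perturbation validation**: impact curves (control minus perturbed
  target trend), lag-searched cross-correlation against TIDES, and
  threshold gating (epithelial / transitional / mesenchymal fractions).
- **Seeded generators** for every input above: transient-edge triples, 3D
  Gaussian benchmark clouds, EMT-like marker panels with planted
  couplings, and paired control/perturbed conditions.

## Worked example

```r
library(tidesr)

# a transient edge: X drives Y early in pseudotime, the coupling then decays
cells <- simulate_transient_edge(5000, seed = 1)
curve <- smooth_curve(tides_curve(cells, "X", "Y"))
print(curve)
#> tides_curve X -> Y: 256 locations in [0.004, 0.996], smoothed (sigma = 0.126)
#>   score range: [0.0537, 1.7414] bits

early <- mean(curve$score[curve$t <= 0.25])
late  <- mean(curve$score[curve$t >= 0.75])
sprintf("early %.2f vs late %.2f bits (ratio %.1f)", early, late, early / late)
#> "early 1.40 vs late 0.06 bits (ratio 24.7)"
```

The edge carries ~1.4 bits of information about `Y` in the first quarter
of the trajectory and essentially none in the last — the transient
coupling is localized in pseudotime. The discrete comparator (DREMI in
five half-overlapping pseudotime bins) dilutes the same signal:

```r
baseline <- binned_dremi_baseline(cells, "X", "Y")
max(baseline$score, na.rm = TRUE)   # 0.68  — less than half the
max(curve$score)                    # 1.74     TIDES peak
dremi_3d(cells, "X", "Y")           # 0.86 bits over the whole trajectory
```

Cell tables are plain data frames (cells × markers, optional
`pseudotime` / `condition` columns) read from delimited text or FCS via
`read_cells()`; `arcsinh_transform()` (cofactor 5) is the standard mass
cytometry preprocessing. A JSON-configured end-to-end run is available as
`run_pipeline()`, and `inst/cli/tidesr` exposes
`simulate / preprocess / kde / dremi / tides / rank / validate / pipeline`
subcommands for shell use.

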