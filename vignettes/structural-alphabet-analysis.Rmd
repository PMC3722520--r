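---
title: "Structural-alphabet analysis of local motions: models and methods"
author: "SAMotions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-alphabet analysis of local motions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SAMotions)
```

# The model

A **structural alphabet** (SA) is a small set of canonical local-backbone
conformations — here, four-residue fragments represented by their Cα atoms
only — each labelled with a letter.  A protein conformation of $n$ residues
is scanned with overlapping four-residue windows (window $i$ covers
residues $i..i{+}3$), and each window is assigned the letter of the
canonical fragment that superposes onto it with minimal RMSD.  The
conformation is thereby condensed into a string of $n-3$ letters, and an
ensemble of $m$ conformers (an MD trajectory, an NMR bundle, a
coarse-grained simulation) becomes an $m \times (n-3)$ alignment of
structural strings: rows are frames in time order, columns are fragment
positions.

Working on strings instead of coordinates buys three things:

1. **Local-motion statistics.** The conformational variability of position
   $i$ is the Shannon entropy $H_i = -\sum_a p_i(a)\log_2 p_i(a)$ of its
   letter distribution (bits); the per-position letter frequencies form a
   sequence profile, and consecutive-frame letter transitions give a
   row-stochastic transition matrix describing local conformational
   kinetics.
2. **Correlated motions and allostery.** The coupling between positions
   $i$ and $j$ is their mutual information
   $\mathrm{MI}(i,j) = \sum_{a,b} p_{ij}(a,b)\log_2
   \frac{p_{ij}(a,b)}{p_i(a)\,p_j(b)}$.  A network over positions built
   from the normalized MI supports eigenvector-centrality ranking of key
   fragments and extraction of communication pathways between allosteric
   and orthosteric sites.
3. **Local–global functional coupling.** Any per-frame scalar describing a
   function-related property (e.g. the projection onto a collective
   motion) can be discretized and correlated, as MI, with every column,
   scoring which local switches carry information about the global
   functional change.

# Superposition and encoding

Fragment-to-fragment fit uses the closed-form least-squares rigid
superposition (Kabsch): both point sets are centered, the rotation is
obtained from the SVD of the cross-covariance matrix, and the smallest
singular value enters with a negative sign when the optimal orthogonal map
would be a reflection, so mirror images never superpose to zero.  The
residual is evaluated from the explicit rotation rather than from the
singular-value identity $E_0 - 2D$, whose floating-point cancellation
(≈1e-7 Å on nearly identical fragments) would otherwise mask exact rigid
equivalence.  `superposeRMSD()` is validated in the test suite against a
brute-force rotation-space search (multi-start Nelder–Mead over rotation
vectors) to 1e-3 Å on random fragment pairs.

Two encoding modes exist:

* **Local** (`encodeLocal()`): every window is fitted independently
  against every canonical fragment; the minimal-RMSD letter wins and ties
  go to the alphabetically earlier letter, so encoding is deterministic.
* **Global** (`encodeGlobal()`): letters are chosen N→C while a model
  chain is rebuilt from the canonical fragments; at each position every
  candidate fragment is fitted onto the last three reconstructed Cα plus
  the next true Cα, and the letter minimizing the running RMSD of the
  reconstructed chain against the true chain is kept.  The exact
  chain-growth bookkeeping of global fitting is not uniquely determined by
  the literature on encoding modes; the scheme above (reconstructed chain
  anchors each step, running-RMSD objective, local criterion at the first
  position) is this package's documented interpretation, not a claim of
  bit-compatibility with other implementations.

Missing Cα atoms are refused rather than gap-encoded (the alphabet defines
no gap state), and an `Ensemble` holds exactly one chain — multi-chain
structures are encoded chain by chain, so windows never span chain breaks.

# Alphabets

The alphabet file format is a small plain-text format (header
`# SA <name> <k>`, then `> <letter>` plus four `x y z` lines per fragment,
6 decimals) chosen for being human-diffable and trivially parseable.
Letters are single characters so the strings stay FASTA-compatible; an
alphabet of more than 25 letters is refused rather than inventing
multi-character letters.

The bundled 25-letter default (`defaultAlphabet()`, letters A–Y) is
**synthetic**: the canonical coordinates of the published 25-state
fragment alphabets are not reproduced here, so the package ships a
reproducible stand-in built by `makeSyntheticAlphabet(25, seed = 101)` —
an ideal α-helical Cα turn, an ideal extended segment, and randomized
fragments drawn in internal coordinates (pseudo-bonds U(3.7, 3.9) Å,
pseudo-angles U(80°, 140°), free torsions — the realistic range of
protein Cα traces), resampled until every fragment pair is at least
0.5 Å apart in minimal superposition RMSD.  Numeric agreement with any
published alphabet is therefore not claimed; all quantitative validation
runs on synthetic ground truth.

A second family, `makeUniformGeometryAlphabet()`, fixes all pseudo-bonds
at 3.8 Å and all pseudo-angles at 110° and varies only the torsion
(fragment A keeps the helical torsion 50°, B the extended/trans torsion
180°).  Its purpose is geometric: because every fragment's leading and
trailing three-point triples are congruent, chain growth by least-squares
fragment concatenation realizes every window as an *exact* rigid copy of
its canonical fragment.  On the torsion circle a 0.5 Å separation admits
at most 8 letters, hence the `k ≤ 8` limit of this family.

# The synthetic-data generator

`syntheticSpec()` + `generateSynthetic()` produce ensembles with known
truth at every level:

* **Strings**: letters drawn per position (uniform by default); a planted
  coupling $(i, j, \rho)$ replaces the letter at $j$ with a fixed
  bijection (cyclic shift) of the letter at $i$ with probability $\rho$
  per frame, giving the closed-form joint
  $p(a,b) = \rho\,\pi_a 1[b{=}f(a)] + (1-\rho)\pi_a\pi_b$ against which
  the MI estimator is tested.  Coupled positions must be ≥ 4 apart so the
  planted signal is never confounded by windows sharing residues.
* **Coordinates**: each frame's chain is grown letter by letter — the
  first canonical fragment placed as-is, each following fragment
  least-squares-fitted with its first three points onto the last three
  placed Cα, appending its fourth point — then isotropic Gaussian jitter
  of `noiseSd` Å is added.  With the uniform-geometry alphabet (the
  generator default, `k = 5`) the growth is exact, so at zero noise local
  re-encoding recovers the generating strings with 100% identity and
  ~1e-15 Å fit RMSD.  With unconstrained alphabets the least-squares fits
  leave a residual window distortion (the overlapping triples of
  consecutive letters are not congruent), and measured recovery drops to
  ≈99%: this is why the generator's default alphabet is the
  uniform-geometry family, a deliberate design choice.
* **Functional index**: the value of frame $t$ is a letter-dependent mean
  (unit-separated per letter) at one chosen position plus Gaussian noise
  whose variance is set so the letter explains a fraction $\rho_f$ of the
  index variance; $\rho_f = 0$ yields pure standard-normal noise.

What the generator does **not** emulate: force-field physics, solvent,
realistic kinetics or autocorrelation between frames (frames are i.i.d.
given the planted couplings), side-chain or full-backbone geometry, and
chain self-avoidance.  Passing tests therefore demonstrate the
correctness of the encoding and inference machinery on data whose truth
is known — not that any particular biological trajectory will show such
clean signals.

# MI normalization, significance and multiplicity

The plug-in MI of finite samples is biased upward; the package corrects
it empirically rather than analytically.  For a pair $(i, j)$,
`normalizedMI()` runs `nPerm` row-wise permutations of column $j$
(column $i$ fixed), and reports

$$\mathrm{nMI}(i,j) \;=\; \mathrm{clamp}\!\left(
\frac{\mathrm{MI}_{\mathrm{obs}} - \overline{\mathrm{MI}}_{\mathrm{perm}}}
     {H(i,j)},\; 0,\; 1\right),$$

with $H(i,j)$ the observed joint entropy (and nMI ≡ 0 when
$H(i,j) = 0$), together with the one-sided permutation p-value with the
add-one convention $p = (1 + \#\{\mathrm{MI}_\pi \ge
\mathrm{MI}_{\mathrm{obs}}\})/(n_{\mathrm{perm}} + 1)$.  Joint-entropy
scaling makes the score dimensionless in $[0,1]$ and symmetric;
permutation-mean subtraction removes the finite-sample offset at exactly
the observed marginals.  Across the matrix, q-values are
Benjamini–Hochberg-adjusted over all off-diagonal pairs.  Pairs of
overlapping windows ($|i-j| < 4$) share residues and are trivially
correlated; they are computed but flagged, and network construction skips
them by default.

Numerical/reproducibility choices worth knowing:

* Each pair's permutation stream is seeded by a deterministic hash of
  `(seed, i, j)`, so the MI matrix is bit-reproducible and independent of
  the order in which pairs are computed; all generator and analysis
  functions restore the caller's RNG state.
* Permutation MI values are compared to the observed value with a 1e-12
  slack so exact ties (e.g. relabelings) count as "as extreme".
* `MI(i, i)` is returned as $H_i$ directly, bypassing the
  entropy-difference arithmetic, so the diagonal identity holds exactly.
* The default `nPerm = 199` is a pragmatic driver default for per-pair
  p-values.  Note that a q-value threshold of 0.05 over $P$ pairs is only
  reachable when $1/(n_{\mathrm{perm}}+1) \cdot P \le 0.05$: planted-edge
  analyses in the tests and the acceptance script use `nPerm = 999` on
  compact chains for exactly this reason.
* `n_bins = 10` equal-width bins is the functional-index default:
  equal-width binning is order-preserving, simple to document, and at the
  test ensemble sizes (m ≥ 500) keeps per-bin counts workable.  A
  constant index is flagged degenerate instead of erroring.

# Network analysis

Edges of the correlation network are pairs with `nmi > threshold` and
`q ≤ qMax` (defaults 0 and 0.05: significance, not magnitude, is the
primary filter), excluding overlapping windows; isolated nodes are kept so
node indices always match fragment positions.  Eigenvector centrality is
the dominant eigenvector of the weighted adjacency of the largest
connected component, computed by direct symmetric eigen-decomposition
(non-negative by Perron–Frobenius; sign-fixed, zeros for nodes outside
the component, unit Euclidean norm overall) and cross-checked in the
tests against an independent power iteration and igraph.

For communication pathways each edge costs $-\log(\mathrm{nMI})$, turning
multiplicative correlation chains into additive costs, so the
highest-correlation route between a source and target set is the
lowest-cost path.  `communicationPathways()` returns up to $k$ loopless
paths in ascending cost (Yen-style k-shortest search via igraph,
validated against exhaustive path enumeration), breaking cost ties by the
lexicographically smaller node sequence.  A disconnected source/target
pair is a warning with an empty result, not an error — allosteric
screening must degrade gracefully.  Networks export to standard GML
(node `id`, `label`, `centrality`; edge `source`, `target`, `weight`) for
Cytoscape and igraph.

# Drivers and provenance

`cmdSynth()`, `cmdEncode()` and `cmdAnalyze()` (and the thin `exec/sa`
script over them) mirror the classic encode/analyze split of
structural-alphabet trajectory tools, reading reference + multi-model PDB
(via bio3d) and writing FASTA (via Biostrings), tab-separated matrices and
GML.  All plain-text outputs carry `#` provenance headers (inputs,
alphabet, mode, seeds, package version) — deliberately without timestamps,
so identical configuration and seeds reproduce byte-identical output
trees; the FASTA and GML files, whose formats do not admit comment
headers, are covered by the run's `MANIFEST.txt` instead.  Outputs are
written to `<name>.partial` and renamed on success, so an interrupted run
never leaves a truncated file under a final name.

# Problem sizes used in validation

The shipped validation uses ensembles of 30 residues × 2000 frames for
string recovery, m = 500 alignments for permutation calibration (500
independent column pairs, 199 permutations), 20 replicate seeds for
planted-edge (ρ = 0.9, 999 permutations) and functional-site (ρ_f = 0.9)
recovery, 100 random fragment pairs for the superposition oracle, and
10-node/6-node graphs for the centrality and pathway oracles — sizes at
which the Monte-Carlo error of each check is comfortably below its
acceptance band.

# Known limitations

* The bundled 25-letter alphabet is a synthetic stand-in; analyses meant
  to be compared against published encodings must load the corresponding
  published alphabet file.
* Global-mode encoding is an interpretation (see above).
* Transition statistics use lag 1 only and assume one contiguous
  trajectory; concatenated trajectories should be analyzed separately.
* MI bias handling is purely permutation-based; no analytic small-sample
  corrections, time-lagged MI or continuous MI estimators.
* The generator's frames are exchangeable, so transition-matrix behaviour
  on realistic, autocorrelated trajectories is exercised only at the
  bookkeeping level.
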