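# SAMotions

Structural-alphabet analysis of local motions in protein conformational
ensembles.

Molecular-dynamics and other conformational ensembles are usually analyzed
through global collective motions, which can hide the small, local backbone
switches that actually drive function.  SAMotions takes the complementary,
local route: every conformer of an *n*-residue chain is scanned with
overlapping four-residue Cα windows and each window is assigned the letter
of the best-superposing canonical fragment from a **structural alphabet**,
condensing the conformer into a string of *n−3* letters.  An ensemble of
*m* conformers becomes an *m* × (*n−3*) alignment of structural strings, on
which the package computes:

* **local-motion statistics** — per-position Shannon entropy
  *H<sub>i</sub>* = −Σ<sub>a</sub> *p<sub>i</sub>*(a) log₂ *p<sub>i</sub>*(a),
  fragment profiles, and consecutive-frame transition matrices;
* **correlated motions / allostery** — the mutual information
  MI(*i*, *j*) = Σ<sub>a,b</sub> *p*(a,b) log₂ [*p*(a,b) / *p*(a)*p*(b)]
  between columns, normalized by permutation-mean subtraction and
  joint-entropy scaling (nMI ∈ [0, 1]) with one-sided permutation p-values
  and Benjamini–Hochberg q-values; a significance-filtered nMI network
  with eigenvector centrality and −log(nMI) shortest-path communication
  pathways, exported as GML;
* **local–global functional coupling** — the MI between every column and a
  binned per-frame functional index (e.g. a collective-motion projection),
  ranking candidate functional sites.

It is aimed at structural bioinformaticians and simulators who want
string-level, statistically controlled analysis of local dynamics without
coupling their pipeline to a specific simulation engine: input is plain
(multi-model) PDB, output is FASTA, tab-separated matrices and GML.

A first-class synthetic-data module generates ensembles with *known*
per-frame strings, planted inter-position couplings and a planted
functional coupling, so every inference stage is validated against ground
truth in the test suite.

## Worked example

Generate a 400-frame, 12-residue synthetic ensemble with one planted
coupling (positions 2 ↔ 7, ρ = 0.9) and a functional index driven by
position 4 (ρ_f = 0.8), then run the full analysis:

```r
library(SAMotions)

a    <- makeUniformGeometryAlphabet(5, seed = 1)
spec <- syntheticSpec(12, 400, alphabet = a,
                      couplings = data.frame(i = 2L, j = 7L, rho = 0.9),
                      functionalPosition = 4L, functionalRho = 0.8, seed = 42)
res  <- generateSynthetic(spec)

aln <- encodeEnsemble(res$ensemble, a, mode = "local")
#> SAAlignment: 400 frames x 9 fragment positions, alphabet 'uniformgeo-k5-s1'
mean(alignmentStrings(aln) == res$strings)   # zero-noise encoding recovery
#> [1] 1
columnEntropy(aln, 2)                        # local variability, bits
#> [1] 2.318

mm  <- miMatrix(aln, nPerm = 999, seed = 42)
net <- buildNetwork(mm)                      # nMI > 0, q <= 0.05, no overlap pairs
networkEdges(net)
#>   from to    weight qvalue
#> 1    2  7 0.6403545  0.036
communicationPathways(net, source = 2, target = 7, k = 3)
#>   rank      cost path
#> 1    1 0.4457333  2,7

prof <- functionalMIProfile(aln, binFunctionalIndex(res$functionalIndex, 10),
                            nPerm = 999, seed = 42)
head(prof, 3)
#>   position label     mi    nmi pvalue qvalue
#> 4        4   4-7 1.1244 0.2428  0.001 0.0090
#> 8        8  8-11 0.0749 0.0012  0.314 0.8696
#> 1        1   1-4 0.0651 0.0000  0.568 0.8696
```

The analysis recovers exactly the planted structure: the only significant
network edge joins positions 2 and 7 (nMI 0.64, q = 0.036), and the
functional profile ranks position 4 first by a wide margin (nMI 0.24
against ≤ 0.002 elsewhere, q = 0.009).

The same pipeline is available as shell-style drivers (`cmdSynth()`,
`cmdEncode()`, `cmdAnalyze()`, or the installed `exec/sa` script) reading
reference + multi-model PDB and writing FASTA, accuracy/entropy/profile
tables, MI/nMI/p/q matrices, the GML network, centrality and pathway
tables — all with provenance headers and byte-reproducible under fixed
seeds.

## The bundled alphabet

The default 25-letter alphabet (`defaultAlphabet()`,
`inst/extdata/sa25_synthetic.txt`) is a synthetic stand-in — see the
methods vignette (`vignettes/structural-alphabet-analysis.Rmd`) for why,
and for the full model, parameter and design documentation.  To analyze
data against a published fragment alphabet, supply its coordinates as an
alphabet file via `readAlphabet()`.
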