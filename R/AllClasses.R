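#' @import methods
NULL

#' StructuralAlphabet: an ordered set of lettered canonical C-alpha fragments
#'
#' A structural alphabet is a finite set of canonical four-residue backbone
#' fragments, represented by their C-alpha coordinates only, each labelled
#' with a single letter.  Conformations of a protein chain are encoded by
#' assigning, to every overlapping four-residue window, the letter of the
#' canonical fragment that superposes onto it with minimal RMSD.
#'
#' Fragments are kept in letter-sorted order, so iteration over an alphabet
#' is deterministic across runs.
#'
#' @slot name Character scalar naming the alphabet.
#' @slot letters Character vector of single, distinct, printable letters,
#'   sorted; one per fragment.
#' @slot coords List of 4x3 numeric matrices (Angstrom), parallel to
#'   `letters`: the canonical C-alpha coordinates of each fragment.
#'
#' @seealso [readAlphabet()], [writeAlphabet()], [makeSyntheticAlphabet()],
#'   [defaultAlphabet()]
#' @export
setClass("StructuralAlphabet",
    representation(name = "character", letters = "character", coords = "list"))

.validFragmentCoords <- function(x) {
    if (!is.matrix(x) || !is.numeric(x) || !all(dim(x) == c(4L, 3L)))
        return("fragment coordinates must be a 4x3 numeric matrix")
    if (!all(is.finite(x)))
        return("fragment coordinates must be finite")
    d <- sqrt(rowSums((x[-1L, , drop = FALSE] - x[-4L, , drop = FALSE])^2))
    if (any(d < 2.0 | d > 5.0))
        return(sprintf(
            "consecutive C-alpha pseudo-bond distances must lie in [2, 5] Angstrom (got %s)",
            paste(sprintf("%.3f", d), collapse = ", ")))
    TRUE
}

setValidity("StructuralAlphabet", function(object) {
    msgs <- character()
    if (length(object@name) != 1L || is.na(object@name))
        msgs <- c(msgs, "'name' must be a single string")
    k <- length(object@letters)
    if (k < 2L)
        msgs <- c(msgs, "an alphabet needs at least 2 fragments")
    if (anyDuplicated(object@letters))
        msgs <- c(msgs, sprintf("duplicate letters: %s",
            paste(unique(object@letters[duplicated(object@letters)]), collapse = ", ")))
    if (any(nchar(object@letters) != 1L))
        msgs <- c(msgs, "letters must be single characters")
    if (is.unsorted(object@letters))
        msgs <- c(msgs, "fragments must be stored in letter-sorted order")
    if (length(object@coords) != k)
        msgs <- c(msgs, "'coords' and 'letters' must have equal length")
    for (i in seq_along(object@coords)) {
        ok <- .validFragmentCoords(object@coords[[i]])
        if (!isTRUE(ok))
            msgs <- c(msgs, sprintf("fragment '%s': %s", object@letters[i], ok))
    }
    if (length(msgs)) msgs else TRUE
})

#' Ensemble: C-alpha coordinates of m conformers of one protein chain
#'
#' Holds a conformational ensemble (e.g. frames of a molecular-dynamics
#' trajectory) as an m x n x 3 array of C-alpha coordinates for a single
#' chain, together with the author residue numbering.
#'
#' @slot coords Numeric array, `m` frames x `n` residues x 3 (Angstrom).
#' @slot residueIds Integer vector of `n` residue numbers.
#' @slot frameTimes Numeric vector of `m` timestamps, or empty.
#'
#' @seealso [readEnsemblePDB()], [stringsToEnsemble()], [encodeEnsemble()]
#' @export
setClass("Ensemble",
    representation(coords = "array", residueIds = "integer",
                   frameTimes = "numeric"))

setValidity("Ensemble", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3L] != 3L)
        return("'coords' must be an m x n x 3 array")
    if (d[1L] < 1L) return("need at least one frame")
    if (d[2L] < 4L) return("need at least 4 residues to encode")
    if (!all(is.finite(object@coords)))
        return("missing or non-finite C-alpha coordinates are not allowed")
    if (length(object@residueIds) != d[2L])
        return("'residueIds' length must equal the residue count")
    if (length(object@frameTimes) && length(object@frameTimes) != d[1L])
        return("'frameTimes' must be empty or one per frame")
    TRUE
})

#' SAAlignment: structural strings of an encoded ensemble
#'
#' The result of encoding an ensemble of m conformers of an n-residue chain:
#' m aligned strings of n-3 letters.  Rows are frames (in time order),
#' columns are fragment positions; position i covers residues i..i+3.
#'
#' @slot letters Character matrix, m frames x (n-3) positions, single letters.
#' @slot alphabetName Name of the alphabet used for encoding.
#' @slot alphabetLetters The alphabet's letter set (sorted).
#' @slot positionLabels Residue-range labels, one per column.
#' @slot fitRMSD Numeric matrix of per-position superposition RMSD
#'   (Angstrom), same shape as `letters`, or a 0x0 matrix when the alignment
#'   was read from file and carries no accuracy records.
#'
#' @seealso [encodeEnsemble()], [readFastaAlignment()], [writeFastaAlignment()]
#' @export
setClass("SAAlignment",
    representation(letters = "matrix", alphabetName = "character",
                   alphabetLetters = "character", positionLabels = "character",
                   fitRMSD = "matrix"))

setValidity("SAAlignment", function(object) {
    L <- object@letters
    if (!is.character(L) || nrow(L) < 1L || ncol(L) < 1L)
        return("'letters' must be a non-empty character matrix")
    if (any(nchar(L) != 1L))
        return("alignment cells must be single letters")
    bad <- matrix(!(L %in% object@alphabetLetters), nrow(L))
    if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        return(sprintf("letter '%s' (frame %d, position %d) is not in alphabet '%s'",
                       L[w[1L], w[2L]], w[1L], w[2L], object@alphabetName))
    }
    if (length(object@positionLabels) != ncol(L))
        return("'positionLabels' must have one entry per column")
    if (length(object@fitRMSD) &&
        !(nrow(object@fitRMSD) == nrow(L) && ncol(object@fitRMSD) == ncol(L)))
        return("'fitRMSD' must match the alignment shape")
    if (length(object@fitRMSD) && any(object@fitRMSD < 0))
        return("'fitRMSD' values must be non-negative")
    TRUE
})

#' MIMatrix: pairwise mutual-information matrices over fragment positions
#'
#' Symmetric matrices of the plug-in mutual information (bits) between all
#' pairs of alignment columns, its permutation-based normalization,
#' permutation p-values, Benjamini-Hochberg q-values and the permutation-mean
#' (expected) MI.  The diagonal of `mi` holds the column entropies.
#'
#' @slot mi,nmi,pvalue,qvalue,expectedMi Numeric (n-3)x(n-3) matrices.
#'   `qvalue` has `NA` on the diagonal (no test of a column against itself).
#' @slot overlap Logical matrix flagging pairs of overlapping windows
#'   (`|i - j| < 4`, off-diagonal): such pairs share residues and are
#'   trivially correlated.
#' @slot nPerm Number of permutations used per pair.
#' @slot seed Base seed of the per-pair permutation streams.
#' @slot positionLabels Residue-range labels of the positions.
#'
#' @seealso [miMatrix()], [buildNetwork()]
#' @export
setClass("MIMatrix",
    representation(mi = "matrix", nmi = "matrix", pvalue = "matrix",
                   qvalue = "matrix", expectedMi = "matrix",
                   overlap = "matrix", nPerm = "integer", seed = "integer",
                   positionLabels = "character"))

setValidity("MIMatrix", function(object) {
    p <- ncol(object@mi)
    for (s in c("mi", "nmi", "pvalue", "qvalue", "expectedMi", "overlap")) {
        m <- slot(object, s)
        if (!all(dim(m) == c(p, p)))
            return(sprintf("'%s' must be %d x %d", s, p, p))
    }
    if (!isTRUE(all.equal(object@mi, t(object@mi), tolerance = 0)))
        return("'mi' must be exactly symmetric")
    if (any(object@mi < -1e-12)) return("MI values must be non-negative")
    if (any(object@nmi < 0 | object@nmi > 1)) return("nMI must lie in [0, 1]")
    pv <- object@pvalue[is.finite(object@pvalue)]
    if (any(pv <= 0 | pv > 1)) return("p-values must lie in (0, 1]")
    TRUE
})

#' FunctionalIndex: a binned per-frame scalar describing a functional property
#'
#' Any time-dependent scalar (one value per frame) describing a
#' function-related property -- for instance the projection of each frame
#' onto a collective motion -- discretized into equal-width bins so that it
#' can enter the mutual-information machinery as a categorical column.
#'
#' @slot values Numeric vector, one value per frame.
#' @slot nBins Number of equal-width bins.
#' @slot binEdges `nBins + 1` ascending edges; bins are half-open
#'   `[lo, hi)`, the last bin closed.
#' @slot symbols Integer bin index per frame, in `1..nBins`.
#' @slot degenerate `TRUE` when the series is constant (single occupied bin).
#'
#' @seealso [binFunctionalIndex()], [functionalMIProfile()]
#' @export
setClass("FunctionalIndex",
    representation(values = "numeric", nBins = "integer", binEdges = "numeric",
                   symbols = "integer", degenerate = "logical"))

setValidity("FunctionalIndex", function(object) {
    if (object@nBins < 2L) return("need at least 2 bins")
    if (length(object@binEdges) != object@nBins + 1L)
        return("'binEdges' must have nBins + 1 entries")
    if (is.unsorted(object@binEdges, strictly = TRUE))
        return("'binEdges' must be strictly ascending")
    if (length(object@symbols) != length(object@values))
        return("'symbols' must have one entry per value")
    if (any(object@symbols < 1L | object@symbols > object@nBins))
        return("bin symbols out of range")
    TRUE
})

#' MINetwork: correlation network of local motions
#'
#' An undirected weighted graph over fragment positions, built from a
#' normalized-MI matrix by thresholding on coupling strength and statistical
#' significance.  Edge weights are nMI values; isolated nodes are retained.
#'
#' @slot nodes Data frame with columns `id` (fragment position) and `label`
#'   (residue range).
#' @slot edges Data frame with columns `from`, `to` (positions, from < to),
#'   `weight` (nMI) and `qvalue`.
#' @slot threshold nMI cutoff used to admit edges.
#' @slot qMax FDR cutoff used to admit edges.
#' @slot skipOverlap Whether overlapping-window pairs were excluded.
#' @slot centrality Named numeric vector of eigenvector-centrality scores
#'   (zeros when the network has no edges).
#'
#' @seealso [buildNetwork()], [eigenvectorCentrality()],
#'   [communicationPathways()], [writeGML()]
#' @export
setClass("MINetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   threshold = "numeric", qMax = "numeric",
                   skipOverlap = "logical", centrality = "numeric"))

setValidity("MINetwork", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (any(e$from == e$to)) return("self-loops are not allowed")
        if (any(e$weight <= object@threshold))
            return("every edge weight must exceed the threshold")
        if (any(e$weight <= 0 | e$weight > 1))
            return("edge weights (nMI) must lie in (0, 1]")
        if (!all(e$from %in% object@nodes$id) || !all(e$to %in% object@nodes$id))
            return("edge endpoints must be network nodes")
    }
    if (length(object@centrality)) {
        if (length(object@centrality) != nrow(object@nodes))
            return("'centrality' must have one score per node")
        if (any(object@centrality < 0))
            return("centrality scores must be non-negative")
        nrm <- sqrt(sum(object@centrality^2))
        if (nrow(e) && abs(nrm - 1) > 1e-6)
            return("centrality scores must have unit Euclidean norm")
    }
    TRUE
})

#' SyntheticSpec: recipe for a ground-truth synthetic ensemble
#'
#' Describes how to generate an ensemble whose true per-frame letter strings,
#' inter-position couplings and functional-index coupling are known, so that
#' every downstream analysis stage can be validated against planted truth.
#'
#' @slot nResidues,mFrames Chain length and frame count.
#' @slot alphabet The [StructuralAlphabet] the strings are drawn from.
#' @slot letterProbs Numeric matrix, (nResidues - 3) x k, of per-position
#'   letter probabilities (rows sum to 1), or a 0x0 matrix for uniform.
#' @slot couplings Data frame with columns `i`, `j`, `rho`: with probability
#'   `rho` the letter at position `j` is a fixed bijective mapping (cyclic
#'   shift in letter order) of the letter at `i`, else independent.  Coupled
#'   positions must be at least 4 apart (non-overlapping windows).
#' @slot noiseSd Isotropic Gaussian C-alpha jitter, Angstrom.
#' @slot functionalPosition,functionalRho Position and explained-variance
#'   fraction of the planted functional-index coupling (`NA` position for
#'   none).
#' @slot seed Integer seed; all generation is deterministic in it.
#'
#' @seealso [syntheticSpec()], [sampleStrings()], [stringsToEnsemble()],
#'   [sampleFunctionalIndex()]
#' @export
setClass("SyntheticSpec",
    representation(nResidues = "integer", mFrames = "integer",
                   alphabet = "StructuralAlphabet", letterProbs = "matrix",
                   couplings = "data.frame", noiseSd = "numeric",
                   functionalPosition = "integer", functionalRho = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@nResidues < 4L) return("'nResidues' must be >= 4")
    if (object@mFrames < 1L) return("'mFrames' must be >= 1")
    if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
    p <- object@nResidues - 3L
    k <- length(object@alphabet@letters)
    if (length(object@letterProbs)) {
        lp <- object@letterProbs
        if (!all(dim(lp) == c(p, k)))
            return(sprintf("'letterProbs' must be %d x %d", p, k))
        if (any(lp < 0) || any(abs(rowSums(lp) - 1) > 1e-9))
            return("'letterProbs' rows must be probability vectors")
    }
    cp <- object@couplings
    if (nrow(cp)) {
        if (!all(c("i", "j", "rho") %in% names(cp)))
            return("'couplings' needs columns i, j, rho")
        if (any(cp$i < 1L | cp$i > p | cp$j < 1L | cp$j > p))
            return("coupling positions out of range")
        if (any(abs(cp$i - cp$j) < 4L))
            return("coupled positions must be >= 4 apart (non-overlapping windows)")
        if (any(cp$rho < 0 | cp$rho > 1))
            return("coupling strengths must lie in [0, 1]")
    }
    if (!is.na(object@functionalPosition)) {
        if (object@functionalPosition < 1L || object@functionalPosition > p)
            return("'functionalPosition' out of range")
        if (object@functionalRho < 0 || object@functionalRho >= 1)
            return("'functionalRho' must lie in [0, 1)")
    }
    TRUE
})
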