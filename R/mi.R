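# --- internal machinery over integer-coded columns -------------------------

.alignmentCodes <- function(alignment) {
    matrix(match(alignment@letters, alignment@alphabetLetters),
           nrow(alignment@letters), ncol(alignment@letters))
}

# entropy (bits) of an integer-coded column with k states
.codeEntropy <- function(c1, k) .entropyFromCounts(tabulate(c1, nbins = k))

# joint entropy (bits) of two coded columns; H = log2(m) - sum(c log2 c)/m
.jointEntropy <- function(ci, cj, ki, kj) {
    m <- length(ci)
    cnt <- tabulate((ci - 1L) * kj + cj, nbins = ki * kj)
    nz <- cnt[cnt > 0L]
    log2(m) - sum(nz * log2(nz)) / m
}

# Observed MI, permutation-mean MI, permutation p-value and joint-entropy
# normalized MI for two coded columns.  The permutation stream is local to
# the given seed so results are independent of evaluation order.
.pairPermStats <- function(ci, ki, cj, kj, nPerm, seed, selfPair = FALSE) {
    m <- length(ci)
    hi <- .codeEntropy(ci, ki)
    hj <- .codeEntropy(cj, kj)
    hij <- .jointEntropy(ci, cj, ki, kj)
    # a column against itself: MI is its entropy, exactly (no rounding from
    # the entropy-difference route)
    miObs <- if (selfPair) hi else max(0, hi + hj - hij)
    .withSeed(seed, {
        miPerm <- vapply(seq_len(nPerm), function(t) {
            hp <- .jointEntropy(ci, cj[sample.int(m)], ki, kj)
            max(0, hi + hj - hp)
        }, numeric(1L))
        expectedMi <- mean(miPerm)
        pvalue <- (1 + sum(miPerm >= miObs - 1e-12)) / (nPerm + 1)
        nmi <- if (hij <= 0) 0 else min(1, max(0, (miObs - expectedMi) / hij))
        list(mi = miObs, expectedMi = expectedMi, pvalue = pvalue, nmi = nmi,
             jointEntropy = hij)
    })
}

# --- exported operations ----------------------------------------------------

#' Mutual information between two alignment columns
#'
#' Plug-in mutual information (bits) between the letter distributions of two
#' fragment positions: `MI = sum p(a,b) log2[p(a,b) / (p(a) p(b))]` over the
#' observed contingency table.  Measures correlated local motions: two
#' positions whose conformational states change together carry high MI.
#'
#' @param alignment An [SAAlignment].
#' @param i,j Column indices.
#' @return MI in bits; symmetric, non-negative, `columnMI(a, i, i)` equals
#'   the column entropy.
#' @seealso [normalizedMI()], [miMatrix()]
#' @export
columnMI <- function(alignment, i, j) {
    stopifnot(is(alignment, "SAAlignment"))
    i <- .checkPosition(alignment, i)
    j <- .checkPosition(alignment, j)
    k <- length(alignment@alphabetLetters)
    codes <- .alignmentCodes(alignment)
    hi <- .codeEntropy(codes[, i], k)
    if (i == j) return(hi)
    hj <- .codeEntropy(codes[, j], k)
    max(0, hi + hj - .jointEntropy(codes[, i], codes[, j], k, k))
}

#' Normalized MI and permutation significance for one column pair
#'
#' Corrects the plug-in MI for its finite-sample bias by subtracting the
#' mean MI over row-wise permutations of column `j` (column `i` fixed), and
#' scales by the observed joint entropy, giving a coupling score in
#' `[0, 1]`:
#' `nMI = clamp((MI - E_perm[MI]) / H(i,j), 0, 1)` (0 when `H(i,j) = 0`).
#' Significance is a one-sided permutation test with the add-one convention
#' `p = (1 + #\{MI_perm >= MI_obs\}) / (n_perm + 1)`.
#'
#' @param alignment An [SAAlignment] with at least 10 frames.
#' @param i,j Column indices.
#' @param nPerm Number of permutations, at least 19 (p-value resolution).
#' @param seed Integer seed; the permutation stream is derived from
#'   `(seed, i, j)` so the result is deterministic and order-independent.
#' @return List with `nmi`, `mi` (bits), `expectedMi` (bits), `pvalue` and
#'   `jointEntropy` (bits).
#' @export
normalizedMI <- function(alignment, i, j, nPerm = 199L, seed = 1L) {
    stopifnot(is(alignment, "SAAlignment"))
    i <- .checkPosition(alignment, i)
    j <- .checkPosition(alignment, j)
    if (nrow(alignment@letters) < 10L)
        .stopInput("permutation normalization needs at least 10 frames")
    if (!is.numeric(nPerm) || nPerm < 19L)
        .stopInput("'nPerm' must be at least 19 for usable p-value resolution")
    k <- length(alignment@alphabetLetters)
    codes <- .alignmentCodes(alignment)
    .pairPermStats(codes[, i], k, codes[, j], k, as.integer(nPerm),
                   .pairSeed(seed, i, j), selfPair = i == j)
}

#' All-pairs MI matrix with normalization and significance
#'
#' Computes MI, normalized MI, permutation p-values and Benjamini-Hochberg
#' q-values for every pair of fragment positions.  The per-pair permutation
#' streams are keyed by `(seed, i, j)`, so the matrix is bit-reproducible
#' and independent of computation order.  Pairs of overlapping windows
#' (`|i - j| < 4`) share residues and are trivially correlated; they are
#' computed but flagged in the `overlap` slot so network construction can
#' skip them.  q-values are BH-adjusted across all off-diagonal pairs.
#'
#' @inheritParams normalizedMI
#' @return An [MIMatrix].
#' @export
miMatrix <- function(alignment, nPerm = 199L, seed = 1L) {
    stopifnot(is(alignment, "SAAlignment"))
    if (nrow(alignment@letters) < 10L)
        .stopInput("permutation normalization needs at least 10 frames")
    if (!is.numeric(nPerm) || nPerm < 19L)
        .stopInput("'nPerm' must be at least 19 for usable p-value resolution")
    nPerm <- as.integer(nPerm)
    k <- length(alignment@alphabetLetters)
    codes <- .alignmentCodes(alignment)
    p <- ncol(codes)
    mi <- nmi <- pv <- emi <- matrix(0, p, p)
    for (i in seq_len(p)) for (j in i:p) {
        st <- .pairPermStats(codes[, i], k, codes[, j], k, nPerm,
                             .pairSeed(seed, i, j), selfPair = i == j)
        mi[i, j] <- mi[j, i] <- st$mi
        nmi[i, j] <- nmi[j, i] <- st$nmi
        pv[i, j] <- pv[j, i] <- st$pvalue
        emi[i, j] <- emi[j, i] <- st$expectedMi
    }
    up <- upper.tri(pv)
    qv <- matrix(NA_real_, p, p)
    qv[up] <- stats::p.adjust(pv[up], method = "BH")
    qv[lower.tri(qv)] <- t(qv)[lower.tri(qv)]
    ov <- abs(outer(seq_len(p), seq_len(p), `-`)) < 4L & !diag(p)
    lab <- alignment@positionLabels
    dimnames(mi) <- dimnames(nmi) <- dimnames(pv) <- dimnames(qv) <-
        dimnames(emi) <- dimnames(ov) <- list(lab, lab)
    new("MIMatrix", mi = mi, nmi = nmi, pvalue = pv, qvalue = qv,
        expectedMi = emi, overlap = ov, nPerm = nPerm,
        seed = as.integer(seed), positionLabels = lab)
}

setMethod("show", "MIMatrix", function(object) {
    p <- ncol(object@mi)
    off <- object@nmi[upper.tri(object@nmi)]
    cat(sprintf("MIMatrix: %d positions, %d permutations (seed %d); max off-diagonal nMI %.4f\n",
                p, object@nPerm, object@seed, if (length(off)) max(off) else NA))
})

#' Discretize a functional index into equal-width bins
#'
#' Any per-frame scalar describing a function-related property (e.g. the
#' projection of each frame onto a collective motion) is discretized into
#' `nBins` equal-width bins spanning its observed range, so it can enter the
#' MI machinery as a categorical column.  Bins are half-open `[lo, hi)`,
#' the last bin closed.  A constant series occupies a single bin and is
#' flagged degenerate.
#'
#' @param values Numeric vector (one value per frame, >= 10 frames), finite.
#' @param nBins Number of bins, >= 2 (default 10).
#' @return A [FunctionalIndex].
#' @export
binFunctionalIndex <- function(values, nBins = 10L) {
    if (!is.numeric(values) || length(values) < 10L)
        .stopInput("'values' must be a numeric vector with at least 10 frames")
    if (any(!is.finite(values)))
        .stopInput("'values' contains non-finite entries")
    if (!is.numeric(nBins) || length(nBins) != 1L || nBins < 2L)
        .stopInput("'nBins' must be a single integer >= 2")
    nBins <- as.integer(nBins)
    degenerate <- min(values) == max(values)
    rng <- if (degenerate) c(values[1L] - 0.5, values[1L] + 0.5) else range(values)
    edges <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
    symbols <- findInterval(values, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
    new("FunctionalIndex", values = as.numeric(values), nBins = nBins,
        binEdges = edges, symbols = as.integer(symbols),
        degenerate = degenerate)
}

setMethod("show", "FunctionalIndex", function(object) {
    cat(sprintf("FunctionalIndex: %d frames in %d equal-width bins (%d occupied)%s\n",
                length(object@values), object@nBins,
                length(unique(object@symbols)),
                if (object@degenerate) " [degenerate: constant series]" else ""))
})

#' MI between a functional index and every fragment position
#'
#' Treats the binned functional index as an extra categorical column and
#' applies the same MI / permutation-normalization / significance machinery
#' as [normalizedMI()] against every alignment column.  The resulting nMI is
#' a score for how much each local fragment's conformational switching
#' carries information about the functional property -- candidate sites for
#' e.g. mutagenesis.
#'
#' @param alignment An [SAAlignment].
#' @param index A [FunctionalIndex] with one value per alignment row.
#' @param nPerm Permutations per position (>= 19).
#' @param seed Base seed of the permutation streams.
#' @return Data frame with one row per position (`position`, `label`, `mi`,
#'   `nmi`, `pvalue`, `qvalue`), ranked by `nmi` descending.  q-values are
#'   BH-adjusted across the positions.
#' @export
functionalMIProfile <- function(alignment, index, nPerm = 199L, seed = 1L) {
    stopifnot(is(alignment, "SAAlignment"), is(index, "FunctionalIndex"))
    if (length(index@values) != nrow(alignment@letters))
        .stopInput("functional index has %d values but the alignment has %d frames",
                   length(index@values), nrow(alignment@letters))
    if (!is.numeric(nPerm) || nPerm < 19L)
        .stopInput("'nPerm' must be at least 19 for usable p-value resolution")
    nPerm <- as.integer(nPerm)
    k <- length(alignment@alphabetLetters)
    codes <- .alignmentCodes(alignment)
    p <- ncol(codes)
    rows <- lapply(seq_len(p), function(i) {
        st <- .pairPermStats(codes[, i], k, index@symbols, index@nBins, nPerm,
                             .pairSeed(seed, i, 0L))
        data.frame(position = i, label = alignment@positionLabels[i],
                   mi = st$mi, nmi = st$nmi, pvalue = st$pvalue)
    })
    out <- do.call(rbind, rows)
    out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
    out[order(-out$nmi, out$position), , drop = FALSE]
}

#' Read a functional-index series from plain text
#'
#' One float per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Numeric vector of per-frame values.
#' @export
readFunctionalIndex <- function(path) {
    if (!file.exists(path)) .stopInput("functional-index file '%s' does not exist", path)
    lines <- trimws(readLines(path))
    lines <- lines[lines != "" & !startsWith(lines, "#")]
    v <- suppressWarnings(as.numeric(lines))
    if (!length(v) || any(is.na(v)))
        .stopInput("'%s' must contain one numeric value per line", path)
    v
}
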