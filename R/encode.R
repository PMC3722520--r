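#' Create an Ensemble from a coordinate array
#'
#' @param coords Numeric m x n x 3 array of C-alpha coordinates (Angstrom),
#'   or an n x 3 matrix for a single conformer.
#' @param residueIds Integer residue numbers (default `1..n`).
#' @param frameTimes Optional per-frame timestamps.
#' @return An [Ensemble].
#' @export
ensemble <- function(coords, residueIds = NULL, frameTimes = numeric()) {
    if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
    if (is.null(residueIds)) residueIds <- seq_len(dim(coords)[2L])
    new("Ensemble", coords = coords, residueIds = as.integer(residueIds),
        frameTimes = as.numeric(frameTimes))
}

#' @describeIn ensemble Number of frames.
#' @param x An `Ensemble`.
#' @export
nFrames <- function(x) dim(x@coords)[1L]

#' @describeIn ensemble Number of residues.
#' @export
nResidues <- function(x) dim(x@coords)[2L]

#' @describeIn ensemble n x 3 C-alpha coordinates of one frame.
#' @param i Frame index.
#' @export
frameCoords <- function(x, i) {
    m <- x@coords[i, , , drop = FALSE]
    dim(m) <- dim(x@coords)[2:3]
    m
}

setMethod("show", "Ensemble", function(object) {
    cat(sprintf("Ensemble: %d frames x %d residues (C-alpha), residues %d..%d\n",
                nFrames(object), nResidues(object),
                min(object@residueIds), max(object@residueIds)))
})

#' Split a conformation into overlapping four-residue fragments
#'
#' An n-residue chain yields n-3 overlapping windows; window i (1-based)
#' covers residues i..i+3.  This is the window bookkeeping behind the
#' "string of length n-3" encoding.
#'
#' @param frame Numeric n x 3 matrix of C-alpha coordinates, n >= 4.
#' @return List of n-3 matrices, each 4 x 3.
#' @export
extractFragments <- function(frame) {
    frame <- .checkFragmentChain(frame)
    n <- nrow(frame)
    lapply(seq_len(n - 3L), function(i) frame[i:(i + 3L), , drop = FALSE])
}

.checkFragmentChain <- function(frame) {
    if (!is.matrix(frame) || ncol(frame) != 3L || !is.numeric(frame))
        .stopInput("'frame' must be a numeric n x 3 matrix")
    if (nrow(frame) < 4L)
        .stopInput("need at least 4 residues to form a fragment (got %d)", nrow(frame))
    if (!all(is.finite(frame)))
        .stopInput("'frame' contains non-finite coordinates")
    frame
}

# Pre-center alphabet fragments once for the inner encoding loop.
.alphabetFitData <- function(alphabet) {
    list(centered = lapply(alphabet@coords, function(m) sweep(m, 2L, colMeans(m))),
         letters = alphabet@letters)
}

# Letter index and RMSD of the best-fitting canonical fragment for one
# 4-point window; ties broken by alphabet (letter) order via which.min.
.bestLetter <- function(window, fit) {
    wc <- sweep(window, 2L, colMeans(window))
    r <- vapply(fit$centered, function(fc) .kabschRMSD(fc, wc), numeric(1L))
    i <- which.min(r)
    c(i, r[i])
}

#' Encode one conformation with independent local fits
#'
#' Each overlapping four-residue window is superposed independently onto
#' every canonical fragment; the letter with minimal RMSD wins (ties go to
#' the alphabetically earlier letter).
#'
#' @param frame Numeric n x 3 C-alpha coordinate matrix.
#' @param alphabet A [StructuralAlphabet].
#' @return List with `string` (character scalar of n-3 letters) and
#'   `fitRMSD` (numeric vector of the winning superposition RMSD per
#'   position, Angstrom).
#' @seealso [encodeGlobal()], [encodeEnsemble()]
#' @export
encodeLocal <- function(frame, alphabet) {
    frame <- .checkFragmentChain(frame)
    fit <- .alphabetFitData(alphabet)
    p <- nrow(frame) - 3L
    idx <- integer(p)
    rmsd <- numeric(p)
    for (i in seq_len(p)) {
        best <- .bestLetter(frame[i:(i + 3L), , drop = FALSE], fit)
        idx[i] <- best[1L]
        rmsd[i] <- best[2L]
    }
    list(string = paste(fit$letters[idx], collapse = ""), fitRMSD = rmsd)
}

#' Encode one conformation by sequential global chain reconstruction
#'
#' Letters are chosen N- to C-terminally while a model chain is rebuilt from
#' the canonical fragments.  The first position uses the local criterion and
#' seeds the reconstruction with the fitted fragment.  At each later
#' position i, every candidate canonical fragment is rigidly fitted onto the
#' last three reconstructed C-alpha positions plus the next true C-alpha;
#' its transformed fourth point extends the candidate chain, and the letter
#' minimizing the RMSD of the reconstructed chain against the true chain
#' over residues 1..i+3 is kept.  `fitRMSD` stores that running RMSD, so it
#' measures cumulative reconstruction accuracy rather than per-window fit.
#'
#' @inheritParams encodeLocal
#' @return As [encodeLocal()].
#' @export
encodeGlobal <- function(frame, alphabet) {
    frame <- .checkFragmentChain(frame)
    fit <- .alphabetFitData(alphabet)
    n <- nrow(frame)
    p <- n - 3L
    idx <- integer(p)
    rmsd <- numeric(p)

    first <- .bestLetter(frame[1:4, , drop = FALSE], fit)
    idx[1L] <- first[1L]
    rmsd[1L] <- first[2L]
    recon <- .kabschTransform(alphabet@coords[[first[1L]]],
                              frame[1:4, , drop = FALSE])(alphabet@coords[[first[1L]]])
    if (p >= 2L) for (i in 2:p) {
        anchor <- rbind(recon[(i):(i + 2L), , drop = FALSE],
                        frame[i + 3L, , drop = FALSE])
        bestRun <- Inf
        bestK <- NA_integer_
        bestPt <- NULL
        for (k in seq_along(fit$letters)) {
            placed <- .kabschTransform(alphabet@coords[[k]], anchor)(alphabet@coords[[k]])
            cand <- placed[4L, ]
            dev <- rbind(recon, cand) - frame[seq_len(i + 3L), , drop = FALSE]
            run <- sqrt(sum(dev * dev) / (i + 3L))
            if (run < bestRun) {  # strict improvement; earlier letter wins ties
                bestRun <- run
                bestK <- k
                bestPt <- cand
            }
        }
        idx[i] <- bestK
        rmsd[i] <- bestRun
        recon <- rbind(recon, bestPt)
    }
    list(string = paste(fit$letters[idx], collapse = ""), fitRMSD = rmsd)
}

#' Encode a conformational ensemble into a structural-string alignment
#'
#' Encodes every frame of an ensemble and stacks the resulting strings into
#' an m x (n-3) alignment, retaining the per-position superposition RMSD of
#' every frame for accuracy inspection.
#'
#' @param ens An [Ensemble].
#' @param alphabet A [StructuralAlphabet].
#' @param mode `"local"` (independent best fit per window) or `"global"`
#'   (sequential chain reconstruction).
#' @return An [SAAlignment].
#' @export
encodeEnsemble <- function(ens, alphabet, mode = c("local", "global")) {
    stopifnot(is(ens, "Ensemble"), is(alphabet, "StructuralAlphabet"))
    validObject(ens)
    mode <- match.arg(mode)
    enc <- if (mode == "local") encodeLocal else encodeGlobal
    m <- nFrames(ens)
    p <- nResidues(ens) - 3L
    L <- matrix(NA_character_, m, p)
    R <- matrix(NA_real_, m, p)
    for (f in seq_len(m)) {
        res <- tryCatch(enc(frameCoords(ens, f), alphabet),
            error = function(e) stop(sprintf("frame %d: %s", f, conditionMessage(e)),
                                     call. = FALSE))
        L[f, ] <- strsplit(res$string, "")[[1L]]
        R[f, ] <- res$fitRMSD
    }
    rid <- ens@residueIds
    new("SAAlignment", letters = L, alphabetName = alphabet@name,
        alphabetLetters = alphabet@letters,
        positionLabels = sprintf("%d-%d", rid[seq_len(p)], rid[seq_len(p) + 3L]),
        fitRMSD = R)
}

#' Per-position encoding-accuracy summary
#'
#' Summarizes the per-frame superposition RMSD of an encoded alignment into
#' a per-position table, for inspecting where the alphabet represents the
#' ensemble well or poorly.
#'
#' @param alignment An [SAAlignment] carrying fit-RMSD records (i.e. one
#'   produced by [encodeEnsemble()], not read from FASTA).
#' @return Data frame with columns `position`, `label`, `mean_rmsd`,
#'   `sd_rmsd`, `max_rmsd` (Angstrom; `sd_rmsd` is 0 for a single frame).
#' @export
encodingAccuracy <- function(alignment) {
    stopifnot(is(alignment, "SAAlignment"))
    if (!length(alignment@fitRMSD))
        stop("alignment carries no encoding-accuracy records", call. = FALSE)
    R <- alignment@fitRMSD
    sds <- apply(R, 2L, stats::sd)
    sds[is.na(sds)] <- 0
    data.frame(position = seq_len(ncol(R)), label = alignment@positionLabels,
               mean_rmsd = colMeans(R), sd_rmsd = sds,
               max_rmsd = apply(R, 2L, max))
}
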