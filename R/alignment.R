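#' Build an SAAlignment from structural strings
#'
#' @param strings Character vector of m equal-length strings over the
#'   alphabet's letters (rows in frame/time order).
#' @param alphabet The [StructuralAlphabet] the strings are written in.
#' @param positionLabels Optional residue-range labels (default
#'   `"i-(i+3)"`).
#' @return An [SAAlignment] without accuracy records.
#' @export
alignmentFromStrings <- function(strings, alphabet, positionLabels = NULL) {
    if (!length(strings)) .stopInput("empty alignment: no strings given")
    w <- unique(nchar(strings))
    if (length(w) != 1L)
        .stopInput("ragged alignment: record lengths %s differ",
                   paste(sort(w), collapse = ", "))
    if (w[1L] < 1L) .stopInput("empty alignment: zero-length strings")
    L <- matrix(unlist(strsplit(strings, ""), use.names = FALSE),
                nrow = length(strings), byrow = TRUE)
    if (is.null(positionLabels))
        positionLabels <- sprintf("%d-%d", seq_len(w), seq_len(w) + 3L)
    bad <- matrix(!(L %in% alphabet@letters), nrow(L))
    if (any(bad)) {
        ix <- which(bad, arr.ind = TRUE)[1L, ]
        .stopInput("record %d, column %d: letter '%s' is not in alphabet '%s'",
                   ix[1L], ix[2L], L[ix[1L], ix[2L]], alphabet@name)
    }
    new("SAAlignment", letters = L, alphabetName = alphabet@name,
        alphabetLetters = alphabet@letters, positionLabels = positionLabels,
        fitRMSD = matrix(numeric(), 0L, 0L))
}

#' @describeIn alignmentFromStrings The m structural strings of an alignment.
#' @param x An `SAAlignment`.
#' @export
alignmentStrings <- function(x) apply(x@letters, 1L, paste, collapse = "")

#' @describeIn alignmentFromStrings Number of frames (rows).
#' @export
alignmentFrames <- function(x) nrow(x@letters)

#' @describeIn alignmentFromStrings Number of fragment positions (columns).
#' @export
alignmentPositions <- function(x) ncol(x@letters)

setMethod("show", "SAAlignment", function(object) {
    cat(sprintf("SAAlignment: %d frames x %d fragment positions, alphabet '%s'%s\n",
                nrow(object@letters), ncol(object@letters), object@alphabetName,
                if (length(object@fitRMSD)) " (with accuracy records)" else ""))
})

#' Write / read a structural-string alignment in FASTA format
#'
#' The alignment is written as standard FASTA (width 60) with record ids
#' `frame_00001`, `frame_00002`, ...; rows stay in frame order so the file
#' can be re-read for correlation analysis.  On read, records must be
#' uppercase, of equal length, and use only the alphabet's letters.
#'
#' @param alignment An [SAAlignment].
#' @param path FASTA file path.
#' @return `writeFastaAlignment` invisibly returns `path`;
#'   `readFastaAlignment` returns an [SAAlignment] (without accuracy
#'   records).
#' @export
writeFastaAlignment <- function(alignment, path) {
    stopifnot(is(alignment, "SAAlignment"))
    validObject(alignment)
    s <- alignmentStrings(alignment)
    set <- Biostrings::BStringSet(s)
    names(set) <- sprintf("frame_%05d", seq_along(s))
    tmp <- paste0(path, ".partial")
    Biostrings::writeXStringSet(set, tmp, width = 60L)
    if (!file.rename(tmp, path))
        stop(sprintf("cannot write '%s'", path), call. = FALSE)
    invisible(path)
}

#' @rdname writeFastaAlignment
#' @param alphabet The [StructuralAlphabet] the strings must belong to.
#' @export
readFastaAlignment <- function(path, alphabet) {
    if (!file.exists(path)) .stopInput("FASTA file '%s' does not exist", path)
    set <- tryCatch(Biostrings::readBStringSet(path),
        error = function(e) .stopInput("cannot parse FASTA '%s': %s",
                                       path, conditionMessage(e)))
    if (!length(set)) .stopInput("empty alignment: '%s' has no FASTA records", path)
    alignmentFromStrings(as.character(set), alphabet)
}

.columnCounts <- function(alignment, position) {
    tab <- tabulate(match(alignment@letters[, position], alignment@alphabetLetters),
                    nbins = length(alignment@alphabetLetters))
    names(tab) <- alignment@alphabetLetters
    tab
}

#' Shannon entropy of one alignment column
#'
#' The conformational variability of a fragment position, measured as the
#' plug-in Shannon entropy H = -sum p log2 p (bits) of its observed letter
#' frequencies.  No finite-sample bias correction is applied at this layer.
#'
#' @param alignment An [SAAlignment].
#' @param position Column index in `1..(n-3)`.
#' @return Entropy in bits, between 0 and log2(k).
#' @export
columnEntropy <- function(alignment, position) {
    stopifnot(is(alignment, "SAAlignment"))
    .checkPosition(alignment, position)
    .entropyFromCounts(.columnCounts(alignment, position))
}

.checkPosition <- function(alignment, position) {
    if (!is.numeric(position) || length(position) != 1L ||
        position < 1L || position > ncol(alignment@letters))
        .stopInput("position %s out of range 1..%d",
                   format(position), ncol(alignment@letters))
    invisible(as.integer(position))
}

#' Per-column fragment profile of an alignment
#'
#' The relative frequency of every alphabet letter at every position,
#' together with the column entropy: the sequence profile of the encoded
#' ensemble.
#'
#' @param alignment An [SAAlignment].
#' @return Data frame with `position`, `label`, `entropy` (bits) and one
#'   relative-frequency column per alphabet letter (unobserved letters have
#'   frequency 0; each row's frequencies sum to 1).
#' @export
sequenceProfile <- function(alignment) {
    stopifnot(is(alignment, "SAAlignment"))
    m <- nrow(alignment@letters)
    p <- ncol(alignment@letters)
    freqs <- t(vapply(seq_len(p), function(i) .columnCounts(alignment, i) / m,
                      numeric(length(alignment@alphabetLetters))))
    colnames(freqs) <- alignment@alphabetLetters
    cbind(data.frame(position = seq_len(p), label = alignment@positionLabels,
                     entropy = apply(freqs, 1L, function(f) .entropyFromCounts(f))),
          as.data.frame(freqs))
}

#' Fragment-transition probability matrix at one position
#'
#' Counts letter transitions between consecutive frames at one column and
#' normalizes each row by its outgoing count, estimating the relative
#' frequency of specific fragment transitions (local conformational
#' kinetics).  Rows whose letter is never a transition source are all zero
#' and reported in the `"unobserved"` attribute.
#'
#' @param alignment An [SAAlignment] with at least 2 frames, rows in time
#'   order (lag-1 transitions only).
#' @param position Column index.
#' @return k x k row-stochastic matrix (row = from-letter, column =
#'   to-letter) with letter dimnames and attributes `"counts"` (raw
#'   transition counts) and `"unobserved"` (logical per row).
#' @export
transitionMatrix <- function(alignment, position) {
    stopifnot(is(alignment, "SAAlignment"))
    .checkPosition(alignment, position)
    if (nrow(alignment@letters) < 2L)
        stop("transition statistics need at least 2 frames", call. = FALSE)
    lets <- alignment@alphabetLetters
    k <- length(lets)
    col <- match(alignment@letters[, position], lets)
    m <- length(col)
    counts <- matrix(0L, k, k, dimnames = list(from = lets, to = lets))
    idx <- cbind(col[-m], col[-1L])
    for (r in seq_len(nrow(idx)))
        counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
    rs <- rowSums(counts)
    P <- counts / ifelse(rs > 0, rs, 1)
    attr(P, "counts") <- counts
    attr(P, "unobserved") <- rs == 0
    P
}
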