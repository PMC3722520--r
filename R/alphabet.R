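#' Construct a structural alphabet
#'
#' @param name Alphabet name.
#' @param letters Character vector of single distinct letters.
#' @param coords List of 4x3 numeric matrices, parallel to `letters`.
#' @return A [StructuralAlphabet] with fragments in letter-sorted order.
#' @export
structuralAlphabet <- function(name, letters, coords) {
    if (length(letters) != length(coords))
        .stopInput("need one coordinate block per letter")
    o <- order(letters)
    coords <- lapply(coords, function(m) {
        m <- unname(as.matrix(m))
        storage.mode(m) <- "double"
        m
    })
    new("StructuralAlphabet", name = as.character(name),
        letters = as.character(letters)[o], coords = coords[o])
}

#' @describeIn structuralAlphabet Number of fragments (letters).
#' @param x,object A `StructuralAlphabet`.
#' @export
nFragments <- function(x) length(x@letters)

#' @describeIn structuralAlphabet The sorted letter set.
#' @export
fragmentLetters <- function(x) x@letters

#' @describeIn structuralAlphabet 4x3 coordinate matrix of one fragment.
#' @param letter Single letter selecting the fragment.
#' @export
fragmentCoords <- function(x, letter) {
    i <- match(letter, x@letters)
    if (is.na(i)) .stopInput("no fragment with letter '%s' in alphabet '%s'",
                             letter, x@name)
    x@coords[[i]]
}

#' @describeIn structuralAlphabet Alphabet name.
#' @export
alphabetName <- function(x) x@name

setMethod("show", "StructuralAlphabet", function(object) {
    cat(sprintf("StructuralAlphabet '%s' with %d canonical fragments (4 C-alpha points each)\n",
                object@name, length(object@letters)))
    cat("letters:", paste(object@letters, collapse = ""), "\n")
})

#' Read a structural alphabet from its plain-text format
#'
#' The format is: a header line `# SA <name> <k>`, then for each fragment a
#' line `> <letter>` followed by four `x y z` coordinate lines (Angstrom).
#' Lines starting with `#` after the header are comments.
#'
#' @param path Path to an alphabet file.
#' @return A [StructuralAlphabet].
#' @seealso [writeAlphabet()], [defaultAlphabet()]
#' @export
readAlphabet <- function(path) {
    if (!file.exists(path)) .stopInput("alphabet file '%s' does not exist", path)
    lines <- readLines(path)
    header <- grep("^# SA ", lines)
    if (!length(header))
        .stopInput("'%s' line 1: missing '# SA <name> <k>' header", path)
    hdr <- strsplit(sub("^# SA +", "", lines[header[1L]]), "[ \t]+")[[1L]]
    name <- hdr[1L]
    letters <- character()
    coords <- list()
    i <- header[1L] + 1L
    n <- length(lines)
    while (i <= n) {
        line <- trimws(lines[i])
        if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
        if (!grepl("^> *\\S$", line))
            .stopInput("'%s' line %d: expected '> <letter>', got '%s'",
                       path, i, lines[i])
        letter <- sub("^> *", "", line)
        pts <- matrix(NA_real_, 4L, 3L)
        for (r in 1:4) {
            i <- i + 1L
            if (i > n) .stopInput("'%s': fragment '%s' truncated (needs 4 coordinate lines)",
                                  path, letter)
            v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1L]]))
            if (length(v) != 3L || any(!is.finite(v)))
                .stopInput("'%s' line %d: expected three coordinates, got '%s'",
                           path, i, lines[i])
            pts[r, ] <- v
        }
        if (letter %in% letters)
            .stopInput("'%s': duplicate fragment letter '%s'", path, letter)
        letters <- c(letters, letter)
        coords <- c(coords, list(pts))
        i <- i + 1L
    }
    if (length(letters) < 2L)
        .stopInput("'%s': an alphabet needs at least 2 fragments", path)
    structuralAlphabet(name, letters, coords)
}

#' Write a structural alphabet to its plain-text format
#'
#' Coordinates are printed with 6 decimals, so a read/write round trip
#' reproduces the alphabet to 1e-6 Angstrom.
#'
#' @param alphabet A valid [StructuralAlphabet].
#' @param path Output file path.
#' @export
writeAlphabet <- function(alphabet, path) {
    validObject(alphabet)
    lines <- sprintf("# SA %s %d", alphabet@name, length(alphabet@letters))
    for (i in seq_along(alphabet@letters)) {
        lines <- c(lines, sprintf("> %s", alphabet@letters[i]),
                   apply(alphabet@coords[[i]], 1L,
                         function(p) sprintf("%.6f %.6f %.6f", p[1L], p[2L], p[3L])))
    }
    .writeLinesAtomic(lines, path)
    invisible(path)
}

#' The bundled default 25-letter alphabet
#'
#' Loads the 25-fragment alphabet shipped with the package (letters A..Y).
#' Its fragment coordinates are synthetic: a reproducible stand-in with the
#' canonical structure of the field's 25-state C-alpha fragment alphabets
#' (an ideal helical turn, an ideal extended segment, and well-separated
#' randomized local geometries), generated with
#' `makeSyntheticAlphabet(25, seed = 101)`.
#'
#' @return A [StructuralAlphabet] with 25 fragments.
#' @export
defaultAlphabet <- function() {
    readAlphabet(system.file("extdata", "sa25_synthetic.txt",
                             package = "SAMotions", mustWork = TRUE))
}

# Place a fourth point from three anchor points and internal coordinates
# (bond length d, planar angle theta and torsion tau, radians): standard
# natural-extension chain-growth construction.
.nerfPlace <- function(p1, p2, p3, d, theta, tau) {
    bc <- p3 - p2
    bc <- bc / sqrt(sum(bc^2))
    ab <- p2 - p1
    n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
           ab[3L] * bc[1L] - ab[1L] * bc[3L],
           ab[1L] * bc[2L] - ab[2L] * bc[1L])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
           n[3L] * bc[1L] - n[1L] * bc[3L],
           n[1L] * bc[2L] - n[2L] * bc[1L])
    d2 <- c(-d * cos(theta), d * sin(theta) * cos(tau), d * sin(theta) * sin(tau))
    p3 + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Build a 4-point fragment from internal coordinates (lengths, angles, torsion).
.fragmentFromInternal <- function(d12, d23, d34, theta123, theta234, tau) {
    p1 <- c(0, 0, 0)
    p2 <- c(d12, 0, 0)
    p3 <- p2 + d23 * c(-cos(theta123), sin(theta123), 0)
    p4 <- .nerfPlace(p1, p2, p3, d34, theta234, tau)
    m <- rbind(p1, p2, p3, p4)
    sweep(m, 2L, colMeans(m))
}

.idealHelixFragment <- function() {
    # canonical alpha-helical C-alpha turn: radius 2.3 A, 100 deg/residue,
    # rise 1.5 A/residue
    i <- 0:3
    m <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
               1.5 * i)
    sweep(m, 2L, colMeans(m))
}

.idealExtendedFragment <- function() {
    # ideal extended (beta-like) C-alpha trace: 3.8 A pseudo-bonds,
    # 124 deg pseudo-angles, trans torsion
    .fragmentFromInternal(3.8, 3.8, 3.8, 124 * pi / 180, 124 * pi / 180, pi)
}

#' Generate a synthetic structural alphabet
#'
#' Produces a deterministic, well-separated alphabet for testing and
#' simulation: fragment `A` is an ideal alpha-helical C-alpha turn, fragment
#' `B` an ideal extended segment, and the remaining fragments are randomized
#' local geometries drawn in internal coordinates (pseudo-bonds 3.7-3.9
#' Angstrom, pseudo-angles 80-140 degrees, free torsions -- the realistic
#' range of protein C-alpha traces).  Fragments closer than 0.5 Angstrom
#' minimal superposition RMSD to any other are resampled until the whole set
#' is mutually distinguishable.
#'
#' @param k Number of fragments, between 2 and 25 (letters `A` onward;
#'   single-letter labels keep the strings FASTA-compatible).
#' @param seed Integer seed; the result is deterministic in it.
#' @return A [StructuralAlphabet] named `sprintf("synthetic-k%d-s%d", k, seed)`.
#' @export
makeSyntheticAlphabet <- function(k, seed = 1L) {
    if (!is.numeric(k) || length(k) != 1L || k < 2L || k > 25L)
        .stopInput("'k' must be between 2 and 25 (got %s)", format(k))
    k <- as.integer(k)
    .withSeed(seed, {
        randomFrag <- function() .fragmentFromInternal(
            stats::runif(1L, 3.7, 3.9), stats::runif(1L, 3.7, 3.9),
            stats::runif(1L, 3.7, 3.9),
            stats::runif(1L, 80, 140) * pi / 180,
            stats::runif(1L, 80, 140) * pi / 180,
            stats::runif(1L, -pi, pi))
        coords <- vector("list", k)
        coords[[1L]] <- .idealHelixFragment()
        if (k >= 2L) coords[[2L]] <- .idealExtendedFragment()
        if (k > 2L) for (i in 3:k) coords[[i]] <- randomFrag()
        # resample the later member of any too-close pair until separated
        for (iter in seq_len(2000L)) {
            rms <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
                if (i < j) superposeRMSD(coords[[i]], coords[[j]]) else Inf))
            if (min(rms) >= 0.5) break
            w <- which(rms == min(rms), arr.ind = TRUE)[1L, ]
            coords[[max(w)]] <- randomFrag()
            if (iter == 2000L)
                stop("could not separate synthetic fragments by 0.5 Angstrom",
                     call. = FALSE)
        }
        structuralAlphabet(sprintf("synthetic-k%d-s%d", k, as.integer(seed)),
                           LETTERS[seq_len(k)], coords)
    })
}

#' Generate a uniform-geometry (torsion-only) synthetic alphabet
#'
#' Produces an alphabet whose fragments all share the same pseudo-bond
#' length (3.8 Angstrom) and pseudo-angle (110 degrees) and differ only in
#' the torsion of the fourth point.  Because every fragment's leading and
#' trailing 3-point triples are then congruent, a chain grown by
#' least-squares fragment concatenation ([stringsToEnsemble()]) realizes
#' every window as an *exact* rigid copy of its canonical fragment, so
#' zero-noise ensembles re-encode to their generating strings with zero fit
#' RMSD.  This is the default alphabet of the synthetic-ensemble generator.
#'
#' Fragment `A` carries the helical torsion (50 degrees), fragment `B` the
#' extended/trans torsion (180 degrees); further fragments get random
#' torsions, resampled until all pairwise superposition RMSDs are at least
#' 0.5 Angstrom.  On the torsion circle that separation supports at most 8
#' letters, hence the `k` limit.
#'
#' @param k Number of fragments, between 2 and 8.
#' @param seed Integer seed.
#' @return A [StructuralAlphabet] named
#'   `sprintf("uniformgeo-k%d-s%d", k, seed)`.
#' @seealso [makeSyntheticAlphabet()] for the general (unconstrained)
#'   synthetic alphabet.
#' @export
makeUniformGeometryAlphabet <- function(k, seed = 1L) {
    if (!is.numeric(k) || length(k) != 1L || k < 2L || k > 8L)
        .stopInput("'k' must be between 2 and 8 for a 0.5-Angstrom-separated torsion family (got %s)",
                   format(k))
    k <- as.integer(k)
    theta <- 110 * pi / 180
    frag <- function(tauDeg) .fragmentFromInternal(3.8, 3.8, 3.8, theta, theta,
                                                   tauDeg * pi / 180)
    .withSeed(seed, {
        taus <- c(50, 180, stats::runif(max(0L, k - 2L), -180, 180))[seq_len(k)]
        coords <- lapply(taus, frag)
        for (iter in seq_len(5000L)) {
            rms <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
                if (i < j) superposeRMSD(coords[[i]], coords[[j]]) else Inf))
            if (min(rms) >= 0.5) break
            w <- which(rms == min(rms), arr.ind = TRUE)[1L, ]
            resample <- max(w)
            if (resample <= 2L) resample <- 3L   # keep helix/extended fixed
            taus[resample] <- stats::runif(1L, -180, 180)
            coords[[resample]] <- frag(taus[resample])
            if (iter == 5000L)
                stop("could not separate torsion fragments by 0.5 Angstrom",
                     call. = FALSE)
        }
        structuralAlphabet(sprintf("uniformgeo-k%d-s%d", k, as.integer(seed)),
                           LETTERS[seq_len(k)], coords)
    })
}
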