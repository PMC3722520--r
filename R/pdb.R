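#' Read a conformational ensemble from PDB
#'
#' Reads a (possibly multi-model) PDB file and extracts the C-alpha trace
#' of one chain into an [Ensemble].  Trajectory alignment/imaging is
#' assumed done upstream; frames are taken in model order.
#'
#' @param path PDB file path (single- or multi-model).
#' @param chain Chain identifier; `NULL` is accepted only when the file
#'   contains a single chain.
#' @return An [Ensemble].
#' @export
readEnsemblePDB <- function(path, chain = NULL) {
    if (!file.exists(path)) .stopInput("PDB file '%s' does not exist", path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
    if (!length(sel$atom)) .stopInput("'%s' contains no C-alpha atoms", path)
    chains <- unique(pdb$atom$chain[sel$atom])
    if (is.null(chain)) {
        if (length(chains) > 1L)
            .stopInput("'%s' has chains %s; pick one with 'chain='",
                       path, paste(chains, collapse = ", "))
        chain <- chains[1L]
    } else if (!chain %in% chains) {
        .stopInput("chain '%s' not found in '%s' (has %s)", chain, path,
                   paste(chains, collapse = ", "))
    }
    keep <- sel$atom[pdb$atom$chain[sel$atom] %in% chain]
    resno <- pdb$atom$resno[keep]
    if (anyDuplicated(resno))
        .stopInput("'%s': duplicate C-alpha records within chain '%s' (alt-locs?)",
                   path, chain)
    xyzIdx <- as.vector(t(outer(keep, 1:3, function(a, o) (a - 1L) * 3L + o)))
    xyz <- pdb$xyz[, xyzIdx, drop = FALSE]
    m <- nrow(xyz)
    n <- length(keep)
    coords <- aperm(array(t(xyz), c(3L, n, m)), c(3L, 2L, 1L))
    ensemble(coords, residueIds = resno)
}

#' Write an ensemble as a multi-model C-alpha PDB
#'
#' One MODEL per frame, poly-alanine C-alpha records, chain `A`.
#'
#' @param ens An [Ensemble].
#' @param path Output PDB path.
#' @export
writeEnsemblePDB <- function(ens, path) {
    stopifnot(is(ens, "Ensemble"))
    validObject(ens)
    n <- nResidues(ens)
    m <- nFrames(ens)
    xyz <- matrix(NA_real_, m, 3L * n)
    for (f in seq_len(m)) xyz[f, ] <- as.vector(t(frameCoords(ens, f)))
    tmp <- paste0(path, ".partial")
    bio3d::write.pdb(file = tmp, xyz = xyz, resno = ens@residueIds,
                     resid = rep("ALA", n), elety = rep("CA", n),
                     chain = rep("A", n))
    if (!file.rename(tmp, path))
        stop(sprintf("cannot write '%s'", path), call. = FALSE)
    invisible(path)
}
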