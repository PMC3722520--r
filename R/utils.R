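# internal helpers shared across modules

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite integer", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic substream seed for the (i, j) pair under a base seed;
# independent of the order in which pairs are visited.  Kept within 2^31.
.pairSeed <- function(seed, i, j) {
    as.integer((abs(as.numeric(seed)) %% 1e6) * 1000003 +
               as.numeric(i) * 4099 + as.numeric(j)) %% 2147483647L
}

# Shannon entropy (bits) from a vector of non-negative counts.
.entropyFromCounts <- function(counts) {
    n <- sum(counts)
    if (n == 0L) return(0)
    p <- counts[counts > 0] / n
    -sum(p * log2(p))
}

.stopInput <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...), class = c("sa_input_error", "error")))
}

# Write lines atomically: compose at <path>.partial, rename on success.
.writeLinesAtomic <- function(lines, path) {
    tmp <- paste0(path, ".partial")
    con <- file(tmp, open = "wb")
    ok <- FALSE
    tryCatch({
        writeLines(lines, con, sep = "\n")
        ok <- TRUE
    }, finally = close(con))
    if (ok && !file.rename(tmp, path))
        stop(sprintf("cannot write output file '%s'", path), call. = FALSE)
    invisible(path)
}

# Provenance header lines for plain-text outputs.  Deliberately contains no
# timestamps: identical inputs and seed must produce byte-identical files.
.provenanceHeader <- function(...) {
    kv <- list(...)
    c(sprintf("# SAMotions %s", as.character(utils::packageVersion("SAMotions"))),
      vapply(names(kv), function(k) sprintf("# %s: %s", k, as.character(kv[[k]])),
             character(1L)))
}

# Format a numeric matrix as header + tab-separated text with row/col labels.
.matrixLines <- function(m, rowLabels, colLabels, digits = 6L) {
    body <- apply(m, 1L, function(r)
        paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
    c(paste(c("position", colLabels), collapse = "\t"),
      paste(rowLabels, body, sep = "\t"))
}
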