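toy5 <- makeUniformGeometryAlphabet(5, seed = 1)
toy2 <- makeUniformGeometryAlphabet(2, seed = 1)

test_that("column MI matches closed forms and the contingency oracle", {
    # identical uniform two-letter columns: MI = H = 1 bit
    half <- rep(c("A", "B"), each = 50)
    aln <- alignmentFromColumns(list(half, half, rep("C", 100)), toy5)
    expect_equal(columnMI(aln, 1, 2), 1)
    expect_equal(columnMI(aln, 1, 2), columnEntropy(aln, 1))
    # constant partner column: MI = 0
    expect_equal(columnMI(aln, 1, 3), 0)
    # random 3-letter columns against hand enumeration of the 9-cell table
    set.seed(7)
    for (r in 1:5) {
        x <- sample(c("A", "B", "C"), 50, replace = TRUE)
        y <- sample(c("A", "B", "C"), 50, replace = TRUE)
        a2 <- alignmentFromColumns(list(x, y), toy5)
        expect_equal(columnMI(a2, 1, 2), contingencyMI(x, y), tolerance = 1e-12)
        # symmetry and self-MI
        expect_identical(columnMI(a2, 1, 2), columnMI(a2, 2, 1))
        expect_identical(columnMI(a2, 1, 1), columnEntropy(a2, 1))
    }
})

test_that("MI is bounded by the smaller column entropy", {
    set.seed(19)
    for (r in 1:20) {
        spec <- syntheticSpec(12, 30, alphabet = toy5, seed = r)
        aln <- alignmentFromStrings(sampleStrings(spec), toy5)
        i <- sample(9, 1)
        j <- sample(9, 1)
        expect_lte(columnMI(aln, i, j),
                   min(columnEntropy(aln, i), columnEntropy(aln, j)) + 1e-9)
        expect_gte(columnMI(aln, i, j), 0)
    }
})

test_that("permutation normalization follows the add-one convention", {
    half <- rep(c("A", "B"), each = 50)
    aln <- alignmentFromColumns(list(half, half), toy2)
    st <- normalizedMI(aln, 1, 2, nPerm = 99, seed = 1)
    # no permutation reproduces a perfect 1-bit matching
    expect_equal(st$pvalue, 1 / 100)
    expect_gt(st$nmi, 0.5)
    # degenerate: constant column against itself, joint entropy 0
    const <- alignmentFromColumns(list(rep("A", 20), rep("B", 20)), toy2)
    st0 <- normalizedMI(const, 1, 1, nPerm = 19, seed = 1)
    expect_equal(st0$nmi, 0)
    expect_error(normalizedMI(aln, 1, 2, nPerm = 5), "at least 19")
})

test_that("null couplings give near-zero nMI and well-behaved p-values", {
    spec <- syntheticSpec(11, 500, alphabet = toy5, seed = 23)
    aln <- alignmentFromStrings(sampleStrings(spec), toy5)
    for (pair in list(c(1, 5), c(2, 7), c(3, 8))) {
        st <- normalizedMI(aln, pair[1], pair[2], nPerm = 199, seed = 11)
        expect_lt(abs(st$nmi), 0.05)
        expect_gt(st$pvalue, 0)
        expect_lte(st$pvalue, 1)
    }
})

test_that("nMI is invariant under alphabet relabeling of either column", {
    set.seed(31)
    x <- sample(fragmentLetters(toy5), 60, replace = TRUE)
    y <- sample(fragmentLetters(toy5), 60, replace = TRUE)
    relabel <- c(A = "D", B = "A", C = "E", D = "C", E = "B")
    a1 <- alignmentFromColumns(list(x, y), toy5)
    a2 <- alignmentFromColumns(list(x, unname(relabel[y])), toy5)
    s1 <- normalizedMI(a1, 1, 2, nPerm = 99, seed = 3)
    s2 <- normalizedMI(a2, 1, 2, nPerm = 99, seed = 3)
    expect_equal(s1$nmi, s2$nmi, tolerance = 1e-12)
    expect_equal(s1$pvalue, s2$pvalue, tolerance = 1e-12)
})

test_that("the MI matrix is symmetric, reproducible and order-independent", {
    spec <- syntheticSpec(12, 60, alphabet = toy5,
                          couplings = data.frame(i = 2L, j = 7L, rho = 1),
                          seed = 13)
    aln <- alignmentFromStrings(sampleStrings(spec), toy5)
    mm <- miMatrix(aln, nPerm = 49, seed = 5)
    expect_identical(mm@mi, t(mm@mi))
    expect_identical(mm@nmi, t(mm@nmi))
    expect_equal(unname(diag(mm@mi)),
                 vapply(1:9, function(i) columnEntropy(aln, i), numeric(1)))
    # bit-identical rerun
    expect_identical(mm, miMatrix(aln, nPerm = 49, seed = 5))
    # matrix entries equal the pairwise operation (same substream key)
    st <- normalizedMI(aln, 3, 8, nPerm = 49, seed = 5)
    expect_identical(unname(mm@nmi[3, 8]), st$nmi)
    expect_identical(unname(mm@pvalue[8, 3]), st$pvalue)
    # overlap flags: windows closer than 4 share residues
    expect_true(mm@overlap[1, 2])
    expect_false(mm@overlap[1, 5])
    expect_false(mm@overlap[1, 1])
    # constant alignment: all off-diagonal MI is zero
    cst <- alignmentFromStrings(rep("AAAAAAAAA", 20), toy5)
    mmc <- miMatrix(cst, nPerm = 19, seed = 1)
    expect_true(all(mmc@mi == 0))
    expect_true(all(mmc@nmi == 0))
})

test_that("functional indices bin into equal-width categories", {
    fi <- binFunctionalIndex(0:9, nBins = 2)
    expect_identical(fi@symbols, rep(c(1L, 2L), each = 5))
    expect_false(fi@degenerate)
    # constant series: degenerate flag, single occupied bin
    fc <- binFunctionalIndex(rep(3.2, 12), nBins = 4)
    expect_true(fc@degenerate)
    expect_identical(length(unique(fc@symbols)), 1L)
    # entropy of binned symbols is bounded by log2(nBins)
    set.seed(5)
    fr <- binFunctionalIndex(rnorm(200), nBins = 8)
    h <- SAMotions:::.entropyFromCounts(tabulate(fr@symbols, 8))
    expect_lte(h, log2(8))
    expect_error(binFunctionalIndex(c(1, NA, rep(2, 10))), "non-finite")
    expect_error(binFunctionalIndex(1:20, nBins = 1), ">= 2")
})

test_that("the functional MI profile finds a planted identity coupling", {
    set.seed(9)
    spec <- syntheticSpec(12, 200, alphabet = toy2, seed = 3)
    strings <- sampleStrings(spec)
    aln <- alignmentFromStrings(strings, toy2)
    # index identical to the letter codes of position 4 (two states)
    idx <- match(substr(strings, 4, 4), fragmentLetters(toy2)) + 0.0
    prof <- functionalMIProfile(aln, binFunctionalIndex(idx, 2),
                                nPerm = 99, seed = 2)
    expect_identical(nrow(prof), 9L)
    expect_identical(prof$position[1], 4L)
    expect_gt(prof$nmi[1], max(prof$nmi[-1]))
    # length mismatch is rejected
    expect_error(functionalMIProfile(aln, binFunctionalIndex(rnorm(50), 4)),
                 "50 values .* 200 frames")
})

test_that("functional index files round-trip through plain text", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# a comment", "1.5", "", "-2.25", "3"), path)
    expect_equal(readFunctionalIndex(path), c(1.5, -2.25, 3))
    writeLines(c("1.5", "abc"), path)
    expect_error(readFunctionalIndex(path), "numeric")
})
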