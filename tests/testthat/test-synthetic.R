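toy2 <- makeUniformGeometryAlphabet(2, seed = 1)
toy5 <- makeUniformGeometryAlphabet(5, seed = 1)

test_that("planted couplings produce the stated joint distribution", {
    # rho = 1: column j is a bijection of column i in every frame
    spec1 <- syntheticSpec(12, 300, alphabet = toy5,
                           couplings = data.frame(i = 2L, j = 7L, rho = 1),
                           seed = 4)
    L <- do.call(rbind, strsplit(sampleStrings(spec1), ""))
    map <- tapply(L[, 7], L[, 2], function(x) unique(x))
    expect_true(all(lengths(map) == 1L))            # deterministic mapping
    expect_identical(anyDuplicated(unlist(map)), 0L)  # bijective
    aln <- alignmentFromStrings(sampleStrings(spec1), toy5)
    expect_equal(columnMI(aln, 2, 7), columnEntropy(aln, 2), tolerance = 1e-12)

    # rho = 0: columns stay independent; large-m MI stays near zero
    spec0 <- syntheticSpec(12, 2000, alphabet = toy5, seed = 4)
    aln0 <- alignmentFromStrings(sampleStrings(spec0), toy5)
    expect_lt(columnMI(aln0, 2, 7), 0.02)

    # rho = 0.5, two uniform letters: empirical MI matches the closed-form
    # mixture MI computed by direct summation
    spec5 <- syntheticSpec(12, 2000, alphabet = toy2,
                           couplings = data.frame(i = 2L, j = 7L, rho = 0.5),
                           seed = 9)
    aln5 <- alignmentFromStrings(sampleStrings(spec5), toy2)
    expect_lt(abs(columnMI(aln5, 2, 7) - plantedCouplingMI(0.5, 2)), 0.02)
})

test_that("coupling specifications are validated", {
    expect_error(syntheticSpec(12, 10, alphabet = toy5,
                               couplings = data.frame(i = 2L, j = 4L, rho = 0.5)),
                 ">= 4 apart")
    expect_error(syntheticSpec(12, 10, alphabet = toy5,
                               couplings = data.frame(i = 2L, j = 7L, rho = 1.5)),
                 "\\[0, 1\\]")
    expect_error(syntheticSpec(12, 10, alphabet = toy5, noiseSd = -1), ">= 0")
})

test_that("chain growth realizes strings exactly at zero noise", {
    spec <- syntheticSpec(20, 30, alphabet = toy5, seed = 6)
    s <- sampleStrings(spec)
    ens <- stringsToEnsemble(s, toy5, noiseSd = 0)
    expect_identical(c(nFrames(ens), nResidues(ens)), c(30L, 20L))
    aln <- encodeEnsemble(ens, toy5, "local")
    expect_identical(alignmentStrings(aln), s)
    expect_lt(max(aln@fitRMSD), 1e-6)
    expect_error(stringsToEnsemble("AAZA", toy5), "outside alphabet")
})

test_that("moderate noise still recovers well-separated alphabets", {
    spec <- syntheticSpec(15, 100, alphabet = toy5, seed = 8)
    s <- sampleStrings(spec)
    ens <- stringsToEnsemble(s, toy5, noiseSd = 0.1, seed = 3)
    aln <- encodeEnsemble(ens, toy5, "local")
    truth <- do.call(rbind, strsplit(s, ""))
    expect_gte(mean(aln@letters == truth), 0.99)
})

test_that("the functional index explains the planted variance fraction", {
    spec <- syntheticSpec(12, 1000, alphabet = toy5, seed = 10)
    s <- sampleStrings(spec)
    v <- sampleFunctionalIndex(s, toy5, position = 4, rhoF = 0.8, seed = 2)
    expect_length(v, 1000L)
    mu <- match(substr(s, 4, 4), fragmentLetters(toy5))
    fit <- summary(stats::lm(v ~ factor(mu)))
    expect_equal(fit$r.squared, 0.8, tolerance = 0.05)
    # rho_f = 0: independent of every column
    v0 <- sampleFunctionalIndex(s, toy5, position = 4, rhoF = 0, seed = 2)
    expect_lt(abs(stats::cor(v0, mu)), 0.1)
    expect_error(sampleFunctionalIndex(s, toy5, position = 4, rhoF = 1),
                 "\\[0, 1\\)")
    expect_error(sampleFunctionalIndex(s, toy5, position = 99, rhoF = 0.5),
                 "out of range")
})

test_that("generation is bit-reproducible in the seed", {
    spec <- syntheticSpec(12, 40, alphabet = toy5,
                          couplings = data.frame(i = 1L, j = 6L, rho = 0.7),
                          noiseSd = 0.1, functionalPosition = 3L,
                          functionalRho = 0.5, seed = 21)
    r1 <- generateSynthetic(spec)
    r2 <- generateSynthetic(spec)
    expect_identical(r1$strings, r2$strings)
    expect_identical(r1$ensemble@coords, r2$ensemble@coords)
    expect_identical(r1$functionalIndex, r2$functionalIndex)
    # a different seed changes the draw
    spec2 <- spec; spec2@seed <- 22L
    expect_false(identical(r1$strings, generateSynthetic(spec2)$strings))
})

test_that("synthetic config files parse into equivalent specs", {
    path <- withr::local_tempfile(fileext = ".cfg")
    writeLines(c("# demo", "n_residues = 14", "m_frames = 25",
                 "alphabet = uniform:4", "noise_sd = 0.05", "seed = 12",
                 "couplings = 2,8,0.9;3,9,0.4", "functional = 5,0.75"), path)
    spec <- readSyntheticConfig(path)
    expect_identical(spec@nResidues, 14L)
    expect_identical(spec@mFrames, 25L)
    expect_identical(nFragments(spec@alphabet), 4L)
    expect_identical(spec@couplings$j, c(8L, 9L))
    expect_identical(spec@functionalPosition, 5L)
    expect_equal(spec@noiseSd, 0.05)
    # invalid (overlapping) coupling is rejected at spec validation
    writeLines(c("n_residues = 14", "m_frames = 25", "couplings = 2,4,0.9"),
               path)
    expect_error(readSyntheticConfig(path), ">= 4 apart")
    writeLines("n_residues = 14", path)
    expect_error(readSyntheticConfig(path), "m_frames")
})
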