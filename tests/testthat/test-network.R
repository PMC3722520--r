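plantedMatrix <- function(seed = 13, rho = 1, nPerm = 199) {
    toy <- makeUniformGeometryAlphabet(5, seed = 1)
    spec <- syntheticSpec(12, 200, alphabet = toy,
                          couplings = data.frame(i = 2L, j = 7L, rho = rho),
                          seed = seed)
    miMatrix(alignmentFromStrings(sampleStrings(spec), toy),
             nPerm = nPerm, seed = seed)
}

test_that("network construction filters on strength, significance and overlap", {
    mm <- plantedMatrix(nPerm = 999)
    net <- buildNetwork(mm, threshold = 0, qMax = 0.05, skipOverlap = TRUE)
    expect_identical(nrow(networkNodes(net)), 9L)   # isolated nodes retained
    e <- networkEdges(net)
    expect_identical(nrow(e), 1L)                   # exactly the planted pair
    expect_identical(c(e$from, e$to), c(2L, 7L))
    # near-unity threshold with no admissible edge: edgeless but full node set
    empty <- buildNetwork(mm, threshold = 1 - 1e-9)
    expect_identical(nrow(networkEdges(empty)), 0L)
    expect_identical(nrow(networkNodes(empty)), 9L)
    # monotonicity: lowering the threshold or raising qMax never removes edges
    loose <- buildNetwork(mm, threshold = 0, qMax = 1, skipOverlap = TRUE)
    key <- function(d) paste(d$from, d$to)
    expect_true(all(key(e) %in% key(networkEdges(loose))))
    noskip <- buildNetwork(mm, threshold = 0, qMax = 1, skipOverlap = FALSE)
    expect_true(all(key(networkEdges(loose)) %in% key(networkEdges(noskip))))
    expect_error(buildNetwork(mm, threshold = 1), "\\[0, 1\\)")
    expect_error(buildNetwork(mm, threshold = -0.1), "\\[0, 1\\)")
})

test_that("eigenvector centrality matches symmetric closed forms", {
    triangle <- makeTestNetwork(data.frame(from = c(1, 1, 2), to = c(2, 3, 3),
                                           weight = rep(0.8, 3)))
    sc <- eigenvectorCentrality(triangle)
    expect_equal(unname(sc), rep(1 / sqrt(3), 3), tolerance = 1e-10)
    star <- makeTestNetwork(data.frame(from = rep(1, 4), to = 2:5,
                                       weight = rep(0.5, 4)))
    scs <- eigenvectorCentrality(star)
    expect_gt(scs[["1"]], max(scs[-1]))
    expect_equal(sum(scs^2), 1, tolerance = 1e-12)
})

test_that("centrality matches dense eigen and power-iteration oracles", {
    set.seed(77)
    for (r in 1:5) {
        n <- 10L
        pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        take <- sample(nrow(pairs), 16)
        edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2],
                            weight = runif(16, 0.1, 1))
        net <- makeTestNetwork(edges, n = n)
        sc <- eigenvectorCentrality(net)
        # dense adjacency oracle restricted to the largest component
        A <- matrix(0, n, n)
        A[cbind(edges$from, edges$to)] <- edges$weight
        A <- A + t(A)
        g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
        comp <- igraph::components(g)
        big <- which(comp$membership == which.max(comp$csize))
        ev <- eigen(A[big, big, drop = FALSE], symmetric = TRUE)$vectors[, 1]
        if (sum(ev) < 0) ev <- -ev
        expected <- numeric(n)
        expected[big] <- ev
        expected <- expected / sqrt(sum(expected^2))
        expect_equal(unname(sc), expected, tolerance = 1e-8)
        # independent power-iteration route
        pw <- powerIterationCentrality(A[big, big, drop = FALSE])
        expect_equal(unname(sc[big]) / sqrt(sum(sc[big]^2)), pw,
                     tolerance = 1e-8)
        # igraph as a third, external cross-check (max-normalized)
        ig <- igraph::eigen_centrality(
            igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                                weighted = TRUE))$vector
        expect_equal(unname(sc / max(sc)), unname(ig / max(ig)),
                     tolerance = 1e-6)
    }
    edgeless <- makeTestNetwork(data.frame(from = integer(), to = integer(),
                                           weight = numeric()), n = 4)
    expect_error(eigenvectorCentrality(edgeless), "edgeless")
})

test_that("communication pathways minimize additive -log(nMI) costs", {
    # single edge: the one-edge path
    single <- makeTestNetwork(data.frame(from = 1, to = 2, weight = 0.5))
    pw <- communicationPathways(single, 1, 2, k = 3)
    expect_identical(pw$path, "1,2")
    expect_equal(pw$cost, -log(0.5))

    # strong chain beats weak direct edge iff the cost arithmetic says so
    chain <- makeTestNetwork(data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                                        weight = c(0.9, 0.9, 0.5)))
    pw2 <- communicationPathways(chain, 1, 3, k = 2)
    expect_identical(pw2$path[1], "1,2,3")   # 2*(-log .9) < -log .5
    expect_identical(pw2$path[2], "1,3")
    expect_true(all(diff(pw2$cost) >= 0))

    # no route: empty result with a warning, not an error
    parts <- makeTestNetwork(data.frame(from = 1, to = 2, weight = 0.5), n = 4)
    expect_warning(none <- communicationPathways(parts, 1, 4), "no path")
    expect_identical(nrow(none), 0L)
    expect_error(communicationPathways(parts, 1, 99), "unknown node")
})

test_that("k-shortest paths match exhaustive enumeration on toy graphs", {
    set.seed(55)
    for (r in 1:5) {
        n <- 6L
        pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        take <- sample(nrow(pairs), 9)
        edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2],
                            weight = runif(9, 0.2, 0.95))
        net <- makeTestNetwork(edges, n = n)
        ref <- enumerateSimplePaths(edges, 1, n)
        k <- 4L
        got <- suppressWarnings(communicationPathways(net, 1, n, k = k))
        expect_identical(nrow(got), min(k, nrow(ref)))
        if (nrow(got)) {
            expect_equal(got$cost, ref$cost[seq_len(nrow(got))],
                         tolerance = 1e-9)
            expect_identical(got$path, ref$path[seq_len(nrow(got))])
            expect_true(all(diff(got$cost) >= 0))
            # every returned path is simple
            for (p in strsplit(got$path, ","))
                expect_false(anyDuplicated(p) > 0)
        }
    }
})

test_that("GML export re-parses into an isomorphic network", {
    triangle <- makeTestNetwork(data.frame(from = c(1, 1, 2), to = c(2, 3, 3),
                                           weight = c(0.8, 0.6, 0.4)))
    triangle@centrality <- eigenvectorCentrality(triangle)
    path <- withr::local_tempfile(fileext = ".gml")
    writeGML(triangle, path)
    g <- readGML(path)
    expect_equal(igraph::vcount(g), 3)
    expect_equal(igraph::ecount(g), 3)
    expect_equal(sort(igraph::E(g)$weight), c(0.4, 0.6, 0.8), tolerance = 1e-6)
    expect_equal(sort(igraph::V(g)$centrality),
                 sort(unname(triangle@centrality)), tolerance = 1e-6)
    expect_identical(sort(igraph::V(g)$id), c(1, 2, 3))
    # edgeless network: nodes only
    edgeless <- makeTestNetwork(data.frame(from = integer(), to = integer(),
                                           weight = numeric()), n = 3)
    writeGML(edgeless, path)
    g0 <- readGML(path)
    expect_equal(igraph::vcount(g0), 3)
    expect_equal(igraph::ecount(g0), 0)
})
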