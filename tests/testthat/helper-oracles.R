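# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately implemented by a different route than the
# package code it checks.

# --- brute-force rotation-search RMSD oracle --------------------------------
# Scans rotation space (random multi-start + Nelder-Mead refinement over
# rotation vectors) instead of the closed-form decomposition used by
# superposeRMSD().

rotvecToMatrix <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

bruteForceRMSD <- function(a, b, nStarts = 16L) {
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    obj <- function(v) {
        d <- ac %*% t(rotvecToMatrix(v)) - bc
        sqrt(sum(d * d) / nrow(a))
    }
    starts <- rbind(c(0, 0, 0),
                    t(replicate(nStarts - 1L, {
                        ax <- stats::rnorm(3)
                        ax / sqrt(sum(ax^2)) * stats::runif(1, 0, pi)
                    })))
    best <- Inf
    for (s in seq_len(nrow(starts))) {
        r <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 2000))
        best <- min(best, r$value)
    }
    best
}

randomFragment <- function(scale = 2) {
    matrix(stats::rnorm(12, sd = scale), 4, 3)
}

randomRotation <- function() {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

rigidCopy <- function(frag) {
    frag %*% randomRotation() + matrix(stats::rnorm(3, sd = 10), 4, 3,
                                       byrow = TRUE)
}

# --- direct contingency-table MI oracle -------------------------------------
# Hand enumeration over the observed joint table, as an independent check of
# columnMI()'s entropy-difference route.

contingencyMI <- function(x, y) {
    tab <- table(x, y)
    p <- tab / sum(tab)
    px <- rowSums(p)
    py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
        if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    as.numeric(s)
}

# Closed-form MI of the planted coupling's mixture joint distribution
# p(a, b) = rho * pi_a * 1[b = f(a)] + (1 - rho) * pi_a * pi_b,
# computed by direct summation (f = cyclic shift by one).

plantedCouplingMI <- function(rho, k) {
    p <- matrix((1 - rho) / k^2, k, k)
    for (a in seq_len(k)) p[a, (a %% k) + 1L] <- p[a, (a %% k) + 1L] + rho / k
    pa <- rowSums(p)
    pb <- colSums(p)
    sum(ifelse(p > 0, p * log2(p / outer(pa, pb)), 0))
}

# --- dense power-iteration centrality oracle --------------------------------

powerIterationCentrality <- function(A, tol = 1e-10, maxit = 100000L) {
    v <- rep(1, nrow(A)) / sqrt(nrow(A))
    for (i in seq_len(maxit)) {
        w <- as.numeric(A %*% v)
        w <- w / sqrt(sum(w^2))
        if (max(abs(w - v)) < tol) return(w)
        v <- w
    }
    stop("power iteration did not converge")
}

# --- exhaustive simple-path enumeration oracle ------------------------------
# Recursive DFS over the edge list; costs are -log(weight) as in
# communicationPathways().

enumerateSimplePaths <- function(edges, s, t) {
    res <- list()
    nbr <- function(v) {
        i <- which(edges$from == v)
        j <- which(edges$to == v)
        data.frame(n = c(edges$to[i], edges$from[j]),
                   w = c(edges$weight[i], edges$weight[j]))
    }
    walk <- function(path, cost) {
        v <- path[length(path)]
        if (v == t) {
            res[[length(res) + 1L]] <<- data.frame(
                path = paste(path, collapse = ","), cost = cost)
            return(invisible())
        }
        nb <- nbr(v)
        for (r in seq_len(nrow(nb)))
            if (!(nb$n[r] %in% path))
                walk(c(path, nb$n[r]), cost - log(nb$w[r]))
    }
    walk(s, 0)
    if (!length(res)) return(data.frame(path = character(), cost = numeric()))
    out <- do.call(rbind, res)
    out[order(out$cost, out$path), , drop = FALSE]
}

# --- fixture builders --------------------------------------------------------

# A bare MINetwork from an edge table (weights in (0, 1]), for graph-layer
# tests that do not need the MI machinery.
makeTestNetwork <- function(edges, n = max(edges$from, edges$to)) {
    if (is.null(edges$qvalue)) edges$qvalue <- rep(0, nrow(edges))
    net <- new("MINetwork",
               nodes = data.frame(id = seq_len(n),
                                  label = sprintf("%d-%d", seq_len(n), seq_len(n) + 3L)),
               edges = edges, threshold = 0, qMax = 1, skipOverlap = FALSE,
               centrality = numeric())
    validObject(net)
    net
}

# Alignment built from explicit columns (list of equal-length letter vectors).
alignmentFromColumns <- function(cols, alphabet) {
    alignmentFromStrings(do.call(paste0, cols), alphabet)
}

toyAlphabet2 <- function() {
    structuralAlphabet("toy2", c("A", "B"),
        list(SAMotions:::.idealHelixFragment(),
             SAMotions:::.idealExtendedFragment()))
}
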