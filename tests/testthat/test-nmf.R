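test_that("rank-1 structure is recovered essentially exactly", {
    ## constant matrix: objective -> 0, W H ~ c everywhere
    V <- matrix(0.6, 10, 8, dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
    fr <- runNMF(V, 1, seed = 1)
    expect_lt(max(abs(basisMatrix(fr) %*% coefficientMatrix(fr) - 0.6)), 1e-6)
    ## exact rank-1 outer product
    V2 <- outer(c(1, 2, 3), c(1, 1, 2))
    dimnames(V2) <- list(paste0("p", 1:3), paste0("s", 1:3))
    fr2 <- runNMF(V2, 1, seed = 2)
    rec <- basisMatrix(fr2) %*% coefficientMatrix(fr2)
    expect_lt(norm(V2 - rec, "F") / norm(V2, "F"), 1e-4)
})

test_that("multiplicative updates are monotone and non-negative for both objectives", {
    set.seed(9)
    V <- matrix(runif(40 * 15), 40, 15,
                dimnames = list(paste0("p", 1:40), paste0("s", 1:15)))
    for (obj in c("kl", "frobenius")) {
        fr <- runNMF(V, 3, seed = 4, objective = obj, maxIter = 200L,
                     tol = 1e-16)
        tr <- objectiveTrace(fr)
        expect_equal(length(tr), 200L)
        rel <- diff(tr) / pmax(abs(tr[-length(tr)]), 1e-300)
        expect_true(all(rel <= 1e-9))
        expect_true(all(basisMatrix(fr) >= 0))
        expect_true(all(coefficientMatrix(fr) >= 0))
    }
})

test_that("factorization is deterministic given the seed and validates inputs", {
    set.seed(2)
    V <- matrix(runif(60), 12, 5,
                dimnames = list(paste0("p", 1:12), paste0("s", 1:5)))
    expect_identical(basisMatrix(runNMF(V, 2, seed = 3)),
                     basisMatrix(runNMF(V, 2, seed = 3)))
    Vneg <- V; Vneg[1, 1] <- -0.1
    expect_error(runNMF(Vneg, 2), "non-negative")
    expect_error(runNMF(V, 5), "out of range")
    expect_error(runNMF(V, 0), "out of range")
})

test_that("scale normalization preserves the product W H", {
    set.seed(5)
    W <- matrix(runif(30), 10, 3)
    H <- matrix(runif(18), 3, 6)
    nf <- normalizeFactors(W, H)
    expect_equal(nf$W %*% nf$H, W %*% H, tolerance = 1e-12)
    expect_equal(unname(colSums(nf$W)), rep(1, 3))
})

## two disjoint sample blocks driven by orthogonal basis vectors
twoBlockMatrix <- function(nPerBlock = 6) {
    W <- cbind(c(rep(1, 10), rep(0, 10)), c(rep(0, 10), rep(1, 10)))
    H <- cbind(matrix(rep(c(0.9, 0.02), nPerBlock), 2),
               matrix(rep(c(0.02, 0.9), nPerBlock), 2))
    V <- W %*% H
    dimnames(V) <- list(paste0("p", 1:20), paste0("s", 1:(2 * nPerBlock)))
    V
}

test_that("consensus over restarts is block-constant for separable data", {
    V <- twoBlockMatrix()
    cr <- consensusNMF(V, 2, nRuns = 10, baseSeed = 1)
    C <- consensusMatrix(cr)
    block <- rep(1:2, each = 6)
    expect_true(all(C[outer(block, block, "==")] == 1))
    expect_true(all(C[outer(block, block, "!=")] == 0))
    ## ultrametric consensus -> cophenetic exactly 1
    expect_equal(copheneticScore(cr), 1.0)
    expect_error(consensusNMF(V, 2, nRuns = 1), "at least 2 runs")
})

test_that("planted metagenes are recovered up to permutation", {
    set.seed(21)
    k <- 3
    W0 <- matrix(0, 60, k)
    for (g in 1:k) W0[(g - 1) * 20 + 1:20, g] <- runif(20, 0.5, 1)
    H0 <- matrix(0.02, k, 30)
    for (g in 1:k) H0[g, (g - 1) * 10 + 1:10] <- runif(10, 0.7, 1)
    V <- W0 %*% H0
    dimnames(V) <- list(paste0("p", 1:60), paste0("s", 1:30))
    fr <- runNMF(V, k, seed = 8, maxIter = 3000L, tol = 1e-10)
    H <- coefficientMatrix(fr)
    ## greedy matching by maximal correlation
    cors <- abs(cor(t(H0), t(H)))
    matched <- numeric(k)
    for (i in seq_len(k)) {
        j <- which.max(apply(cors, 2, max))
        i0 <- which.max(cors[, j])
        matched[i] <- cors[i0, j]
        cors[i0, ] <- -1; cors[, j] <- -1
    }
    expect_true(all(matched >= 0.99))
})

test_that("cophenetic coefficient matches an independent merge simulation", {
    ## perfect two-block consensus is ultrametric -> exactly 1
    C2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
    expect_equal(copheneticCoefficient(C2), 1.0, tolerance = 1e-12)
    ## noisy 5-sample consensus: agree with the brute-force oracle to 1e-10
    set.seed(13)
    for (rep in 1:5) {
        M <- matrix(runif(25, 0.1, 0.9), 5, 5)
        C <- (M + t(M)) / 2
        diag(C) <- 1
        expect_equal(copheneticCoefficient(C),
                     bruteCopheneticCoefficient(C), tolerance = 1e-10)
    }
    ## degenerate inputs
    expect_error(copheneticCoefficient(matrix(1, 4, 4)), "degenerate")
    expect_error(copheneticCoefficient(matrix(1, 2, 2)), "at least 3")
})

test_that("rank scan is tabulated per rank and finds trivial structure", {
    V <- twoBlockMatrix()
    tab <- rankScan(V, ranks = 2L, nRuns = 5, baseSeed = 3)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$rank, 2L)
    expect_equal(tab$cophenetic, 1.0)
})
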