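test_that("NNLS solves textbook instances exactly", {
    ## identity basis
    fit <- nnlsSolve(diag(2), c(3, 4))
    expect_equal(fit$h, c(3, 4))
    expect_equal(fit$residual, 0)
    ## constrained case: unconstrained solution (-1, 2) is infeasible
    W <- cbind(c(1, 0), c(1, 1))
    fit2 <- nnlsSolve(W, c(1, 2))
    expect_equal(fit2$h, c(0, 1.5), tolerance = 1e-12)
    expect_equal(fit2$residual^2, 0.5, tolerance = 1e-12)
    ## zero target
    expect_equal(nnlsSolve(W, c(0, 0))$h, c(0, 0))
    ## input validation
    expect_error(nnlsSolve(cbind(c(1, 1), c(0, 0)), c(1, 1)), "all-zero")
    expect_error(nnlsSolve(W, c(1, NA)), "non-finite")
})

test_that("NNLS agrees with the exhaustive support-set oracle", {
    set.seed(31)
    for (i in 1:120) {
        k <- sample(2:6, 1)
        m <- k + sample(0:6, 1)
        W <- matrix(runif(m * k), m, k)
        v <- if (i %% 3 == 0) W %*% runif(k, -0.5, 1) + rnorm(m, 0, 0.1)
             else runif(m, -0.5, 1.5)
        fit <- nnlsSolve(W, as.numeric(v))
        oracle <- bruteNNLS(W, as.numeric(v))
        expect_equal(fit$residual, oracle$residual, tolerance = 1e-8)
        expect_equal(fit$h, oracle$h, tolerance = 1e-6)
        ## KKT: objective gradient at zero coordinates is >= -1e-8
        grad <- as.numeric(crossprod(W, W %*% fit$h - v))
        expect_true(all(grad[fit$h == 0] >= -1e-8 * max(1, max(abs(grad)))))
        expect_true(all(fit$h >= 0))
    }
})

test_that("NNLS returns the unconstrained fit when it is feasible", {
    set.seed(17)
    for (i in 1:25) {
        k <- sample(2:5, 1)
        W <- matrix(runif(8 * k, 0.1, 1), 8, k)
        v <- as.numeric(W %*% runif(k, 0.5, 1)) + rnorm(8, 0, 0.01)
        ls <- qr.coef(qr(W), v)
        fit <- nnlsSolve(W, v)
        lsResidual <- sqrt(sum((v - W %*% ls)^2))
        expect_gte(fit$residual, lsResidual - 1e-10)
        if (all(ls >= 0)) {
            expect_equal(fit$h, unname(ls), tolerance = 1e-10)
            expect_equal(fit$residual, lsResidual, tolerance = 1e-10)
        }
    }
})

test_that("projection onto a fixed basis recovers exact coefficients", {
    set.seed(41)
    W <- matrix(runif(50 * 4), 50, 4,
                dimnames = list(paste0("p", 1:50), paste0("V", 1:4)))
    Htrue <- matrix(runif(4 * 7), 4, 7,
                    dimnames = list(paste0("V", 1:4), paste0("s", 1:7)))
    V <- W %*% Htrue
    pr <- projectCohort(W, V)
    expect_lt(max(abs(projectedCoefficients(pr) - Htrue)), 1e-6)
    ## single-sample cohort equals a single NNLS solve
    pr1 <- projectCohort(W, V[, 1, drop = FALSE])
    expect_equal(projectedCoefficients(pr1)[, 1],
                 setNames(nnlsSolve(W, V[, 1])$h, paste0("V", 1:4)))
    ## permuting sample columns permutes the result identically
    perm <- c(3, 1, 7, 2, 6, 4, 5)
    prP <- projectCohort(W, V[, perm])
    expect_equal(projectedCoefficients(prP),
                 projectedCoefficients(pr)[, perm])
    ## dimension mismatch
    expect_error(projectCohort(W, V[-1, ]), "mismatch")
})

test_that("projecting the training matrix reproduces its own coefficients", {
    co <- generateCohort(nProbes = 300, nSamples = 90, seed = 6,
                         warp = FALSE, missingRate = 0)
    V <- betaValues(co$betaSet)
    fr <- runNMF(V, 6, seed = 2, maxIter = 3000L, tol = 1e-9)
    pr <- projectCohort(basisMatrix(fr), V)
    HP <- coefficientMatrix(fr)
    HV <- projectedCoefficients(pr)
    cors <- vapply(1:6, function(g) cor(HP[g, ], HV[g, ]), numeric(1))
    expect_true(all(cors >= 0.99))
})

test_that("probe alignment reorders, fills per policy, and enforces coverage", {
    set.seed(51)
    basis <- paste0("p", 1:50)
    V <- matrix(runif(50 * 3), 50, 3, dimnames = list(basis, paste0("s", 1:3)))
    shuffled <- V[sample(50), ]
    al <- alignProbes(shuffled, basis)
    expect_identical(al$matrix, V)
    expect_equal(al$coverage, 1.0)
    ## one basis probe absent: train-mean policy fills and flags it
    V2 <- V[-7, ]
    means <- setNames(rep(0.5, 50), basis)
    al2 <- alignProbes(V2, basis, fillPolicy = "train-mean",
                       trainMeans = means)
    expect_identical(al2$filled, "p7")
    expect_equal(unname(al2$matrix["p7", ]), rep(0.5, 3))
    expect_equal(al2$coverage, 49 / 50)
    ## error policy refuses any absence
    expect_error(alignProbes(V2, basis, fillPolicy = "error"), "absent")
    ## coverage floor applies under either policy
    expect_error(alignProbes(V[1:20, ], basis, fillPolicy = "train-mean",
                             trainMeans = means), "coverage")
})
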