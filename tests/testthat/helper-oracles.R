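## Independent brute-force oracles and small fixture builders. Each oracle
## re-derives the quantity from first principles, sharing no code with the
## implementation it checks.

makeBetaSet <- function(beta, detP = NULL) {
    if (is.null(rownames(beta)))
        rownames(beta) <- sprintf("cg%05d", seq_len(nrow(beta)))
    if (is.null(colnames(beta)))
        colnames(beta) <- sprintf("S%03d", seq_len(ncol(beta)))
    BetaSet(beta, detP = detP)
}

randomBetaSet <- function(nProbes, nSamples, seed, missingFrac = 0,
                          withDetP = TRUE) {
    set.seed(seed)
    beta <- matrix(runif(nProbes * nSamples), nProbes, nSamples)
    if (missingFrac > 0)
        beta[sample(length(beta), round(missingFrac * length(beta)))] <- NA
    detP <- if (withDetP)
        matrix(runif(nProbes * nSamples, 0, 0.04), nProbes, nSamples)
    makeBetaSet(beta, detP = detP)
}

## KNN imputation oracle: full pairwise distance table, explicit top-k.
## Distance: Euclidean over mutually observed probes, rescaled by
## sqrt(nProbes / nShared); candidates restricted to samples observed at
## the target probe; unweighted mean of the k nearest.
bruteKNNImpute <- function(beta, k) {
    np <- nrow(beta); ns <- ncol(beta)
    D <- matrix(Inf, ns, ns)
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
        shared <- which(!is.na(beta[, i]) & !is.na(beta[, j]))
        if (length(shared) > 0)
            D[i, j] <- sqrt(sum((beta[shared, i] - beta[shared, j])^2) *
                            np / length(shared))
    }
    out <- beta
    for (s in seq_len(ns)) for (p in which(is.na(beta[, s]))) {
        cand <- setdiff(which(!is.na(beta[p, ])), s)
        cand <- cand[order(D[s, cand], cand)]
        out[p, s] <- mean(beta[p, cand[seq_len(min(k, length(cand)))]])
    }
    pmin(pmax(out, 0), 1)
}

## Average-linkage cophenetic distances by explicit pairwise merge
## simulation: cluster distance = mean of the original dissimilarities over
## all cross pairs; the cophenetic distance of a pair is the height of the
## merge that joins them.
bruteCopheneticDistances <- function(D) {
    n <- nrow(D)
    clusters <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    while (length(clusters) > 1L) {
        m <- length(clusters)
        bestD <- Inf; bi <- bj <- NA
        for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
            d <- mean(D[clusters[[i]], clusters[[j]]])
            if (d < bestD) { bestD <- d; bi <- i; bj <- j }
        }
        for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
            coph[a, b] <- bestD; coph[b, a] <- bestD
        }
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
    }
    coph
}

bruteCopheneticCoefficient <- function(consensus) {
    D <- 1 - consensus
    coph <- bruteCopheneticDistances(D)
    lower <- lower.tri(D)
    cor(D[lower], coph[lower])
}

## NNLS oracle: enumerate all 2^k support sets, solve ordinary least
## squares on each, keep feasible (non-negative) solutions, return the one
## with the smallest residual.
bruteNNLS <- function(W, v) {
    k <- ncol(W)
    best <- list(h = numeric(k), residual = sqrt(sum(v^2)))
    for (bits in seq_len(2^k - 1L)) {
        S <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0)
        h <- numeric(k)
        fit <- tryCatch(qr.coef(qr(W[, S, drop = FALSE]), v),
                        error = function(e) NULL)
        if (is.null(fit) || anyNA(fit)) next
        if (any(fit < 0)) next
        h[S] <- fit
        r <- sqrt(sum((v - W %*% h)^2))
        if (r < best$residual - 1e-12) best <- list(h = h, residual = r)
    }
    best
}

## AUC oracle: exhaustive pair counting, ties counted one half.
bruteAUC <- function(scores, positive) {
    pos <- scores[positive]; neg <- scores[!positive]
    total <- 0
    for (a in pos) for (b in neg)
        total <- total + (a > b) + 0.5 * (a == b)
    total / (length(pos) * length(neg))
}

## well-separated seven-cluster features for classifier tests
separableClusters <- function(nPerClass = 10, sd = 0.02, seed = 1) {
    set.seed(seed)
    classes <- mbSubgroups()
    centers <- rbind(diag(6) * 0.9, c(0.45, 0.45, 0, 0, 0, 0.9))
    X <- do.call(rbind, lapply(seq_along(classes), function(i)
        matrix(rep(centers[i, ], each = nPerClass), nPerClass) +
            matrix(rnorm(nPerClass * 6, 0, sd), nPerClass)))
    X <- pmin(pmax(X, 0), 1)
    colnames(X) <- paste0("V", 1:6)
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
    list(features = X,
         labels = factor(rep(classes, each = nPerClass), levels = classes))
}
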