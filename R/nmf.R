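## Metagene extraction: multiplicative-update NMF, consensus clustering over
## seeded restarts, cophenetic rank diagnostics.

.asNonnegMatrix <- function(V) {
    if (is(V, "BetaSet")) V <- betaValues(V)
    if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix")
    if (anyNA(V)) stop("V must be complete (no missing values)")
    if (any(V < 0)) stop("V must be non-negative")
    V
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative probes x samples matrix \eqn{V \approx W H}
#' with \eqn{W \ge 0} (probes x rank; per-probe metagene contributions) and
#' \eqn{H \ge 0} (rank x samples; per-sample metagene coefficients), using
#' the classical multiplicative update rules. The default objective is the
#' generalized Kullback-Leibler divergence, the convention of metagene NMF
#' on methylation and expression arrays; a Frobenius (squared-error)
#' objective is available by flag. Factors are initialized uniform(0, 1]
#' from a seeded generator, so the fit is deterministic given \code{seed}.
#' Iteration stops when the relative objective change drops below \code{tol}
#' or after \code{maxIter} updates; a small epsilon (1e-12) in update
#' denominators guards against division by zero (entries multiplicatively
#' locked at zero stay at zero).
#'
#' @param V non-negative numeric matrix or complete \linkS4class{BetaSet}.
#' @param k factorization rank, \code{1 <= k < min(dim(V))}.
#' @param seed integer seed for the initialization.
#' @param objective \code{"kl"} (generalized Kullback-Leibler, default) or
#'   \code{"frobenius"}.
#' @param maxIter,tol iteration cap (default 2000) and relative convergence
#'   tolerance (default 1e-5).
#' @return A \linkS4class{FactorizationResult}.
#' @export
runNMF <- function(V, k, seed = 1L, objective = c("kl", "frobenius"),
                   maxIter = 2000L, tol = 1e-5) {
    objective <- match.arg(objective)
    V <- .asNonnegMatrix(V)
    if (k < 1 || k >= min(dim(V)))
        stop(sprintf("rank k = %d out of range [1, %d)", k, min(dim(V))))
    np <- nrow(V); ns <- ncol(V)
    set.seed(seed)
    ## uniform (0, 1] init: avoid exact zeros, which multiplicative updates
    ## would lock permanently
    W0 <- matrix(1 - runif(np * k), np, k)
    H0 <- matrix(1 - runif(k * ns), k, ns)
    fit <- .nmfUpdateLoop(V, W0, H0, objective, as.integer(maxIter), tol)
    W <- fit$W
    H <- fit$H
    dimnames(W) <- list(rownames(V), paste0("V", seq_len(k)))
    dimnames(H) <- list(paste0("V", seq_len(k)), colnames(V))
    new("FactorizationResult", W = W, H = H,
        objectiveTrace = fit$trace, rank = as.integer(k),
        seed = as.integer(seed), nIter = as.integer(fit$nIter),
        converged = fit$converged, objective = objective)
}

#' Scale-normalize a factorization
#'
#' Rescales W columns to unit sum with the compensating rescale of H rows,
#' leaving the product \eqn{W H} unchanged. Removes the per-component scale
#' indeterminacy of NMF before comparing coefficient rows (used for the
#' dominant-metagene assignment in \code{\link{consensusNMF}}).
#'
#' @param W,H non-negative factor matrices.
#' @return list with normalized \code{W} and \code{H}.
#' @export
normalizeFactors <- function(W, H) {
    s <- colSums(W)
    s[s == 0] <- 1
    list(W = sweep(W, 2L, s, "/"), H = H * s)
}

## dominant metagene per sample; ties -> lowest metagene index (which.max)
.dominantMetagene <- function(fr) {
    nf <- normalizeFactors(fr@W, fr@H)
    apply(nf$H, 2L, which.max)
}

#' Consensus NMF over seeded restarts
#'
#' Runs \code{\link{runNMF}} with seeds \code{baseSeed, ..., baseSeed +
#' nRuns - 1}. In each run every sample is assigned to its dominant metagene
#' (argmax over its coefficient column after scale normalization, ties to
#' the lowest index); the run's connectivity matrix has entry 1 where two
#' samples share an assignment. The consensus matrix is the mean
#' connectivity over runs, and its cophenetic correlation coefficient
#' summarizes the stability of the rank.
#'
#' @inheritParams runNMF
#' @param nRuns number of restarts, at least 2.
#' @param baseSeed seed of the first restart.
#' @param ... further arguments to \code{\link{runNMF}}.
#' @return A \linkS4class{ConsensusResult}; its \code{best} slot holds the
#'   restart with the lowest final objective. The cophenetic slot is
#'   \code{NA} when the consensus is degenerate (all off-diagonal entries
#'   equal).
#' @export
consensusNMF <- function(V, k, nRuns = 30L, baseSeed = 1L, ...) {
    if (nRuns < 2L)
        stop("consensus requires at least 2 runs (stability is undefined for 1)")
    V <- .asNonnegMatrix(V)
    ns <- ncol(V)
    consensus <- matrix(0, ns, ns)
    best <- NULL
    bestObj <- Inf
    for (r in seq_len(nRuns)) {
        fr <- runNMF(V, k, seed = baseSeed + r - 1L, ...)
        a <- .dominantMetagene(fr)
        consensus <- consensus + outer(a, a, "==")
        fin <- tail(fr@objectiveTrace, 1L)
        if (fin < bestObj) {
            bestObj <- fin
            best <- fr
        }
    }
    consensus <- consensus / nRuns
    dimnames(consensus) <- list(colnames(V), colnames(V))
    coph <- tryCatch(copheneticCoefficient(consensus),
                     error = function(e) NA_real_)
    new("ConsensusResult", consensus = consensus, cophenetic = coph,
        rank = as.integer(k), nRuns = as.integer(nRuns), best = best)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Converts the consensus matrix to distances \eqn{1 - consensus}, builds an
#' average-linkage dendrogram, and returns the Pearson correlation between
#' the dendrogram's cophenetic distances and the input distances over all
#' off-diagonal pairs. A value near 1 indicates that the consensus is close
#' to ultrametric, i.e. the factorization rank is stable.
#'
#' @param consensus symmetric samples x samples matrix in \eqn{[0,1]} with
#'   unit diagonal; at least 3 samples.
#' @param linkage linkage method for the dendrogram (default
#'   \code{"average"}, the consensus-clustering convention).
#' @return The cophenetic correlation coefficient.
#' @export
copheneticCoefficient <- function(consensus, linkage = "average") {
    if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus))
        stop("consensus must be a square matrix")
    if (nrow(consensus) < 3L)
        stop("cophenetic correlation requires at least 3 samples")
    if (max(abs(consensus - t(consensus))) > 1e-8)
        stop("consensus must be symmetric")
    D <- as.dist(1 - consensus)
    if (max(D) - min(D) < .Machine$double.eps)
        stop("degenerate consensus: all off-diagonal distances are equal")
    hc <- hclust(D, method = linkage)
    cor(as.numeric(D), as.numeric(cophenetic(hc)))
}

#' Scan factorization ranks
#'
#' Runs \code{\link{consensusNMF}} for each rank and tabulates the
#' cophenetic coefficient and the best final objective. Deterministic given
#' \code{baseSeed} (each rank reuses the same restart seeds).
#'
#' @inheritParams consensusNMF
#' @param ranks integer vector of ranks to scan.
#' @return data.frame with columns \code{rank}, \code{cophenetic},
#'   \code{finalObjective}, \code{nRuns}.
#' @export
rankScan <- function(V, ranks, nRuns = 30L, baseSeed = 1L, ...) {
    V <- .asNonnegMatrix(V)
    rows <- lapply(ranks, function(k) {
        cr <- consensusNMF(V, k, nRuns = nRuns, baseSeed = baseSeed, ...)
        data.frame(rank = k, cophenetic = cr@cophenetic,
                   finalObjective = tail(cr@best@objectiveTrace, 1L),
                   nRuns = nRuns)
    })
    do.call(rbind, rows)
}

#' Serialize factorization artifacts
#'
#' Writes W (probes x metagenes) and H (metagenes x samples) as TSV, and a
#' consensus summary (rank, runs, cophenetic, final objective) as JSON.
#'
#' @param cr a \linkS4class{ConsensusResult}.
#' @param wPath,hPath,summaryPath output paths (\code{NULL} to skip).
#' @return Invisibly, the summary list.
#' @export
writeFactorization <- function(cr, wPath = NULL, hPath = NULL,
                               summaryPath = NULL) {
    fr <- bestFit(cr)
    if (!is.null(wPath))
        .writeNamedMatrix(basisMatrix(fr), wPath, "probe_id")
    if (!is.null(hPath))
        .writeNamedMatrix(coefficientMatrix(fr), hPath, "metagene")
    summary <- list(rank = cr@rank, n_runs = cr@nRuns,
                    cophenetic = cr@cophenetic,
                    final_objective = tail(fr@objectiveTrace, 1L),
                    objective = fr@objective, seed = fr@seed,
                    n_iter = fr@nIter, converged = fr@converged)
    if (!is.null(summaryPath))
        jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE,
                             digits = NA)
    invisible(summary)
}

.writeNamedMatrix <- function(m, path, idColumn) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1L] <- idColumn
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

.readNamedMatrix <- function(path) {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    m
}
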