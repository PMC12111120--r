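## Projection of an independent cohort onto a fixed metagene basis by
## per-sample non-negative least squares (Lawson-Hanson active set).

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves \eqn{\min_h \|W h - v\|_2} subject to \eqn{h \ge 0} with the
#' Lawson-Hanson active-set algorithm. At the solution the
#' Karush-Kuhn-Tucker conditions hold: the gradient component of every
#' zero-valued coordinate is non-negative (dual feasibility tolerance
#' 1e-11). The unconstrained least-squares fit is returned unchanged
#' whenever it is already non-negative.
#'
#' @param W non-negative numeric matrix (m x k), no all-zero column;
#'   \code{m >= k} recommended.
#' @param v numeric vector of length m.
#' @param maxIter main-loop iteration cap, by convention \code{3 * k};
#'   exceeding it is an error.
#' @return list with \code{h} (length-k non-negative coefficients) and
#'   \code{residual} (Euclidean norm of \eqn{W h - v}).
#' @export
nnlsSolve <- function(W, v, maxIter = 3L * ncol(W)) {
    if (!is.matrix(W) || !is.numeric(W)) stop("W must be a numeric matrix")
    if (!all(is.finite(W)) || !all(is.finite(v)))
        stop("non-finite values in the NNLS input")
    if (length(v) != nrow(W)) stop("length(v) must equal nrow(W)")
    k <- ncol(W)
    zero <- colSums(abs(W)) == 0
    if (any(zero))
        stop("all-zero basis column(s): ", paste(which(zero), collapse = ", "))
    tolDual <- 1e-11 * max(1, max(abs(crossprod(W, v))))
    h <- numeric(k)
    P <- logical(k)
    iter <- 0L
    repeat {
        grad <- as.numeric(crossprod(W, v - W %*% h))
        cand <- which(!P & grad > tolDual)
        if (length(cand) == 0L) break
        iter <- iter + 1L
        if (iter > maxIter)
            stop("NNLS failed to converge within ", maxIter, " iterations")
        j <- cand[which.max(grad[cand])]
        P[j] <- TRUE
        repeat {
            z <- numeric(k)
            z[P] <- qr.coef(qr(W[, P, drop = FALSE]), v)
            z[is.na(z)] <- 0   # rank-deficient support: drop dependent column
            if (all(z[P] > 0)) {
                h <- z
                break
            }
            neg <- P & z <= 0
            alpha <- min(h[neg] / (h[neg] - z[neg]))
            h <- h + alpha * (z - h)
            P[P & h <= tolDual] <- FALSE
            h[!P] <- 0
        }
    }
    list(h = h, residual = sqrt(sum((v - W %*% h)^2)))
}

#' Project a cohort onto a fixed metagene basis
#'
#' Estimates the coefficient matrix \eqn{H_V} of an independent cohort
#' against the fixed basis \eqn{W_P} of the primary factorization: column
#' \eqn{s} of \eqn{H_V} is the NNLS solution of \eqn{W_P h = V[, s]}.
#' Columns are solved independently, so the result is invariant to sample
#' order. A plain pseudoinverse would not guarantee non-negative
#' coefficients, which is why the projection goes through
#' \code{\link{nnlsSolve}}.
#'
#' @param W fixed non-negative basis (probes x metagenes), or a
#'   \linkS4class{FactorizationResult} whose basis is used.
#' @param V probes x samples matrix (or complete \linkS4class{BetaSet}) with
#'   rows aligned to the basis probe order (see \code{\link{alignProbes}}).
#' @param probeCoverage coverage fraction recorded in the result (set by
#'   \code{\link{alignProbes}}; 1 when probes match exactly).
#' @param filledProbes identifiers of filled-in probes, if any.
#' @return A \linkS4class{ProjectionResult}.
#' @export
projectCohort <- function(W, V, probeCoverage = 1, filledProbes = character(0)) {
    if (is(W, "FactorizationResult")) W <- basisMatrix(W)
    if (is(V, "BetaSet")) V <- betaValues(V)
    if (nrow(V) != nrow(W))
        stop(sprintf("probe dimension mismatch: basis has %d probes, cohort %d",
                     nrow(W), nrow(V)))
    if (!is.null(rownames(W)) && !is.null(rownames(V)) &&
        !identical(rownames(W), rownames(V)))
        stop("cohort probes are not aligned to the basis order; run alignProbes")
    k <- ncol(W)
    HV <- matrix(0, k, ncol(V),
                 dimnames = list(colnames(W), colnames(V)))
    res <- numeric(ncol(V))
    for (s in seq_len(ncol(V))) {
        fit <- nnlsSolve(W, V[, s])
        HV[, s] <- fit$h
        res[s] <- fit$residual
    }
    names(res) <- colnames(V)
    new("ProjectionResult", HV = HV, residualNorms = res,
        probeCoverage = probeCoverage, filledProbes = filledProbes)
}

#' Align cohort probes to a basis probe order
#'
#' Reorders the rows of a cohort matrix to the basis probe order. Probes
#' absent from the cohort are handled per policy: \code{"error"} stops,
#' \code{"train-mean"} fills the row with the stored training-probe mean.
#' Under either policy, coverage (the fraction of basis probes the cohort
#' carries) below \code{coverageFloor} is an error.
#'
#' @param V probes x samples matrix or \linkS4class{BetaSet}.
#' @param basisProbeIDs non-empty character vector, the basis probe order.
#' @param fillPolicy \code{"error"} or \code{"train-mean"}.
#' @param trainMeans named numeric vector of training-probe means (required
#'   for the \code{"train-mean"} policy).
#' @param coverageFloor minimum acceptable coverage (default 0.95).
#' @return list with \code{matrix} (rows in basis order), \code{coverage}
#'   and \code{filled} (identifiers of filled probes).
#' @export
alignProbes <- function(V, basisProbeIDs,
                        fillPolicy = c("error", "train-mean"),
                        trainMeans = NULL, coverageFloor = 0.95) {
    fillPolicy <- match.arg(fillPolicy)
    if (is(V, "BetaSet")) V <- betaValues(V)
    if (length(basisProbeIDs) == 0L) stop("basisProbeIDs must be non-empty")
    idx <- match(basisProbeIDs, rownames(V))
    present <- !is.na(idx)
    coverage <- mean(present)
    if (coverage < coverageFloor)
        stop(sprintf("probe coverage %.3f below the floor %.2f",
                     coverage, coverageFloor))
    missing <- basisProbeIDs[!present]
    if (length(missing) && fillPolicy == "error")
        stop(sprintf("%d basis probe(s) absent from the cohort, e.g.: %s",
                     length(missing), paste(head(missing, 5L), collapse = ", ")))
    out <- matrix(NA_real_, length(basisProbeIDs), ncol(V),
                  dimnames = list(basisProbeIDs, colnames(V)))
    out[present, ] <- V[idx[present], , drop = FALSE]
    if (length(missing)) {
        if (is.null(trainMeans) || !all(missing %in% names(trainMeans)))
            stop("train-mean policy requires trainMeans covering all absent probes")
        out[missing, ] <- trainMeans[missing]
    }
    list(matrix = out, coverage = coverage, filled = missing)
}

#' Serialize a ProjectionResult
#'
#' Writes the projected coefficients as a metagenes x samples TSV and a
#' JSON coverage report (coverage fraction, filled probes, residual norms).
#'
#' @param pr a \linkS4class{ProjectionResult}.
#' @param hPath,reportPath output paths (\code{NULL} to skip).
#' @return Invisibly, the report list.
#' @export
writeProjection <- function(pr, hPath = NULL, reportPath = NULL) {
    if (!is.null(hPath))
        .writeNamedMatrix(projectedCoefficients(pr), hPath, "metagene")
    report <- list(probe_coverage = probeCoverage(pr),
                   filled_probes = pr@filledProbes,
                   residual_norms = as.list(residualNorms(pr)))
    if (!is.null(reportPath))
        jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA)
    invisible(report)
}
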