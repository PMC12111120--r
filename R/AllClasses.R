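#' @import methods
#' @useDynLib mbMetagene, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor cophenetic hclust as.dist var runif rnorm predict setNames median rank
#' @importFrom utils head tail packageVersion
NULL

#' Seven-subgroup label vocabulary
#'
#' The closed label vocabulary used throughout the package: the seven
#' molecular subgroups of medulloblastoma (WNT, SHH split by age at
#' diagnosis, and Group 3 / Group 4 each split by clinical risk), plus the
#' sentinel \code{"Non-classifiable"} used for samples excluded from
#' supervised analysis.
#'
#' @param includeNonClassifiable logical; if \code{TRUE} the sentinel label
#'   is appended after the seven subgroups.
#' @return Character vector of labels in the fixed encoding order.
#' @examples
#' mbSubgroups()
#' @export
mbSubgroups <- function(includeNonClassifiable = FALSE) {
    labs <- c("WNT", "SHH-Infant", "SHH-Child",
              "Group3-LowRisk", "Group3-HighRisk",
              "Group4-LowRisk", "Group4-HighRisk")
    if (includeNonClassifiable) c(labs, "Non-classifiable") else labs
}

.NON_CLASSIFIABLE <- "Non-classifiable"

## ---------------------------------------------------------------------------
## BetaSet: probes x samples beta values with optional paired detection
## p-values, carried as assays of a SummarizedExperiment.
## ---------------------------------------------------------------------------

#' BetaSet: methylation beta values with paired detection p-values
#'
#' \code{BetaSet} extends \linkS4class{SummarizedExperiment}. The first assay,
#' \code{"beta"}, holds probes x samples methylation proportions in
#' \eqn{[0, 1]} (closed interval; \code{NA} marks missing measurements). An
#' optional second assay, \code{"detP"}, holds the paired detection p-values
#' with identical dimensions.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases BetaSet-class
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

.validBetaSet <- function(object) {
    msg <- character(0)
    anames <- SummarizedExperiment::assayNames(object)
    if (length(anames) == 0L || anames[1L] != "beta")
        msg <- c(msg, "first assay must be named 'beta'")
    if (!all(anames %in% c("beta", "detP")))
        msg <- c(msg, "assays must be 'beta' and optionally 'detP'")
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
        msg <- c(msg, "beta values must lie in [0, 1]")
    if ("detP" %in% anames) {
        p <- SummarizedExperiment::assay(object, "detP")
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("BetaSet", .validBetaSet)

#' Construct a BetaSet
#'
#' @param beta numeric matrix, probes x samples, values in \eqn{[0,1]} or
#'   \code{NA}; must carry unique row and column names.
#' @param detP optional numeric matrix of detection p-values, same dimensions
#'   and dimnames as \code{beta}.
#' @param rowData,colData optional probe / sample annotation passed to
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @return A \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaSet(b)
#' @export
BetaSet <- function(beta, detP = NULL, rowData = NULL, colData = NULL) {
    if (!is.matrix(beta) || !is.numeric(beta))
        stop("'beta' must be a numeric matrix")
    assays <- list(beta = beta)
    if (!is.null(detP)) {
        if (!identical(dim(detP), dim(beta)))
            stop("'detP' must have the same dimensions as 'beta'")
        dimnames(detP) <- dimnames(beta)
        assays$detP <- detP
    }
    args <- list(assays = assays)
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("BetaSet", se)
}

#' @describeIn BetaSet the beta-value matrix (probes x samples).
#' @param x,object a \code{BetaSet}.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn BetaSet the detection p-value matrix, or \code{NULL} when the
#'   cohort was read without one.
#' @export
detectionP <- function(x) {
    if (hasDetectionP(x)) SummarizedExperiment::assay(x, "detP") else NULL
}

#' @describeIn BetaSet whether a detection p-value block is present.
#' @export
hasDetectionP <- function(x) "detP" %in% SummarizedExperiment::assayNames(x)

#' @describeIn BetaSet probe identifiers, in matrix order.
#' @export
probeIDs <- function(x) rownames(x)

#' @describeIn BetaSet sample identifiers, in matrix order.
#' @export
sampleIDs <- function(x) colnames(x)

setMethod("show", "BetaSet", function(object) {
    b <- betaValues(object)
    cat(sprintf("BetaSet: %d probes x %d samples\n", nrow(b), ncol(b)))
    cat(sprintf("  detection p-values: %s\n",
                if (hasDetectionP(object)) "present" else "absent"))
    cat(sprintf("  missing beta values: %d (%.2f%%)\n",
                sum(is.na(b)), 100 * mean(is.na(b))))
})

## ---------------------------------------------------------------------------
## FilterReport
## ---------------------------------------------------------------------------

#' FilterReport: probe-filter accounting
#'
#' Per-category identifier sets and counts produced by
#' \code{\link{filterProbes}}: sex-chromosome (XY) probes, cross-reactive
#' probes, SNP-proximal probes (minor allele frequency at or above the
#' threshold within 50 bp of the target CpG), and low-confidence probes
#' (post-masking missing fraction above the threshold). A probe may fall in
#' several categories; \code{nUniqueRemoved} counts the union once.
#'
#' @slot removedIDs named list of four character vectors
#'   (\code{xy}, \code{crossReactive}, \code{snp}, \code{lowConfidence}).
#' @slot nUniqueRemoved integer, size of the union.
#' @aliases FilterReport-class
#' @exportClass FilterReport
setClass("FilterReport",
    representation(removedIDs = "list", nUniqueRemoved = "integer"))

.validFilterReport <- function(object) {
    msg <- character(0)
    want <- c("xy", "crossReactive", "snp", "lowConfidence")
    if (!identical(names(object@removedIDs), want))
        msg <- c(msg, "removedIDs must be named xy, crossReactive, snp, lowConfidence")
    u <- length(unique(unlist(object@removedIDs, use.names = FALSE)))
    if (object@nUniqueRemoved != u)
        msg <- c(msg, "nUniqueRemoved must equal the size of the category union")
    if (u > sum(lengths(object@removedIDs)))
        msg <- c(msg, "union exceeds the sum of category sizes")
    if (length(msg)) msg else TRUE
}
setValidity("FilterReport", .validFilterReport)

FilterReport <- function(xy, crossReactive, snp, lowConfidence) {
    ids <- list(xy = as.character(xy), crossReactive = as.character(crossReactive),
                snp = as.character(snp), lowConfidence = as.character(lowConfidence))
    new("FilterReport", removedIDs = ids,
        nUniqueRemoved = length(unique(unlist(ids, use.names = FALSE))))
}

#' @describeIn FilterReport per-category and unique removal counts as a
#'   named integer vector.
#' @param object a \code{FilterReport}.
#' @export
filterCounts <- function(object) {
    c(nXY = length(object@removedIDs$xy),
      nCrossReactive = length(object@removedIDs$crossReactive),
      nSNP = length(object@removedIDs$snp),
      nLowConfidence = length(object@removedIDs$lowConfidence),
      nUniqueRemoved = object@nUniqueRemoved)
}

#' @describeIn FilterReport the per-category identifier sets.
#' @export
removedProbeIDs <- function(object) object@removedIDs

setMethod("show", "FilterReport", function(object) {
    cts <- filterCounts(object)
    cat("FilterReport (removed probes)\n")
    cat(sprintf("  XY mapped:       %d\n", cts["nXY"]))
    cat(sprintf("  cross-reactive:  %d\n", cts["nCrossReactive"]))
    cat(sprintf("  SNP affected:    %d\n", cts["nSNP"]))
    cat(sprintf("  low confidence:  %d\n", cts["nLowConfidence"]))
    cat(sprintf("  total unique:    %d\n", cts["nUniqueRemoved"]))
})

## ---------------------------------------------------------------------------
## FactorizationResult / ConsensusResult
## ---------------------------------------------------------------------------

#' FactorizationResult: a single NMF fit
#'
#' Result of one multiplicative-update non-negative matrix factorization
#' \eqn{V \approx W H}: \code{W} (probes x rank) holds the contribution of
#' each CpG probe to each metagene, \code{H} (rank x samples) the metagene
#' coefficients of each sample.
#'
#' @slot W,H non-negative factor matrices.
#' @slot objectiveTrace per-iteration objective values (non-increasing).
#' @slot rank,seed,nIter integers.
#' @slot converged logical; relative objective change fell below tolerance.
#' @slot objective \code{"kl"} or \code{"frobenius"}.
#' @aliases FactorizationResult-class
#' @exportClass FactorizationResult
setClass("FactorizationResult",
    representation(W = "matrix", H = "matrix", objectiveTrace = "numeric",
                   rank = "integer", seed = "integer", nIter = "integer",
                   converged = "logical", objective = "character"))

.validFactorizationResult <- function(object) {
    msg <- character(0)
    if (any(object@W < 0) || any(object@H < 0))
        msg <- c(msg, "W and H must be non-negative")
    if (ncol(object@W) != object@rank || nrow(object@H) != object@rank)
        msg <- c(msg, "factor dimensions must match the rank")
    tr <- object@objectiveTrace
    if (length(tr) > 1) {
        ## tolerance scaled to the trace magnitude: at the convergence floor
        ## (objective near 0 for exactly factorizable input) point-wise
        ## relative comparisons are dominated by floating-point noise
        if (any(diff(tr) > 1e-9 * max(abs(tr[1]), 1)))
            msg <- c(msg, "objective trace must be non-increasing (rel. tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("FactorizationResult", .validFactorizationResult)

#' @describeIn FactorizationResult the basis matrix W (probes x metagenes).
#' @param object a \code{FactorizationResult}.
#' @export
basisMatrix <- function(object) object@W

#' @describeIn FactorizationResult the coefficient matrix H
#'   (metagenes x samples).
#' @export
coefficientMatrix <- function(object) object@H

#' @describeIn FactorizationResult per-iteration objective values.
#' @export
objectiveTrace <- function(object) object@objectiveTrace

setMethod("show", "FactorizationResult", function(object) {
    cat(sprintf(
        "FactorizationResult: rank %d (%s), %d probes x %d samples\n",
        object@rank, object@objective, nrow(object@W), ncol(object@H)))
    cat(sprintf("  %d iterations, converged: %s, final objective %.6g (seed %d)\n",
                object@nIter, object@converged,
                tail(object@objectiveTrace, 1L), object@seed))
})

#' ConsensusResult: stability of a factorization rank
#'
#' Aggregates \code{nRuns} seeded NMF restarts: the samples x samples
#' consensus matrix (fraction of runs in which two samples share a dominant
#' metagene), its cophenetic correlation coefficient, and the restart with
#' the lowest final objective.
#'
#' @slot consensus samples x samples matrix in \eqn{[0,1]}, symmetric with
#'   unit diagonal.
#' @slot cophenetic numeric in \eqn{[-1,1]} (\code{NA} when the consensus is
#'   degenerate, i.e. all off-diagonal entries equal).
#' @slot rank,nRuns integers.
#' @slot best the \linkS4class{FactorizationResult} with the lowest final
#'   objective.
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(consensus = "matrix", cophenetic = "numeric",
                   rank = "integer", nRuns = "integer",
                   best = "FactorizationResult"))

.validConsensusResult <- function(object) {
    msg <- character(0)
    C <- object@consensus
    if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-12)
        msg <- c(msg, "consensus must be symmetric")
    if (any(abs(diag(C) - 1) > 1e-12))
        msg <- c(msg, "consensus diagonal must be 1")
    if (any(C < 0 | C > 1)) msg <- c(msg, "consensus entries must lie in [0,1]")
    if (length(msg)) msg else TRUE
}
setValidity("ConsensusResult", .validConsensusResult)

#' @describeIn ConsensusResult the consensus matrix.
#' @param object a \code{ConsensusResult}.
#' @export
consensusMatrix <- function(object) object@consensus

#' @describeIn ConsensusResult the cophenetic correlation coefficient.
#' @export
copheneticScore <- function(object) object@cophenetic

#' @describeIn ConsensusResult the best restart (lowest final objective).
#' @export
bestFit <- function(object) object@best

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: rank %d, %d runs, cophenetic %.4f\n",
                object@rank, object@nRuns, object@cophenetic))
})

## ---------------------------------------------------------------------------
## ProjectionResult
## ---------------------------------------------------------------------------

#' ProjectionResult: a cohort projected onto a fixed metagene basis
#'
#' Per-sample non-negative least-squares coefficients of an independent
#' cohort against a fixed basis \code{W}, with the Euclidean residual of each
#' fit and the fraction of basis probes the cohort covered.
#'
#' @slot HV metagenes x samples non-negative coefficient matrix.
#' @slot residualNorms per-sample Euclidean residuals.
#' @slot probeCoverage fraction of basis probes present in the cohort.
#' @slot filledProbes identifiers of basis probes absent from the cohort and
#'   filled from training means (empty under the \code{"error"} policy).
#' @aliases ProjectionResult-class
#' @exportClass ProjectionResult
setClass("ProjectionResult",
    representation(HV = "matrix", residualNorms = "numeric",
                   probeCoverage = "numeric", filledProbes = "character"))

.validProjectionResult <- function(object) {
    msg <- character(0)
    if (any(object@HV < 0)) msg <- c(msg, "H_V must be non-negative")
    if (any(object@residualNorms < 0)) msg <- c(msg, "residuals must be >= 0")
    if (length(object@residualNorms) != ncol(object@HV))
        msg <- c(msg, "one residual per sample required")
    if (length(msg)) msg else TRUE
}
setValidity("ProjectionResult", .validProjectionResult)

#' @describeIn ProjectionResult the projected coefficient matrix
#'   (metagenes x samples).
#' @param object a \code{ProjectionResult}.
#' @export
projectedCoefficients <- function(object) object@HV

#' @describeIn ProjectionResult per-sample Euclidean residual norms.
#' @export
residualNorms <- function(object) object@residualNorms

#' @describeIn ProjectionResult fraction of basis probes present in the
#'   projected cohort.
#' @export
probeCoverage <- function(object) object@probeCoverage

setMethod("show", "ProjectionResult", function(object) {
    cat(sprintf(
        "ProjectionResult: %d metagenes x %d samples (coverage %.3f)\n",
        nrow(object@HV), ncol(object@HV), object@probeCoverage))
    cat(sprintf("  median residual norm %.4g\n", median(object@residualNorms)))
})

## ---------------------------------------------------------------------------
## EvaluationReport
## ---------------------------------------------------------------------------

#' EvaluationReport: multiclass classifier evaluation
#'
#' Confusion matrix (true rows x predicted columns), per-class precision /
#' recall / specificity / F1, macro averages, standard accuracy, both
#' balanced-accuracy conventions, one-vs-rest AUC per class, and the
#' per-sample class-probability table.
#'
#' Two balanced-accuracy conventions are reported: macro recall (the
#' unweighted mean of per-class recall) and the unweighted mean of per-class
#' \eqn{(recall + specificity)/2}. Summaries label both explicitly.
#'
#' @slot confusion integer matrix, true rows x predicted columns.
#' @slot perClass data.frame of per-class metrics (one row per class;
#'   \code{NA} for classes absent from the true labels).
#' @slot accuracy,balancedAccuracyMacroRecall,balancedAccuracySensSpec,
#'   macroPrecision,macroRecall,macroF1,macroAUC numeric scalars.
#' @slot probabilities samples x classes probability matrix.
#' @slot trueLabels,predictedLabels factors over the class vocabulary.
#' @aliases EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(confusion = "matrix", perClass = "data.frame",
                   accuracy = "numeric",
                   balancedAccuracyMacroRecall = "numeric",
                   balancedAccuracySensSpec = "numeric",
                   macroPrecision = "numeric", macroRecall = "numeric",
                   macroF1 = "numeric", macroAUC = "numeric",
                   probabilities = "matrix",
                   trueLabels = "factor", predictedLabels = "factor"))

.validEvaluationReport <- function(object) {
    msg <- character(0)
    C <- object@confusion
    if (nrow(C) != ncol(C)) msg <- c(msg, "confusion matrix must be square")
    if (length(object@trueLabels) &&
        sum(C) != length(object@trueLabels))
        msg <- c(msg, "confusion total must equal the number of samples")
    sc <- c(object@accuracy, object@balancedAccuracyMacroRecall,
            object@balancedAccuracySensSpec, object@macroPrecision,
            object@macroRecall, object@macroF1)
    if (any(sc < -1e-12 | sc > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "summary metrics must lie in [0, 1]")
    if (length(msg)) msg else TRUE
}
setValidity("EvaluationReport", .validEvaluationReport)

#' @describeIn EvaluationReport the confusion matrix (true rows x predicted
#'   columns).
#' @param object an \code{EvaluationReport}.
#' @export
confusionMatrix <- function(object) object@confusion

#' @describeIn EvaluationReport per-class metric table.
#' @export
perClassMetrics <- function(object) object@perClass

#' @describeIn EvaluationReport named vector of summary metrics.
#' @export
macroMetrics <- function(object) {
    c(accuracy = object@accuracy,
      macroPrecision = object@macroPrecision,
      macroRecall = object@macroRecall,
      macroF1 = object@macroF1,
      balancedAccuracyMacroRecall = object@balancedAccuracyMacroRecall,
      balancedAccuracySensSpec = object@balancedAccuracySensSpec,
      macroAUC = object@macroAUC)
}

#' @describeIn EvaluationReport the per-sample class-probability table.
#' @export
classProbabilities <- function(object) object@probabilities

setMethod("show", "EvaluationReport", function(object) {
    m <- macroMetrics(object)
    cat(sprintf("EvaluationReport: %d samples, %d classes\n",
                sum(object@confusion), nrow(object@confusion)))
    cat(sprintf("  accuracy %.4f | macro precision %.4f | macro recall %.4f | macro F1 %.4f\n",
                m["accuracy"], m["macroPrecision"], m["macroRecall"], m["macroF1"]))
    cat(sprintf("  balanced accuracy: %.4f (macro recall) / %.4f (mean (sens+spec)/2)\n",
                m["balancedAccuracyMacroRecall"], m["balancedAccuracySensSpec"]))
    cat(sprintf("  macro one-vs-rest AUC %.4f\n", m["macroAUC"]))
})

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' SyntheticTruth: ground truth of a simulated cohort
#'
#' Records the latent structure behind a cohort from
#' \code{\link{generateCohort}}: the true non-negative factors, the subgroup
#' labels, the positions planted as unreliable (detection p-value above
#' 0.05), the planted probe annotation, and the complete (pre-corruption)
#' beta matrix.
#'
#' @slot WTrue,HTrue the generating factors.
#' @slot labels factor of subgroup labels per sample.
#' @slot maskedPositions two-column integer matrix (probe row, sample column)
#'   of planted low-confidence positions.
#' @slot annotation planted probe annotation data.frame.
#' @slot completeBeta the uncorrupted beta matrix.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(WTrue = "matrix", HTrue = "matrix", labels = "factor",
                   maskedPositions = "matrix", annotation = "data.frame",
                   completeBeta = "matrix"))

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d probes x %d samples, rank %d, %d masked positions\n",
                nrow(object@WTrue), ncol(object@HTrue), ncol(object@WTrue),
                nrow(object@maskedPositions)))
})
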