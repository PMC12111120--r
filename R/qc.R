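## Quality-control chain: detection-p masking, four-category probe filtering,
## non-classifiable sample removal, KNN imputation, top-variance selection.

#' QC configuration
#'
#' Bundles the thresholds of the quality-control chain. Defaults follow the
#' framework's standard settings: detection p-value threshold 0.05 (strict
#' \code{>} masks a value), maximum post-masking missing fraction 0.5 (strict
#' \code{>} removes a probe), SNP minor-allele-frequency threshold 0.05
#' (\code{>=} removes a probe), 10,000 top-variance probes, and K = 10
#' imputation neighbours.
#'
#' @param detectionPThreshold,maxMissingFraction,mafThreshold fractions in
#'   \eqn{(0,1)}.
#' @param nTopVariance,knnK positive counts.
#' @return A validated list of class \code{"QCConfig"}.
#' @export
qcConfig <- function(detectionPThreshold = 0.05, maxMissingFraction = 0.5,
                     mafThreshold = 0.05, nTopVariance = 10000L, knnK = 10L) {
    thr <- c(detectionPThreshold = detectionPThreshold,
             maxMissingFraction = maxMissingFraction,
             mafThreshold = mafThreshold)
    if (any(thr <= 0 | thr >= 1))
        stop("thresholds must lie strictly in (0, 1): ",
             paste(names(thr)[thr <= 0 | thr >= 1], collapse = ", "))
    if (nTopVariance < 1 || knnK < 1)
        stop("nTopVariance and knnK must be positive counts")
    structure(list(detectionPThreshold = detectionPThreshold,
                   maxMissingFraction = maxMissingFraction,
                   mafThreshold = mafThreshold,
                   nTopVariance = as.integer(nTopVariance),
                   knnK = as.integer(knnK)),
              class = "QCConfig")
}

#' Mask low-confidence beta values
#'
#' Sets a beta value to missing wherever its paired detection p-value is
#' strictly above \code{threshold}; everything else, including the detection
#' p-values themselves, is untouched. A value with p exactly equal to the
#' threshold is retained.
#'
#' @param bs a \linkS4class{BetaSet} with detection p-values.
#' @param threshold detection p-value threshold (default 0.05).
#' @return The masked \linkS4class{BetaSet}.
#' @export
maskLowConfidence <- function(bs, threshold = 0.05) {
    stopifnot(is(bs, "BetaSet"))
    if (!hasDetectionP(bs))
        stop("detection p-values are absent; cannot mask low-confidence values")
    beta <- betaValues(bs)
    detP <- detectionP(bs)
    beta[!is.na(detP) & detP > threshold] <- NA_real_
    SummarizedExperiment::assay(bs, "beta") <- beta
    bs
}

#' Filter probes by annotation category and missingness
#'
#' Removes the union of four probe categories: (a) probes mapped to the sex
#' chromosomes X and Y; (b) cross-reactive / multi-mapping probes; (c)
#' probes with a SNP of minor allele frequency at or above
#' \code{cfg$mafThreshold} within 50 bp of the target CpG; (d) low-confidence
#' probes whose post-masking missing fraction across samples is strictly
#' above \code{cfg$maxMissingFraction}. Surviving probes keep their original
#' order. Every probe in \code{bs} must be annotated.
#'
#' @param bs a \linkS4class{BetaSet} (typically after
#'   \code{\link{maskLowConfidence}}).
#' @param annotation data.frame as returned by
#'   \code{\link{readProbeAnnotation}}.
#' @param cfg a \code{\link{qcConfig}}.
#' @return list with elements \code{betaSet} (surviving probes) and
#'   \code{report} (a \linkS4class{FilterReport}).
#' @export
filterProbes <- function(bs, annotation, cfg = qcConfig()) {
    stopifnot(is(bs, "BetaSet"))
    probes <- probeIDs(bs)
    idx <- match(probes, annotation$probe_id)
    if (anyNA(idx)) {
        gaps <- probes[is.na(idx)]
        stop(sprintf("%d probe(s) lack annotation records, e.g.: %s",
                     length(gaps), paste(head(gaps, 5L), collapse = ", ")))
    }
    ann <- annotation[idx, , drop = FALSE]
    beta <- betaValues(bs)
    xy <- probes[ann$chromosome %in% c("X", "Y")]
    cross <- probes[ann$cross_reactive]
    snp <- probes[ann$max_maf_within_50bp >= cfg$mafThreshold]
    lowConf <- probes[rowMeans(is.na(beta)) > cfg$maxMissingFraction]
    report <- FilterReport(xy, cross, snp, lowConf)
    keep <- !(probes %in% unique(c(xy, cross, snp, lowConf)))
    if (!any(keep))
        stop("all probes were removed by filtering; nothing survives")
    list(betaSet = bs[keep, ], report = report)
}

#' Drop non-classifiable samples
#'
#' Removes samples whose sheet label is \code{"Non-classifiable"} from both
#' the matrix and the sheet, preserving order. Every sample in the matrix
#' must appear in the sheet.
#'
#' @param bs a \linkS4class{BetaSet}.
#' @param sheet data.frame as returned by \code{\link{readSampleSheet}}.
#' @return list with elements \code{betaSet} and \code{sheet}, both reduced
#'   to classifiable samples.
#' @export
filterSamples <- function(bs, sheet) {
    stopifnot(is(bs, "BetaSet"))
    samples <- sampleIDs(bs)
    idx <- match(samples, sheet$sample_id)
    if (anyNA(idx))
        stop("sample(s) missing from the sheet: ",
             paste(head(samples[is.na(idx)], 5L), collapse = ", "))
    lab <- as.character(sheet$label[idx])
    keep <- lab != .NON_CLASSIFIABLE
    if (!any(keep))
        stop("all samples are Non-classifiable; nothing survives")
    keptSheet <- sheet[idx[keep], , drop = FALSE]
    keptSheet$label <- droplevels(factor(keptSheet$label, levels = mbSubgroups()))
    rownames(keptSheet) <- NULL
    list(betaSet = bs[, keep], sheet = keptSheet)
}

## Pairwise sample distances over mutually observed probes, rescaled by
## sqrt(nProbes / nShared) so sparsity does not shrink distances.
.sampleDistances <- function(X) {
    ## X: samples x probes, NAs allowed
    O <- !is.na(X)
    X0 <- X
    X0[!O] <- 0
    A <- X0^2
    sharedSq <- A %*% t(O) + O %*% t(A) - 2 * X0 %*% t(X0)
    sharedSq[sharedSq < 0] <- 0   # numerical noise
    nShared <- O %*% t(O)
    d <- sqrt(sharedSq * ncol(X) / pmax(nShared, 1L))
    d[nShared == 0] <- Inf
    diag(d) <- 0
    d
}

#' KNN imputation of missing beta values
#'
#' Replaces every missing beta value by the unweighted mean of the values at
#' that probe in the K nearest samples. Neighbour distances are Euclidean
#' over mutually observed probes, rescaled by \eqn{\sqrt{n_{probes} /
#' n_{shared}}} so that sparsity does not shrink distances. Only samples
#' observed at the target probe are candidate neighbours; ties break by
#' sample order. Imputation operates internally on the samples-as-rows
#' orientation; the returned object stays probes x samples. Observed values
#' are never altered, so the operation is idempotent on complete matrices.
#'
#' @param bs a \linkS4class{BetaSet}; no probe may be missing in all samples
#'   (such probes must already have been removed by
#'   \code{\link{filterProbes}}) and no sample may be entirely missing.
#' @param k number of neighbours; must satisfy \code{k < n_samples}.
#' @return A complete \linkS4class{BetaSet} with imputed values clipped to
#'   \eqn{[0,1]}.
#' @export
knnImpute <- function(bs, k = 10L) {
    stopifnot(is(bs, "BetaSet"))
    beta <- betaValues(bs)
    ns <- ncol(beta)
    if (k >= ns)
        stop(sprintf("k = %d must be smaller than the number of samples (%d)",
                     k, ns))
    miss <- is.na(beta)
    if (!any(miss)) return(bs)
    allMissProbes <- rowSums(!miss) == 0L
    if (any(allMissProbes))
        stop("probe(s) missing in all samples (remove via filterProbes): ",
             paste(head(rownames(beta)[allMissProbes], 5L), collapse = ", "))
    if (any(colSums(!miss) == 0L))
        stop("sample(s) entirely missing: ",
             paste(head(colnames(beta)[colSums(!miss) == 0L], 5L),
                   collapse = ", "))
    X <- t(beta)                          # samples x probes
    d <- .sampleDistances(X)
    ## per-sample neighbour ordering (stable: ties by sample index)
    ord <- apply(d, 1L, function(row) order(row, seq_along(row)))
    out <- beta
    for (s in which(colSums(miss) > 0L)) {
        nbr <- ord[, s]
        nbr <- nbr[nbr != s]
        for (p in which(miss[, s])) {
            cand <- nbr[!miss[p, nbr]]
            use <- head(cand, k)
            out[p, s] <- mean(beta[p, use])
        }
    }
    out[out < 0] <- 0
    out[out > 1] <- 1
    SummarizedExperiment::assay(bs, "beta") <- out
    bs
}

#' Select the top-variance probes
#'
#' Retains the \code{n} probes with the largest sample variance across
#' samples (divisor \eqn{n_{samples} - 1}). Ties break by probe identifier
#' in lexicographic (C-locale) order, smaller identifier first; retained
#' probes keep their original matrix order.
#'
#' @param bs a complete (post-imputation) \linkS4class{BetaSet}.
#' @param n number of probes to keep; \code{n <= n_probes}.
#' @return The reduced \linkS4class{BetaSet}.
#' @export
selectTopVariance <- function(bs, n = 10000L) {
    stopifnot(is(bs, "BetaSet"))
    beta <- betaValues(bs)
    if (anyNA(beta))
        stop("matrix must be complete (run knnImpute first)")
    if (n > nrow(beta))
        stop(sprintf("n = %d exceeds the number of probes (%d)", n, nrow(beta)))
    v <- rowSums((beta - rowMeans(beta))^2) / (ncol(beta) - 1L)
    sel <- order(-v, rownames(beta), method = "radix")[seq_len(n)]
    bs[sort(sel), ]
}

#' Serialize a FilterReport
#'
#' Writes the report as JSON (counts plus per-category identifier sets) and
#' as a two-column category/count TSV.
#'
#' @param report a \linkS4class{FilterReport}.
#' @param jsonPath,tsvPath output paths (\code{NULL} to skip either form).
#' @return Invisibly, the list serialized to JSON.
#' @export
writeFilterReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
    cts <- filterCounts(report)
    payload <- list(counts = as.list(cts),
                    removed_ids = removedProbeIDs(report))
    if (!is.null(jsonPath))
        jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)
    if (!is.null(tsvPath)) {
        tab <- data.frame(
            category = c("XY mapped", "Non-specific binding", "SNPs affected",
                         "Low confidence", "Total unique"),
            count = as.integer(cts))
        data.table::fwrite(tab, tsvPath, sep = "\t", quote = FALSE)
    }
    invisible(payload)
}
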