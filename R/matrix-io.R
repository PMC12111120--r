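## TSV readers/writers for the array data model: paired beta/detection-p
## tables, probe annotations, sample sheets. GEO supplements vary in header
## conventions, so the paired-column suffixes and NA tokens are configurable.

.DEFAULT_NA_TOKENS <- c("", "NA", "NaN")

## parse a character matrix column-wise to numeric; error names the offending
## probe/column instead of silently introducing NA
.parseNumeric <- function(chr, probeID, colName, naTokens) {
    isNA <- chr %in% naTokens
    out <- suppressWarnings(as.numeric(chr))
    bad <- which(!isNA & is.na(out))
    if (length(bad))
        stop(sprintf("non-numeric value '%s' at probe '%s', column '%s'",
                     chr[bad[1L]], probeID[bad[1L]], colName), call. = FALSE)
    out[isNA] <- NA_real_
    out
}

.checkUnitInterval <- function(x, what, probeID, colName) {
    bad <- which(x < 0 | x > 1)
    if (length(bad))
        stop(sprintf("%s %g out of [0, 1] at probe '%s', column '%s'",
                     what, x[bad[1L]], probeID[bad[1L]], colName),
             call. = FALSE)
    invisible(x)
}

#' Read a beta-value table
#'
#' Reads a tab-separated probes x samples table into a
#' \linkS4class{BetaSet}. In the \code{"paired-columns"} dialect every sample
#' contributes exactly two adjacent data columns, \code{<sample><betaSuffix>}
#' and \code{<sample><pvalSuffix>} (beta value and detection p-value); in the
#' \code{"beta-only"} dialect each data column is one sample and no detection
#' p-values are read. The first column always holds the probe identifier.
#' Values outside \eqn{[0,1]} are rejected, never clipped.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @param dialect \code{"paired-columns"} or \code{"beta-only"}.
#' @param betaSuffix,pvalSuffix header suffixes of the paired columns.
#' @param naTokens strings read as missing (default \code{""}, \code{"NA"},
#'   \code{"NaN"}).
#' @return A \linkS4class{BetaSet}; in the paired dialect the number of
#'   samples is exactly half the number of data columns.
#' @seealso \code{\link{writeBetaTable}}
#' @export
readBetaTable <- function(path,
                          dialect = c("paired-columns", "beta-only"),
                          betaSuffix = ".beta", pvalSuffix = ".pval",
                          naTokens = .DEFAULT_NA_TOKENS) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            data.table = FALSE, encoding = "UTF-8")
    if (ncol(dt) < 2L) stop("no data columns in ", path)
    probeID <- dt[[1L]]
    dup <- probeID[duplicated(probeID)]
    if (length(dup))
        stop("duplicate probe identifier(s): ",
             paste(unique(dup), collapse = ", "))
    dataCols <- names(dt)[-1L]

    if (dialect == "paired-columns") {
        if (length(dataCols) %% 2L != 0L)
            stop(sprintf(
                "paired-columns dialect requires an even data-column count, got %d",
                length(dataCols)))
        bIdx <- seq(1L, length(dataCols), by = 2L)
        bCols <- dataCols[bIdx]
        pCols <- dataCols[bIdx + 1L]
        okB <- endsWith(bCols, betaSuffix)
        okP <- endsWith(pCols, pvalSuffix)
        if (!all(okB) || !all(okP))
            stop("paired columns must alternate '<sample>", betaSuffix,
                 "' / '<sample>", pvalSuffix, "'; offending column: ",
                 c(bCols[!okB], pCols[!okP])[1L])
        samples <- substr(bCols, 1L, nchar(bCols) - nchar(betaSuffix))
        pSamples <- substr(pCols, 1L, nchar(pCols) - nchar(pvalSuffix))
        if (!identical(samples, pSamples))
            stop("beta/p-value column pairs disagree on sample names: ",
                 paste(head(samples[samples != pSamples], 3L), collapse = ", "))
        if (anyDuplicated(samples))
            stop("duplicate sample identifier(s): ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", "))
        beta <- matrix(NA_real_, nrow(dt), length(samples),
                       dimnames = list(probeID, samples))
        detP <- beta
        for (j in seq_along(samples)) {
            b <- .parseNumeric(dt[[bCols[j]]], probeID, bCols[j], naTokens)
            p <- .parseNumeric(dt[[pCols[j]]], probeID, pCols[j], naTokens)
            .checkUnitInterval(b, "beta value", probeID, bCols[j])
            .checkUnitInterval(p, "detection p-value", probeID, pCols[j])
            beta[, j] <- b
            detP[, j] <- p
        }
        BetaSet(beta, detP = detP)
    } else {
        if (anyDuplicated(dataCols))
            stop("duplicate sample identifier(s): ",
                 paste(unique(dataCols[duplicated(dataCols)]), collapse = ", "))
        beta <- matrix(NA_real_, nrow(dt), length(dataCols),
                       dimnames = list(probeID, dataCols))
        for (j in seq_along(dataCols)) {
            b <- .parseNumeric(dt[[dataCols[j]]], probeID, dataCols[j], naTokens)
            .checkUnitInterval(b, "beta value", probeID, dataCols[j])
            beta[, j] <- b
        }
        BetaSet(beta)
    }
}

## bit-stable decimal rendering: %.17g round-trips doubles exactly
.renderNumeric <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
}

#' Write a beta-value table
#'
#' Inverse of \code{\link{readBetaTable}}: writes a \linkS4class{BetaSet} as
#' a tab-separated table with bit-stable decimal rendering, so that a
#' read-back reproduces the object exactly. Missing values become empty
#' cells. The \code{"beta-only"} dialect drops the detection p-value block.
#'
#' @inheritParams readBetaTable
#' @param bs a \linkS4class{BetaSet}.
#' @return \code{path}, invisibly.
#' @export
writeBetaTable <- function(bs, path,
                           dialect = c("paired-columns", "beta-only"),
                           betaSuffix = ".beta", pvalSuffix = ".pval") {
    dialect <- match.arg(dialect)
    stopifnot(is(bs, "BetaSet"))
    beta <- betaValues(bs)
    if (dialect == "paired-columns") {
        if (!hasDetectionP(bs))
            stop("paired-columns dialect requires detection p-values")
        detP <- detectionP(bs)
        out <- vector("list", 1L + 2L * ncol(beta))
        nms <- character(length(out))
        out[[1L]] <- rownames(beta); nms[1L] <- "probe_id"
        for (j in seq_len(ncol(beta))) {
            out[[2L * j]] <- .renderNumeric(beta[, j])
            out[[2L * j + 1L]] <- .renderNumeric(detP[, j])
            nms[2L * j] <- paste0(colnames(beta)[j], betaSuffix)
            nms[2L * j + 1L] <- paste0(colnames(beta)[j], pvalSuffix)
        }
    } else {
        out <- c(list(rownames(beta)),
                 lapply(seq_len(ncol(beta)), function(j) .renderNumeric(beta[, j])))
        nms <- c("probe_id", colnames(beta))
    }
    names(out) <- nms
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
    invisible(path)
}

#' Read a probe annotation table
#'
#' Expects a tab-separated file with mandatory headers \code{probe_id},
#' \code{chromosome}, \code{cross_reactive} and \code{max_maf_within_50bp}
#' (the largest minor allele frequency of any SNP within 50 bp of the target
#' CpG, 0 if none).
#'
#' @param path path to a tab-separated annotation file.
#' @return data.frame with one validated record per probe.
#' @export
readProbeAnnotation <- function(path) {
    ann <- data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE, encoding = "UTF-8")
    need <- c("probe_id", "chromosome", "cross_reactive", "max_maf_within_50bp")
    miss <- setdiff(need, names(ann))
    if (length(miss))
        stop("annotation is missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    ann <- ann[need]
    ann$probe_id <- as.character(ann$probe_id)
    if (anyDuplicated(ann$probe_id))
        stop("duplicate probe_id in annotation: ",
             ann$probe_id[duplicated(ann$probe_id)][1L])
    ann$chromosome <- as.character(ann$chromosome)
    ann$cross_reactive <- .parseLogical(ann$cross_reactive)
    maf <- ann$max_maf_within_50bp
    if (!is.numeric(maf) || anyNA(maf) || any(maf < 0 | maf > 0.5))
        stop("max_maf_within_50bp must be numeric in [0, 0.5]")
    ann
}

.parseLogical <- function(x) {
    if (is.logical(x)) return(x)
    out <- as.logical(toupper(as.character(x)))
    num <- suppressWarnings(as.numeric(x))
    out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)] != 0
    if (anyNA(out)) stop("cross_reactive must be logical (TRUE/FALSE or 0/1)")
    out
}

#' Read a sample sheet
#'
#' Expects a tab-separated file with mandatory headers \code{sample_id} and
#' \code{label}, and optional \code{age_years} and \code{sex}. Labels must
#' come from the closed vocabulary of \code{\link{mbSubgroups}} (seven
#' subgroups plus \code{"Non-classifiable"}); anything else is a validation
#' error naming the offending value.
#'
#' @param path path to a tab-separated sample sheet.
#' @return data.frame with \code{label} as a factor over the vocabulary.
#' @export
readSampleSheet <- function(path) {
    sheet <- data.table::fread(path, sep = "\t", header = TRUE,
                               data.table = FALSE, encoding = "UTF-8",
                               colClasses = list(character = "sample_id"))
    need <- c("sample_id", "label")
    miss <- setdiff(need, names(sheet))
    if (length(miss))
        stop("sample sheet is missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    sheet$sample_id <- as.character(sheet$sample_id)
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sheet: ",
             sheet$sample_id[duplicated(sheet$sample_id)][1L])
    vocab <- mbSubgroups(includeNonClassifiable = TRUE)
    bad <- setdiff(unique(as.character(sheet$label)), vocab)
    if (length(bad))
        stop("label(s) outside the subgroup vocabulary: ",
             paste(bad, collapse = ", "))
    sheet$label <- factor(sheet$label, levels = vocab)
    if ("age_years" %in% names(sheet)) {
        if (any(sheet$age_years < 0, na.rm = TRUE))
            stop("age_years must be non-negative")
    }
    if ("sex" %in% names(sheet)) {
        badSex <- setdiff(unique(as.character(sheet$sex)), c("M", "F", "unknown"))
        if (length(badSex))
            stop("sex must be one of M, F, unknown; got: ",
                 paste(badSex, collapse = ", "))
    }
    sheet
}

#' Write a probe annotation table or sample sheet
#'
#' Plumbing counterparts of \code{\link{readProbeAnnotation}} and
#' \code{\link{readSampleSheet}}, used by the synthetic-cohort generator and
#' the pipeline stages.
#'
#' @param x a data.frame of the corresponding read function's shape.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbeAnnotation <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "")
    invisible(path)
}

#' @rdname writeProbeAnnotation
#' @export
writeSampleSheet <- function(x, path) {
    x$label <- as.character(x$label)
    data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "")
    invisible(path)
}
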