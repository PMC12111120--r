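## Imbalance-aware multiclass evaluation: confusion-matrix metrics, two
## balanced-accuracy conventions, one-vs-rest ROC/AUC, misclassification
## reporting.

## per-class counts from a square confusion matrix (true rows x pred cols)
.confusionStats <- function(C) {
    C <- as.matrix(C)
    total <- sum(C)
    tp <- diag(C)
    fn <- rowSums(C) - tp
    fp <- colSums(C) - tp
    tn <- total - tp - fn - fp
    present <- rowSums(C) > 0
    precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    specificity <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
    f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
                 2 * precision * recall / (precision + recall), NA_real_)
    list(tp = tp, fn = fn, fp = fp, tn = tn, present = present,
         precision = precision, recall = recall,
         specificity = specificity, f1 = f1, total = total)
}

#' Metrics from a confusion matrix
#'
#' Computes the full per-class and macro metric suite from a square
#' confusion matrix with true classes as rows and predicted classes as
#' columns: precision, recall (sensitivity), specificity, F1; unweighted
#' macro averages; standard accuracy (trace over total); and both
#' balanced-accuracy conventions (macro recall, and the mean over classes of
#' \eqn{(recall + specificity)/2}). Classes absent from the true labels
#' (empty rows) get \code{NA} per-class metrics and are excluded from the
#' macro means with a warning.
#'
#' @param confusion square numeric matrix, true rows x predicted columns.
#' @return list with \code{perClass} (data.frame) and the scalar summary
#'   metrics.
#' @export
confusionMetrics <- function(confusion) {
    C <- as.matrix(confusion)
    if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
    st <- .confusionStats(C)
    if (!all(st$present))
        warning("class(es) absent from the true labels, excluded from macro means: ",
                paste(rownames(C)[!st$present], collapse = ", "))
    per <- data.frame(class = rownames(C),
                      n = rowSums(C),
                      precision = st$precision, recall = st$recall,
                      specificity = st$specificity, f1 = st$f1,
                      row.names = NULL)
    per[!st$present, c("precision", "recall", "specificity", "f1")] <- NA_real_
    ok <- st$present
    list(perClass = per,
         accuracy = sum(st$tp) / st$total,
         macroPrecision = mean(st$precision[ok], na.rm = TRUE),
         macroRecall = mean(st$recall[ok], na.rm = TRUE),
         macroF1 = mean(st$f1[ok], na.rm = TRUE),
         balancedAccuracyMacroRecall = mean(st$recall[ok], na.rm = TRUE),
         balancedAccuracySensSpec =
             mean(((st$recall + st$specificity) / 2)[ok], na.rm = TRUE))
}

## Mann-Whitney AUC with average ranks (ties counted 1/2)
.aucRank <- function(scores, positive) {
    nPos <- sum(positive)
    nNeg <- sum(!positive)
    if (nPos == 0L || nNeg == 0L)
        stop("AUC requires both positive and negative examples")
    r <- rank(scores)
    (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores of \code{positiveClass} (a
#' sample is called positive when its score is at or above the threshold)
#' and returns the false/true positive rates at every threshold together
#' with the AUC, computed as the rank-based Mann-Whitney statistic with ties
#' counted one half (equal, up to ties handling, to trapezoidal integration
#' of the curve).
#'
#' @param trueLabels factor/character of true classes.
#' @param probabilities samples x classes score matrix with named columns
#'   (class probabilities or any monotone score).
#' @param positiveClass the class treated as positive; both positive and
#'   negative examples must be present.
#' @return list with \code{points} (data.frame: threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocCurveOvr <- function(trueLabels, probabilities, positiveClass) {
    if (!positiveClass %in% colnames(probabilities))
        stop("positiveClass not found among probability columns")
    scores <- probabilities[, positiveClass]
    positive <- as.character(trueLabels) == positiveClass
    if (!any(positive) || all(positive))
        stop("single-class input: both positive and negative examples required")
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    pts <- vapply(thr, function(t) {
        pred <- scores >= t
        c(fpr = sum(pred & !positive) / sum(!positive),
          tpr = sum(pred & positive) / sum(positive))
    }, numeric(2L))
    list(points = data.frame(threshold = thr,
                             fpr = pts["fpr", ], tpr = pts["tpr", ]),
         auc = .aucRank(scores, positive))
}

#' Evaluate a fitted classifier
#'
#' Predicts class probabilities on \code{features}, takes the
#' highest-probability class as the prediction (ties to the first class in
#' vocabulary order), and fills the full \linkS4class{EvaluationReport}:
#' confusion matrix, per-class and macro metrics, both balanced-accuracy
#' conventions, per-class one-vs-rest AUC and macro AUC, and the
#' probability table. Classes without positive (or without negative)
#' examples get \code{NA} AUC and are excluded from the macro AUC.
#'
#' @param model an \code{"mbModel"} from \code{\link{tuneAndTrain}}.
#' @param features samples x metagenes matrix on the training scale.
#' @param labels true labels (factor over the model's class vocabulary).
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(model, features, labels) {
    probs <- predictProbabilities(model, features)
    classLevels <- model$classLevels
    labels <- factor(as.character(labels), levels = classLevels)
    if (anyNA(labels))
        stop("labels contain classes outside the model vocabulary")
    predicted <- factor(classLevels[max.col(probs, ties.method = "first")],
                        levels = classLevels)
    C <- unclass(table(labels, predicted))
    dimnames(C) <- list(classLevels, classLevels)
    cm <- confusionMetrics(C)
    auc <- vapply(classLevels, function(cl) {
        pos <- labels == cl
        if (!any(pos) || all(pos)) return(NA_real_)
        .aucRank(probs[, cl], pos)
    }, numeric(1L))
    per <- cm$perClass
    per$auc <- auc
    new("EvaluationReport", confusion = C, perClass = per,
        accuracy = cm$accuracy,
        balancedAccuracyMacroRecall = cm$balancedAccuracyMacroRecall,
        balancedAccuracySensSpec = cm$balancedAccuracySensSpec,
        macroPrecision = cm$macroPrecision, macroRecall = cm$macroRecall,
        macroF1 = cm$macroF1, macroAUC = mean(auc, na.rm = TRUE),
        probabilities = probs, trueLabels = labels,
        predictedLabels = predicted)
}

#' Misclassification overview
#'
#' One row per misclassified sample: true label, predicted label, the
#' probability the model assigned to the true class, and the probability
#' assigned to the predicted (argmax) class. The predicted-label probability
#' is by construction at least the true-label probability. Probability rows
#' must sum to 1 (tolerance 1e-6) and the argmax must agree with the
#' supplied predictions.
#'
#' @param trueLabels,predictedLabels factors/characters per sample.
#' @param probabilities samples x classes matrix with named columns.
#' @return data.frame with columns \code{sample}, \code{trueLabel},
#'   \code{predictedLabel}, \code{trueLabelProbability},
#'   \code{predictedLabelProbability}; empty when nothing is misclassified.
#' @export
misclassificationReport <- function(trueLabels, predictedLabels,
                                    probabilities) {
    trueLabels <- as.character(trueLabels)
    predictedLabels <- as.character(predictedLabels)
    rs <- rowSums(probabilities)
    if (any(abs(rs - 1) > 1e-6))
        stop("probability rows must sum to 1 (worst deviation ",
             format(max(abs(rs - 1))), ")")
    argmax <- colnames(probabilities)[max.col(probabilities,
                                              ties.method = "first")]
    if (!all(argmax == predictedLabels))
        stop("internal consistency error: predicted labels disagree with the probability argmax")
    bad <- which(trueLabels != predictedLabels)
    samples <- if (!is.null(rownames(probabilities)))
        rownames(probabilities) else as.character(seq_len(nrow(probabilities)))
    data.frame(
        sample = samples[bad],
        trueLabel = trueLabels[bad],
        predictedLabel = predictedLabels[bad],
        trueLabelProbability =
            probabilities[cbind(bad, match(trueLabels[bad],
                                           colnames(probabilities)))],
        predictedLabelProbability =
            probabilities[cbind(bad, match(predictedLabels[bad],
                                           colnames(probabilities)))],
        row.names = NULL)
}

#' Serialize an EvaluationReport
#'
#' Writes the report as JSON (summary + per-class metrics) plus TSV
#' artifacts: the confusion matrix, the per-class metric table, the
#' misclassification table, and the per-sample probability table.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
writeEvaluationReport <- function(report, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    summary <- c(as.list(macroMetrics(report)),
                 list(n_samples = sum(confusionMatrix(report))))
    jsonlite::write_json(
        list(summary = summary, per_class = perClassMetrics(report)),
        file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
    .writeNamedMatrix(confusionMatrix(report),
                      file.path(dir, "confusion.tsv"), "true_label")
    data.table::fwrite(perClassMetrics(report),
                       file.path(dir, "per_class_metrics.tsv"), sep = "\t")
    mis <- misclassificationReport(report@trueLabels,
                                   report@predictedLabels,
                                   classProbabilities(report))
    data.table::fwrite(mis, file.path(dir, "misclassifications.tsv"),
                       sep = "\t")
    probs <- classProbabilities(report)
    data.table::fwrite(
        data.frame(sample = rownames(probs) %||%
                       as.character(seq_len(nrow(probs))),
                   trueLabel = as.character(report@trueLabels),
                   predictedLabel = as.character(report@predictedLabels),
                   probs, check.names = FALSE),
        file.path(dir, "probabilities.tsv"), sep = "\t")
    invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
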