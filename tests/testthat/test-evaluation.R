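## build a probability matrix that deterministically encodes predictions
probsFor <- function(pred, classes, pTop = 0.8) {
    P <- matrix((1 - pTop) / (length(classes) - 1), length(pred),
                length(classes), dimnames = list(NULL, classes))
    P[cbind(seq_along(pred), match(pred, classes))] <- pTop
    P
}

test_that("confusion-matrix metrics follow the standard formulas", {
    classes <- c("A", "B", "C")
    C <- rbind(c(8, 1, 1), c(0, 10, 0), c(2, 0, 8))
    dimnames(C) <- list(classes, classes)
    cm <- confusionMetrics(C)
    expect_equal(cm$accuracy, 26 / 30)
    expect_equal(cm$perClass$recall, c(0.8, 1.0, 0.8))
    expect_equal(cm$perClass$precision, c(8 / 10, 10 / 11, 8 / 9))
    expect_equal(cm$perClass$specificity, c(18 / 20, 19 / 20, 19 / 20))
    expect_equal(cm$balancedAccuracyMacroRecall, mean(c(0.8, 1, 0.8)))
    expect_equal(cm$balancedAccuracySensSpec,
                 mean((c(0.8, 1, 0.8) + c(0.9, 0.95, 0.95)) / 2))
    ## the two balanced-accuracy conventions relate through macro specificity
    expect_equal(cm$balancedAccuracySensSpec,
                 (cm$macroRecall + mean(cm$perClass$specificity)) / 2)
})

test_that("binary macro recall equals (sensitivity + specificity) / 2", {
    set.seed(8)
    for (i in 1:20) {
        C <- matrix(sample(0:20, 4, replace = TRUE), 2, 2,
                    dimnames = list(c("pos", "neg"), c("pos", "neg")))
        if (any(rowSums(C) == 0)) next
        cm <- confusionMetrics(C)
        sens <- C[1, 1] / sum(C[1, ])
        spec <- C[2, 2] / sum(C[2, ])
        expect_equal(cm$balancedAccuracyMacroRecall, (sens + spec) / 2)
        expect_equal(cm$balancedAccuracySensSpec, (sens + spec) / 2)
    }
})

test_that("classes absent from the true labels are excluded with a warning", {
    C <- rbind(c(5, 0, 1), c(0, 0, 0), c(1, 0, 7))
    dimnames(C) <- list(c("A", "B", "C"), c("A", "B", "C"))
    expect_warning(cm <- confusionMetrics(C), "absent")
    expect_true(is.na(cm$perClass$recall[2]))
    expect_equal(cm$macroRecall, mean(c(5 / 6, 7 / 8)))
})

test_that("a perfect predictor scores 1 on every metric", {
    d <- separableClusters(nPerClass = 4, sd = 0.01, seed = 2)
    model <- tuneAndTrain(d$features, d$labels, family = "knn",
                          nCandidates = 2, cvFolds = 4, seed = 5)
    rep <- evaluateModel(model, d$features, d$labels)
    m <- macroMetrics(rep)
    expect_equal(unname(m), rep(1, length(m)), tolerance = 1e-12)
    expect_equal(unname(diag(confusionMatrix(rep))),
                 unname(table(d$labels)), ignore_attr = TRUE)
    expect_equal(nrow(misclassificationReport(
        rep@trueLabels, rep@predictedLabels, classProbabilities(rep))), 0)
})

test_that("a constant predictor on a balanced binary task scores chance", {
    C <- rbind(c(10, 0), c(10, 0))
    dimnames(C) <- list(c("A", "B"), c("A", "B"))
    expect_equal(confusionMetrics(C)$balancedAccuracyMacroRecall, 0.5)
})

test_that("label-permuted perfect predictions permute the confusion matrix", {
    classes <- c("A", "B", "C")
    true <- factor(rep(classes, c(4, 5, 6)), levels = classes)
    perm <- c(B = "C", C = "A", A = "B")[as.character(true)]
    C <- table(true, factor(perm, levels = classes))
    expect_equal(unname(C["A", "B"]), 4)
    expect_equal(unname(C["B", "C"]), 5)
    expect_equal(unname(C["C", "A"]), 6)
    expect_equal(sum(diag(C)), 0)
})

test_that("one-vs-rest AUC equals exhaustive pair counting", {
    ## the worked case: one positive below two negatives' worth of order
    scores <- c(0.9, 0.8, 0.4, 0.35, 0.1)
    pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
    P <- cbind(X = scores, Y = 1 - scores)
    roc <- rocCurveOvr(ifelse(pos, "X", "Y"), P, "X")
    expect_equal(roc$auc, 5 / 6)
    ## perfectly ordered scores and all-tied scores
    expect_equal(rocCurveOvr(c("X", "X", "Y", "Y"),
                             cbind(X = c(0.9, 0.8, 0.2, 0.1)), "X")$auc, 1.0)
    expect_equal(rocCurveOvr(c("X", "X", "Y", "Y"),
                             cbind(X = rep(0.5, 4)), "X")$auc, 0.5)
    ## random instances against the oracle; invariance under monotone maps;
    ## agreement with trapezoidal integration of the swept curve
    set.seed(19)
    for (i in 1:30) {
        n <- sample(6:20, 1)
        s <- round(runif(n), 2)           # rounded scores force ties
        p <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(p) || all(p)) next
        r <- rocCurveOvr(ifelse(p, "X", "Y"), cbind(X = s), "X")
        expect_equal(r$auc, bruteAUC(s, p))
        r2 <- rocCurveOvr(ifelse(p, "X", "Y"), cbind(X = exp(3 * s)), "X")
        expect_equal(r2$auc, r$auc)
        pts <- r$points[order(r$points$fpr, r$points$tpr), ]
        trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
        expect_equal(trap, r$auc)
    }
    expect_error(rocCurveOvr(c("X", "X"), cbind(X = c(0.2, 0.4)), "X"),
                 "single-class")
})

test_that("misclassification rows carry true- and predicted-class probabilities", {
    classes <- c("A", "B", "C")
    P <- rbind(c(0.30, 0.33, 0.37),
               c(0.10, 0.80, 0.10),
               c(0.85, 0.10, 0.05))
    colnames(P) <- classes
    true <- c("A", "B", "A")
    pred <- c("C", "B", "A")
    tab <- misclassificationReport(true, pred, P)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$trueLabel, "A")
    expect_equal(tab$predictedLabel, "C")
    expect_equal(tab$trueLabelProbability, 0.30)
    expect_equal(tab$predictedLabelProbability, 0.37)
    expect_true(all(tab$predictedLabelProbability >=
                    tab$trueLabelProbability))
    ## rows not summing to 1 are rejected
    bad <- P; bad[1, 1] <- 0.2
    expect_error(misclassificationReport(true, pred, bad), "sum to 1")
    ## argmax disagreement is an internal consistency error
    expect_error(misclassificationReport(true, c("B", "B", "A"), P),
                 "consistency")
})

test_that("the uncertain-call convention reports (true 0.30, predicted 0.33)", {
    classes <- mbSubgroups()
    P <- matrix((1 - 0.63) / 5, 1, 7, dimnames = list("s1", classes))
    P[1, "Group4-LowRisk"] <- 0.30
    P[1, "Group4-HighRisk"] <- 0.33
    tab <- misclassificationReport("Group4-LowRisk", "Group4-HighRisk", P)
    expect_equal(tab$trueLabelProbability, 0.30)
    expect_equal(tab$predictedLabelProbability, 0.33)
})
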