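## Seven-subgroup classification on metagene features: stratified splitting,
## 0-1 scaling, four model families with randomized-grid 10-fold CV tuning.

#' Stratified train/test split
#'
#' Splits samples into training and test sets class by class: each class
#' contributes \code{ceiling(trainFraction * n_c)} samples, drawn uniformly
#' at random under the seed, to the training set; the remainder go to the
#' test set. Ceiling rounding makes the per-class training counts of the
#' canonical 409-sample cohort (class sizes 33, 38, 65, 65, 50, 85, 73)
#' exactly 27, 31, 52, 52, 40, 68, 59 with an 80/20 split.
#'
#' @param labels factor (or character) of class labels; every class must
#'   have at least 2 members.
#' @param trainFraction fraction of each class assigned to training
#'   (default 0.8). With \code{trainFraction = 1} the test set is empty,
#'   which is flagged with a warning.
#' @param seed integer seed.
#' @return list of class \code{"TrainTestSplit"}: \code{trainIdx},
#'   \code{testIdx}, \code{seed}, \code{trainCounts} (named per-class
#'   training counts).
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.8, seed = 1L) {
    labels <- droplevels(as.factor(labels))
    sizes <- table(labels)
    if (any(sizes < 2L))
        stop("every class needs at least 2 members; too small: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    if (trainFraction <= 0 || trainFraction > 1)
        stop("trainFraction must lie in (0, 1]")
    set.seed(seed)
    trainIdx <- integer(0)
    counts <- integer(0)
    for (cl in levels(labels)) {
        idx <- which(labels == cl)
        nTrain <- as.integer(ceiling(trainFraction * length(idx)))
        take <- sort(sample(idx, nTrain))
        trainIdx <- c(trainIdx, take)
        counts[cl] <- nTrain
    }
    trainIdx <- sort(trainIdx)
    testIdx <- setdiff(seq_along(labels), trainIdx)
    if (length(testIdx) == 0L)
        warning("test set is empty (trainFraction = 1)")
    structure(list(trainIdx = trainIdx, testIdx = testIdx,
                   seed = as.integer(seed), trainCounts = counts),
              class = "TrainTestSplit")
}

#' Min-max scaling fitted on training features
#'
#' Learns, per metagene, the training minimum and range, and maps features
#' to \eqn{(x - min) / range}. The scaler is applied unchanged to other
#' feature sets and the result clipped to \eqn{[0, 1]}; a metagene constant
#' in training maps to 0 everywhere.
#'
#' @param train samples x metagenes training feature matrix (complete).
#' @return list of class \code{"MinMaxScaler"} with \code{min} and
#'   \code{range} vectors.
#' @export
minMaxScaler <- function(train) {
    if (anyNA(train)) stop("training features must be complete")
    mins <- apply(train, 2L, min)
    rng <- apply(train, 2L, max) - mins
    structure(list(min = mins, range = rng), class = "MinMaxScaler")
}

#' @rdname minMaxScaler
#' @param scaler a \code{"MinMaxScaler"}.
#' @param x feature matrix to scale.
#' @param clip clip the result to \eqn{[0,1]} (the convention for any set
#'   other than the one the scaler was fitted on).
#' @return Scaled matrix.
#' @export
scaleFeatures <- function(scaler, x, clip = TRUE) {
    stopifnot(inherits(scaler, "MinMaxScaler"))
    out <- sweep(x, 2L, scaler$min, "-")
    rng <- scaler$range
    rng[rng == 0] <- Inf   # constant training metagene -> 0 everywhere
    out <- sweep(out, 2L, rng, "/")
    if (clip) {
        out[out < 0] <- 0
        out[out > 1] <- 1
    }
    out
}

#' Default randomized-search grids
#'
#' Per-family hyperparameter ranges: SVM (radial) cost in \eqn{[0.01, 50]}
#' and kernel width sigma in \eqn{[0.001, 1]}; random forest mtry in
#' \eqn{[2, 6]}; gradient boosting rounds in \{50, 100, 150, 200\}, eta in
#' \eqn{[0.01, 0.3]}, depth in \eqn{[3, 10]}, gamma in \eqn{[0, 5]},
#' column subsample in \eqn{[0.5, 1]}, minimum child weight in
#' \eqn{[1, 10]}, row subsample in \eqn{[0.5, 1]}; KNN with odd k in
#' \eqn{[3, 15]}.
#'
#' @param family one of \code{"svm_rbf"}, \code{"random_forest"},
#'   \code{"gradient_boosting"}, \code{"knn"}.
#' @return Named list of parameter specifications (each a uniform range,
#'   integer range, or discrete choice set).
#' @export
defaultTuningGrid <- function(family = c("svm_rbf", "random_forest",
                                         "gradient_boosting", "knn")) {
    family <- match.arg(family)
    switch(family,
        svm_rbf = list(
            C = list(type = "uniform", min = 0.01, max = 50),
            sigma = list(type = "uniform", min = 0.001, max = 1)),
        random_forest = list(
            mtry = list(type = "integer", min = 2L, max = 6L)),
        gradient_boosting = list(
            nrounds = list(type = "choice", values = c(50L, 100L, 150L, 200L)),
            eta = list(type = "uniform", min = 0.01, max = 0.3),
            max_depth = list(type = "integer", min = 3L, max = 10L),
            gamma = list(type = "uniform", min = 0, max = 5),
            colsample_bytree = list(type = "uniform", min = 0.5, max = 1),
            min_child_weight = list(type = "uniform", min = 1, max = 10),
            subsample = list(type = "uniform", min = 0.5, max = 1)),
        knn = list(
            k = list(type = "choice", values = seq(3L, 15L, by = 2L))))
}

.sampleCandidate <- function(grid) {
    lapply(grid, function(spec) {
        switch(spec$type,
               uniform = runif(1L, spec$min, spec$max),
               integer = sample(seq(spec$min, spec$max), 1L),
               choice = spec$values[sample.int(length(spec$values), 1L)],
               stop("unknown grid spec type: ", spec$type))
    })
}

## one fitted model; features: samples x metagenes, labels: factor
.fitFamily <- function(family, features, labels, params, seed) {
    set.seed(seed)
    switch(family,
        svm_rbf = e1071::svm(x = features, y = labels, kernel = "radial",
                             cost = params$C, gamma = params$sigma,
                             probability = TRUE, scale = FALSE),
        random_forest = randomForest::randomForest(
            x = features, y = labels,
            mtry = min(params$mtry, ncol(features)), ntree = 500L),
        gradient_boosting = {
            d <- xgboost::xgb.DMatrix(features,
                                      label = as.integer(labels) - 1L)
            xgboost::xgb.train(
                params = list(objective = "multi:softprob",
                              num_class = nlevels(labels),
                              eta = params$eta, max_depth = params$max_depth,
                              gamma = params$gamma,
                              colsample_bytree = params$colsample_bytree,
                              min_child_weight = params$min_child_weight,
                              subsample = params$subsample,
                              nthread = 1L, seed = seed),
                data = d, nrounds = params$nrounds, verbose = 0L)
        },
        knn = caret::knn3(x = features, y = labels, k = params$k),
        stop("unknown model family: ", family))
}

.familyProbabilities <- function(family, fit, features, classLevels) {
    p <- switch(family,
        svm_rbf = {
            pr <- predict(fit, features, probability = TRUE)
            attr(pr, "probabilities")
        },
        random_forest = predict(fit, features, type = "prob"),
        gradient_boosting = {
            m <- predict(fit, xgboost::xgb.DMatrix(features))
            colnames(m) <- classLevels
            m
        },
        knn = predict(fit, features, type = "prob"))
    p <- p[, classLevels, drop = FALSE]
    rs <- rowSums(p)
    bad <- rs <= 0 | !is.finite(rs)
    if (any(bad)) p[bad, ] <- 1 / length(classLevels)
    p / rowSums(p)
}

## balanced accuracy, (recall + specificity) / 2 convention, from labels
.cvBalancedAccuracy <- function(true, predicted, classLevels) {
    C <- table(factor(true, levels = classLevels),
               factor(predicted, levels = classLevels))
    st <- .confusionStats(C)
    mean(((st$recall + st$specificity) / 2)[st$present])
}

#' Tune and train a subgroup classifier
#'
#' Samples \code{nCandidates} hyperparameter configurations from the
#' family's grid (seeded), scores each by \code{cvFolds}-fold stratified
#' cross-validation on the training set, selects the configuration with the
#' highest mean CV balanced accuracy (the \eqn{(recall + specificity)/2}
#' convention), and refits it on the full training set. The fitted model
#' exposes class probabilities normalized over the class vocabulary.
#'
#' @param features samples x metagenes numeric matrix (scaled).
#' @param labels factor of class labels aligned to rows of \code{features}.
#' @param family model family, see \code{\link{defaultTuningGrid}}.
#' @param grid parameter grid (defaults to the family grid).
#' @param nCandidates number of sampled configurations (default 20).
#' @param cvFolds number of cross-validation folds (default 10); the
#'   training set must hold at least this many samples.
#' @param seed integer seed governing candidate sampling, fold assignment
#'   and every model fit.
#' @return list of class \code{"mbModel"}: \code{family}, \code{fit},
#'   \code{params}, \code{cvScore}, \code{cvTable}, \code{classLevels},
#'   \code{seed}.
#' @export
tuneAndTrain <- function(features, labels,
                         family = c("svm_rbf", "random_forest",
                                    "gradient_boosting", "knn"),
                         grid = NULL, nCandidates = 20L, cvFolds = 10L,
                         seed = 1L) {
    family <- match.arg(family)
    if (is.null(grid)) grid <- defaultTuningGrid(family)
    labels <- droplevels(as.factor(labels))
    features <- as.matrix(features)
    if (nrow(features) != length(labels))
        stop("features and labels disagree on sample count")
    if (nrow(features) < cvFolds)
        stop(sprintf("fewer training samples (%d) than folds (%d)",
                     nrow(features), cvFolds))
    classLevels <- levels(labels)
    set.seed(seed)
    candidates <- replicate(nCandidates, .sampleCandidate(grid),
                            simplify = FALSE)
    ## stratified fold assignment
    fold <- integer(length(labels))
    for (cl in classLevels) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(cvFolds), length(idx)))
    }
    scores <- vapply(seq_along(candidates), function(ci) {
        params <- candidates[[ci]]
        fs <- vapply(seq_len(cvFolds), function(f) {
            tr <- fold != f
            if (all(tr) || !any(tr)) return(NA_real_)
            fit <- .fitFamily(family, features[tr, , drop = FALSE],
                              labels[tr], params,
                              seed = seed + 1000L * ci + f)
            p <- .familyProbabilities(family, fit,
                                      features[!tr, , drop = FALSE],
                                      classLevels)
            pred <- classLevels[max.col(p, ties.method = "first")]
            .cvBalancedAccuracy(labels[!tr], pred, classLevels)
        }, numeric(1L))
        mean(fs, na.rm = TRUE)
    }, numeric(1L))
    bestIdx <- which.max(scores)
    bestParams <- candidates[[bestIdx]]
    fit <- .fitFamily(family, features, labels, bestParams,
                      seed = seed + 999L)
    cvTable <- data.frame(candidate = seq_along(candidates),
                          do.call(rbind, lapply(candidates, as.data.frame)),
                          cvBalancedAccuracy = scores)
    structure(list(family = family, fit = fit, params = bestParams,
                   cvScore = scores[bestIdx], cvTable = cvTable,
                   classLevels = classLevels, seed = as.integer(seed)),
              class = "mbModel")
}

#' Class probabilities of a fitted subgroup classifier
#'
#' Returns the samples x classes probability matrix of an
#' \code{\link{tuneAndTrain}} model on new features, columns in the model's
#' class order, every row normalized to sum to 1.
#'
#' @param model an \code{"mbModel"}.
#' @param features samples x metagenes matrix on the same scale as training.
#' @return Probability matrix.
#' @export
predictProbabilities <- function(model, features) {
    stopifnot(inherits(model, "mbModel"))
    features <- as.matrix(features)
    .familyProbabilities(model$family, model$fit, features, model$classLevels)
}

#' @export
print.mbModel <- function(x, ...) {
    cat(sprintf("mbModel: %s (%d classes), CV balanced accuracy %.4f\n",
                x$family, length(x$classLevels), x$cvScore))
    cat("  params:", paste(names(x$params),
                           vapply(x$params, format, character(1L)),
                           sep = "=", collapse = ", "), "\n")
    invisible(x)
}
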