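## Pipeline orchestration: a single YAML-backed run configuration,
## deterministic seeding, per-stage output directories with fixed file
## names, and JSON manifests carrying input/output hashes.

#' Default run configuration
#'
#' A fully populated, self-describing configuration: every tunable default
#' of the framework appears explicitly, so a stored config fully documents a
#' run. Stage commands read their inputs from the previous stage's fixed
#' file names under \code{output_dir}.
#'
#' @param outputDir run directory (one subdirectory per stage).
#' @param seed master seed; every source of randomness derives from it.
#' @return Nested list of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function(outputDir = "mb_run", seed = 1L) {
    structure(list(
        version = 1L,
        seed = as.integer(seed),
        output_dir = outputDir,
        simulate = list(
            n_probes = 2000L, n_samples = 350L,
            n_validation_samples = 276L, k = 6L,
            separation = 0.8, noise_sd = 0.02, missing_rate = 0.02,
            n_non_classifiable = 0L, warp = TRUE, warp_strength = 3,
            annotation_fractions = list(xy = 0.03, crossReactive = 0.05,
                                        snp = 0.06)),
        qc = list(
            detection_p_threshold = 0.05, max_missing_fraction = 0.5,
            maf_threshold = 0.05, n_top_variance = 1000L, knn_k = 10L),
        factorization = list(
            rank = 6L, n_runs = 30L, objective = "kl",
            max_iter = 2000L, tol = 1e-6),
        projection = list(
            fill_policy = "train-mean", coverage_floor = 0.95),
        classifier = list(
            family = "svm_rbf", n_candidates = 20L, cv_folds = 10L,
            train_fraction = 0.8)),
        class = "RunConfig")
}

#' Read / write a run configuration
#'
#' YAML round-trip of a \code{"RunConfig"}: \code{writeRunConfig} followed
#' by \code{readRunConfig} reproduces the configuration unchanged.
#'
#' @param config a \code{"RunConfig"}.
#' @param path YAML file path.
#' @return \code{readRunConfig}: the configuration; \code{writeRunConfig}:
#'   \code{path}, invisibly.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$version)) stop("config lacks a version field")
    structure(cfg, class = "RunConfig")
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

.stageDir <- function(config, stage) {
    d <- file.path(config$output_dir, stage)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
}

.hashFiles <- function(paths) {
    h <- as.list(tools::md5sum(paths))
    names(h) <- basename(paths)
    h
}

.writeManifest <- function(config, stage, inputs, outputs, stageConfig) {
    manifest <- list(stage = stage,
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("mbMetagene")),
                     config = stageConfig,
                     inputs = .hashFiles(inputs),
                     outputs = .hashFiles(outputs))
    jsonlite::write_json(manifest,
                         file.path(.stageDir(config, stage), "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
}

.requireArtifact <- function(path, producer) {
    if (!file.exists(path))
        stop(sprintf("missing artifact '%s': run %s first", path, producer),
             call. = FALSE)
    path
}

#' Pipeline stage commands
#'
#' Each command reads its inputs from the fixed file layout under
#' \code{config$output_dir}, writes its typed outputs plus a
#' \code{manifest.json} (stage config, seed, input/output MD5 hashes), and
#' returns the manifest invisibly. \code{cmdFull} chains
#' qc/extract/train on the primary cohort and qc/project/evaluate on the
#' validation cohort. Missing upstream artifacts raise an error naming the
#' stage to run first. No stage mutates its inputs; all randomness flows
#' from \code{config$seed}.
#'
#' @param config a \code{"RunConfig"}.
#' @param cohort \code{"primary"} or \code{"validation"}.
#' @name pipeline
#' @return The stage manifest (list), invisibly; \code{cmdFull} returns the
#'   final \linkS4class{EvaluationReport}.
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(config) {
    d <- .stageDir(config, "simulate")
    sc <- config$simulate
    prim <- generateCohort(
        nProbes = sc$n_probes, nSamples = sc$n_samples, k = sc$k,
        separation = sc$separation, noiseSD = sc$noise_sd,
        missingRate = sc$missing_rate,
        annotationFractions = unlist(sc$annotation_fractions),
        warp = sc$warp, warpStrength = sc$warp_strength,
        nNonClassifiable = sc$n_non_classifiable, seed = config$seed)
    val <- generateCohort(
        nProbes = sc$n_probes, nSamples = sc$n_validation_samples, k = sc$k,
        separation = sc$separation, noiseSD = sc$noise_sd,
        missingRate = sc$missing_rate, warp = sc$warp,
        warpStrength = sc$warp_strength, seed = config$seed + 1L,
        WTrue = prim$truth@WTrue, annotation = prim$truth@annotation)
    writeBetaTable(prim$betaSet, file.path(d, "primary_beta.tsv"))
    writeSampleSheet(prim$sheet, file.path(d, "primary_sheet.tsv"))
    writeBetaTable(val$betaSet, file.path(d, "validation_beta.tsv"))
    writeSampleSheet(val$sheet, file.path(d, "validation_sheet.tsv"))
    writeProbeAnnotation(prim$truth@annotation, file.path(d, "annotation.tsv"))
    .writeNamedMatrix(prim$truth@WTrue, file.path(d, "truth_W.tsv"), "probe_id")
    .writeNamedMatrix(prim$truth@HTrue, file.path(d, "truth_H.tsv"), "metagene")
    outs <- file.path(d, c("primary_beta.tsv", "primary_sheet.tsv",
                           "validation_beta.tsv", "validation_sheet.tsv",
                           "annotation.tsv", "truth_W.tsv", "truth_H.tsv"))
    invisible(.writeManifest(config, "simulate", character(0), outs, sc))
}

.qcChain <- function(bs, sheet, annotation, qc, selectVariance) {
    bs <- maskLowConfidence(bs, qc$detection_p_threshold)
    cfg <- qcConfig(detectionPThreshold = qc$detection_p_threshold,
                    maxMissingFraction = qc$max_missing_fraction,
                    mafThreshold = qc$maf_threshold,
                    nTopVariance = qc$n_top_variance, knnK = qc$knn_k)
    fp <- filterProbes(bs, annotation, cfg)
    fs <- filterSamples(fp$betaSet, sheet)
    bs <- knnImpute(fs$betaSet, k = qc$knn_k)
    if (selectVariance)
        bs <- selectTopVariance(bs, min(qc$n_top_variance, nrow(bs)))
    list(betaSet = bs, sheet = fs$sheet, report = fp$report)
}

#' @rdname pipeline
#' @export
cmdQC <- function(config, cohort = c("primary", "validation")) {
    cohort <- match.arg(cohort)
    sim <- .stageDir(config, "simulate")
    betaPath <- .requireArtifact(
        file.path(sim, paste0(cohort, "_beta.tsv")), "cmdSimulate")
    sheetPath <- file.path(sim, paste0(cohort, "_sheet.tsv"))
    annPath <- file.path(sim, "annotation.tsv")
    bs <- readBetaTable(betaPath)
    sheet <- readSampleSheet(sheetPath)
    annotation <- readProbeAnnotation(annPath)
    res <- .qcChain(bs, sheet, annotation, config$qc,
                    selectVariance = cohort == "primary")
    d <- .stageDir(config, paste0("qc_", cohort))
    writeBetaTable(res$betaSet, file.path(d, "matrix.tsv"),
                   dialect = "beta-only")
    writeSampleSheet(res$sheet, file.path(d, "sheet.tsv"))
    writeFilterReport(res$report, file.path(d, "filter_report.json"),
                      file.path(d, "filter_report.tsv"))
    outs <- file.path(d, c("matrix.tsv", "sheet.tsv", "filter_report.json",
                           "filter_report.tsv"))
    invisible(.writeManifest(config, paste0("qc_", cohort),
                             c(betaPath, sheetPath, annPath), outs,
                             config$qc))
}

#' @rdname pipeline
#' @export
cmdExtract <- function(config) {
    qcDir <- file.path(config$output_dir, "qc_primary")
    mPath <- .requireArtifact(file.path(qcDir, "matrix.tsv"), "cmdQC")
    V <- .readNamedMatrix(mPath)
    fc <- config$factorization
    cr <- consensusNMF(V, k = fc$rank, nRuns = fc$n_runs,
                       baseSeed = config$seed, objective = fc$objective,
                       maxIter = fc$max_iter, tol = fc$tol)
    d <- .stageDir(config, "extract")
    writeFactorization(cr, file.path(d, "W.tsv"), file.path(d, "H.tsv"),
                       file.path(d, "consensus_summary.json"))
    means <- data.frame(probe_id = rownames(V), mean = rowMeans(V))
    data.table::fwrite(means, file.path(d, "train_probe_means.tsv"),
                       sep = "\t")
    outs <- file.path(d, c("W.tsv", "H.tsv", "consensus_summary.json",
                           "train_probe_means.tsv"))
    invisible(.writeManifest(config, "extract", mPath, outs, fc))
}

#' @rdname pipeline
#' @export
cmdProject <- function(config) {
    exDir <- file.path(config$output_dir, "extract")
    wPath <- .requireArtifact(file.path(exDir, "W.tsv"), "cmdExtract")
    vPath <- .requireArtifact(
        file.path(config$output_dir, "qc_validation", "matrix.tsv"),
        "cmdQC(cohort = 'validation')")
    W <- .readNamedMatrix(wPath)
    V <- .readNamedMatrix(vPath)
    meansTab <- data.table::fread(file.path(exDir, "train_probe_means.tsv"),
                                  data.table = FALSE)
    trainMeans <- setNames(meansTab$mean, meansTab$probe_id)
    pc <- config$projection
    al <- alignProbes(V, rownames(W), fillPolicy = pc$fill_policy,
                      trainMeans = trainMeans,
                      coverageFloor = pc$coverage_floor)
    pr <- projectCohort(W, al$matrix, probeCoverage = al$coverage,
                        filledProbes = al$filled)
    d <- .stageDir(config, "project")
    writeProjection(pr, file.path(d, "H_V.tsv"),
                    file.path(d, "coverage.json"))
    outs <- file.path(d, c("H_V.tsv", "coverage.json"))
    invisible(.writeManifest(config, "project", c(wPath, vPath), outs, pc))
}

#' @rdname pipeline
#' @export
cmdTrain <- function(config) {
    exDir <- file.path(config$output_dir, "extract")
    hPath <- .requireArtifact(file.path(exDir, "H.tsv"), "cmdExtract")
    sheetPath <- .requireArtifact(
        file.path(config$output_dir, "qc_primary", "sheet.tsv"), "cmdQC")
    H <- .readNamedMatrix(hPath)
    sheet <- readSampleSheet(sheetPath)
    features <- t(H)
    labels <- factor(as.character(
        sheet$label[match(rownames(features), sheet$sample_id)]),
        levels = mbSubgroups())
    cc <- config$classifier
    split <- stratifiedSplit(labels, trainFraction = cc$train_fraction,
                             seed = config$seed)
    scaler <- minMaxScaler(features[split$trainIdx, , drop = FALSE])
    trainX <- scaleFeatures(scaler, features[split$trainIdx, , drop = FALSE])
    model <- tuneAndTrain(trainX, labels[split$trainIdx],
                          family = cc$family, nCandidates = cc$n_candidates,
                          cvFolds = cc$cv_folds, seed = config$seed)
    d <- .stageDir(config, "train")
    saveRDS(list(model = model, scaler = scaler, split = split,
                 classLevels = model$classLevels),
            file.path(d, "model.rds"))
    data.table::fwrite(model$cvTable, file.path(d, "cv_table.tsv"),
                       sep = "\t")
    jsonlite::write_json(
        list(seed = split$seed,
             train_counts = as.list(split$trainCounts),
             n_train = length(split$trainIdx),
             n_test = length(split$testIdx),
             selected = model$params, family = cc$family),
        file.path(d, "split.json"), auto_unbox = TRUE, digits = NA)
    if (length(split$testIdx)) {
        testX <- scaleFeatures(scaler,
                               features[split$testIdx, , drop = FALSE])
        rep <- evaluateModel(model, testX, labels[split$testIdx])
        writeEvaluationReport(rep, file.path(d, "evaluation_test"))
    }
    outs <- file.path(d, c("cv_table.tsv", "split.json"))
    invisible(.writeManifest(config, "train", c(hPath, sheetPath), outs, cc))
}

#' @rdname pipeline
#' @export
cmdEvaluate <- function(config) {
    modelPath <- .requireArtifact(
        file.path(config$output_dir, "train", "model.rds"), "cmdTrain")
    hvPath <- .requireArtifact(
        file.path(config$output_dir, "project", "H_V.tsv"), "cmdProject")
    sheetPath <- .requireArtifact(
        file.path(config$output_dir, "qc_validation", "sheet.tsv"),
        "cmdQC(cohort = 'validation')")
    stored <- readRDS(modelPath)
    HV <- .readNamedMatrix(hvPath)
    sheet <- readSampleSheet(sheetPath)
    features <- scaleFeatures(stored$scaler, t(HV))
    labels <- factor(as.character(
        sheet$label[match(rownames(features), sheet$sample_id)]),
        levels = mbSubgroups())
    rep <- evaluateModel(stored$model, features, labels)
    d <- .stageDir(config, "evaluate")
    writeEvaluationReport(rep, d)
    for (cl in stored$classLevels) {
        pos <- labels == cl
        if (any(pos) && !all(pos)) {
            roc <- rocCurveOvr(labels, classProbabilities(rep), cl)
            data.table::fwrite(roc$points,
                               file.path(d, paste0("roc_", make.names(cl), ".tsv")),
                               sep = "\t")
        }
    }
    outs <- file.path(d, c("evaluation.json", "confusion.tsv",
                           "per_class_metrics.tsv"))
    .writeManifest(config, "evaluate", c(modelPath, hvPath, sheetPath),
                   outs, list())
    invisible(rep)
}

#' @rdname pipeline
#' @export
cmdFull <- function(config) {
    cmdQC(config, "primary")
    cmdExtract(config)
    cmdTrain(config)
    cmdQC(config, "validation")
    cmdProject(config)
    cmdEvaluate(config)
}
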