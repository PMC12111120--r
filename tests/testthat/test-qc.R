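test_that("detection-p masking applies the strict-inequality rule per value", {
    beta <- matrix(0.5, 2, 2)
    detP <- matrix(c(0.20, 0.05, 0.01, 0.06), 2, 2)
    bs <- makeBetaSet(beta, detP = detP)
    masked <- maskLowConfidence(bs, 0.05)
    m <- betaValues(masked)
    expect_true(is.na(m[1, 1]))          # p = 0.20 > 0.05 -> masked
    expect_equal(m[2, 1], 0.5)           # p = 0.05 exactly -> retained
    expect_equal(m[1, 2], 0.5)
    expect_true(is.na(m[2, 2]))
    expect_identical(detectionP(masked), detectionP(bs))  # detP untouched
    ## all-confident matrix is unchanged
    ok <- makeBetaSet(beta, detP = matrix(0.01, 2, 2))
    expect_identical(betaValues(maskLowConfidence(ok)), betaValues(ok))
    ## masking requires detection p-values
    expect_error(maskLowConfidence(makeBetaSet(beta)), "absent")
})

makeAnnotation <- function(probeIDs, xy = character(0), cross = character(0),
                           snp = character(0)) {
    data.frame(probe_id = probeIDs,
               chromosome = ifelse(probeIDs %in% xy, "X", "3"),
               cross_reactive = probeIDs %in% cross,
               max_maf_within_50bp = ifelse(probeIDs %in% snp, 0.05, 0))
}

test_that("probe filtering reports category sets with union semantics", {
    beta <- matrix(0.4, 6, 4,
                   dimnames = list(paste0("cg0", 1:6), paste0("s", 1:4)))
    beta["cg05", 1:3] <- NA               # 75% missing -> low confidence
    bs <- makeBetaSet(beta)
    ann <- makeAnnotation(rownames(beta), xy = c("cg01", "cg02"),
                          cross = c("cg02", "cg03"), snp = "cg04")
    res <- filterProbes(bs, ann, qcConfig())
    cts <- filterCounts(res$report)
    expect_equal(unname(cts), c(2L, 2L, 1L, 1L, 5L))   # cg02 counted once in union
    expect_identical(probeIDs(res$betaSet), "cg06")
    ## MAF exactly at the threshold is removed (>= rule)
    expect_true("cg04" %in% removedProbeIDs(res$report)$snp)
    ## annotation gaps are an error listing the probes
    expect_error(filterProbes(bs, ann[-1, ], qcConfig()), "cg01")
    ## nothing surviving is an error
    allBad <- makeAnnotation(rownames(beta), xy = rownames(beta))
    expect_error(filterProbes(bs, allBad, qcConfig()), "nothing survives")
})

test_that("probe order is preserved and missing-fraction uses strict inequality", {
    beta <- matrix(0.5, 4, 4,
                   dimnames = list(c("cgB", "cgA", "cgD", "cgC"),
                                   paste0("s", 1:4)))
    beta["cgA", 1:2] <- NA                # exactly 50% missing -> retained
    beta["cgD", 1:3] <- NA                # 75% -> removed
    bs <- makeBetaSet(beta)
    ann <- makeAnnotation(rownames(beta))
    res <- filterProbes(bs, ann, qcConfig())
    expect_identical(probeIDs(res$betaSet), c("cgB", "cgA", "cgC"))
    expect_identical(removedProbeIDs(res$report)$lowConfidence, "cgD")
})

test_that("non-classifiable samples are dropped, order preserved", {
    beta <- matrix(runif(12), 2, 6,
                   dimnames = list(c("cg1", "cg2"), paste0("s", 1:6)))
    bs <- makeBetaSet(beta)
    sheet <- data.frame(
        sample_id = paste0("s", 1:6),
        label = c("WNT", "Non-classifiable", "SHH-Child", "WNT",
                  "Non-classifiable", "Group3-LowRisk"))
    res <- filterSamples(bs, sheet)
    expect_identical(sampleIDs(res$betaSet), c("s1", "s3", "s4", "s6"))
    expect_identical(res$sheet$sample_id, c("s1", "s3", "s4", "s6"))
    ## no non-classifiable labels -> identity
    clean <- sheet[sheet$label != "Non-classifiable", ]
    res2 <- filterSamples(res$betaSet, clean)
    expect_identical(betaValues(res2$betaSet), betaValues(res$betaSet))
    ## all non-classifiable -> degenerate error
    allNC <- data.frame(sample_id = paste0("s", 1:6),
                        label = "Non-classifiable")
    expect_error(filterSamples(bs, allNC), "nothing survives")
    ## samples absent from the sheet -> error
    expect_error(filterSamples(bs, sheet[-1, ]), "s1")
})

test_that("KNN imputation recovers values from duplicate neighbours", {
    ## s2 duplicates s1 on its observed probes; k = 1 copies s1's value
    beta <- cbind(s1 = c(0.1, 0.9, 0.5), s2 = c(0.1, 0.9, NA),
                  s3 = c(0.9, 0.1, 0.3))
    rownames(beta) <- paste0("cg", 1:3)
    out <- betaValues(knnImpute(makeBetaSet(beta), k = 1))
    expect_equal(out["cg3", "s2"], 0.5)
    ## three identical samples with scattered masking, k = 2: the common
    ## value is recovered exactly
    common <- c(0.2, 0.8, 0.4, 0.6)
    beta3 <- matrix(rep(common, 3), 4, 3,
                    dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
    beta3[1, 1] <- NA; beta3[3, 2] <- NA; beta3[4, 3] <- NA
    out3 <- betaValues(knnImpute(makeBetaSet(beta3), k = 2))
    expect_equal(unname(out3), matrix(rep(common, 3), 4, 3))
})

test_that("KNN imputation matches the brute-force neighbour search", {
    bs <- randomBetaSet(30, 20, seed = 11, missingFrac = 0.05,
                        withDetP = FALSE)
    out <- betaValues(knnImpute(bs, k = 3))
    oracle <- bruteKNNImpute(betaValues(bs), k = 3)
    expect_equal(out, oracle, tolerance = 1e-12)
    ## observed entries are never altered
    obs <- !is.na(betaValues(bs))
    expect_identical(out[obs], betaValues(bs)[obs])
    ## idempotent on complete matrices
    expect_identical(betaValues(knnImpute(makeBetaSet(out), k = 3)), out)
})

test_that("KNN imputation contract errors", {
    beta <- matrix(runif(9), 3, 3,
                   dimnames = list(paste0("cg", 1:3), paste0("s", 1:3)))
    expect_error(knnImpute(makeBetaSet(beta), k = 3), "smaller than")
    beta[2, ] <- NA
    expect_error(knnImpute(makeBetaSet(beta), k = 1), "missing in all samples")
})

test_that("top-variance selection ranks by n-1 variance with lexicographic ties", {
    beta <- rbind(p1 = c(0, 1, 0, 1),         # var 1/3
                  p2 = c(0.5, 0.5, 0.5, 0.5), # var 0
                  p3 = c(0.4, 0.6, 0.4, 0.6)) # var 0.0133...
    colnames(beta) <- paste0("s", 1:4)
    kept <- probeIDs(selectTopVariance(makeBetaSet(beta), 2))
    expect_identical(kept, c("p1", "p3"))
    ## n = n_probes is the identity
    expect_identical(probeIDs(selectTopVariance(makeBetaSet(beta), 3)),
                     rownames(beta))
    ## identical rows: the lexicographically smaller id is kept
    tie <- rbind(pB = c(0, 1), pA = c(0, 1))
    colnames(tie) <- c("s1", "s2")
    expect_identical(probeIDs(selectTopVariance(makeBetaSet(tie), 1)), "pA")
    expect_error(selectTopVariance(makeBetaSet(tie), 3), "exceeds")
    ## kept variances dominate excluded variances; original order retained
    bs <- randomBetaSet(40, 8, seed = 5, withDetP = FALSE)
    sel <- selectTopVariance(bs, 15)
    v <- apply(betaValues(bs), 1, var)
    expect_gte(min(v[probeIDs(sel)]), max(v[setdiff(names(v), probeIDs(sel))]))
    expect_identical(probeIDs(sel),
                     intersect(probeIDs(bs), probeIDs(sel)))
})
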