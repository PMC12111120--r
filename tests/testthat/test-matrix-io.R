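test_that("paired-columns tables round-trip exactly, including missing cells", {
    bs <- randomBetaSet(5, 3, seed = 42)
    beta <- betaValues(bs)
    beta[c(2, 9)] <- NA
    bs <- makeBetaSet(beta, detP = detectionP(bs))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeBetaTable(bs, path, dialect = "paired-columns")
    back <- readBetaTable(path, dialect = "paired-columns")
    expect_identical(betaValues(back), betaValues(bs))
    expect_identical(detectionP(back), detectionP(bs))
    ## missing values appear as empty cells on disk
    raw <- readLines(path)
    expect_true(any(grepl("\t\t|\t$", raw[-1])))
})

test_that("beta-only dialect round-trips and drops the detection-p block", {
    bs <- randomBetaSet(6, 4, seed = 7)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeBetaTable(bs, path, dialect = "beta-only")
    back <- readBetaTable(path, dialect = "beta-only")
    expect_identical(betaValues(back), betaValues(bs))
    expect_false(hasDetectionP(back))
})

test_that("a 2-probe 1-sample paired table yields exactly its values", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\t0.25\t0.01",
                 "cg02\t0.75\t0.02"), path)
    bs <- readBetaTable(path)
    expect_equal(ncol(bs), 1L)
    expect_equal(unname(betaValues(bs)[, 1]), c(0.25, 0.75))
    expect_equal(unname(detectionP(bs)[, 1]), c(0.01, 0.02))
})

test_that("format violations are rejected with informative errors", {
    path <- withr::local_tempfile(fileext = ".tsv")
    ## odd data-column count in paired dialect
    writeLines(c("probe_id\ts1.beta\ts1.pval\ts2.beta",
                 "cg01\t0.1\t0.01\t0.2"), path)
    expect_error(readBetaTable(path), "even data-column count")
    ## duplicate probe identifier
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\t0.1\t0.01", "cg01\t0.2\t0.01"), path)
    expect_error(readBetaTable(path), "duplicate probe")
    ## non-numeric cell named with row and column
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\t0.1\t0.01", "cg02\toops\t0.01"), path)
    expect_error(readBetaTable(path), "cg02.*s1\\.beta")
    ## out-of-range values raise instead of being clipped
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\t1.2\t0.01"), path)
    expect_error(readBetaTable(path), "out of \\[0, 1\\]")
    ## 0 and 1 are legal (closed interval)
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\t0\t0.01", "cg02\t1\t0"), path)
    expect_equal(unname(betaValues(readBetaTable(path))[, 1]), c(0, 1))
})

test_that("NA tokens are configurable on read", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("probe_id\ts1.beta\ts1.pval",
                 "cg01\tNA\t0.01", "cg02\tNaN\t0.02", "cg03\t\t0.03"), path)
    bs <- readBetaTable(path)
    expect_true(all(is.na(betaValues(bs))))
    expect_false(anyNA(detectionP(bs)))
})

test_that("sample sheets enforce the closed label vocabulary", {
    path <- withr::local_tempfile(fileext = ".tsv")
    labs <- mbSubgroups(includeNonClassifiable = TRUE)
    writeLines(c("sample_id\tlabel",
                 paste(sprintf("S%02d", seq_along(labs)), labs, sep = "\t")),
               path)
    sheet <- readSampleSheet(path)
    expect_equal(nrow(sheet), 8L)
    expect_s3_class(sheet$label, "factor")
    writeLines(c("sample_id\tlabel", "S01\tGroup5"), path)
    expect_error(readSampleSheet(path), "Group5")
})

test_that("probe annotations are validated and X/Y probes recognized downstream", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("probe_id\tchromosome\tcross_reactive\tmax_maf_within_50bp",
                 "cg01\tX\tFALSE\t0",
                 "cg02\t7\tTRUE\t0.3",
                 "cg03\t7\tFALSE\t0"), path)
    ann <- readProbeAnnotation(path)
    expect_identical(ann$cross_reactive, c(FALSE, TRUE, FALSE))
    bs <- makeBetaSet(matrix(runif(6), 3, 2,
                             dimnames = list(c("cg01", "cg02", "cg03"),
                                             c("a", "b"))))
    res <- filterProbes(bs, ann, qcConfig())
    expect_setequal(removedProbeIDs(res$report)$xy, "cg01")
    ## MAF outside [0, 0.5] is invalid
    writeLines(c("probe_id\tchromosome\tcross_reactive\tmax_maf_within_50bp",
                 "cg01\t1\tFALSE\t0.9"), path)
    expect_error(readProbeAnnotation(path), "0.5")
})
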