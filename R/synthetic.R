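## Seeded synthetic cohorts with the statistical structure the pipeline
## assumes: bimodal beta marginals over a latent non-negative rank-6
## structure, seven imbalanced subgroups with Group3/Group4 adjacency,
## detection p-values, planted missingness, planted annotation categories.

#' Canonical primary-cohort class proportions
#'
#' Classifiable class sizes of the canonical 409-sample primary cohort
#' (WNT 33, SHH-Infant 65, SHH-Child 38, Group3-LowRisk 50,
#' Group3-HighRisk 65, Group4-LowRisk 73, Group4-HighRisk 85), normalized
#' to proportions in the fixed vocabulary order.
#'
#' @return Named numeric vector summing to 1.
#' @examples
#' table5Proportions()["WNT"] * 409   # 33 samples
#' @export
table5Proportions <- function() {
    sizes <- c("WNT" = 33, "SHH-Infant" = 65, "SHH-Child" = 38,
               "Group3-LowRisk" = 50, "Group3-HighRisk" = 65,
               "Group4-LowRisk" = 73, "Group4-HighRisk" = 85)
    sizes <- sizes[mbSubgroups()]
    sizes / sum(sizes)
}

## largest-remainder rounding of proportions to integer counts summing to n
.roundCounts <- function(proportions, n) {
    raw <- proportions * n
    counts <- floor(raw)
    short <- n - sum(counts)
    if (short > 0) {
        extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
        counts[extra] <- counts[extra] + 1
    }
    as.integer(counts)
}

## monotone odds-power warp pushing mid-range values toward 0/1; strength
## a > 1 sharpens bimodality, a = 1 is the identity
.bimodalWarp <- function(x, a) x^a / (x^a + (1 - x)^a)

## subgroup mean coefficient vectors over k = 6 metagenes: metagenes 1-3
## drive WNT / SHH-Infant / SHH-Child, 4 and 5 carry the Group3 and Group4
## identities, and 6 is a shared high-risk component dominating both
## high-risk classes, so each metagene is the dominant component of some
## subgroup and the planted rank is recoverable by consensus clustering.
## separation in (0, 1] controls the Group3/Group4 adjacency
## (cross-group leakage (1-sep)/2).
.classMeans <- function(separation) {
    leak <- (1 - separation) / 2
    m <- rbind(
        "WNT"             = c(1, 0, 0, 0,    0,    0),
        "SHH-Infant"      = c(0, 1, 0, 0,    0,    0),
        "SHH-Child"       = c(0, 0, 1, 0,    0,    0),
        "Group3-LowRisk"  = c(0, 0, 0, 1,    leak, 0.1),
        "Group3-HighRisk" = c(0, 0, 0, 0.35, leak, 1),
        "Group4-LowRisk"  = c(0, 0, 0, leak, 1,    0.1),
        "Group4-HighRisk" = c(0, 0, 0, leak, 0.35, 1))
    m[mbSubgroups(), , drop = FALSE]
}

#' Generate a synthetic methylation cohort
#'
#' Builds a probes x samples beta matrix \code{clip(W H + noise, 0, 1)} from
#' a planted non-negative rank-\code{k} structure: \code{W} has sparse
#' blocks over disjoint probe sets plus a low background, and every
#' subgroup has a characteristic mean coefficient vector (Group3/Group4
#' risk variants drawn closer together per \code{separation}). An optional
#' monotone odds-power warp pushes the marginals toward the bimodal shape
#' of real beta values (peaks near 0 and 1) without changing the value
#' order; it is applied after noise and before corruption. Planted
#' low-confidence positions carry a detection p-value above 0.05 and a
#' corrupted beta value; all other positions carry small p-values.
#' Annotation categories (XY, cross-reactive, SNP-proximal) are planted at
#' the requested disjoint fractions. Fully seeded: the same seed reproduces
#' the cohort bit for bit.
#'
#' @param nProbes,nSamples cohort dimensions (defaults 2000 x 350).
#' @param k latent rank (default 6).
#' @param classProportions named proportions over the seven subgroups,
#'   summing to 1 (default \code{\link{table5Proportions}}).
#' @param separation per-pair overlap control in \eqn{(0, 1]}; 1 separates
#'   all subgroups fully, lower values move the Group3/Group4 risk variants
#'   together (default 0.8).
#' @param noiseSD standard deviation of the additive Gaussian noise
#'   (default 0.02).
#' @param missingRate fraction of positions planted as low-confidence
#'   (default 0.02).
#' @param annotationFractions named fractions (\code{xy},
#'   \code{crossReactive}, \code{snp}) of probes planted into each
#'   annotation category; must sum to at most 1.
#' @param warp apply the bimodal warp (default \code{TRUE}); off, the
#'   noiseless matrix equals \code{clip(W H, 0, 1)} exactly.
#' @param warpStrength exponent of the warp (default 3).
#' @param nNonClassifiable number of extra samples with diffuse metagene
#'   profiles labelled \code{"Non-classifiable"} (default 0).
#' @param seed integer seed.
#' @param WTrue,annotation optional planted structure reused from a previous
#'   cohort (to simulate an independent validation cohort over the same
#'   probe universe).
#' @return list with \code{betaSet} (a \linkS4class{BetaSet} with detection
#'   p-values), \code{sheet} (sample sheet data.frame) and \code{truth}
#'   (a \linkS4class{SyntheticTruth}).
#' @export
generateCohort <- function(nProbes = 2000L, nSamples = 350L, k = 6L,
                           classProportions = table5Proportions(),
                           separation = 0.8, noiseSD = 0.02,
                           missingRate = 0.02,
                           annotationFractions = c(xy = 0.03,
                                                   crossReactive = 0.05,
                                                   snp = 0.06),
                           warp = TRUE, warpStrength = 3,
                           nNonClassifiable = 0L, seed = 1L,
                           WTrue = NULL, annotation = NULL) {
    if (abs(sum(classProportions) - 1) > 1e-8)
        stop("classProportions must sum to 1")
    if (!setequal(names(classProportions), mbSubgroups()))
        stop("classProportions must cover exactly the seven subgroups")
    if (k > nSamples) stop("k must not exceed nSamples")
    if (sum(annotationFractions) > 1)
        stop("annotationFractions sum to more than 1; infeasible")
    if (k != 6L)
        stop("the subgroup coefficient design is defined for k = 6")
    classProportions <- classProportions[mbSubgroups()]
    set.seed(seed)
    probeIDs <- sprintf("cg%06d", seq_len(nProbes))

    ## planted basis: disjoint probe blocks (~70% of probes) + background
    if (is.null(WTrue)) {
        W <- matrix(runif(nProbes * k, 0, 0.02), nProbes, k)
        blockProbes <- sample(nProbes, floor(0.7 * nProbes))
        blocks <- split(blockProbes,
                        rep_len(seq_len(k), length(blockProbes)))
        for (g in seq_len(k))
            W[blocks[[g]], g] <- runif(length(blocks[[g]]), 0.7, 1)
        rownames(W) <- probeIDs
        colnames(W) <- paste0("V", seq_len(k))
    } else {
        W <- WTrue
        if (nrow(W) != nProbes || ncol(W) != k)
            stop("supplied WTrue disagrees with nProbes/k")
        probeIDs <- rownames(W)
    }

    ## planted annotation: disjoint category draws
    if (is.null(annotation)) {
        nXY <- round(annotationFractions[["xy"]] * nProbes)
        nCross <- round(annotationFractions[["crossReactive"]] * nProbes)
        nSNP <- round(annotationFractions[["snp"]] * nProbes)
        picked <- sample(nProbes, nXY + nCross + nSNP)
        xyIdx <- picked[seq_len(nXY)]
        crossIdx <- picked[nXY + seq_len(nCross)]
        snpIdx <- picked[nXY + nCross + seq_len(nSNP)]
        chrom <- as.character(rep_len(1:22, nProbes))
        chrom[xyIdx] <- sample(c("X", "Y"), nXY, replace = TRUE)
        maf <- numeric(nProbes)
        maf[snpIdx] <- runif(nSNP, 0.05, 0.5)
        annotation <- data.frame(
            probe_id = probeIDs, chromosome = chrom,
            cross_reactive = seq_len(nProbes) %in% crossIdx,
            max_maf_within_50bp = maf)
    }

    ## subgroup labels and coefficient matrix
    counts <- .roundCounts(classProportions, nSamples)
    labels <- factor(rep(mbSubgroups(), counts), levels = mbSubgroups())
    mu <- .classMeans(separation)
    nTotal <- nSamples + nNonClassifiable
    H <- matrix(0, k, nTotal)
    for (j in seq_len(nSamples)) {
        v <- mu[as.character(labels[j]), ] +
             abs(rnorm(k, 0, 0.05)) * (mu[as.character(labels[j]), ] > 0) +
             runif(k, 0, 0.03)
        H[, j] <- v / sum(v) * runif(1L, 0.85, 1)
    }
    if (nNonClassifiable > 0L) {
        for (j in nSamples + seq_len(nNonClassifiable)) {
            v <- runif(k, 0.5, 1)
            H[, j] <- v / sum(v) * runif(1L, 0.85, 1)
        }
    }
    sampleID <- sprintf("S%04d", seq_len(nTotal))
    colnames(H) <- sampleID
    rownames(H) <- colnames(W)

    ## beta = warp(clip(WH + noise)) with planted corrupted positions
    clean <- W %*% H
    beta <- clean + if (noiseSD > 0)
        matrix(rnorm(length(clean), 0, noiseSD), nrow(clean)) else 0
    beta[beta < 0] <- 0
    beta[beta > 1] <- 1
    if (warp) beta <- .bimodalWarp(beta, warpStrength)
    completeBeta <- beta

    nMask <- round(missingRate * length(beta))
    maskIdx <- if (nMask > 0) sample(length(beta), nMask) else integer(0)
    masked <- arrayInd(maskIdx, dim(beta))
    colnames(masked) <- c("probe", "sample")
    detP <- matrix(runif(length(beta), 0, 0.04), nrow(beta))
    if (nMask > 0) {
        beta[maskIdx] <- runif(nMask)        # unreliable measurement
        detP[maskIdx] <- runif(nMask, 0.06, 0.5)
    }
    dimnames(beta) <- list(probeIDs, sampleID)

    allLabels <- factor(
        c(as.character(labels), rep(.NON_CLASSIFIABLE, nNonClassifiable)),
        levels = mbSubgroups(includeNonClassifiable = TRUE))
    age <- ifelse(allLabels == "SHH-Infant", runif(nTotal, 0.3, 4.2),
                  runif(nTotal, 4.5, 16))
    sheet <- data.frame(sample_id = sampleID,
                        label = allLabels,
                        age_years = round(age, 2),
                        sex = sample(c("M", "F"), nTotal, replace = TRUE))
    truth <- new("SyntheticTruth", WTrue = W, HTrue = H,
                 labels = allLabels, maskedPositions = masked,
                 annotation = annotation, completeBeta = completeBeta)
    list(betaSet = BetaSet(beta, detP = detP), sheet = sheet, truth = truth)
}
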