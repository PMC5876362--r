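#' Configuration for the synthetic dataset generator
#'
#' Describes a seed-reproducible synthetic study: grayscale stimuli with
#' rectangular category regions, pixel-label maps, ROI-structured
#' category-selective voxel responses, and feature vectors correlated with
#' category identity.  The defaults emulate a single-subject natural-scene
#' decoding regime at desk scale: 64 x 64 images, the seven higher-level
#' visual ROIs, and effect sizes a few times the amplitude noise so that
#' voxel decoding is possible but imperfect.
#'
#' @param nStimuli number of stimuli.
#' @param imageSide image side length in pixels (square images).
#' @param categories character vector of category names.
#' @param rois character vector of ROI names.
#' @param voxelsPerRoi voxels simulated per ROI.
#' @param selectivity numeric matrix (rois x categories) of mean response
#'   shifts, in amplitude units; \code{NULL} uses a default map in which EBA
#'   and FFA respond to humans/animals and PPA, RSC and TOS to
#'   buildings/foods, with weak general object responses in LO and OFA.
#' @param noiseSd standard deviation of the additive Gaussian amplitude
#'   noise.
#' @param mixedFraction fraction of stimuli carrying two category regions.
#' @param backgroundFraction fraction of stimuli with no category region
#'   (clear negatives by construction).
#' @param clarityLink scalar in [0, 1]: 0 makes the selective response (and
#'   the feature-space margin) independent of a stimulus's clarity (its
#'   dominant-category pixel fraction); 1 makes both fully proportional to
#'   clarity.
#' @param featureDim dimension of the synthetic feature vectors.
#' @param separation feature-space effect size: the distance of a fully
#'   clear category mean from the background mean, in units of the
#'   unit-variance feature noise.
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#' @return A list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nStimuli = 200L, imageSide = 64L,
    categories = c("humans", "animals", "buildings", "foods"),
    rois = c("EBA", "FFA", "LO", "OFA", "PPA", "RSC", "TOS"),
    voxelsPerRoi = 10L, selectivity = NULL, noiseSd = 0.35,
    mixedFraction = 0.1, backgroundFraction = 0.25, clarityLink = 1,
    featureDim = 24L, separation = 1.5, seed = 1L) {
    stopifnot2(nStimuli >= 0, "nStimuli must be nonnegative")
    stopifnot2(imageSide >= 8, "imageSide too small to place category regions")
    stopifnot2(!anyDuplicated(categories) && length(categories) > 0,
        "category names must be nonempty and unique")
    stopifnot2(!anyDuplicated(rois) && length(rois) > 0,
        "ROI names must be nonempty and unique")
    stopifnot2(voxelsPerRoi >= 1, "voxelsPerRoi must be positive")
    fr <- c(mixedFraction, backgroundFraction, clarityLink)
    stopifnot2(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
    stopifnot2(mixedFraction + backgroundFraction <= 1,
        "mixedFraction + backgroundFraction must be <= 1")
    stopifnot2(noiseSd >= 0 && separation >= 0, "scales must be nonnegative")
    if (is.null(selectivity))
        selectivity <- defaultSelectivity(rois, categories)
    selectivity <- as.matrix(selectivity)
    stopifnot2(all(rois %in% rownames(selectivity)) &&
        all(categories %in% colnames(selectivity)),
        "selectivity must be a rois x categories matrix")
    structure(list(nStimuli = as.integer(nStimuli),
        imageSide = as.integer(imageSide), categories = categories,
        rois = rois, voxelsPerRoi = as.integer(voxelsPerRoi),
        selectivity = selectivity[rois, categories, drop = FALSE],
        noiseSd = noiseSd, mixedFraction = mixedFraction,
        backgroundFraction = backgroundFraction, clarityLink = clarityLink,
        featureDim = as.integer(featureDim), separation = separation,
        seed = as.integer(seed)), class = "SyntheticConfig")
}

# Default ROI -> category effect-size map (amplitude units), loosely shaped
# after known body/face/place selectivities.  Cross-category responses are
# deliberately strong (EBA responds to animal as well as human bodies, LO to
# objects of every category): category-selective regions in visual cortex
# prefer, rather than exclusively encode, their favoured category.
defaultSelectivity <- function(rois, categories) {
    sel <- matrix(0, length(rois), length(categories),
        dimnames = list(rois, categories))
    set1 <- function(r, c, v) if (r %in% rois && c %in% categories)
        sel[r, c] <<- v
    set1("EBA", "humans", 1.0); set1("EBA", "animals", 0.5)
    set1("FFA", "humans", 0.8); set1("FFA", "animals", 0.4)
    set1("OFA", "humans", 0.6); set1("OFA", "animals", 0.3)
    set1("PPA", "buildings", 1.0); set1("PPA", "foods", 0.6)
    set1("RSC", "buildings", 0.8); set1("RSC", "foods", 0.3)
    set1("TOS", "buildings", 0.6)
    if ("LO" %in% rois) sel["LO", ] <- 0.5
    sel
}

#' Generate synthetic stimuli and pixel-label maps
#'
#' Each stimulus is a grayscale intensity grid in [0, 1] containing zero,
#' one, or two axis-aligned rectangular category regions over a textured
#' background; its pixel-label map assigns each pixel a category tag or
#' \code{"background"}.  Region area fractions are drawn from a range that
#' straddles the 20\% labeling threshold, so downstream clear-sample
#' filtering is exercised.  The fraction of two-category stimuli matches
#' \code{mixedFraction} in expectation.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with elements \code{stimuli} (named list of intensity
#'   matrices) and \code{labelMaps} (named list of character matrices, with a
#'   \code{"vocabulary"} attribute on the list giving all category tags).
#' @export
generateStimuli <- function(config) {
    stopifnot2(inherits(config, "SyntheticConfig"), "need a SyntheticConfig")
    side <- config$imageSide
    cats <- config$categories
    baseInt <- 0.15 + 0.7 * (seq_along(cats) - 1) / max(1, length(cats) - 1)
    names(baseInt) <- cats
    withLocalSeed(deriveSeed(config$seed, "stimuli"), {
        stimuli <- vector("list", config$nStimuli)
        maps <- vector("list", config$nStimuli)
        for (i in seq_len(config$nStimuli)) {
            img <- matrix(pmin(1, pmax(0, 0.5 + rnorm(side^2, 0, 0.08))),
                side, side)
            map <- matrix("background", side, side)
            u <- runif(1)
            ncat <- if (u < config$mixedFraction) 2L
                else if (u < config$mixedFraction + config$backgroundFraction) 0L
                else 1L
            chosen <- if (ncat > 0)
                sample(cats, ncat, replace = FALSE) else character(0)
            for (cat in chosen) {
                areaFrac <- runif(1, 0.05, 0.65)
                aspect <- runif(1, 0.7, 1.4)
                w <- max(2L, min(side, round(side * sqrt(areaFrac * aspect))))
                h <- max(2L, min(side, round(side * sqrt(areaFrac / aspect))))
                r0 <- sample.int(side - h + 1L, 1L)
                c0 <- sample.int(side - w + 1L, 1L)
                rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
                map[rows, cols] <- cat
                img[rows, cols] <- pmin(1, pmax(0,
                    baseInt[cat] + rnorm(h * w, 0, 0.08)))
            }
            stimuli[[i]] <- img
            maps[[i]] <- map
        }
        ids <- sprintf("stim%04d", seq_len(config$nStimuli))
        names(stimuli) <- ids
        names(maps) <- ids
        attr(maps, "vocabulary") <- c(cats, "background")
        list(stimuli = stimuli, labelMaps = maps)
    })
}

#' Generate an ROI-structured synthetic voxel table
#'
#' Voxel response amplitudes follow
#' \deqn{x_{sv} = \sum_{c} S_{r(v), c}\, g(\pi_{sc}) + \epsilon,\qquad
#'   \epsilon \sim N(0, \sigma^2),}
#' where \eqn{\pi_{sc}} is stimulus \eqn{s}'s pixel fraction for category
#' \eqn{c}, \eqn{S} the configured selectivity map, and
#' \eqn{g(\pi) = (1 - \lambda)\,1[\pi \ge \theta] + \lambda \pi} with
#' \eqn{\lambda} = \code{clarityLink} and \eqn{\theta} the labeling
#' threshold.  The response is graded: the brain responds to category
#' content in proportion to how much of it is present, whether or not the
#' stimulus crosses the annotation threshold.  With \code{clarityLink = 0}
#' and zero noise, stimuli above threshold for a category exceed negatives
#' by exactly the configured effect; with \code{clarityLink > 0}, clearer
#' stimuli receive stochastically larger selective responses.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param labeling a \linkS4class{CategoryLabeling} covering all stimuli
#'   (from \code{\link{assignCategoryLabels}}).
#' @return An unscaled \linkS4class{VoxelTable} of dimension
#'   nStimuli x (voxelsPerRoi * number of ROIs).
#' @export
generateVoxels <- function(config, labeling) {
    stopifnot2(inherits(config, "SyntheticConfig"), "need a SyntheticConfig")
    stopifnot2(methods::is(labeling, "CategoryLabeling"),
        "need a CategoryLabeling")
    frac <- labeling@fractions
    stopifnot2(all(config$categories %in% colnames(frac)),
        "labeling must cover all configured categories")
    ids <- rownames(frac)
    nv <- config$voxelsPerRoi * length(config$rois)
    roiOf <- rep(config$rois, each = config$voxelsPerRoi)
    vids <- sprintf("v_%s_%02d", roiOf,
        rep(seq_len(config$voxelsPerRoi), times = length(config$rois)))
    g <- clarityGain(frac[, config$categories, drop = FALSE],
        config$clarityLink, labeling@threshold)
    # stimuli x voxels signal: g %*% t(selectivity rows per voxel)
    selV <- config$selectivity[roiOf, , drop = FALSE]   # nv x categories
    signal <- g %*% t(selV)
    withLocalSeed(deriveSeed(config$seed, "voxels"), {
        amp <- signal + matrix(rnorm(length(ids) * nv, 0, config$noiseSd),
            length(ids), nv)
        dimnames(amp) <- list(ids, vids)
        VoxelTable(amp, stats::setNames(roiOf, vids))
    })
}

# graded response gain of category content: with link = 0, a step at the
# annotation threshold (exact configured effect); with link = 1, fully
# proportional to the pixel fraction
clarityGain <- function(frac, link, threshold) {
    (1 - link) * (frac >= threshold) + link * frac
}

#' Generate synthetic feature vectors
#'
#' Fixed-dimension vectors with category-dependent means plus unit-variance
#' Gaussian noise: each category present in a stimulus contributes
#' \code{separation} times its clarity gain \eqn{g(\pi)} (see
#' \code{\link{generateVoxels}}) along a fixed category direction.
#' Background-only stimuli are pure noise.  \code{separation = 0} renders
#' features uninformative (chance-level classification); large values make
#' the task easy.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param labeling a \linkS4class{CategoryLabeling}.
#' @return numeric matrix (stimuli x featureDim) with rownames = stimulus
#'   ids and attribute \code{featureType = "synthetic"}.
#' @export
generateFeatures <- function(config, labeling) {
    stopifnot2(inherits(config, "SyntheticConfig"), "need a SyntheticConfig")
    frac <- labeling@fractions
    ids <- rownames(frac)
    d <- config$featureDim
    k <- length(config$categories)
    stopifnot2(d >= k, "featureDim must be >= number of categories")
    # fixed orthonormal category directions, deterministic in the seed
    dirs <- withLocalSeed(deriveSeed(config$seed, "feature-dirs"), {
        q <- qr.Q(qr(matrix(rnorm(d * k), d, k)))
        t(q)   # k x d, orthonormal rows
    })
    g <- clarityGain(frac[, config$categories, drop = FALSE],
        config$clarityLink, labeling@threshold)
    signal <- (g %*% dirs) * config$separation
    withLocalSeed(deriveSeed(config$seed, "features"), {
        x <- signal + matrix(rnorm(length(ids) * d), length(ids), d)
        dimnames(x) <- list(ids, sprintf("f%03d", seq_len(d)))
        attr(x, "featureType") <- "synthetic"
        x
    })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running \code{\link{generateStimuli}},
#' \code{\link{assignCategoryLabels}}, \code{\link{generateVoxels}} and
#' \code{\link{generateFeatures}} for one config.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param threshold pixel-fraction labeling threshold (default 0.2).
#' @return list with elements \code{stimuli}, \code{labelMaps},
#'   \code{labeling}, \code{voxels}, \code{features}, \code{config}.
#' @export
simulateDataset <- function(config, threshold = 0.2) {
    sm <- generateStimuli(config)
    labeling <- assignCategoryLabels(sm$labelMaps, config$categories,
        threshold = threshold)
    list(stimuli = sm$stimuli, labelMaps = sm$labelMaps, labeling = labeling,
        voxels = generateVoxels(config, labeling),
        features = generateFeatures(config, labeling),
        config = config)
}

#' Plant annotation noise: low-clarity stimuli mislabeled as positives
#'
#' Emulates the characteristic annotation error of pixel-outline labeling:
#' a stimulus with little or no actual category content (near-empty scene,
#' or an object far below the labeling threshold) is nevertheless recorded
#' as a positive example.  A fraction \code{p} of the resulting positive
#' training set consists of such mislabeled low-clarity stimuli:
#' \code{round(p * nPos / (1 - p))} training negatives are relabeled +1,
#' drawn from the low-clarity half of the negative pool when clarities are
#' supplied (preferring the emptiest stimuli), uniformly otherwise.
#'
#' Because the mislabeled stimuli carry weak image features \emph{and} weak
#' voxel responses, stage-one cross-validated Platt scores for them are
#' small: the activity-weighted loss penalizes their misclassification
#' barely more than plain hinge loss, while genuine clear positives are
#' penalized up to twice as hard.  This is the planted mechanism that
#' activity weighting is designed to exploit.
#'
#' @param labels named numeric vector of training labels in {-1, +1}.
#' @param p target fraction of mislabeled stimuli among the returned
#'   positives, in [0, 1).
#' @param seed integer seed.
#' @param clarity optional named numeric vector of dominant-category pixel
#'   fractions (see \code{\link{clarity}}) used to target the flips at
#'   low-clarity stimuli.
#' @return labels with some -1 entries flipped to +1; the flipped ids are
#'   recorded in attribute \code{"corrupted"}.
#' @export
corruptPositiveLabels <- function(labels, p, seed, clarity = NULL) {
    stopifnot2(p >= 0 && p < 1, "p must lie in [0, 1)")
    pos <- names(labels)[labels > 0]
    neg <- names(labels)[labels < 0]
    pool <- neg
    if (!is.null(clarity) && length(neg) > 1) {
        cl <- clarity[neg]
        pool <- neg[cl <= stats::quantile(cl, 0.5)]
    }
    # cap the flips so the negative class remains the larger one, the
    # regime the balanced-subsampling design assumes
    nFlip <- min(length(pool), round(p * length(pos) / (1 - p)),
        max(0L, floor((length(neg) - length(pos)) / 2)))
    if (nFlip == 0) {
        attr(labels, "corrupted") <- character(0)
        return(labels)
    }
    flip <- withLocalSeed(deriveSeed(seed, "label-noise"), {
        if (!is.null(clarity)) {
            # prefer the emptiest stimuli within the low-clarity pool
            w <- (max(clarity[pool]) + 0.02) - clarity[pool]
            sample(pool, nFlip, prob = w)
        } else sample(pool, nFlip)
    })
    labels[flip] <- 1
    attr(labels, "corrupted") <- flip
    labels
}
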