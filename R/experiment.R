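#' Create random train/test partitions of the clear sample set
#'
#' Each partition is an independent random 80/20 split (by default),
#' deterministic under the seed.  When labels are supplied the split is
#' stratified per class, which guarantees both classes appear in every test
#' set.
#'
#' @param ids character stimulus ids (the clear sample set of the task
#'   universe); at least 5.
#' @param n number of partitions (default 4).
#' @param testFraction fraction held out for testing (default 0.2).
#' @param seed integer seed.
#' @param labels optional named labels in {-1, +1} used for stratification.
#' @return list of partitions, each a list with \code{train}, \code{test},
#'   \code{index}, \code{seed}.
#' @export
makePartitions <- function(ids, n = 4L, testFraction = 0.2, seed = 1L,
    labels = NULL) {
    stopifnot2(length(ids) >= 5, "need at least 5 ids to partition")
    stopifnot2(testFraction > 0 && testFraction < 1,
        "testFraction must lie in (0, 1)")
    lapply(seq_len(n), function(p) {
        s <- deriveSeed(seed, "partition", p)
        test <- withLocalSeed(s, {
            if (is.null(labels)) {
                sample(ids, max(1L, round(testFraction * length(ids))))
            } else {
                unlist(lapply(split(ids, labels[ids]), function(grp)
                    sample(grp, max(1L, round(testFraction * length(grp))))),
                    use.names = FALSE)
            }
        })
        list(train = setdiff(ids, test), test = test, index = p, seed = s)
    })
}

#' Create balanced classification problems from a partition's training data
#'
#' Each balanced problem uses all positive training samples plus an
#' independently drawn uniform random subset of negatives of equal size; the
#' partition's test set is left untouched and shared by all problems (only
#' the training data are balanced).
#'
#' @param partition one element of \code{\link{makePartitions}}.
#' @param labeling a \linkS4class{CategoryLabeling}.
#' @param category the task's category.
#' @param n number of balanced problems (default 5).
#' @param seed integer seed.
#' @param labels optional named training labels in {-1, +1} overriding
#'   \code{\link{binaryLabels}} (used to inject annotation noise).
#' @return list of problems, each a list with \code{ids} (balanced training
#'   ids), \code{index}, \code{seed}.
#' @export
makeBalancedProblems <- function(partition, labeling, category, n = 5L,
    seed = 1L, labels = NULL) {
    if (is.null(labels))
        labels <- binaryLabels(labeling, category, partition$train)
    y <- labels[partition$train]
    pos <- partition$train[y > 0]
    neg <- partition$train[y < 0]
    stopifnot2(length(pos) <= length(neg),
        paste0("positives exceed negatives in the training set; the ",
            "balancing scheme assumes the negative class is the larger one"))
    lapply(seq_len(n), function(b) {
        s <- deriveSeed(seed, "balanced", b)
        negSub <- withLocalSeed(s, sample(neg, length(pos)))
        list(ids = c(pos, negSub), index = b, seed = s)
    })
}

#' Train and test HL and AWL classifiers for one experimental condition
#'
#' For each balanced problem, trains one hinge-loss and one
#' activity-weighted-loss RBF-SVM (\code{\link{trainSVM}}, no parameter
#' tuning: C = 1 and gamma = 1/number of features by default) on the
#' balanced training features and evaluates accuracy on the partition's
#' held-out test set.  Appends two rows per problem.
#'
#' @param category task category name.
#' @param combo ROI combination the weights were generated from (bookkeeping
#'   only here).
#' @param partition one element of \code{\link{makePartitions}}.
#' @param problems list from \code{\link{makeBalancedProblems}}.
#' @param features feature matrix (stimuli x features).
#' @param weights an \linkS4class{ActivityWeights} generated from the SAME
#'   partition's training data only.
#' @param trainLabels named training labels in {-1, +1}.
#' @param testLabels named test labels in {-1, +1} (clean labels).
#' @param cost,gamma stage-two SVM parameters (defaults 1 and
#'   1/n_features).
#' @param featureType tag recorded in the output rows.
#' @return data.frame of accuracy records (category, roi_combination,
#'   partition, problem, loss, feature_type, accuracy, n_test).
#' @export
runCondition <- function(category, combo, partition, problems, features,
    weights, trainLabels, testLabels, cost = 1, gamma = NULL,
    featureType = "synthetic") {
    xTest <- features[partition$test, , drop = FALSE]
    yTest <- testLabels[partition$test]
    stopifnot2(!anyNA(yTest), "test labels must cover the test set")
    rows <- lapply(problems, function(pb) {
        xTr <- features[pb$ids, , drop = FALSE]
        yTr <- trainLabels[pb$ids]
        out <- lapply(c("hl", "awl"), function(lossType) {
            fit <- trainSVM(xTr, yTr, weights = weights, loss = lossType,
                cost = cost, gamma = gamma)
            acc <- mean(predict(fit, xTest)$label == yTest)
            data.frame(category = category, roi_combination = roiKey(combo),
                partition = partition$index, problem = pb$index,
                loss = lossType, feature_type = featureType,
                accuracy = acc, n_test = length(yTest),
                stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
    })
    do.call(rbind, rows)
}

#' Run the full two-stage experiment over partitions, problems and combos
#'
#' The stage-two harness: for every category, draws stratified train/test
#' partitions of the clear sample set; per partition, min--max-scales the
#' voxel table against the training rows, generates activity weights per ROI
#' combination from the training stimuli only
#' (\code{\link{generateActivityWeights}}), creates balanced problems, and
#' trains/tests paired HL and AWL classifiers
#' (\code{\link{runCondition}}).  With 4 partitions and 5 balanced problems
#' this yields the canonical 20 paired accuracy samples per combination.
#'
#' @param voxels an unscaled \linkS4class{VoxelTable} covering the stimuli.
#' @param labeling a \linkS4class{CategoryLabeling}.
#' @param features feature matrix (stimuli x features).
#' @param categories categories to run (default: all in the labeling).
#' @param combos list of ROI combinations (default: all non-empty subsets of
#'   the ROIs annotated in the table).
#' @param nPartitions,nProblems counts (defaults 4 and 5).
#' @param testFraction held-out fraction per partition (default 0.2).
#' @param gridSpec stage-one \linkS4class{GridSearchSpec}.
#' @param k stage-one folds (default 5).
#' @param cost,gamma stage-two SVM parameters.
#' @param labelNoiseP if positive, training labels receive planted
#'   annotation noise via \code{\link{corruptPositiveLabels}} (test labels
#'   stay clean).
#' @param featureType tag recorded in the output.
#' @param seed master seed; all randomness is derived from it.
#' @return data.frame accuracy table (see \code{\link{runCondition}}).
#' @export
runExperiment <- function(voxels, labeling, features,
    categories = colnames(labeling@fractions), combos = NULL,
    nPartitions = 4L, nProblems = 5L, testFraction = 0.2,
    gridSpec = gridSearchSpec(), k = 5L, cost = 1, gamma = NULL,
    labelNoiseP = 0, featureType = "synthetic", seed = 1L) {
    if (is.null(combos)) {
        rois <- setdiff(unique(voxelROIs(voxels)), "unlabeled")
        combos <- enumerateROICombinations(rois)
    }
    allRows <- list()
    for (category in categories) {
        ids <- intersect(clearSampleSet(labeling, category),
            intersect(stimulusIds(voxels), rownames(features)))
        y <- binaryLabels(labeling, category, ids)
        partitions <- makePartitions(ids, n = nPartitions,
            testFraction = testFraction,
            seed = deriveSeed(seed, "partitions", category), labels = y)
        for (part in partitions) {
            trainLabels <- y[part$train]
            if (labelNoiseP > 0)
                trainLabels <- corruptPositiveLabels(trainLabels,
                    labelNoiseP,
                    seed = deriveSeed(seed, "noise", category, part$index),
                    clarity = clarity(labeling))
            scaled <- minmaxScale(voxels, referenceIds = part$train)
            trainVox <- scaled[, part$train]
            for (ci in seq_along(combos)) {
                combo <- combos[[ci]]
                condSeed <- deriveSeed(seed, category, roiKey(combo),
                    part$index)
                w <- generateActivityWeights(trainVox, labeling, category,
                    combo, spec = gridSpec, k = k, seed = condSeed,
                    labels = trainLabels)
                problems <- makeBalancedProblems(part, labeling, category,
                    n = nProblems, seed = condSeed, labels = trainLabels)
                allRows[[length(allRows) + 1L]] <- runCondition(category,
                    combo, part, problems, features, w,
                    trainLabels = trainLabels, testLabels = y,
                    cost = cost, gamma = gamma, featureType = featureType)
            }
        }
    }
    do.call(rbind, allRows)
}

#' Paired one-tailed t-test for AWL vs HL accuracies
#'
#' Standard paired t-test on the differences \code{accAwl - accHl} with
#' alternative "AWL greater", df = n - 1, pairs matched by
#' (partition, problem).  Zero-variance differences are resolved by
#' convention: p = 0 if the common difference is positive, p = 1 if
#' negative, p = 0.5 if all differences are zero.
#'
#' @param accAwl,accHl paired accuracy vectors of equal length >= 2.
#' @return list with \code{statistic}, \code{p.value}, \code{df}.
#' @examples
#' pairedOneTailedT(c(0.6, 0.7, 0.8), c(0.5, 0.5, 0.5))
#' @export
pairedOneTailedT <- function(accAwl, accHl) {
    stopifnot2(length(accAwl) == length(accHl) && length(accAwl) >= 2,
        "need paired vectors of equal length >= 2")
    d <- accAwl - accHl
    if (sd(d) == 0) {
        p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
        stat <- if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else 0
        return(list(statistic = stat, p.value = p,
            df = length(d) - 1L))
    }
    tt <- t.test(accAwl, accHl, paired = TRUE, alternative = "greater")
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
        df = unname(tt$parameter))
}

#' Mean error reduction from switching HL to AWL
#'
#' The reduction in misclassification error,
#' \eqn{(1 - \mathrm{acc}_{HL}) - (1 - \mathrm{acc}_{AWL})
#'   = \mathrm{acc}_{AWL} - \mathrm{acc}_{HL}}, averaged over paired
#' trials, with its standard error.
#'
#' @param accAwl,accHl paired accuracy vectors.
#' @return list with \code{reduction} and \code{se}.
#' @export
errorReduction <- function(accAwl, accHl) {
    stopifnot2(length(accAwl) == length(accHl) && length(accAwl) >= 1,
        "need paired vectors")
    d <- accAwl - accHl
    list(reduction = mean(d),
        se = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0)
}
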