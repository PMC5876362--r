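#' Construct a grid-search specification
#'
#' @param costGrid candidate soft-margin penalties C (default the coarse log
#'   grid \code{2^seq(-5, 15, 2)}).
#' @param gammaGrid candidate RBF parameters (default \code{2^seq(-15, 3, 2)}).
#' @param innerFolds inner cross-validation folds used to score each grid
#'   point (default 3).
#' @return A \linkS4class{GridSearchSpec}.
#' @export
gridSearchSpec <- function(costGrid = 2^seq(-5, 15, 2),
    gammaGrid = 2^seq(-15, 3, 2), innerFolds = 3L) {
    methods::new("GridSearchSpec", costGrid = as.numeric(costGrid),
        gammaGrid = as.numeric(gammaGrid), innerFolds = as.integer(innerFolds))
}

#' Split ids into k folds
#'
#' Random partition into \code{k} folds whose sizes differ by at most one,
#' deterministic under the seed.  With \code{stratifyBy}, the split is drawn
#' within each class so every fold preserves the class ratio (used for the
#' activity-weight folds to avoid single-class training parts).
#'
#' @param ids character vector, length at least \code{k}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratifyBy optional vector (named by id or aligned with ids) whose
#'   levels are balanced across folds.
#' @return list of \code{k} disjoint character vectors covering \code{ids}.
#' @export
kfoldSplit <- function(ids, k = 5L, seed = 1L, stratifyBy = NULL) {
    stopifnot2(length(ids) >= k, "need at least k ids")
    withLocalSeed(deriveSeed(seed, "kfold", k), {
        assignFolds <- function(v) {
            # cycle fold labels over a shuffled vector: sizes differ by <= 1
            v <- sample(v)
            split(v, rep_len(seq_len(k), length(v)))
        }
        if (is.null(stratifyBy)) {
            folds <- assignFolds(ids)
        } else {
            if (!is.null(names(stratifyBy))) stratifyBy <- stratifyBy[ids]
            parts <- split(ids, stratifyBy)
            # offset fold assignment per class so fold sizes stay balanced
            folds <- rep(list(character(0)), k)
            offset <- 0L
            for (p in parts) {
                p <- sample(p)
                lab <- (seq_along(p) + offset - 1L) %% k + 1L
                for (f in seq_len(k))
                    folds[[f]] <- c(folds[[f]], p[lab == f])
                offset <- (offset + length(p)) %% k
            }
        }
        unname(lapply(folds, as.character))
    })
}

# oriented decision scores from an e1071 svm fit: positive score always
# means the "+1" class, regardless of libsvm's internal class order
svmDecisionScores <- function(fit, newx) {
    pr <- predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    s <- dv[, 1L]
    lab <- colnames(dv)[1L]                       # e.g. "-1/1" or "1/-1"
    if (startsWith(lab, "-1/")) s <- -s
    names(s) <- rownames(newx)
    s
}

#' Fit the stage-one voxel classifier with grid search and calibration
#'
#' Performs an inner cross-validated grid search over (C, gamma) for an
#' RBF-kernel SVM on scaled voxel data, selecting the pair with the highest
#' inner CV accuracy (ties broken toward the smallest C, then the smallest
#' gamma).  The Platt sigmoid is fitted to the inner cross-validated
#' decision scores at the selected grid point, so no training point's
#' calibration target uses a model trained on that point.  The returned
#' model is refitted on all provided rows at the selected parameters.
#'
#' @param trainVoxels numeric matrix (stimuli x voxels) of scaled
#'   amplitudes, or a scaled \linkS4class{VoxelTable}.
#' @param trainLabels named numeric labels in {-1, +1}.
#' @param spec a \linkS4class{GridSearchSpec}.
#' @param seed integer seed driving the inner fold assignment.
#' @return list with elements \code{model} (e1071 svm fit),
#'   \code{calibration} (\linkS4class{PlattCalibration}), \code{cost},
#'   \code{gamma}, \code{cvAccuracy}.
#' @export
fitVoxelClassifier <- function(trainVoxels, trainLabels, spec = gridSearchSpec(),
    seed = 1L) {
    if (methods::is(trainVoxels, "VoxelTable")) {
        stopifnot2(isScaled(trainVoxels), "voxel table must be scaled")
        trainVoxels <- voxelMatrix(trainVoxels)
    }
    x <- as.matrix(trainVoxels)
    y <- trainLabels[rownames(x)]
    stopifnot2(!anyNA(y), "labels must cover all training rows")
    stopifnot2(any(y > 0) && any(y < 0), "both classes must be present")
    methods::validObject(spec)
    folds <- kfoldSplit(rownames(x), k = spec@innerFolds, seed = seed,
        stratifyBy = y)
    grid <- expand.grid(cost = sort(spec@costGrid),
        gamma = sort(spec@gammaGrid))
    fitOne <- function(ids, cost, gamma)
        e1071::svm(x[ids, , drop = FALSE],
            factor(y[ids], levels = c(-1, 1)),
            type = "C-classification", kernel = "radial",
            cost = cost, gamma = gamma, scale = FALSE)
    cvScore <- function(cost, gamma) {
        correct <- 0L
        for (f in folds) {
            tr <- setdiff(rownames(x), f)
            if (!any(y[tr] > 0) || !any(y[tr] < 0)) next
            fit <- fitOne(tr, cost, gamma)
            pred <- sign(svmDecisionScores(fit, x[f, , drop = FALSE]))
            pred[pred == 0] <- 1
            correct <- correct + sum(pred == y[f])
        }
        correct / length(y)
    }
    acc <- mapply(cvScore, grid$cost, grid$gamma)
    # ties -> smallest C then smallest gamma: grid is sorted by gamma-major,
    # so order explicitly
    ord <- order(-acc, grid$cost, grid$gamma)
    best <- grid[ord[1L], ]
    # cross-validated scores at the selected point, for sigmoid fitting
    scores <- numeric(0)
    for (f in folds) {
        tr <- setdiff(rownames(x), f)
        fit <- fitOne(tr, best$cost, best$gamma)
        scores <- c(scores, svmDecisionScores(fit, x[f, , drop = FALSE]))
    }
    scores <- scores[rownames(x)]
    calibration <- fitPlattScaling(scores, y)
    model <- fitOne(rownames(x), best$cost, best$gamma)
    list(model = model, calibration = calibration, cost = best$cost,
        gamma = best$gamma, cvAccuracy = acc[ord[1L]])
}

#' Generate Platt-calibrated activity weights by held-out-fold testing
#'
#' Stage one of the paradigm.  The clear-sample training stimuli are split
#' into \code{k} stratified folds; for each fold, an RBF-SVM voxel
#' classifier is grid-search-tuned and Platt-calibrated on the other
#' \code{k - 1} folds (\code{\link{fitVoxelClassifier}}), then applied to
#' the held-out fold's decision scores to produce that fold's activity
#' weights \eqn{c_x \in [0, 1]}.  The union over folds covers every clear
#' training stimulus exactly once; all other stimuli are absent from the map
#' and therefore carry \eqn{c_x = 0}.
#'
#' @param voxels a scaled \linkS4class{VoxelTable} whose stimuli are the
#'   training rows (test stimuli must not be present; their rows play no
#'   part in weight generation).
#' @param labeling a \linkS4class{CategoryLabeling}.
#' @param category the task's category name.
#' @param combo character vector of ROI names to restrict the voxels to.
#' @param spec a \linkS4class{GridSearchSpec}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param labels optional named labels in {-1, +1} overriding
#'   \code{\link{binaryLabels}} (used to inject annotation noise); must
#'   cover the clear-sample training stimuli.
#' @return An \linkS4class{ActivityWeights}.
#' @export
generateActivityWeights <- function(voxels, labeling, category, combo,
    spec = gridSearchSpec(), k = 5L, seed = 1L, labels = NULL) {
    stopifnot2(isScaled(voxels), "voxel table must be min-max scaled")
    ids <- intersect(stimulusIds(voxels), clearSampleSet(labeling, category))
    stopifnot2(length(ids) >= k,
        "clear sample set too small among the provided stimuli")
    if (is.null(labels)) labels <- binaryLabels(labeling, category, ids)
    y <- labels[ids]
    stopifnot2(!anyNA(y), "labels must cover the clear training stimuli")
    xt <- restrictToROIs(voxels, combo)
    x <- voxelMatrix(xt)[ids, , drop = FALSE]
    folds <- kfoldSplit(ids, k = k, seed = deriveSeed(seed, "aw-folds"),
        stratifyBy = y)
    w <- numeric(0)
    for (f in seq_along(folds)) {
        hold <- folds[[f]]
        tr <- setdiff(ids, hold)
        fit <- fitVoxelClassifier(x[tr, , drop = FALSE], y[tr], spec = spec,
            seed = deriveSeed(seed, "aw-grid", f))
        s <- svmDecisionScores(fit$model, x[hold, , drop = FALSE])
        w <- c(w, plattProbability(fit$calibration, s))
    }
    methods::new("ActivityWeights", weights = w[ids],
        provenance = list(category = category, combo = roiKey(combo),
            k = as.integer(k), seed = as.integer(seed),
            folds = folds))
}

#' Look up activity weights, defaulting to zero
#'
#' @param weights an \linkS4class{ActivityWeights}, a named numeric vector,
#'   or \code{NULL} (all zero).
#' @param ids stimulus ids.
#' @return numeric vector of c_x values, 0 for ids absent from the map.
#' @export
weightFor <- function(weights, ids) {
    w <- if (is.null(weights)) numeric(0)
        else if (methods::is(weights, "ActivityWeights")) weights@weights
        else weights
    out <- stats::setNames(rep(0, length(ids)), ids)
    hit <- intersect(ids, names(w))
    out[hit] <- w[hit]
    out
}

setMethod("show", "ActivityWeights", function(object) {
    w <- object@weights
    cat("ActivityWeights:", length(w), "stimuli",
        if (length(object@provenance))
            sprintf("(category %s, combo %s)", object@provenance$category,
                object@provenance$combo) else "", "\n")
    if (length(w))
        cat(sprintf("  mean c_x = %.3f, range [%.3f, %.3f]\n",
            mean(w), min(w), max(w)))
})
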