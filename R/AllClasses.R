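#' @import methods
#' @importFrom stats predict rnorm runif sd t.test ecdf optim cor
#' @importFrom utils read.delim write.table
NULL

#' VoxelTable: per-stimulus voxel response amplitudes with ROI annotation
#'
#' A \linkS4class{SummarizedExperiment} whose assay holds one response
#' amplitude per voxel (rows) and stimulus (columns).  Each voxel carries a
#' region-of-interest (ROI) annotation in \code{rowData(x)$roi}
#' (\code{"unlabeled"} for voxels outside every named ROI).  The
#' \code{scaled} slot records whether per-voxel min--max scaling has been
#' applied; \code{degenerateVoxels} counts voxels that were constant over the
#' scaling reference rows (these are mapped to 0 everywhere).
#'
#' Most user code sees the table in the stimuli-by-voxels orientation via
#' \code{\link{voxelMatrix}}.
#'
#' @slot scaled logical scalar, TRUE after \code{\link{minmaxScale}}.
#' @slot degenerateVoxels integer, number of constant reference columns.
#'
#' @seealso \code{\link{VoxelTable}}, \code{\link{minmaxScale}},
#'   \code{\link{restrictToROIs}}
#' @export
setClass("VoxelTable",
    contains = "SummarizedExperiment",
    representation(scaled = "logical", degenerateVoxels = "integer"),
    prototype(scaled = FALSE, degenerateVoxels = 0L))

setValidity("VoxelTable", function(object) {
    msg <- NULL
    if (!"roi" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain a 'roi' column")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "stimulus ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "voxel ids must be unique")
    if (length(object@scaled) != 1L)
        msg <- c(msg, "'scaled' must be a logical scalar")
    if (isTRUE(object@scaled)) {
        a <- SummarizedExperiment::assay(object)
        if (length(a) && (min(a) < -1e-9 || max(a) > 1 + 1e-9))
            msg <- c(msg, "scaled table must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-stimulus activity weights
#'
#' Maps stimulus ids to activity weights \eqn{c_x \in [0, 1]}, the Platt
#' probability that the stimulus is a positive class member according to its
#' voxel response pattern.  Stimuli absent from the map implicitly carry
#' \eqn{c_x = 0}, which reduces the activity-weighted loss to a plain hinge
#' loss for those samples.  Only clear-sample training stimuli ever appear.
#'
#' @slot weights named numeric vector in [0, 1].
#' @slot provenance list recording category, ROI combination, fold
#'   assignment and seed.
#' @seealso \code{\link{generateActivityWeights}}, \code{\link{weightFor}}
#' @export
setClass("ActivityWeights",
    representation(weights = "numeric", provenance = "list"),
    prototype(weights = numeric(0), provenance = list()))

setValidity("ActivityWeights", function(object) {
    w <- object@weights
    if (length(w) && (is.null(names(w)) || anyDuplicated(names(w))))
        return("weights must be uniquely named by stimulus id")
    if (length(w) && (min(w) < 0 || max(w) > 1))
        return("all activity weights must lie in [0, 1]")
    TRUE
})

#' Platt sigmoid calibration
#'
#' Parameters of the logistic transformation
#' \eqn{p(f) = 1 / (1 + \exp(A f + B))} that maps SVM decision scores
#' \eqn{f} to class-inclusion probabilities.  Fitted on held-out or
#' cross-validated scores, never on the scores of the points being
#' calibrated.
#'
#' @slot A numeric slope (negative when larger scores mean more positive).
#' @slot B numeric intercept.
#' @seealso \code{\link{fitPlattScaling}}, \code{\link{plattProbability}}
#' @export
setClass("PlattCalibration",
    representation(A = "numeric", B = "numeric"),
    prototype(A = 0, B = 0))

#' Grid-search specification for the stage-one voxel classifier
#'
#' Candidate soft-margin costs and RBF bandwidths, and the number of inner
#' cross-validation folds used to score each grid point.  The default grid is
#' the conventional coarse log-spaced grid
#' \eqn{C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}},
#' \eqn{\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}}.
#'
#' @slot costGrid numeric candidate soft-margin penalties C.
#' @slot gammaGrid numeric candidate RBF parameters gamma.
#' @slot innerFolds integer, folds of the inner CV used for selection.
#' @seealso \code{\link{gridSearchSpec}}, \code{\link{fitVoxelClassifier}}
#' @export
setClass("GridSearchSpec",
    representation(costGrid = "numeric", gammaGrid = "numeric",
        innerFolds = "integer"))

setValidity("GridSearchSpec", function(object) {
    if (!length(object@costGrid) || !length(object@gammaGrid))
        return("cost and gamma candidate lists must be nonempty")
    if (any(object@costGrid <= 0) || any(object@gammaGrid <= 0))
        return("cost and gamma candidates must be positive")
    if (object@innerFolds < 2L)
        return("innerFolds must be at least 2")
    TRUE
})

#' Kernel SVM model with per-sample loss multipliers
#'
#' A trained RBF-kernel support vector machine.  The decision function is
#' \deqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b,}
#' stored through the support vectors and their signed dual coefficients
#' \code{coef}\eqn{{}_i = \alpha_i y_i}.  Training used the per-sample loss
#' multipliers \eqn{m_i = 1 + c_{x_i}} (all 1 under plain hinge loss), which
#' enter the dual as box constraints \eqn{0 \le \alpha_i \le C m_i}.
#'
#' @slot sv numeric matrix of support-vector feature rows.
#' @slot coef numeric, signed dual coefficients (alpha_i * y_i), one per
#'   support vector.
#' @slot bias numeric scalar b.
#' @slot gamma,cost numeric RBF parameter and soft-margin penalty.
#' @slot multipliers named numeric, per-training-sample loss multipliers.
#' @slot svIds character ids of the support vectors.
#' @slot loss character, \code{"hl"} or \code{"awl"}.
#' @slot objective numeric, optimal value of the regularized empirical risk.
#' @slot iterations integer, SMO iterations used.
#' @slot converged logical.
#' @slot tol numeric, KKT violation tolerance used.
#' @seealso \code{\link{trainSVM}}, \code{\link{predict,KernelSVMModel-method}}
#' @export
setClass("KernelSVMModel",
    representation(sv = "matrix", coef = "numeric", bias = "numeric",
        gamma = "numeric", cost = "numeric", multipliers = "numeric",
        svIds = "character", loss = "character", objective = "numeric",
        iterations = "integer", converged = "logical", tol = "numeric"))

setValidity("KernelSVMModel", function(object) {
    if (nrow(object@sv) != length(object@coef))
        return("one dual coefficient per support vector required")
    if (length(object@bias) != 1L)
        return("bias must be scalar")
    if (any(object@multipliers < 1 - 1e-12))
        return("loss multipliers 1 + c_x must be >= 1")
    TRUE
})

#' Null distribution of the fraction-above-mean statistic
#'
#' Monte-Carlo samples of the fraction of a random ROI-combination subset
#' (without replacement, default 64 of 127) whose mean classification
#' accuracy strictly exceeds the overall mean over all combinations.
#'
#' @slot samples numeric fractions in [0, 1].
#' @slot reps integer number of samples drawn.
#' @slot subsetSize integer size of each random subset.
#' @slot seed integer seed used.
#' @seealso \code{\link{sampleNull}}, \code{\link{significanceCall}}
#' @export
setClass("NullDistribution",
    representation(samples = "numeric", reps = "integer",
        subsetSize = "integer", seed = "integer"))

setValidity("NullDistribution", function(object) {
    s <- object@samples
    if (length(s) && (min(s) < 0 || max(s) > 1))
        return("null samples must lie in [0, 1]")
    if (length(s) != object@reps)
        return("reps must equal the number of stored samples")
    TRUE
})

#' Clear-sample category labeling
#'
#' Holds, for every stimulus, the per-category pixel fractions, the
#' tentative-positive category set (categories whose pixel fraction meets the
#' threshold), and the clear flag (tentative-positive for at most one
#' category).  Binary labels for a classification task are defined only on a
#' task's clear sample set: stimuli tentative-positive for exactly that
#' category (y = +1) plus stimuli tentative-positive for no category
#' (y = -1).  Multi-category stimuli belong to no clear set and later receive
#' activity weight 0.
#'
#' @slot fractions numeric matrix, stimuli x categories pixel fractions.
#' @slot tentative list of character vectors, per-stimulus tentative set.
#' @slot clear named logical.
#' @slot threshold numeric pixel-fraction threshold (default 0.2).
#' @seealso \code{\link{assignCategoryLabels}}, \code{\link{clearSampleSet}},
#'   \code{\link{binaryLabels}}
#' @export
setClass("CategoryLabeling",
    representation(fractions = "matrix", tentative = "list",
        clear = "logical", threshold = "numeric"))

setValidity("CategoryLabeling", function(object) {
    n <- nrow(object@fractions)
    if (length(object@tentative) != n || length(object@clear) != n)
        return("tentative and clear must have one entry per stimulus")
    if (any(object@fractions < -1e-12) || any(rowSums(object@fractions) > 1 + 1e-9))
        return("pixel fractions must be nonnegative and sum to <= 1 per stimulus")
    bad <- object@clear & vapply(object@tentative, length, 1L) > 1L
    if (any(bad))
        return("a clear stimulus cannot be tentative-positive for > 1 category")
    TRUE
})
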