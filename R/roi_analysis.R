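#' Per-combination mean accuracies from an accuracy table
#'
#' Averages accuracy over the trials (partitions x balanced problems) of
#' each ROI combination, for one loss type, feature type and category.
#'
#' @param accTable data.frame from \code{\link{runExperiment}}.
#' @param loss,featureType,category optional filters.
#' @return named numeric vector, combination key -> mean accuracy.
#' @export
comboAccuracies <- function(accTable, loss = "awl", featureType = NULL,
    category = NULL) {
    keep <- accTable$loss == loss
    if (!is.null(featureType)) keep <- keep & accTable$feature_type == featureType
    if (!is.null(category)) keep <- keep & accTable$category == category
    sub <- accTable[keep, , drop = FALSE]
    stopifnot2(nrow(sub) > 0, "no matching accuracy records")
    res <- tapply(sub$accuracy, sub$roi_combination, mean)
    stats::setNames(as.numeric(res), names(res))
}

#' Fraction of a combination subset above the overall mean accuracy
#'
#' \eqn{|\{k \in S : \mathrm{acc}(k) > \bar a\}| / |S|}, where \eqn{\bar a}
#' is the mean over \emph{all} combinations in \code{comboAcc} and the
#' inequality is strict (ties count as not-above).
#'
#' @param comboAcc named numeric vector of per-combination mean accuracies
#'   (the full universe, e.g. all 127).
#' @param subset character keys of the subset; must be present and nonempty.
#' @return fraction in [0, 1].
#' @export
fractionAboveMean <- function(comboAcc, subset) {
    stopifnot2(length(subset) > 0, "subset must be nonempty")
    stopifnot2(all(subset %in% names(comboAcc)),
        "subset keys must be present in comboAcc")
    overall <- mean(comboAcc)
    mean(comboAcc[subset] > overall)
}

#' Sample the null distribution of the fraction-above-mean statistic
#'
#' Draws \code{reps} independent uniform random subsets of
#' \code{subsetSize} combinations without replacement and records, for
#' each, the fraction whose mean accuracy strictly exceeds the overall mean
#' over all combinations.  This simulates randomly assigning ROI labels to
#' the combinations, and is the reference distribution against which the
#' observed per-ROI percentage is compared.
#'
#' @param comboAcc named numeric vector of per-combination mean accuracies.
#' @param reps number of null samples (default 1e6).
#' @param subsetSize subset size (default 64, the number of combinations
#'   containing any fixed ROI out of 127).
#' @param seed integer seed.
#' @return A \linkS4class{NullDistribution}.
#' @export
sampleNull <- function(comboAcc, reps = 1000000L, subsetSize = 64L,
    seed = 1L) {
    n <- length(comboAcc)
    stopifnot2(subsetSize <= n, "subsetSize cannot exceed the universe size")
    above <- comboAcc > mean(comboAcc)
    samples <- withLocalSeed(deriveSeed(seed, "null"), {
        vapply(seq_len(reps), function(r)
            mean(above[sample.int(n, subsetSize)]), numeric(1))
    })
    methods::new("NullDistribution", samples = as.numeric(samples),
        reps = as.integer(reps), subsetSize = as.integer(subsetSize),
        seed = as.integer(seed))
}

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf(
        "NullDistribution: %d samples of %d-combination subsets\n",
        object@reps, object@subsetSize))
    if (object@reps > 0)
        cat(sprintf("  mean %.4f, sd %.4f\n", mean(object@samples),
            sd(object@samples)))
})

#' Observed above-average percentage for one ROI
#'
#' The fraction of the combinations containing the given ROI (64 of 127 for
#' a 7-ROI universe) whose mean accuracy strictly exceeds the overall mean
#' over all combinations.
#'
#' @param comboAcc named numeric vector keyed by canonical combination keys
#'   (\code{\link{roiKey}}).
#' @param roi an ROI name present in the universe.
#' @return fraction in [0, 1].
#' @export
roiObservedPercentage <- function(comboAcc, roi) {
    members <- strsplit(names(comboAcc), "+", fixed = TRUE)
    hit <- vapply(members, function(m) roi %in% m, logical(1))
    stopifnot2(any(hit), paste0("ROI not found in any combination: ", roi))
    fractionAboveMean(comboAcc, names(comboAcc)[hit])
}

#' Significance call for an observed percentage against the null
#'
#' Upper-tail empirical p-value \eqn{p = 1 - F_X(\mathrm{observed})}
#' (the plain empirical CDF comparison; optionally the conservative
#' \eqn{(r + 1)/(n + 1)} correction), judged against the
#' Bonferroni-adjusted threshold \eqn{\alpha / m}.  With
#' \eqn{\alpha = 0.05} and \eqn{m = 127} the threshold is 0.0004 at four
#' decimal places.
#'
#' @param observed observed fraction (see
#'   \code{\link{roiObservedPercentage}}).
#' @param null a \linkS4class{NullDistribution}.
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of comparisons (default 127).
#' @param conservative if TRUE, use \eqn{(r + 1)/(n + 1)}.
#' @return list with \code{p.value}, \code{significant}, \code{threshold}.
#' @export
significanceCall <- function(observed, null, alpha = 0.05, m = 127L,
    conservative = FALSE) {
    stopifnot2(null@reps > 0, "null distribution is empty")
    s <- null@samples
    p <- if (conservative) (sum(s >= observed) + 1) / (length(s) + 1)
        else mean(s > observed)
    threshold <- alpha / m
    list(p.value = p, significant = p < threshold, threshold = threshold)
}

#' Per-ROI permutation report
#'
#' Runs \code{\link{roiObservedPercentage}} and
#' \code{\link{significanceCall}} for every ROI of the universe against a
#' single null distribution sampled from the supplied combination
#' accuracies.
#'
#' @param comboAcc named numeric vector of per-combination mean accuracies.
#' @param rois ROI names; default: all names occurring in the keys.
#' @param reps,subsetSize,seed passed to \code{\link{sampleNull}};
#'   \code{subsetSize} defaults to the number of combinations containing a
#'   single ROI, i.e. \code{2^(k - 1)} for a k-ROI universe.
#' @param alpha,m passed to \code{\link{significanceCall}}; \code{m}
#'   defaults to the number of combinations.
#' @return data.frame with one row per ROI: observed percentage, p-value,
#'   threshold, significance flag.
#' @export
roiReport <- function(comboAcc, rois = NULL, reps = 100000L,
    subsetSize = NULL, seed = 1L, alpha = 0.05, m = NULL) {
    members <- strsplit(names(comboAcc), "+", fixed = TRUE)
    if (is.null(rois)) rois <- sort(unique(unlist(members)))
    if (is.null(subsetSize))
        subsetSize <- sum(vapply(members, function(x) rois[1L] %in% x,
            logical(1)))
    if (is.null(m)) m <- length(comboAcc)
    null <- sampleNull(comboAcc, reps = reps, subsetSize = subsetSize,
        seed = seed)
    rows <- lapply(rois, function(r) {
        obs <- roiObservedPercentage(comboAcc, r)
        sig <- significanceCall(obs, null, alpha = alpha, m = m)
        data.frame(roi = r, observed = obs, p.value = sig$p.value,
            threshold = sig$threshold, significant = sig$significant,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
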