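# shared small fixtures, built in code at test time

# coarse grid that keeps stage-one fits cheap in unit tests
tinyGrid <- function() gridSearchSpec(costGrid = c(1, 100),
    gammaGrid = c(0.01, 0.1), innerFolds = 2L)

pilotGrid <- function() gridSearchSpec(costGrid = 2^c(-1, 3, 7),
    gammaGrid = 2^c(-7, -3, 1), innerFolds = 3L)

twoCatConfig <- function(n = 140, seed = 1, voxelsPerRoi = 6, ...) {
    syntheticConfig(nStimuli = n, categories = c("humans", "animals"),
        rois = c("EBA", "PPA"), voxelsPerRoi = voxelsPerRoi,
        mixedFraction = 0.05, backgroundFraction = 0.15, seed = seed, ...)
}

# two well-separated Gaussian blobs as a named feature matrix + labels
separableBlobs <- function(n = 20, d = 3, gap = 6, seed = 1) {
    withr_seed <- seed
    set.seed(withr_seed)
    x <- rbind(matrix(rnorm(n / 2 * d), n / 2, d),
        matrix(rnorm(n / 2 * d, mean = gap), n / 2, d))
    rownames(x) <- sprintf("b%03d", seq_len(n))
    y <- stats::setNames(rep(c(-1, 1), each = n / 2), rownames(x))
    list(x = x, y = y)
}
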