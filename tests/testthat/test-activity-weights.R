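test_that("k-fold split partitions ids with near-equal sizes", {
    f10 <- kfoldSplit(sprintf("s%02d", 1:10), k = 5, seed = 1)
    expect_equal(vapply(f10, length, 1L), rep(2L, 5))
    f11 <- kfoldSplit(sprintf("s%02d", 1:11), k = 5, seed = 1)
    expect_setequal(vapply(f11, length, 1L), c(3L, 2L, 2L, 2L, 2L))
    expect_setequal(unlist(f11), sprintf("s%02d", 1:11))
    expect_identical(kfoldSplit(sprintf("s%02d", 1:11), 5, seed = 3),
        kfoldSplit(sprintf("s%02d", 1:11), 5, seed = 3))
    expect_error(kfoldSplit(c("a", "b"), k = 5), "at least k")
})

test_that("stratified folds preserve the class ratio", {
    ids <- sprintf("s%03d", 1:60)
    y <- stats::setNames(rep(c(1, -1), c(20, 40)), ids)
    folds <- kfoldSplit(ids, k = 5, seed = 2, stratifyBy = y)
    for (f in folds) {
        expect_equal(length(f), 12L)
        expect_equal(sum(y[f] > 0), 4L)
    }
})

test_that("Platt scaling calibrates symmetric scores to 0.5 at zero", {
    scores <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
    labels <- sign(scores)
    cal <- fitPlattScaling(scores, labels)
    expect_lt(cal@A, 0)                       # larger score, larger p
    expect_equal(plattProbability(cal, 0), 0.5, tolerance = 0.05)
    p <- plattProbability(cal, seq(-3, 3, 0.5))
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
    expect_error(fitPlattScaling(1:3, c(1, 1, 1)), "both classes")
})

test_that("grid search finds a separating point on separable voxels", {
    bl <- separableBlobs(n = 24, d = 4, gap = 8, seed = 5)
    x <- bl$x; colnames(x) <- sprintf("v%02d", 1:4)
    fit <- fitVoxelClassifier(x, bl$y, spec = tinyGrid(), seed = 3)
    expect_equal(fit$cvAccuracy, 1)
    expect_true(fit$cost %in% tinyGrid()@costGrid)
    expect_error(fitVoxelClassifier(x, abs(bl$y), spec = tinyGrid()),
        "both classes")
    expect_error(gridSearchSpec(costGrid = numeric(0)), "nonempty")
})

test_that("selective voxels yield higher weights for clear positives", {
    cfg <- twoCatConfig(n = 160, seed = 19, voxelsPerRoi = 10,
        noiseSd = 0.25)
    ds <- simulateDataset(cfg)
    sc <- minmaxScale(ds$voxels)
    w <- generateActivityWeights(sc, ds$labeling, "humans",
        combo = c("EBA", "PPA"), spec = pilotGrid(), seed = 7)
    y <- binaryLabels(ds$labeling, "humans")
    ww <- w@weights
    expect_true(all(ww >= 0 & ww <= 1))
    expect_gt(mean(ww[names(which(y > 0))]), mean(ww[names(which(y < 0))]))
    # every clear stimulus weighted exactly once; non-clear absent
    expect_setequal(names(ww), clearSampleSet(ds$labeling, "humans"))
    mixed <- names(ds$labeling@clear)[!ds$labeling@clear]
    expect_false(any(mixed %in% names(ww)))
    expect_equal(unname(weightFor(w, c(names(ww)[1], "ghost"))[2]), 0)
})

test_that("label-independent voxels give near-chance weights", {
    set.seed(41)
    n <- 120
    ids <- sprintf("s%03d", 1:n)
    amp <- matrix(rnorm(n * 12), n, 12,
        dimnames = list(ids, sprintf("v%02d", 1:12)))
    vt <- minmaxScale(VoxelTable(amp, rep(c("EBA", "PPA"), each = 6)))
    maps <- lapply(seq_len(n), function(i) {
        m <- matrix("background", 10, 10)
        if (i <= n / 2) m[1:5, 1:6] <- "humans"
        m
    })
    names(maps) <- ids
    attr(maps, "vocabulary") <- c("humans", "background")
    lab <- assignCategoryLabels(maps, "humans")
    w <- generateActivityWeights(vt, lab, "humans", c("EBA", "PPA"),
        spec = tinyGrid(), seed = 11)
    y <- binaryLabels(lab, "humans")
    expect_equal(mean(w@weights[names(which(y > 0))]), 0.5, tolerance = 0.12)
    expect_equal(mean(w@weights[names(which(y < 0))]), 0.5, tolerance = 0.12)
})

test_that("a stimulus's row never leaks into its own fold's model", {
    cfg <- twoCatConfig(n = 90, seed = 23)
    ds <- simulateDataset(cfg)
    ids <- stimulusIds(ds$voxels)
    target <- clearSampleSet(ds$labeling, "humans")[1L]
    # scale against a reference that excludes the target, so perturbing the
    # target's row cannot move any other stimulus's scaled values
    ref <- setdiff(ids, target)
    sc1 <- minmaxScale(ds$voxels, ref)
    m2 <- voxelMatrix(ds$voxels)
    m2[target, ] <- m2[target, ] * 0.5 + 0.1
    sc2 <- minmaxScale(VoxelTable(m2, voxelROIs(ds$voxels)), ref)
    v1 <- generateActivityWeights(sc1, ds$labeling, "humans", "EBA",
        spec = tinyGrid(), seed = 13)
    v2 <- generateActivityWeights(sc2, ds$labeling, "humans", "EBA",
        spec = tinyGrid(), seed = 13)
    folds <- v1@provenance$folds
    expect_identical(folds, v2@provenance$folds)   # fold draw is id-driven
    own <- folds[[which(vapply(folds, function(f) target %in% f,
        logical(1)))]]
    # stimuli sharing the target's fold are scored by a model fitted on the
    # other folds, which never saw the target's row: bit-identical weights
    expect_identical(v1@weights[setdiff(own, target)],
        v2@weights[setdiff(own, target)])
    # the target's own weight does move with its row
    expect_false(isTRUE(all.equal(v1@weights[[target]],
        v2@weights[[target]])))
})

test_that("activity weights IO round-trips with provenance", {
    w <- methods::new("ActivityWeights",
        weights = c(a = 0.25, b = 0.75),
        provenance = list(category = "humans", combo = "EBA", k = 5L,
            seed = 3L))
    path <- file.path(withr::local_tempdir(), "aw.tsv")
    writeActivityWeights(w, path)
    back <- readActivityWeights(path)
    expect_equal(back@weights, w@weights, tolerance = 1e-12)
    expect_identical(back@provenance$combo, "EBA")
})
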