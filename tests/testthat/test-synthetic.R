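test_that("generator is a pure function of config and seed", {
    cfg <- twoCatConfig(n = 40, seed = 11)
    a <- simulateDataset(cfg)
    b <- simulateDataset(cfg)
    expect_identical(a$labelMaps, b$labelMaps)
    expect_identical(voxelMatrix(a$voxels), voxelMatrix(b$voxels))
    expect_identical(a$features, b$features)

    cfg2 <- twoCatConfig(n = 40, seed = 12)
    c <- generateStimuli(cfg2)
    expect_false(identical(a$labelMaps, c$labelMaps))
})

test_that("empty and undersized configs are handled", {
    cfg <- twoCatConfig(n = 0)
    sm <- generateStimuli(cfg)
    expect_length(sm$stimuli, 0)
    expect_length(sm$labelMaps, 0)
    expect_error(syntheticConfig(imageSide = 4), "too small")
    expect_error(syntheticConfig(mixedFraction = 1.4), "fractions")
})

test_that("mixed-stimulus fraction matches the configured rate", {
    cfg <- syntheticConfig(nStimuli = 100, mixedFraction = 0.2,
        categories = c("humans", "animals"), seed = 7)
    sm <- generateStimuli(cfg)
    nMixed <- sum(vapply(sm$labelMaps, function(m)
        length(setdiff(unique(as.vector(m)), "background")) >= 2, logical(1)))
    # binomial(100, 0.2): 3 sd ~ 12
    expect_gt(nMixed, 20 - 12)
    expect_lt(nMixed, 20 + 12)
})

test_that("pixel fractions straddle the labeling threshold by construction", {
    cfg <- twoCatConfig(n = 120, seed = 3)
    sm <- generateStimuli(cfg)
    lab <- assignCategoryLabels(sm$labelMaps, cfg$categories)
    fr <- lab@fractions[lab@fractions > 0]
    expect_true(any(fr < 0.2) && any(fr > 0.2))
    # stimuli and maps agree in shape and vocabulary
    expect_true(all(vapply(sm$stimuli, function(s)
        all(dim(s) == cfg$imageSide) && min(s) >= 0 && max(s) <= 1,
        logical(1))))
})

test_that("zero selectivity gives label-indistinguishable voxel means", {
    sel <- matrix(0, 2, 2, dimnames = list(c("EBA", "PPA"),
        c("humans", "animals")))
    cfg <- twoCatConfig(n = 300, seed = 5, selectivity = sel)
    ds <- simulateDataset(cfg)
    y <- binaryLabels(ds$labeling, "humans")
    m <- rowMeans(voxelMatrix(ds$voxels))[names(y)]
    p <- t.test(m[y > 0], m[y < 0])$p.value
    expect_gt(p, 0.001)
})

test_that("noiseless gated voxels show exactly the configured effect", {
    sel <- matrix(c(1.5, 0, 0, 0), 2, 2, dimnames = list(c("EBA", "PPA"),
        c("humans", "animals")))
    cfg <- twoCatConfig(n = 80, seed = 9, selectivity = sel, noiseSd = 0,
        clarityLink = 0)
    ds <- simulateDataset(cfg)
    y <- binaryLabels(ds$labeling, "humans")
    eba <- voxelMatrix(restrictToROIs(ds$voxels, "EBA"))[names(y), 1L]
    expect_equal(unname(min(eba[y > 0]) - max(eba[y < 0])), 1.5,
        tolerance = 1e-12)
    expect_equal(unname(max(eba[y < 0])), 0, tolerance = 1e-12)
})

test_that("clarity raises selective responses when linked", {
    cfg <- twoCatConfig(n = 250, seed = 13, clarityLink = 1)
    ds <- simulateDataset(cfg)
    y <- binaryLabels(ds$labeling, "humans")
    pos <- names(y)[y > 0]
    eba <- rowMeans(voxelMatrix(restrictToROIs(ds$voxels, "EBA")))[pos]
    cl <- clarity(ds$labeling)[pos]
    ct <- cor.test(cl, eba, method = "spearman", exact = FALSE)
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
})

test_that("feature separation controls baseline decodability", {
    runAcc <- function(separation, seed) {
        cfg <- syntheticConfig(nStimuli = 700, separation = separation,
            categories = c("humans", "animals"), rois = "EBA",
            voxelsPerRoi = 2, backgroundFraction = 0.15,
            mixedFraction = 0.05, clarityLink = 0, seed = seed)
        ds <- simulateDataset(cfg)
        y <- binaryLabels(ds$labeling, "humans")
        pos <- names(y)[y > 0]; neg <- names(y)[y < 0]
        set.seed(seed)
        n <- min(length(pos), length(neg))
        pos <- sample(pos, n); neg <- sample(neg, n)
        tr <- c(pos[1:(n %/% 2)], neg[1:(n %/% 2)])
        te <- c(pos[(n %/% 2 + 1):n], neg[(n %/% 2 + 1):n])
        fit <- trainSVM(ds$features[tr, ], y[tr], loss = "hl")
        mean(predict(fit, ds$features[te, ])$label == y[te])
    }
    expect_equal(runAcc(0, 21), 0.5, tolerance = 0.05)
    expect_gt(runAcc(6, 22), 0.9)
    cfg <- twoCatConfig(n = 30, featureDim = 17)
    ds <- simulateDataset(cfg)
    expect_equal(ncol(ds$features), 17L)
})

test_that("annotation noise targets low-clarity negatives and is capped", {
    cfg <- twoCatConfig(n = 260, seed = 31)
    ds <- simulateDataset(cfg)
    y <- binaryLabels(ds$labeling, "humans")
    cl <- clarity(ds$labeling)
    noisy <- corruptPositiveLabels(y, 0.3, seed = 4, clarity = cl)
    corr <- attr(noisy, "corrupted")
    expect_true(all(y[corr] == -1) && all(noisy[corr] == 1))
    # corrupted fraction of the positive set tracks p
    expect_equal(length(corr) / sum(noisy > 0), 0.3, tolerance = 0.05)
    # flips come from the low-clarity side of the negative pool
    negCl <- cl[names(y)[y < 0]]
    expect_lt(mean(cl[corr]), mean(negCl))
    # negatives always remain the majority
    expect_lte(sum(noisy > 0), sum(noisy < 0))
    # p = 0 is the identity
    clean <- corruptPositiveLabels(y, 0, seed = 4, clarity = cl)
    expect_identical(as.numeric(clean), as.numeric(y))
})
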