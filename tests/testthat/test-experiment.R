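test_that("partitions split 80/20, stratified and reproducible", {
    ids <- sprintf("s%03d", 1:100)
    y <- stats::setNames(rep(c(1, -1), c(30, 70)), ids)
    parts <- makePartitions(ids, n = 4, seed = 5, labels = y)
    expect_length(parts, 4L)
    for (p in parts) {
        expect_length(p$test, 20L)
        expect_length(p$train, 80L)
        expect_length(intersect(p$train, p$test), 0L)
        expect_setequal(c(p$train, p$test), ids)
        expect_true(any(y[p$test] > 0) && any(y[p$test] < 0))
    }
    expect_identical(makePartitions(ids, n = 4, seed = 5, labels = y), parts)
    expect_false(identical(parts[[1L]]$test, parts[[2L]]$test))
    expect_error(makePartitions(ids[1:3]), "at least 5")
})

test_that("balanced problems use all positives plus matched negatives", {
    ids <- sprintf("s%03d", 1:40)
    y <- stats::setNames(rep(c(1, -1), c(10, 30)), ids)
    part <- list(train = ids, test = character(0), index = 1L, seed = 1L)
    pbs <- makeBalancedProblems(part, labeling = NULL, category = NULL,
        n = 5, seed = 2, labels = y)
    expect_length(pbs, 5L)
    for (pb in pbs) {
        expect_length(pb$ids, 20L)
        expect_true(all(ids[1:10] %in% pb$ids))          # every positive
        expect_equal(sum(y[pb$ids] > 0), sum(y[pb$ids] < 0))
    }
    negSets <- lapply(pbs, function(pb) sort(setdiff(pb$ids, ids[1:10])))
    expect_gt(length(unique(negSets)), 1L)   # subsets differ w.h.p.
    yBad <- stats::setNames(rep(c(1, -1), c(30, 10)), ids)
    expect_error(makeBalancedProblems(part, NULL, NULL, labels = yBad),
        "exceed")
})

test_that("zero weights make the HL and AWL arms coincide", {
    cfg <- twoCatConfig(n = 90, seed = 29)
    ds <- simulateDataset(cfg)
    ids <- clearSampleSet(ds$labeling, "humans")
    y <- binaryLabels(ds$labeling, "humans")
    part <- makePartitions(ids, n = 1, seed = 3, labels = y)[[1L]]
    pbs <- makeBalancedProblems(part, ds$labeling, "humans", n = 2, seed = 3)
    rows <- runCondition("humans", c("EBA", "PPA"), part, pbs, ds$features,
        weights = NULL, trainLabels = y[part$train], testLabels = y)
    expect_equal(nrow(rows), 4L)             # 2 problems x 2 loss rows
    acc <- split(rows$accuracy, rows$loss)
    expect_equal(acc$awl, acc$hl)
    expect_true(all(rows$accuracy >= 0 & rows$accuracy <= 1))
    expect_true(all(rows$n_test == length(part$test)))
})

test_that("experiment bookkeeping yields paired rows per condition", {
    cfg <- twoCatConfig(n = 110, seed = 37)
    ds <- simulateDataset(cfg)
    acc <- runExperiment(ds$voxels, ds$labeling, ds$features,
        categories = "humans", combos = list(EBA = "EBA"),
        nPartitions = 2L, nProblems = 2L, gridSpec = tinyGrid(),
        seed = 17)
    expect_equal(nrow(acc), 2 * 2 * 2)       # partitions x problems x loss
    counts <- table(acc$loss)
    expect_equal(unname(counts[["hl"]]), 4L)
    expect_equal(unname(counts[["awl"]]), 4L)
    # deterministic under the seed
    acc2 <- runExperiment(ds$voxels, ds$labeling, ds$features,
        categories = "humans", combos = list(EBA = "EBA"),
        nPartitions = 2L, nProblems = 2L, gridSpec = tinyGrid(),
        seed = 17)
    expect_identical(acc, acc2)
})

test_that("paired one-tailed t matches closed-form arithmetic", {
    res <- pairedOneTailedT(c(0.6, 0.7, 0.8), c(0.5, 0.5, 0.5))
    expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
    expect_equal(res$df, 2L)
    # agrees with the reference implementation
    set.seed(1)
    a <- runif(20, 0.5, 0.9); b <- runif(20, 0.5, 0.9)
    res <- pairedOneTailedT(a, b)
    ref <- t.test(a, b, paired = TRUE, alternative = "greater")
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p.value, ref$p.value)
    # zero-variance conventions
    expect_equal(pairedOneTailedT(rep(0.6, 5), rep(0.59, 5))$p.value, 0)
    expect_equal(pairedOneTailedT(rep(0.6, 5), rep(0.61, 5))$p.value, 1)
    same <- pairedOneTailedT(rep(0.6, 5), rep(0.6, 5))
    expect_equal(same$p.value, 0.5)
    expect_equal(same$statistic, 0)
})

test_that("error reduction is the mean paired accuracy difference", {
    expect_equal(errorReduction(c(0.7, 0.8), c(0.7, 0.8))$reduction, 0)
    r <- errorReduction(c(0.75, 0.85), c(0.70, 0.80))
    expect_equal(r$reduction, 0.05)
    expect_equal(r$se, 0)
    set.seed(2)
    a <- runif(20); b <- runif(20)
    r <- errorReduction(a, b)
    expect_equal(r$reduction, mean((1 - b) - (1 - a)))
    expect_equal(r$se, sd(a - b) / sqrt(20))
})

test_that("accuracy table IO round-trips", {
    df <- data.frame(category = "humans", roi_combination = "EBA",
        partition = 1L, problem = 1L, loss = c("hl", "awl"),
        feature_type = "synthetic", accuracy = c(0.7, 0.72), n_test = 20L,
        stringsAsFactors = FALSE)
    path <- file.path(withr::local_tempdir(), "acc.tsv")
    writeAccuracyTable(df, path)
    expect_equal(readAccuracyTable(path), df)
})
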