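test_that("hinge and activity-weighted losses match their definitions", {
    expect_equal(hingeLoss(c(1, 0, -1, 1.5)), c(0, 1, 2, 0))
    expect_equal(awlLoss(0, 1), 2)
    expect_equal(awlLoss(1.5, 0.9), 0)
    expect_equal(awlLoss(-1, 0.9), 2 * 1.9)
    zs <- seq(-3, 3, 0.25)
    expect_equal(awlLoss(zs, 0), hingeLoss(zs))      # c = 0 reduces to HL
    # AWL is the per-sample weighted hinge on both branches
    for (cc in c(0, 0.4, 1))
        expect_equal(awlLoss(zs, cc), (1 + cc) * hingeLoss(zs))
    expect_error(awlLoss(0, -0.1), "nonnegative")
    expect_error(hingeLoss(c(1, NaN)), "finite")
})

test_that("two separable points are classified with unit margins", {
    x <- rbind(a = c(0, 0), b = c(2, 2))
    m <- trainSVM(x, c(a = -1, b = 1), loss = "hl", cost = 100)
    pr <- predict(m, x)
    expect_equal(unname(pr$label), c(-1, 1))
    expect_true(all(abs(pr$decision) >= 1 - 1e-6))
})

test_that("prediction conventions hold", {
    bl <- separableBlobs(n = 16, d = 3, seed = 2)
    m <- trainSVM(bl$x, bl$y, loss = "hl")
    pr <- predict(m, bl$x)
    # support vectors of a separable fit keep their own labels
    expect_equal(pr$label[m@svIds], bl$y[m@svIds])
    # deterministic across calls
    expect_identical(pr$decision, predict(m, bl$x)$decision)
    expect_error(predict(m, bl$x[, 1:2]), "dimension")
    # tie at f = 0 resolves to +1
    zero <- methods::new("KernelSVMModel", sv = matrix(0, 1, 2),
        coef = 0, bias = 0, gamma = 1, cost = 1, multipliers = c(a = 1),
        svIds = "a", loss = "hl", objective = 0, iterations = 0L,
        converged = TRUE, tol = 1e-6)
    expect_equal(unname(predict(zero, matrix(5, 1, 2))$label), 1)
})

test_that("solver objective matches the brute-force primal minimizer", {
    for (seed in 1:10) {
        inst <- randomInstance(seed)
        m <- trainSVM(inst$x, inst$y, weights = inst$c, loss = "awl",
            cost = inst$cost, gamma = inst$gamma)
        po <- svmPrimalObjective(m, inst$x, inst$y)
        oo <- oraclePrimal(inst$x, inst$y, 1 + inst$c, inst$cost,
            inst$gamma)
        expect_lt(abs(po - oo) / max(abs(oo), 1e-8), 1e-4)
    }
})

test_that("all-zero weights reproduce the hinge-loss fit exactly", {
    bl <- separableBlobs(n = 20, d = 3, gap = 2.5, seed = 9)
    zeroW <- stats::setNames(rep(0, 20), rownames(bl$x))
    mh <- trainSVM(bl$x, bl$y, loss = "hl")
    ma <- trainSVM(bl$x, bl$y, weights = zeroW, loss = "awl")
    expect_equal(predict(ma, bl$x)$decision, predict(mh, bl$x)$decision,
        tolerance = 1e-8)
    expect_equal(ma@objective, mh@objective, tolerance = 1e-10)
})

test_that("the dual respects the per-sample boxes 0 <= alpha <= C(1+c)", {
    inst <- randomInstance(42)
    m <- trainSVM(inst$x, inst$y, weights = inst$c, loss = "awl",
        cost = inst$cost, gamma = inst$gamma)
    alpha <- abs(m@coef)
    bound <- inst$cost * (1 + inst$c[m@svIds])
    expect_true(all(alpha <= bound + 1e-9))
    expect_true(all(alpha > 0))
})

test_that("raising a violator's weight does not relax its margin", {
    worse <- 0
    for (seed in 1:15) {
        set.seed(seed + 100)
        n <- 14; d <- 2
        x <- matrix(rnorm(n * d), n, d)
        rownames(x) <- sprintf("s%02d", 1:n)
        y <- stats::setNames(sample(c(-1, 1), n, replace = TRUE), rownames(x))
        while (length(unique(y)) < 2)
            y <- stats::setNames(sample(c(-1, 1), n, TRUE), rownames(x))
        m0 <- trainSVM(x, y, loss = "hl")
        viol <- names(which(y * predict(m0, x)$decision < 1))
        if (!length(viol)) next
        v <- viol[1L]
        w <- stats::setNames(rep(0, n), rownames(x)); w[v] <- 1
        m1 <- trainSVM(x, y, weights = w, loss = "awl")
        h0 <- hingeLoss(y[v] * predict(m0, x[v, , drop = FALSE])$decision)
        h1 <- hingeLoss(y[v] * predict(m1, x[v, , drop = FALSE])$decision)
        if (h1 > h0 + 1e-6) worse <- worse + 1
    }
    expect_lte(worse, 1)   # statistically: upweighting pulls the fit closer
})

test_that("decision function agrees with an independent SVM library", {
    set.seed(7)
    x <- matrix(rnorm(120), 40, 3)
    rownames(x) <- sprintf("s%02d", 1:40)
    y <- sign(x[, 1] + rnorm(40, 0, 0.5)); y[y == 0] <- 1
    names(y) <- rownames(x)
    m <- trainSVM(x, y, loss = "hl", cost = 1)
    fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "radial",
        cost = 1, gamma = 1 / 3, scale = FALSE)
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
    s <- dv[, 1L]
    if (startsWith(colnames(dv)[1L], "-1/")) s <- -s
    f <- predict(m, x)$decision
    expect_gt(cor(f, s), 0.999)
    expect_lt(max(abs(f - s)), 0.01)
})

test_that("model serialization round-trips losslessly", {
    inst <- randomInstance(3)
    m <- trainSVM(inst$x, inst$y, weights = inst$c, loss = "awl")
    path <- file.path(withr::local_tempdir(), "model.json")
    writeSVMModel(m, path)
    back <- readSVMModel(path)
    expect_identical(back@sv, m@sv)
    expect_identical(back@coef, m@coef)
    expect_identical(back@bias, m@bias)
    expect_identical(predict(back, inst$x)$decision,
        predict(m, inst$x)$decision)
})

test_that("degenerate inputs are rejected", {
    x <- matrix(c(0, 1, Inf, 1), 2, 2)
    expect_error(trainSVM(x, c(-1, 1)), "finite")
    x2 <- matrix(rnorm(8), 4, 2)
    expect_error(trainSVM(x2, rep(1, 4)), "both classes")
})

test_that("solver agrees with an interior-point solution of the dual", {
    for (seed in c(5, 23)) {
        inst <- randomInstance(seed)
        K <- oracleRbf(inst$x, inst$x, inst$gamma)
        n <- length(inst$y)
        Q <- (inst$y %o% inst$y) * K
        sol <- kernlab::ipop(c = rep(-1, n), H = Q,
            A = matrix(inst$y, 1), b = 0, l = rep(0, n),
            u = inst$cost * (1 + inst$c), r = 0, sigf = 9)
        alpha <- kernlab::primal(sol)
        dualObj <- sum(alpha) - 0.5 * as.numeric(t(alpha) %*% Q %*% alpha)
        m <- trainSVM(inst$x, inst$y, weights = inst$c, loss = "awl",
            cost = inst$cost, gamma = inst$gamma)
        expect_equal(m@objective, dualObj, tolerance = 1e-6)
    }
})
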