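# Brute-force kernelized-primal minimizer, independent of the SMO path.
# Minimizes 0.5 b'Kb + C sum m_i hinge(1 - y f) over (b, bias) by BFGS on a
# Huber-smoothed hinge with a decreasing smoothing schedule, then reports
# the exact (nonsmooth) objective at the smoothed optimum.  The residual
# smoothing bias is bounded by C * sum(m) * delta / 2 with delta = 1e-6.
oracleRbf <- function(x, z, gamma) {
    d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
    d2[d2 < 0] <- 0
    exp(-gamma * d2)
}

oraclePrimal <- function(X, y, mult, cost, gamma) {
    K <- oracleRbf(X, X, gamma)
    n <- length(y)
    sfun <- function(u, d) ifelse(u <= 0, 0, ifelse(u >= d, u - d / 2,
        u^2 / (2 * d)))
    sgrad <- function(u, d) ifelse(u <= 0, 0, ifelse(u >= d, 1, u / d))
    par <- rep(0, n + 1)
    for (d in c(1e-1, 1e-3, 1e-6)) {
        obj <- function(p) {
            b <- p[1:n]; f <- K %*% b + p[n + 1]; u <- 1 - y * f
            0.5 * sum(b * (K %*% b)) + cost * sum(mult * sfun(u, d))
        }
        gr <- function(p) {
            b <- p[1:n]; f <- K %*% b + p[n + 1]; u <- 1 - y * f
            sp <- cost * mult * sgrad(u, d)
            c(as.numeric(K %*% b - K %*% (y * sp)), -sum(y * sp))
        }
        par <- stats::optim(par, obj, gr, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-14))$par
    }
    b <- par[1:n]; f <- K %*% b + par[n + 1]
    0.5 * sum(b * (K %*% b)) + cost * sum(mult * pmax(0, 1 - y * f))
}

# random small weighted instance for solver audits
randomInstance <- function(seed) {
    set.seed(seed)
    n <- sample(6:20, 1); d <- sample(2:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    rownames(X) <- sprintf("s%02d", seq_len(n))
    y <- sample(c(-1, 1), n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
    names(y) <- rownames(X)
    cx <- stats::setNames(round(runif(n), 3), rownames(X))
    cx[sample(n, n %/% 3)] <- 0
    list(x = X, y = y, c = cx, cost = sample(c(0.5, 1, 2), 1), gamma = 1 / d)
}
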