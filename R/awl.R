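#' Hinge loss
#'
#' \eqn{\varphi_h(z) = \max(0, 1 - z)} where \eqn{z = y f(x)} measures the
#' correctness of a prediction.
#'
#' @param z numeric margin values.
#' @return nonnegative loss values.
#' @export
hingeLoss <- function(z) {
    stopifnot2(all(is.finite(z)), "margin values must be finite")
    pmax(0, 1 - z)
}

#' Activity-weighted loss
#'
#' \deqn{\varphi_\psi(x, z) = \max(0, (1 - z) \cdot M(x, z)),\qquad
#'   M(x, z) = \cases{1 + c_x & if z < 1 \cr 1 & otherwise,}}
#' a hinge loss whose penalty is multiplied by \eqn{1 + c_x} for
#' margin-violating samples, with \eqn{c_x \ge 0} an activity weight derived
#' from fMRI data.  \code{c = 0} recovers the plain hinge loss, so samples
#' without neural evidence are penalized conventionally.
#'
#' @param z numeric margin values.
#' @param c activity weights, nonnegative, recycled against \code{z}.
#' @return nonnegative loss values.
#' @examples
#' awlLoss(0, 1)    # 2: (1 - 0) * (1 + 1)
#' awlLoss(1.5, 0.9)  # 0: margin satisfied
#' @export
awlLoss <- function(z, c) {
    stopifnot2(all(is.finite(z)), "margin values must be finite")
    stopifnot2(all(c >= 0), "activity weights must be nonnegative")
    M <- ifelse(z < 1, 1 + c, 1)
    pmax(0, (1 - z) * M)
}

# SMO dual solver for the per-sample box-constrained C-SVM:
#   min_a 0.5 a' Q a - e' a   s.t.  y' a = 0,  0 <= a_i <= upper_i
# with Q_ij = y_i y_j K_ij.  Second-order working-set selection (the libsvm
# WSS2 rule); deterministic for fixed inputs.
smoSolve <- function(K, y, upper, tol = 1e-6, maxIter = 100000L) {
    n <- length(y)
    alpha <- numeric(n)
    G <- rep(-1, n)                   # gradient of the dual at alpha = 0
    Kd <- diag(K)
    eps <- 1e-12
    it <- 0L
    converged <- FALSE
    while (it < maxIter) {
        it <- it + 1L
        yg <- -y * G
        up <- (y > 0 & alpha < upper - eps) | (y < 0 & alpha > eps)
        lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < upper - eps)
        if (!any(up) || !any(lo)) { converged <- TRUE; break }
        i <- which(up)[which.max(yg[up])]
        m <- yg[i]
        M <- min(yg[lo])
        if (m - M <= tol) { converged <- TRUE; break }
        # second-order choice of j among violators
        cand <- which(lo & yg < m - eps)
        if (!length(cand)) { converged <- TRUE; break }
        aij <- pmax(Kd[i] + Kd[cand] - 2 * K[i, cand], eps)
        gain <- (m - yg[cand])^2 / aij
        cand <- cand[order(-gain)]
        progressed <- FALSE
        for (j in cand) {
            # two-variable analytic update (alpha_j is "alpha_2")
            s <- y[i] * y[j]
            fi <- y[i] * (G[i] + 1)   # f(x_i) - b
            fj <- y[j] * (G[j] + 1)
            Ei <- fi - y[i]; Ej <- fj - y[j]
            eta <- max(Kd[i] + Kd[j] - 2 * K[i, j], eps)
            ajNew <- alpha[j] + y[j] * (Ei - Ej) / eta
            if (s < 0) {
                L <- max(0, alpha[j] - alpha[i])
                H <- min(upper[j], upper[i] + alpha[j] - alpha[i])
            } else {
                L <- max(0, alpha[i] + alpha[j] - upper[i])
                H <- min(upper[j], alpha[i] + alpha[j])
            }
            ajNew <- min(max(ajNew, L), H)
            dj <- ajNew - alpha[j]
            if (abs(dj) < 1e-14) next   # pair blocked at its box; try next j
            di <- -s * dj
            alpha[i] <- alpha[i] + di
            alpha[j] <- ajNew
            G <- G + (y * K[, i] * y[i]) * di + (y * K[, j] * y[j]) * dj
            progressed <- TRUE
            break
        }
        if (!progressed) { converged <- TRUE; break }
    }
    yg <- -y * G
    up <- (y > 0 & alpha < upper - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < upper - eps)
    free <- alpha > eps & alpha < upper - eps
    b <- if (any(free)) mean(yg[free])
        else (max(yg[up], -Inf) + min(yg[lo], Inf)) / 2
    if (!is.finite(b)) b <- 0
    dual <- 0.5 * sum(alpha * (G - 1))
    list(alpha = alpha, b = b, iterations = it, converged = converged,
        objective = -dual)
}

#' Train a kernel SVM under hinge or activity-weighted loss
#'
#' Minimizes the regularized empirical risk
#' \deqn{\tfrac12 \lVert w \rVert^2 + C \sum_i \varphi_\psi(x_i, z_i)}
#' with an RBF kernel.  Because
#' \eqn{\varphi_\psi(x, z) = (1 + c_x)\,\varphi_h(z)} for every \eqn{z},
#' the activity-weighted loss is exactly a per-sample-weighted hinge loss,
#' and the problem reduces to a standard SVM dual with per-sample box
#' constraints \eqn{0 \le \alpha_i \le C (1 + c_{x_i})}.  That dual is
#' solved by a deterministic SMO decomposition with second-order working-set
#' selection.  Under \code{loss = "hl"}, or when every weight is zero, all
#' multipliers are 1 and the fit coincides with a plain hinge-loss SVM.
#'
#' @param features numeric matrix (samples x features) with rownames =
#'   stimulus ids.
#' @param labels labels in {-1, +1}, named by id or aligned with rows.
#' @param weights an \linkS4class{ActivityWeights}, a named numeric vector
#'   of c_x values, or \code{NULL}; ids absent from the map get c_x = 0.
#'   Ignored under \code{loss = "hl"}.
#' @param loss \code{"hl"} or \code{"awl"}.
#' @param cost soft-margin penalty C (default 1, the no-tuning stage-two
#'   setting).
#' @param gamma RBF parameter; default \code{1/ncol(features)}.
#' @param tol KKT violation tolerance of the SMO stopping rule.
#' @param maxIter SMO iteration cap; exceeding it is an error.
#' @return A \linkS4class{KernelSVMModel}.
#' @examples
#' x <- rbind(a = c(0, 0), b = c(2, 2))
#' m <- trainSVM(x, c(a = -1, b = 1), loss = "hl")
#' predict(m, x)$label
#' @export
trainSVM <- function(features, labels, weights = NULL,
    loss = c("hl", "awl"), cost = 1, gamma = NULL, tol = 1e-6,
    maxIter = 100000L) {
    loss <- match.arg(loss)
    x <- as.matrix(features)
    stopifnot2(all(is.finite(x)), "features must be finite")
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("row%04d", seq_len(nrow(x)))
    y <- if (!is.null(names(labels))) labels[rownames(x)] else labels
    y <- as.numeric(y)
    stopifnot2(!anyNA(y) && all(y %in% c(-1, 1)),
        "labels must be -1/+1 and cover all rows")
    stopifnot2(any(y > 0) && any(y < 0), "both classes must be present")
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    cvec <- if (loss == "hl") rep(0, nrow(x))
        else weightFor(weights, rownames(x))
    stopifnot2(all(cvec >= 0), "activity weights must be nonnegative")
    mult <- 1 + cvec
    K <- rbfKernel(x, x, gamma)
    sol <- smoSolve(K, y, upper = cost * mult, tol = tol,
        maxIter = as.integer(maxIter))
    if (!sol$converged)
        stop("SMO did not converge within ", maxIter, " iterations ",
            sprintf("(final objective %.6g)", sol$objective), call. = FALSE)
    svIdx <- which(sol$alpha > 1e-12)
    methods::new("KernelSVMModel",
        sv = x[svIdx, , drop = FALSE],
        coef = sol$alpha[svIdx] * y[svIdx],
        bias = sol$b, gamma = gamma, cost = cost,
        multipliers = stats::setNames(mult, rownames(x)),
        svIds = rownames(x)[svIdx], loss = loss,
        objective = sol$objective, iterations = sol$iterations,
        converged = sol$converged, tol = tol)
}

#' Predict with a trained kernel SVM
#'
#' Returns decision scores \eqn{f(x)} and hard labels
#' \eqn{\mathrm{sign}(f(x))}, with the tie at exactly 0 resolved to +1.
#'
#' @param object a \linkS4class{KernelSVMModel}.
#' @param newdata numeric matrix whose columns match the training features.
#' @param ... unused.
#' @return list with numeric \code{decision} and \code{label} vectors,
#'   named by row.
#' @export
setMethod("predict", "KernelSVMModel", function(object, newdata, ...) {
    x <- as.matrix(newdata)
    stopifnot2(ncol(x) == ncol(object@sv),
        "feature dimension mismatch with training data")
    f <- as.numeric(rbfKernel(x, object@sv, object@gamma) %*% object@coef) +
        object@bias
    lab <- ifelse(f >= 0, 1, -1)
    names(f) <- names(lab) <- rownames(x)
    list(decision = f, label = lab)
})

#' Primal objective of a trained model on its training set
#'
#' Evaluates \eqn{\tfrac12 \lVert w \rVert^2 + C \sum_i m_i \varphi_h(z_i)}
#' for a fitted model against a training set; used to audit solver
#' optimality against independent minimizers.
#'
#' @param model a \linkS4class{KernelSVMModel}.
#' @param features training feature matrix (samples x features).
#' @param labels labels in {-1, +1}, named or aligned.
#' @return numeric scalar objective value.
#' @export
svmPrimalObjective <- function(model, features, labels) {
    x <- as.matrix(features)
    y <- if (!is.null(names(labels))) labels[rownames(x)] else labels
    Ksv <- rbfKernel(model@sv, model@sv, model@gamma)
    wnorm2 <- as.numeric(t(model@coef) %*% Ksv %*% model@coef)
    f <- predict(model, x)$decision
    mult <- model@multipliers[rownames(x)]
    if (anyNA(mult)) mult <- rep(1, nrow(x))
    0.5 * wnorm2 + model@cost * sum(mult * hingeLoss(as.numeric(y) * f))
}

setMethod("show", "KernelSVMModel", function(object) {
    cat(sprintf(
        "KernelSVMModel (%s loss): %d support vectors, gamma = %.4g, C = %.4g\n",
        object@loss, nrow(object@sv), object@gamma, object@cost))
    cat(sprintf("  objective %.6g after %d SMO iterations (converged: %s)\n",
        object@objective, object@iterations, object@converged))
})
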