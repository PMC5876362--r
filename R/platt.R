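#' Fit a Platt sigmoid to decision scores
#'
#' Fits \eqn{p(f) = 1 / (1 + \exp(A f + B))} to held-out or cross-validated
#' decision scores by regularized maximum likelihood, using the standard
#' shifted targets \eqn{t_+ = (n_+ + 1)/(n_+ + 2)}, \eqn{t_- = 1/(n_- + 2)}
#' and a damped Newton iteration with backtracking line search.  The scores
#' must come from models that were not trained on the scored points.
#'
#' @param scores numeric decision scores, oriented so larger means more
#'   positive.
#' @param labels numeric labels in {-1, +1}, same length as scores.
#' @param maxIter Newton iteration cap.
#' @return A \linkS4class{PlattCalibration}.
#' @references Platt (1999); Lin, Lin and Weng (2007) give the numerically
#'   stable formulation used here.
#' @export
fitPlattScaling <- function(scores, labels, maxIter = 100L) {
    stopifnot2(length(scores) == length(labels) && length(scores) > 0,
        "scores and labels must be nonempty and equal length")
    stopifnot2(any(labels > 0) && any(labels < 0),
        "both classes required to fit a sigmoid")
    n1 <- sum(labels > 0); n0 <- sum(labels < 0)
    t <- ifelse(labels > 0, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
    minStep <- 1e-10; sigma <- 1e-12
    A <- 0; B <- log((n0 + 1) / (n1 + 1))
    fun <- function(A, B) {
        fApB <- scores * A + B
        sum(ifelse(fApB >= 0,
            t * fApB + log1p(exp(-fApB)),
            (t - 1) * fApB + log1p(exp(fApB))))
    }
    fval <- fun(A, B)
    for (it in seq_len(maxIter)) {
        fApB <- scores * A + B
        p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
            1 / (1 + exp(fApB)))
        q <- 1 - p
        d1 <- t - p
        d2 <- p * q
        g1 <- sum(scores * d1); g2 <- sum(d1)
        if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
        h11 <- sigma + sum(scores^2 * d2)
        h22 <- sigma + sum(d2)
        h21 <- sum(scores * d2)
        det <- h11 * h22 - h21^2
        dA <- -(h22 * g1 - h21 * g2) / det
        dB <- -(-h21 * g1 + h11 * g2) / det
        gd <- g1 * dA + g2 * dB
        stepsize <- 1
        repeat {
            if (stepsize < minStep) {
                warning("Platt line search failed", call. = FALSE)
                stepsize <- 0
                break
            }
            newA <- A + stepsize * dA; newB <- B + stepsize * dB
            newf <- fun(newA, newB)
            if (newf < fval + 1e-4 * stepsize * gd) {
                A <- newA; B <- newB; fval <- newf
                break
            }
            stepsize <- stepsize / 2
        }
        if (stepsize == 0) break
    }
    methods::new("PlattCalibration", A = A, B = B)
}

#' Apply a Platt calibration to decision scores
#'
#' @param calibration a \linkS4class{PlattCalibration}.
#' @param scores numeric decision scores.
#' @return probabilities in [0, 1].
#' @export
plattProbability <- function(calibration, scores) {
    fApB <- scores * calibration@A + calibration@B
    ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

setMethod("show", "PlattCalibration", function(object) {
    cat(sprintf("PlattCalibration: p(f) = 1 / (1 + exp(%.4g f + %.4g))\n",
        object@A, object@B))
})
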