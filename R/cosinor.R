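#' Cosinor regression at a fixed period
#'
#' Least-squares fit of \deqn{y = M + A \cos(2\pi (t - \phi)/T)} via the
#' linear parameterisation \eqn{M + \beta_c \cos\omega t + \beta_s \sin
#' \omega t}, with \eqn{A = \sqrt{\beta_c^2 + \beta_s^2} \ge 0} and the
#' acrophase \eqn{\phi} normalised to [0, T). The peak-to-trough fold change
#' is \eqn{(M+A)/(M-A)} when the fitted trough is positive, otherwise NA.
#' \code{r_squared} is the fraction of variance explained by the rhythmic
#' fit.
#'
#' @param values numeric series, one value per column.
#' @param times times in hours, one per column (replicated times allowed).
#' @param period_h fit period in hours.
#' @return a list with \code{mesor}, \code{amplitude}, \code{phase_h},
#'   \code{r_squared}, \code{fold_change}.
#' @examples
#' t <- seq(0, 46, by = 2)
#' y <- 10 + 3 * cos(2 * pi * (t - 6) / 24)
#' cosinorFit(y, t, 24)  # recovers mesor 10, amplitude 3, phase 6
#' @export
cosinorFit <- function(values, times, period_h) {
    if (length(values) != length(times))
        stop("values and times must have equal length")
    if (length(unique(times)) < 3L)
        stop("cosinor fit needs at least 3 distinct timepoints")
    w <- 2 * pi / period_h
    X <- cbind(1, cos(w * times), sin(w * times))
    if (qr(X)$rank < 3L)
        stop(sprintf(
            "degenerate design: sampling times collapse modulo the %g h period",
            period_h))
    beta <- qr.coef(qr(X), values)
    mesor <- beta[1]
    A <- sqrt(beta[2]^2 + beta[3]^2)
    phase <- if (A > 0) (atan2(beta[3], beta[2]) / w) %% period_h else NA_real_
    fitted <- X %*% beta
    tss <- sum((values - mean(values))^2)
    r2 <- if (tss > 0) 1 - sum((values - fitted)^2) / tss else 0
    fc <- if (mesor - A > 0) (mesor + A) / (mesor - A) else NA_real_
    list(mesor = unname(mesor), amplitude = unname(A),
        phase_h = unname(phase), r_squared = max(0, r2), fold_change = fc)
}

# vectorised cosinor across many series sharing one design (rows of Y)
.cosinorMatrix <- function(Y, times, period_h) {
    w <- 2 * pi / period_h
    X <- cbind(1, cos(w * times), sin(w * times))
    B <- solve(crossprod(X), crossprod(X, t(Y)))  # 3 x nseries
    mesor <- B[1, ]
    A <- sqrt(B[2, ]^2 + B[3, ]^2)
    phase <- (atan2(B[3, ], B[2, ]) / w) %% period_h
    phase[A == 0] <- NA_real_
    res <- t(Y) - X %*% B
    tss <- rowSums((Y - rowMeans(Y))^2)
    r2 <- ifelse(tss > 0, pmax(0, 1 - colSums(res^2) / tss), 0)
    fc <- ifelse(mesor - A > 0, (mesor + A) / (mesor - A), NA_real_)
    list(mesor = mesor, amplitude = A, phase_h = phase, r_squared = r2,
        fold_change = fc)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (via \code{stats::p.adjust}),
#' order-preserving and capped at 1. The FDR should accompany any reported
#' count of rhythmic series.
#'
#' @param p_list p-values in (0, 1].
#' @return adjusted q-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p_list) {
    p <- as.numeric(p_list)
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
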