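#' Tie-aware Kendall S statistic against a reference template
#'
#' \eqn{S = \sum_{(i,j)} \mathrm{sign}(y_j - y_i)\,
#' \mathrm{sign}(r_j - r_i)} over all column pairs whose template ranks
#' \eqn{r} fall in distinct tie groups; pairs tied in the data contribute 0.
#' With n untied columns and a fully concordant series, S = n(n-1)/2.
#'
#' @param values numeric series, one value per grid column.
#' @param template a \linkS4class{ReferenceTemplate} of equal length.
#' @return integer S.
#' @examples
#' g <- buildTimeGrid(24, 4)
#' tpl <- referenceTemplate(g, 24, 0)
#' kendallS(tpl@template_values, tpl)  # perfectly concordant
#' @export
kendallS <- function(values, template) {
    stopifnot(is(template, "ReferenceTemplate"))
    g <- template@tie_groups
    if (length(values) != length(g))
        stop(sprintf("series has %d values but the template has %d columns",
            length(values), length(g)))
    pr <- .columnPairs(length(g))
    sum(sign(values[pr$j] - values[pr$i]) * sign(g[pr$j] - g[pr$i]))
}

.columnPairs <- function(n) {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    list(i = idx[, 1], j = idx[, 2])
}

# polynomial (probability-vector) convolution, exact in double arithmetic
.convp <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (k in seq_along(b)) {
        span <- k:(k + length(a) - 1L)
        out[span] <- out[span] + a * b[k]
    }
    out
}

# coefficients of the Gaussian binomial [a+b, a]_q via
# f(a,b) = f(a-1,b) + q^a f(a,b-1); counts partitions in an a x b box,
# i.e. cross-block inversions when interleaving a new elements into b old.
.qbinomialCoef <- function(a, b) {
    polys <- rep(list(1), a + 1L)
    for (bb in seq_len(b)) {
        newp <- vector("list", a + 1L)
        newp[[1L]] <- 1
        for (aa in seq_len(a)) {
            p1 <- newp[[aa]]
            p2 <- polys[[aa + 1L]]
            n1 <- length(p1); n2 <- length(p2) + aa
            out <- numeric(max(n1, n2))
            out[seq_len(n1)] <- p1
            out[(aa + 1L):n2] <- out[(aa + 1L):n2] + p2
            newp[[aa + 1L]] <- out
        }
        polys <- newp
    }
    polys[[a + 1L]]
}

.nullCache <- new.env(parent = emptyenv())

#' Exact null distribution of S for a tie signature
#'
#' Under the null, all orderings of the (distinct, continuous) data values
#' are equally likely. Writing D for the number of cross-group inversions,
#' S = M - 2D with M the number of cross-group pairs, and the distribution
#' of D is built by convolving, group by group, the inversion-count
#' distribution of a uniformly random interleaving of each new tie group
#' into the columns already placed (a Gaussian-binomial generating
#' function). Results are cached by tie signature.
#'
#' @param tie_group_sizes positive integer tie-group sizes; their sum is the
#'   number of columns (capped at 200).
#' @return a \linkS4class{NullDistribution}.
#' @examples
#' exactNullS(c(1, 1))        # S = -1 or +1, each 1/2
#' exactNullS(c(2, 4, 4, 2))  # 48 h @ 4 h grid vs a 24 h template
#' @export
exactNullS <- function(tie_group_sizes) {
    sizes <- as.integer(tie_group_sizes)
    if (any(sizes < 1L)) stop("tie-group sizes must be positive")
    n <- sum(sizes)
    if (n > 200L)
        stop(sprintf(
            "capacity error: %d columns exceed the exact-null cap of 200", n))
    sig <- sort(sizes)
    key <- paste(sig, collapse = ",")
    hit <- get0(key, envir = .nullCache)
    if (!is.null(hit)) return(hit)
    p <- 1
    m <- 0L
    for (t in sizes) {
        if (m > 0L) {
            q <- .qbinomialCoef(t, m)
            p <- .convp(p, q / sum(q))
        }
        m <- m + t
    }
    M <- length(p) - 1L
    obj <- new("NullDistribution",
        support = as.integer(M - 2L * (0:M)),  # decreasing: M, M-2, ..., -M
        probabilities = p, tie_signature = sig)
    assign(key, obj, envir = .nullCache)
    obj
}

#' Exact tail probability of an observed S
#'
#' @param S observed statistic (vectorised).
#' @param null a \linkS4class{NullDistribution}.
#' @param tail \code{"two.sided"} gives \eqn{P(|S_0| \ge |S|)} (1 when
#'   S = 0); \code{"upper"} gives \eqn{P(S_0 \ge S)}.
#' @return numeric p-values in (0, 1].
#' @export
pKendallS <- function(S, null, tail = c("two.sided", "upper")) {
    tail <- match.arg(tail)
    M <- max(null@support)
    cdfD <- cumsum(null@probabilities)  # P(D <= d), S = M - 2D
    if (tail == "upper") {
        d <- pmin(floor((M - S) / 2), M)
        ifelse(d < 0, 0, cdfD[pmax(d, 0) + 1L])
    } else {
        s0 <- abs(S)
        d <- pmin(floor((M - s0) / 2), M)
        ifelse(s0 == 0, 1, pmin(1, 2 * ifelse(d < 0, 0, cdfD[pmax(d, 0) + 1L])))
    }
}
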