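# independent brute-force oracles used against the analytic implementations

# all permutations of 1:n (n small)
allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    p <- allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
        cbind(k, p + (p >= k))))
}

# S for one data ordering against template groups g (pairs tied in the
# template skipped), by direct pair enumeration
bruteS <- function(values, g) {
    n <- length(values)
    s <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        if (g[i] != g[j])
            s <- s + sign(values[j] - values[i]) * sign(g[j] - g[i])
    s
}

# exact distribution of S for tie-group sizes by full enumeration of all
# n! orderings of distinct data values
bruteNullS <- function(sizes) {
    n <- sum(sizes)
    g <- rep(seq_along(sizes), sizes)
    perms <- allPerms(n)
    s <- apply(perms, 1L, bruteS, g = g)
    tab <- table(s) / nrow(perms)
    list(support = as.integer(names(tab)), prob = as.numeric(tab))
}

# all partitions of n (tie signatures), largest part first
allPartitions <- function(n, max_part = n) {
    if (n == 0L) return(list(integer()))
    out <- list()
    for (k in seq(min(n, max_part), 1L))
        for (p in allPartitions(n - k, k))
            out <- c(out, list(c(k, p)))
    out
}

# step-up FDR oracle, written out directly
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    q[o] <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, q)
}

smallConfig <- function(...) {
    simulationConfig(n_series = 20, seed = 42, ...)
}
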