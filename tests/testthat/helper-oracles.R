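# Independent brute-force oracles used to cross-check the implementation.
# These are written as plain loops / closed forms on purpose and must not
# call package internals.

oracle_size_factors <- function(k) {
    keep <- apply(k, 1L, function(r) all(r > 0))
    kk <- k[keep, , drop = FALSE]
    m <- ncol(kk)
    sf <- numeric(m)
    for (j in seq_len(m)) {
        ratios <- numeric(nrow(kk))
        for (g in seq_len(nrow(kk)))
            ratios[g] <- kk[g, j] / prod(kk[g, ])^(1 / m)
        sf[j] <- median(ratios)
    }
    sf
}

oracle_ols <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    intercept <- (sy - slope * sx) / n
    r <- (n * sxy - sx * sy) /
        sqrt((n * sxx - sx^2) * (n * syy - sy^2))
    list(slope = slope, intercept = intercept, r = r)
}

# walk every position; ATG then codon steps until a stop fits entirely in
# the leader, else overlapping
oracle_scan_uorfs <- function(seq) {
    seq <- chartr("U", "T", toupper(seq))
    L <- nchar(seq)
    stops <- c("TAA", "TAG", "TGA")
    out <- list()
    i <- 1L
    while (i + 2L <= L) {
        if (substr(seq, i, i + 2L) == "ATG") {
            p <- i
            kind <- "overlapping"
            ncod <- NA_integer_
            while (p + 2L <= L) {
                cod <- substr(seq, p, p + 2L)
                if (cod %in% stops) {
                    kind <- "upstream"
                    ncod <- (p - i) %/% 3L + 1L
                    break
                }
                p <- p + 3L
            }
            out[[length(out) + 1L]] <-
                data.frame(start = i - 1L, n_codons = ncod, kind = kind,
                           stringsAsFactors = FALSE)
        }
        i <- i + 1L
    }
    if (!length(out))
        return(data.frame(start = integer(), n_codons = integer(),
                          kind = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

oracle_binom_two_sided <- function(k, n, p0) {
    pmf <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                  numeric(1))
    min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
}

oracle_hyper_upper <- function(k, K, N, n) {
    lo <- max(0L, n - (N - K))
    hi <- min(n, K)
    tot <- 0
    for (i in seq(lo, hi))
        if (i >= k) tot <- tot + choose(K, i) * choose(N - K, n - i)
    tot / choose(N, n)
}

random_dna <- function(n, with_n = FALSE) {
    alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    paste(sample(alph, n, replace = TRUE), collapse = "")
}

# small strictly positive count fixture
random_pos_counts <- function(n_genes = 50L, n_samples = 4L) {
    k <- matrix(rpois(n_genes * n_samples, 100) + 1L, n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    k
}
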