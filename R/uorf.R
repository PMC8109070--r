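#' @importFrom stats dbinom
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a 5' leader for ATG-dependent uORFs
#'
#' Every ATG in the leader is examined. Reading in frame from that ATG,
#' the first in-frame stop codon (TAA/TAG/TGA) lying strictly before the
#' CDS start closes a fully \emph{upstream} uORF; an ATG whose frame
#' reaches the CDS start without an in-frame stop is recorded as
#' \emph{overlapping}. The CDS is taken to begin immediately after the
#' leader. Codons containing N never match ATG or a stop codon.
#'
#' @param leader leader sequence: a character string, \code{DNAString} or
#'   length-one \code{DNAStringSet} over A/C/G/T/N (lowercase and U
#'   accepted).
#'
#' @return data.frame with one row per start codon, sorted by
#'   \code{start}: \code{start} (0-based offset of the ATG in the leader),
#'   \code{n_codons} (codon count including the stop; \code{NA} for
#'   overlapping records) and \code{kind}
#'   (\code{"upstream"}/\code{"overlapping"}).
#' @examples
#' scanUorfs("CCATGAAATAACC")   # one upstream uORF: ATG AAA TAA
#' scanUorfs("CCCCCC")          # no ATG, empty
#' @export
scanUorfs <- function(leader) {
    seq <- chartr("U", "T", toupper(as.character(leader)))
    if (length(seq) != 1L) stop("scanUorfs expects a single leader")
    L <- nchar(seq)
    empty <- data.frame(start = integer(), n_codons = integer(),
                        kind = character(), stringsAsFactors = FALSE)
    if (L < 3L) return(empty)
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(empty)
    res <- lapply(as.integer(hits), function(s1) {
        p <- s1
        while (p + 2L <= L) {
            if (substr(seq, p, p + 2L) %in% .STOP_CODONS)
                return(data.frame(start = s1 - 1L,
                                  n_codons = (p - s1) %/% 3L + 1L,
                                  kind = "upstream",
                                  stringsAsFactors = FALSE))
            p <- p + 3L
        }
        data.frame(start = s1 - 1L, n_codons = NA_integer_,
                   kind = "overlapping", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out[order(out$start), , drop = FALSE]
}

#' Does a gene carry a uORF?
#'
#' @param records uORF table from \code{\link{scanUorfs}} for one gene.
#' @param mode \code{"upstream_only"} (default) counts only fully
#'   upstream uORFs; \code{"any"} also counts CDS-overlapping start
#'   codons.
#' @return logical scalar.
#' @export
geneHasUorf <- function(records, mode = c("upstream_only", "any")) {
    mode <- match.arg(mode)
    if (is.null(records) || nrow(records) == 0L) return(FALSE)
    if (mode == "any") nrow(records) > 0L
    else any(records$kind == "upstream")
}

#' Per-gene uORF summary over a leader set
#'
#' @param leaders named \code{DNAStringSet} (or character vector) of
#'   leaders.
#' @param mode passed to \code{\link{geneHasUorf}}.
#' @return data.frame with \code{gene_id}, \code{n_upstream},
#'   \code{n_overlapping}, \code{has_uorf}.
#' @export
uorfGeneSummary <- function(leaders, mode = c("upstream_only", "any")) {
    mode <- match.arg(mode)
    seqs <- as.character(leaders)
    if (is.null(names(seqs))) stop("leaders must be named by gene id")
    recs <- lapply(seqs, scanUorfs)
    data.frame(
        gene_id = names(seqs),
        n_upstream = vapply(recs, function(r) sum(r$kind == "upstream"), 0L),
        n_overlapping = vapply(recs, function(r) sum(r$kind == "overlapping"), 0L),
        has_uorf = vapply(recs, geneHasUorf, logical(1), mode = mode),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact binomial test of a uORF proportion against an expectation
#'
#' Two-sided exact binomial test of observing \code{k} uORF-containing
#' genes among \code{n} against the genome-wide expected proportion
#' \code{p0}: the p-value sums all Binomial(n, p0) point probabilities not
#' exceeding that of \code{k} (the minimum-likelihood rule, the same
#' convention as \code{\link[stats]{binom.test}}).
#'
#' @param k observed number of uORF-containing genes in the set.
#' @param n set size (> 0).
#' @param p0 expected proportion, in (0, 1); typically the frequency over
#'   the full supplied annotation.
#'
#' @return one-row data.frame: \code{k_observed}, \code{n_set},
#'   \code{p0_expected}, \code{p_value} and \code{direction}
#'   (\code{"depleted"}, \code{"enriched"} or \code{"none"}, by the sign
#'   of \code{k/n - p0}).
#' @examples
#' uorfProportionTest(0, 10, 0.5)  # p = 2/1024, depleted
#' @export
uorfProportionTest <- function(k, n, p0) {
    if (n <= 0L) stop("n must be positive")
    if (k < 0L || k > n) stop("k must lie in [0, n]")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
    d <- stats::dbinom(0:n, n, p0)
    p <- min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
    dir <- if (k / n < p0) "depleted" else if (k / n > p0) "enriched" else "none"
    data.frame(k_observed = as.integer(k), n_set = as.integer(n),
               p0_expected = p0, p_value = p, direction = dir,
               stringsAsFactors = FALSE)
}
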