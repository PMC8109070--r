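#' @importFrom stats phyper
NULL

#' Term over-representation analysis
#'
#' One-sided hypergeometric test per term: with a universe of \eqn{N}
#' genes, \eqn{K} of them in the term and a query set of \eqn{n} genes
#' overlapping the term in \eqn{k}, the p-value is
#' \eqn{P[X \ge k]} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}).
#' BH adjustment across the tested terms; results are sorted by raw
#' p-value.
#'
#' @param gene_set character vector of query genes (must lie in
#'   \code{universe}; genes outside it are dropped with a warning).
#' @param universe character vector, the gene background (for expression
#'   data typically the genes passing the low-expression filter).
#' @param terms term map as returned by \code{\link{readTermMap}} (named
#'   list of gene vectors).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param min_term_size terms with fewer in-universe genes are skipped
#'   (default 3); terms with zero overlap with the universe are always
#'   skipped, with a message.
#'
#' @return data.frame, one row per tested term: \code{term_id},
#'   \code{term_name}, \code{k_overlap}, \code{n_set}, \code{K_term},
#'   \code{N_universe}, \code{fold_enrichment} = (k/n)/(K/N),
#'   \code{p_raw}, \code{p_adj}, \code{significant}.
#' @export
enrichTerms <- function(gene_set, universe, terms, alpha = 0.05,
                        min_term_size = 3L) {
    universe <- unique(universe)
    gene_set <- unique(gene_set)
    if (!length(universe)) stop("empty universe")
    if (!length(gene_set)) stop("empty gene set")
    outside <- setdiff(gene_set, universe)
    if (length(outside)) {
        warning(length(outside), " query gene(s) outside the universe dropped")
        gene_set <- intersect(gene_set, universe)
        if (!length(gene_set)) stop("empty gene set after universe filter")
    }
    term_names <- attr(terms, "term_name")
    if (is.null(term_names))
        term_names <- stats::setNames(names(terms), names(terms))
    N <- length(universe)
    n <- length(gene_set)
    rows <- lapply(names(terms), function(id) {
        tg <- intersect(terms[[id]], universe)
        K <- length(tg)
        if (K == 0L) {
            message("term ", id, " has no genes in the universe; skipped")
            return(NULL)
        }
        if (K < min_term_size) return(NULL)
        k <- length(intersect(gene_set, tg))
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id, term_name = unname(term_names[id]),
                   k_overlap = k, n_set = n, K_term = K, N_universe = N,
                   fold_enrichment = (k / n) / (K / N), p_raw = p,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(term_id = character(), term_name = character(),
                          k_overlap = integer(), n_set = integer(),
                          K_term = integer(), N_universe = integer(),
                          fold_enrichment = numeric(), p_raw = numeric(),
                          p_adj = numeric(), significant = logical()))
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
    out$significant <- out$p_adj < alpha
    out[order(out$p_raw), , drop = FALSE]
}

#' Compare two enrichment results term by term
#'
#' Classifies every term as significant in A only, in B only, in both or
#' in neither — the "enriched only in one type of cells" contrast.
#'
#' @param res_a,res_b \code{\link{enrichTerms}} outputs over the same
#'   universe and term map (mismatched term sets or universes are fatal).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return data.frame per term: \code{term_id}, \code{term_name},
#'   \code{p_adj_a}, \code{p_adj_b}, \code{category} in
#'   \code{{"both", "A_only", "B_only", "neither"}}.
#' @export
compareEnrichments <- function(res_a, res_b, alpha = 0.05) {
    if (!setequal(res_a$term_id, res_b$term_id))
        stop("the two results cover different term sets")
    if (nrow(res_a) && res_a$N_universe[1L] != res_b$N_universe[1L])
        stop("the two results use different universes")
    b <- res_b[match(res_a$term_id, res_b$term_id), ]
    sig_a <- res_a$p_adj < alpha
    sig_b <- b$p_adj < alpha
    category <- ifelse(sig_a & sig_b, "both",
                ifelse(sig_a, "A_only",
                ifelse(sig_b, "B_only", "neither")))
    out <- data.frame(term_id = res_a$term_id, term_name = res_a$term_name,
                      p_adj_a = res_a$p_adj, p_adj_b = b$p_adj,
                      category = category, stringsAsFactors = FALSE)
    out[order(pmin(out$p_adj_a, out$p_adj_b)), , drop = FALSE]
}
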