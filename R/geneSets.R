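#' @importFrom stats cor lm coef
NULL

#' Classify genes by TE change
#'
#' A gene is called \code{up} when its TE fold change exceeds
#' \code{fold_threshold} (strictly) and its p-value is below \code{alpha}
#' (strictly); \code{down} symmetrically when the fold change is below
#' \code{1/fold_threshold}; otherwise \code{unchanged}. Low-expression
#' genes keep the class \code{low_expression}.
#'
#' @param results per-gene table from \code{\link{testTEChange}}.
#' @param fold_threshold TE fold-change threshold (default 1.5, i.e. a
#'   change of more than 50\%).
#' @param alpha p-value threshold (default 0.05).
#' @param p_field which p-value the call uses: \code{"p_raw"} (default)
#'   or \code{"p_adj"}.
#'
#' @return data.frame: \code{gene_id}, \code{log2_te_change}, \code{p},
#'   \code{class}.
#' @export
classifyGenes <- function(results, fold_threshold = 1.5, alpha = 0.05,
                          p_field = c("p_raw", "p_adj")) {
    p_field <- match.arg(p_field)
    stopifnot(fold_threshold > 0, alpha > 0)
    fc <- 2^results$log2_te_change
    p <- results[[p_field]]
    cls <- rep("unchanged", nrow(results))
    cls[fc > fold_threshold & p < alpha] <- "up"
    cls[fc < 1 / fold_threshold & p < alpha] <- "down"
    cls[results$low_expression] <- "low_expression"
    data.frame(gene_id = results$gene_id,
               log2_te_change = results$log2_te_change, p = p, class = cls,
               stringsAsFactors = FALSE)
}

#' Intersect per-strain gene-set calls
#'
#' Counts genes called up in each strain, in both, and the subset up in
#' both whose first-strain log2 TE change exceeds the second strain's by
#' more than \code{margin} (the "much higher activation in WT" set).
#'
#' @param calls_a,calls_b \code{\link{classifyGenes}} output for the two
#'   strains (same genes, same order).
#' @param margin excess log2 TE change required for the
#'   \code{excess_in_a} set (default 1, i.e. two-fold).
#'
#' @return list with \code{summary} (one-row data.frame: \code{n_up_a},
#'   \code{n_up_b}, \code{n_up_both}, \code{n_excess_in_a}) and
#'   \code{genes} (character vectors \code{up_a}, \code{up_b},
#'   \code{up_both}, \code{excess_in_a}).
#' @export
intersectSets <- function(calls_a, calls_b, margin = 1) {
    if (!identical(calls_a$gene_id, calls_b$gene_id))
        stop("calls must cover the same genes in the same order")
    up_a <- calls_a$gene_id[calls_a$class == "up"]
    up_b <- calls_b$gene_id[calls_b$class == "up"]
    up_both <- intersect(up_a, up_b)
    i <- match(up_both, calls_a$gene_id)
    excess <- up_both[calls_a$log2_te_change[i] -
                      calls_b$log2_te_change[match(up_both, calls_b$gene_id)] >
                      margin]
    list(summary = data.frame(n_up_a = length(up_a), n_up_b = length(up_b),
                              n_up_both = length(up_both),
                              n_excess_in_a = length(excess)),
         genes = list(up_a = up_a, up_b = up_b, up_both = up_both,
                      excess_in_a = excess))
}

#' Least-squares fit and correlation of two per-gene quantities
#'
#' Ordinary least-squares line through the finite (x, y) pairs plus the
#' Pearson correlation, as used for scatter comparisons of mRNA-level
#' versus TE changes and of TE changes between strains.
#'
#' @param x,y numeric vectors of equal length; non-finite pairs are
#'   dropped.
#' @return one-row data.frame: \code{n}, \code{slope}, \code{intercept},
#'   \code{pearson_r}, \code{r_squared}.
#' @examples
#' fitScatter(1:10, 2 * (1:10) + 1)  # slope 2, intercept 1, r^2 = 1
#' @export
fitScatter <- function(x, y) {
    stopifnot(length(x) == length(y))
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("need at least 3 finite (x, y) pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("undefined correlation: constant x or y")
    fit <- stats::lm(y ~ x)
    r <- stats::cor(x, y)
    data.frame(n = length(x), slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               pearson_r = r, r_squared = r^2)
}
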