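#' @importFrom stats median pnorm p.adjust quantile var complete.cases
NULL

.size_factors_mor <- function(k) {
    if (!is.matrix(k) || any(k < 0)) stop("counts must be a non-negative matrix")
    pos <- rowSums(k > 0) == ncol(k)
    if (!any(pos))
        stop("no gene has strictly positive counts in every sample; ",
             "pre-filter genes or samples before estimating size factors")
    kp <- k[pos, , drop = FALSE]
    geo <- exp(rowMeans(log(kp)))
    sf <- apply(kp, 2L, function(col) stats::median(col / geo))
    stats::setNames(sf, colnames(k))
}

#' Median-of-ratios size factors
#'
#' For each sample \eqn{j}, the size factor is the median over genes
#' (restricted to genes with strictly positive counts in every sample) of
#' \eqn{K_{gj} / (\prod_{j'} K_{gj'})^{1/m}} — the count divided by the
#' gene's geometric mean across samples. Medians of even-sized sets use
#' the midpoint.
#'
#' @param object a \linkS4class{TranslatomeExperiment} or a non-negative
#'   count matrix.
#' @param ... ignored.
#' @return For a matrix, a named numeric vector of factors; for a
#'   \code{TranslatomeExperiment}, the object with
#'   \code{\link[BiocGenerics]{sizeFactors}} filled in.
#' @examples
#' k <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
#' rownames(k) <- paste0("g", 1:3)
#' estimateSizeFactors(k)  # (1/sqrt(2), sqrt(2))
#' @export
setMethod("estimateSizeFactors", "matrix", function(object, ...) {
    .size_factors_mor(object)
})

#' @rdname estimateSizeFactors-matrix-method
#' @export
setMethod("estimateSizeFactors", "TranslatomeExperiment", function(object, ...) {
    sizeFactors(object) <- .size_factors_mor(counts(object))
    object
})

.norm_counts <- function(te, factors = NULL) {
    if (is.null(factors)) factors <- sizeFactors(te)
    if (is.null(factors))
        stop("no size factors: run estimateSizeFactors() first or pass factors")
    k <- counts(te)
    if (!is.null(names(factors))) factors <- factors[colnames(k)]
    if (any(is.na(factors)) || length(factors) != ncol(k))
        stop("size factors must cover every sample")
    sweep(k, 2L, factors, "/")
}

.two_times <- function(d, time_early, time_late) {
    tms <- unique(d$time)
    if (is.null(time_early)) time_early <- tms[1L]
    if (is.null(time_late)) time_late <- tms[length(tms)]
    if (!all(c(time_early, time_late) %in% tms))
        stop("contrast references time level(s) absent from the design")
    c(time_early, time_late)
}

.cell_cols <- function(d, strain, time, fraction) {
    idx <- which(d$strain == strain & d$time == time & d$fraction == fraction)
    if (!length(idx))
        stop("design has no samples for cell (", strain, ", ", time, ", ",
             fraction, ")")
    idx
}

#' Per-gene translation efficiency
#'
#' Normalized counts \eqn{Y = K / s} are averaged over replicates within
#' each (strain, time, fraction) cell. Translation efficiency is the
#' pseudocounted ratio of the polysome to the total cell mean,
#' \eqn{TE = (\bar Y_{poly} + c) / (\bar Y_{total} + c)}, and the per-gene
#' log2 TE change over time is
#' \eqn{\log_2 TE(\mathrm{late}) - \log_2 TE(\mathrm{early})}; the log2
#' mRNA change is the analogous contrast on the total fraction. Genes with
#' any required cell mean below \code{min_count} are flagged
#' \code{low_expression}.
#'
#' @param te a \linkS4class{TranslatomeExperiment}.
#' @param factors optional size factors (default: those stored in
#'   \code{te}).
#' @param pseudocount added to cell means before ratios (default 0.5).
#' @param min_count low-expression threshold on normalized cell means
#'   (default 10).
#' @param time_early,time_late time labels of the contrast; default the
#'   first and last time level in the design.
#'
#' @return data.frame with one row per gene: \code{gene_id}, cell means
#'   (\code{mean_<strain>_<time>_<fraction>}), \code{te_<strain>_<time>},
#'   \code{log2_te_change_<strain>}, \code{log2_mrna_change_<strain>} and
#'   \code{low_expression}.
#' @export
computeTE <- function(te, factors = NULL, pseudocount = 0.5, min_count = 10,
                      time_early = NULL, time_late = NULL) {
    d <- design(te)
    y <- .norm_counts(te, factors)
    tms <- .two_times(d, time_early, time_late)
    strains <- unique(d$strain)
    out <- data.frame(gene_id = rownames(y), stringsAsFactors = FALSE)
    low <- rep(FALSE, nrow(y))
    means <- list()
    for (s in strains) for (tm in tms) for (fr in .FRACTIONS) {
        idx <- .cell_cols(d, s, tm, fr)
        m <- rowMeans(y[, idx, drop = FALSE])
        means[[paste(s, tm, fr, sep = "_")]] <- m
        out[[paste("mean", s, tm, fr, sep = "_")]] <- m
        low <- low | m < min_count
    }
    for (s in strains) {
        for (tm in tms) {
            po <- means[[paste(s, tm, "polysome", sep = "_")]]
            to <- means[[paste(s, tm, "total", sep = "_")]]
            out[[paste("te", s, tm, sep = "_")]] <-
                (po + pseudocount) / (to + pseudocount)
        }
        out[[paste0("log2_te_change_", s)]] <-
            log2(out[[paste("te", s, tms[2L], sep = "_")]]) -
            log2(out[[paste("te", s, tms[1L], sep = "_")]])
        tot_l <- means[[paste(s, tms[2L], "total", sep = "_")]]
        tot_e <- means[[paste(s, tms[1L], "total", sep = "_")]]
        out[[paste0("log2_mrna_change_", s)]] <-
            log2(tot_l + pseudocount) - log2(tot_e + pseudocount)
    }
    out$low_expression <- low
    out
}

# moderate per-gene variances toward an expression-binned trend:
# equal-occupancy bins of mean log-expression; shrinkage weight
# n_prior / (n_prior + n_rep - 1)
.moderate_var <- function(v, mean_log_expr, n_rep, n_prior, n_bins) {
    n_bins <- max(1L, min(n_bins, floor(length(v) / 2L)))
    # ties.method = "average" so equal-expression genes share a bin and
    # the moderation is invariant to gene order
    bins <- ceiling(rank(mean_log_expr, ties.method = "average") *
                    n_bins / length(v))
    bin_means <- tapply(v, bins, mean)
    w <- n_prior / (n_prior + n_rep - 1)
    w * as.numeric(bin_means[as.character(bins)]) + (1 - w) * v
}

.te_stat_core <- function(y, d, strain, tms, pseudocount, min_count,
                          n_prior, n_bins) {
    cells <- expand.grid(fraction = .FRACTIONS, time = tms,
                         stringsAsFactors = FALSE)
    lg <- log2(y + pseudocount)
    n_genes <- nrow(y)
    delta <- rep(0, n_genes)
    se2 <- rep(0, n_genes)
    low <- rep(FALSE, n_genes)
    all_idx <- integer()
    cell_var <- cell_n <- list()
    for (i in seq_len(nrow(cells))) {
        idx <- .cell_cols(d, strain, cells$time[i], cells$fraction[i])
        if (length(idx) < 2L)
            stop("cell (", strain, ", ", cells$time[i], ", ",
                 cells$fraction[i], ") has fewer than 2 replicates; the ",
                 "Wald test needs replication (see p_mode = 'permutation')")
        all_idx <- c(all_idx, idx)
        m <- rowMeans(y[, idx, drop = FALSE])
        low <- low | m < min_count
        sign <- (if (cells$time[i] == tms[2L]) 1 else -1) *
                (if (cells$fraction[i] == "polysome") 1 else -1)
        delta <- delta + sign * log2(m + pseudocount)
        cell_var[[i]] <- apply(lg[, idx, drop = FALSE], 1L, stats::var)
        cell_n[[i]] <- length(idx)
    }
    mean_expr <- rowMeans(lg[, all_idx, drop = FALSE])
    for (i in seq_len(nrow(cells))) {
        v <- .moderate_var(cell_var[[i]], mean_expr, cell_n[[i]],
                           n_prior, n_bins)
        se2 <- se2 + v / cell_n[[i]]
    }
    list(delta = delta, se2 = se2, low = low)
}

.finish_wald <- function(gene_id, delta, se2, low, var_floor_q = 0.05) {
    if (any(!low)) {
        floor_v <- stats::quantile(se2[!low], var_floor_q, names = FALSE)
        se2 <- pmax(se2, floor_v)
    }
    se <- sqrt(se2)
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
    p[low] <- NA_real_
    z[low] <- NA_real_
    p_adj <- rep(NA_real_, length(p))
    p_adj[!low] <- stats::p.adjust(p[!low], method = "BH")
    data.frame(gene_id = gene_id, log2_te_change = delta, se = se, z = z,
               p_raw = p, p_adj = p_adj, low_expression = low,
               stringsAsFactors = FALSE)
}

#' Test per-gene TE change over time within one strain
#'
#' Wald test on the log2 TE change (ratio of polysome/total pseudocounted
#' cell-mean ratios between the late and early timepoints). The standard
#' error combines per-cell replicate variances of
#' \eqn{\log_2(Y + c)}, each moderated toward an expression-binned trend
#' (equal-occupancy bins of mean log expression, shrinkage weight
#' \eqn{n_{prior}/(n_{prior} + n_{rep} - 1)}), as
#' \eqn{SE^2 = \sum_{cells} v_{cell} / n_{cell}}, floored at the 5th
#' percentile of the moderated values so degenerate replicates never give
#' infinite z. Two-sided normal p-values; BH adjustment over non-flagged
#' genes. Low-expression genes carry NA statistics.
#'
#' An optional permutation mode replaces the normal reference: time labels
#' are permuted within each fraction, jointly over fractions, with exact
#' enumeration when at most 20 distinct relabellings exist and random
#' sampling otherwise.
#'
#' @inheritParams computeTE
#' @param strain strain to test (default: first in the design).
#' @param n_prior prior observations for variance moderation (default 5).
#' @param n_bins equal-occupancy expression bins for the variance trend
#'   (default 20).
#' @param p_mode \code{"wald"} (default) or \code{"permutation"}.
#' @param n_perm random permutations when exhaustive enumeration exceeds
#'   20 relabellings (default 1000).
#'
#' @return data.frame per gene: \code{gene_id}, \code{log2_te_change},
#'   \code{se}, \code{z}, \code{p_raw}, \code{p_adj},
#'   \code{low_expression}.
#' @export
testTEChange <- function(te, strain = NULL, factors = NULL, pseudocount = 0.5,
                         min_count = 10, time_early = NULL, time_late = NULL,
                         n_prior = 5, n_bins = 20,
                         p_mode = c("wald", "permutation"), n_perm = 1000L) {
    p_mode <- match.arg(p_mode)
    d <- design(te)
    if (is.null(strain)) strain <- d$strain[1L]
    if (!strain %in% d$strain) stop("strain '", strain, "' not in design")
    tms <- .two_times(d[d$strain == strain, ], time_early, time_late)
    y <- .norm_counts(te, factors)
    core <- .te_stat_core(y, d, strain, tms, pseudocount, min_count,
                          n_prior, n_bins)
    res <- .finish_wald(rownames(y), core$delta, core$se2, core$low)
    if (p_mode == "permutation") {
        res$p_raw <- .permutation_p(y, d, strain, tms, pseudocount,
                                    core$delta, n_perm)
        res$p_raw[core$low] <- NA_real_
        res$p_adj[!core$low] <- stats::p.adjust(res$p_raw[!core$low], "BH")
    }
    res
}

# permute time labels within each fraction of one strain; exact when the
# number of joint relabellings is <= 20
.permutation_p <- function(y, d, strain, tms, pseudocount, delta_obs, n_perm) {
    idx_by <- lapply(.FRACTIONS, function(fr)
        lapply(tms, function(tm) .cell_cols(d, strain, tm, fr)))
    names(idx_by) <- .FRACTIONS
    pools <- lapply(idx_by, function(x) c(x[[1L]], x[[2L]]))
    n_early <- lapply(idx_by, function(x) length(x[[1L]]))
    combos <- lapply(.FRACTIONS, function(fr)
        utils::combn(pools[[fr]], n_early[[fr]], simplify = FALSE))
    names(combos) <- .FRACTIONS
    n_exact <- prod(lengths(combos))
    stat <- function(et, ef, lt, lf) {
        log2(rowMeans(y[, lf, drop = FALSE]) + pseudocount) -
        log2(rowMeans(y[, lt, drop = FALSE]) + pseudocount) -
        log2(rowMeans(y[, ef, drop = FALSE]) + pseudocount) +
        log2(rowMeans(y[, et, drop = FALSE]) + pseudocount)
    }
    draw <- function(ct, cf) {
        et <- ct; lt <- setdiff(pools$total, ct)
        ef <- cf; lf <- setdiff(pools$polysome, cf)
        stat(et, ef, lt, lf)
    }
    if (n_exact <= 20L) {
        grid <- expand.grid(i = seq_along(combos$total),
                            j = seq_along(combos$polysome))
        perms <- mapply(function(i, j) draw(combos$total[[i]],
                                            combos$polysome[[j]]),
                        grid$i, grid$j, SIMPLIFY = TRUE)
        exceed <- rowSums(abs(perms) >= abs(delta_obs) - 1e-12)
        exceed / ncol(perms)
    } else {
        exceed <- rep(1, length(delta_obs))  # observed counts itself
        for (b in seq_len(n_perm)) {
            ct <- combos$total[[sample.int(length(combos$total), 1L)]]
            cf <- combos$polysome[[sample.int(length(combos$polysome), 1L)]]
            exceed <- exceed + (abs(draw(ct, cf)) >= abs(delta_obs) - 1e-12)
        }
        exceed / (n_perm + 1)
    }
}

#' Test the strain-by-time TE interaction
#'
#' The between-strain difference of the within-strain log2 TE changes,
#' \eqn{\Delta\Delta = \Delta_{strain_1} - \Delta_{strain_2}}, with
#' additive squared standard errors, a two-sided normal p-value and BH
#' adjustment. A gene flagged low-expression in either strain is flagged
#' in the interaction.
#'
#' @inheritParams testTEChange
#' @param strains length-2 character vector (default: the first two
#'   strains in the design; the second is subtracted from the first).
#'
#' @return data.frame per gene: \code{gene_id},
#'   \code{delta_delta_log2_te}, per-strain \code{log2_te_change_*},
#'   \code{se}, \code{z}, \code{p_raw}, \code{p_adj},
#'   \code{low_expression}.
#' @export
testStrainInteraction <- function(te, strains = NULL, factors = NULL,
                                  pseudocount = 0.5, min_count = 10,
                                  time_early = NULL, time_late = NULL,
                                  n_prior = 5, n_bins = 20) {
    d <- design(te)
    if (is.null(strains)) strains <- unique(d$strain)[1:2]
    if (length(strains) != 2L || !all(strains %in% d$strain))
        stop("need exactly two strains present in the design")
    y <- .norm_counts(te, factors)
    tms <- .two_times(d, time_early, time_late)
    a <- .te_stat_core(y, d, strains[1L], tms, pseudocount, min_count,
                       n_prior, n_bins)
    b <- .te_stat_core(y, d, strains[2L], tms, pseudocount, min_count,
                       n_prior, n_bins)
    low <- a$low | b$low
    res <- .finish_wald(rownames(y), a$delta - b$delta, a$se2 + b$se2, low)
    names(res)[names(res) == "log2_te_change"] <- "delta_delta_log2_te"
    res[[paste0("log2_te_change_", strains[1L])]] <- a$delta
    res[[paste0("log2_te_change_", strains[2L])]] <- b$delta
    res
}
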