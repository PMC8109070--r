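# small fixture shared across blocks
.fixture <- function(n_genes = 200, n_reps = 2, seed = 4, ...) {
    p <- simulationParams(n_genes = n_genes, n_reps = n_reps, seed = seed, ...)
    sim <- simulateCounts(makeDesign(n_reps = n_reps), p)
    list(te = estimateSizeFactors(sim$te), truth = sim$truth)
}

test_that("TE is 1 when polysome and total cells are identical", {
    d <- makeDesign(strains = "WT", n_reps = 2)
    k <- matrix(rpois(50 * nrow(d), 200), 50,
                dimnames = list(sprintf("g%02d", 1:50), d$sample_id))
    # copy the total columns onto the polysome columns, per time/replicate
    for (tm in unique(d$time)) for (r in unique(d$replicate)) {
        tot <- d$sample_id[d$time == tm & d$fraction == "total" &
                           d$replicate == r]
        pol <- d$sample_id[d$time == tm & d$fraction == "polysome" &
                           d$replicate == r]
        k[, pol] <- k[, tot]
    }
    storage.mode(k) <- "integer"
    te <- TranslatomeExperiment(k, d)
    sizeFactors(te) <- setNames(rep(1, ncol(k)), colnames(k))
    tab <- computeTE(te)
    expect_equal(tab$te_WT_0h, rep(1, 50))
    expect_equal(tab$te_WT_6h, rep(1, 50))
    expect_equal(tab$log2_te_change_WT, rep(0, 50))
})

test_that("TE arithmetic follows the pseudocounted cell-mean ratio", {
    d <- makeDesign(strains = "WT", n_reps = 1)
    # poly mean 20, total mean 10 at both times; with pseudocount 0 the TE
    # is exactly 2 and its change over time exactly 0
    k <- matrix(0L, 1, 4, dimnames = list("g1", d$sample_id))
    k[1, d$fraction == "total"] <- 10L
    k[1, d$fraction == "polysome"] <- 20L
    te <- TranslatomeExperiment(k, d)
    sizeFactors(te) <- setNames(rep(1, 4), colnames(k))
    tab <- computeTE(te, pseudocount = 0, min_count = 0)
    expect_equal(tab$te_WT_0h, 2)
    expect_equal(log2(tab$te_WT_0h), 1)
    expect_equal(tab$log2_te_change_WT, 0)
})

test_that("estimated TE changes track the planted truth", {
    f <- .fixture(n_genes = 1200, n_reps = 4, seed = 31,
                  effect_fixed_log2 = 1,
                  baseline_log_mean_mu = log(800), baseline_log_mean_sd = 1)
    res <- testTEChange(f$te, strain = "WT")
    keep <- !res$low_expression & f$truth$baseline_mean > 100
    expect_gt(cor(res$log2_te_change[keep], f$truth$true_te_log2fc_WT[keep]),
              0.9)
})

test_that("swapping the time contrast negates the statistics", {
    f <- .fixture(seed = 12)
    a <- testTEChange(f$te, strain = "WT", time_early = "0h", time_late = "6h")
    b <- testTEChange(f$te, strain = "WT", time_early = "6h", time_late = "0h")
    expect_equal(b$log2_te_change, -a$log2_te_change, tolerance = 1e-12)
    expect_equal(b$z, -a$z, tolerance = 1e-12)
    expect_equal(b$p_raw, a$p_raw, tolerance = 1e-12)
})

test_that("low-expression genes are flagged and carry no p-values", {
    f <- .fixture(seed = 3, baseline_log_mean_mu = 2, baseline_log_mean_sd = 2)
    res <- testTEChange(f$te, strain = "WT", min_count = 10)
    expect_gt(sum(res$low_expression), 0)
    expect_true(all(is.na(res$p_raw[res$low_expression])))
    expect_true(all(is.na(res$p_adj[res$low_expression])))
    expect_true(all(!is.na(res$p_raw[!res$low_expression])))
})

test_that("one-sample scaling behaves as the estimator's equivariance dictates", {
    set.seed(77)
    d <- makeDesign(strains = "WT", n_reps = 2)
    m <- nrow(d)
    k <- matrix(rpois(300 * m, 300) + 1L, 300,
                dimnames = list(sprintf("g%03d", 1:300), d$sample_id))
    storage.mode(k) <- "integer"
    k2 <- k; k2[, 1] <- k2[, 1] * 3L
    sf1 <- estimateSizeFactors(k)
    sf2 <- estimateSizeFactors(k2)
    # factor of the scaled sample rises by c modulo the common geometric
    # anchor c^(1/m); the others keep their ratios exactly
    anchor <- 3^(1 / m)
    expect_equal(unname(sf2[1] / sf1[1]), 3 / anchor, tolerance = 1e-9)
    expect_equal(unname(sf2[-1] / sf1[-1]), rep(1 / anchor, m - 1),
                 tolerance = 1e-9)
    # with pseudocount 0 the anchor cancels from every ratio statistic
    te1 <- TranslatomeExperiment(k, d); sizeFactors(te1) <- sf1
    te2 <- TranslatomeExperiment(k2, d); sizeFactors(te2) <- sf2
    r1 <- testTEChange(te1, strain = "WT", pseudocount = 0, min_count = 0)
    r2 <- testTEChange(te2, strain = "WT", pseudocount = 0, min_count = 0)
    expect_equal(r2$log2_te_change, r1$log2_te_change, tolerance = 1e-9)
    expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-9)
    t1 <- computeTE(te1, pseudocount = 0, min_count = 0)
    t2 <- computeTE(te2, pseudocount = 0, min_count = 0)
    expect_equal(t2$te_WT_0h, t1$te_WT_0h, tolerance = 1e-9)
})

test_that("gene order permutation permutes the outputs identically", {
    f <- .fixture(seed = 19)
    res <- testTEChange(f$te, strain = "WT")
    perm <- sample(nrow(f$te))
    te_p <- TranslatomeExperiment(counts(f$te)[perm, ], design(f$te))
    sizeFactors(te_p) <- sizeFactors(f$te)
    res_p <- testTEChange(te_p, strain = "WT")
    expect_identical(res_p$gene_id, res$gene_id[perm])
    expect_equal(res_p$p_raw, res$p_raw[perm], tolerance = 1e-12)
    expect_equal(res_p$z, res$z[perm], tolerance = 1e-12)
})

test_that("BH adjustment is monotone and bounded", {
    f <- .fixture(seed = 23)
    res <- testTEChange(f$te, strain = "S52A")
    ok <- !res$low_expression
    expect_true(all(res$p_adj[ok] >= res$p_raw[ok]))
    expect_true(all(res$p_adj[ok] <= 1))
    o <- order(res$p_raw[ok])
    expect_true(all(diff(res$p_adj[ok][o]) >= -1e-15))
    # and it matches stats::p.adjust directly
    expect_equal(res$p_adj[ok], p.adjust(res$p_raw[ok], "BH"))
})

test_that("the interaction is zero for mirrored strains and antisymmetric", {
    d <- makeDesign(n_reps = 2)
    set.seed(55)
    half <- makeDesign(strains = "WT", n_reps = 2)
    kw <- matrix(rpois(100 * nrow(half), 150) + 1L, 100,
                 dimnames = list(sprintf("g%03d", 1:100), half$sample_id))
    k <- cbind(kw, kw)
    colnames(k) <- d$sample_id
    storage.mode(k) <- "integer"
    te <- TranslatomeExperiment(k, d)
    sizeFactors(te) <- setNames(rep(1, ncol(k)), colnames(k))
    res <- testStrainInteraction(te)
    expect_equal(res$delta_delta_log2_te, rep(0, 100))
    # swapping the strain order negates the interaction
    f <- .fixture(seed = 29)
    a <- testStrainInteraction(f$te, strains = c("WT", "S52A"))
    b <- testStrainInteraction(f$te, strains = c("S52A", "WT"))
    expect_equal(b$delta_delta_log2_te, -a$delta_delta_log2_te,
                 tolerance = 1e-12)
    expect_equal(b$p_raw, a$p_raw, tolerance = 1e-12)
})

test_that("WT-only planted effects rank above null genes in the interaction", {
    p <- simulationParams(n_genes = 800, n_reps = 4, seed = 41,
                          frac_mrna_de = 0,
                          frac_te_de = c(WT = 0.1, S52A = 0),
                          effect_fixed_log2 = 1,
                          baseline_log_mean_mu = log(800),
                          baseline_log_mean_sd = 1)
    sim <- simulateCounts(makeDesign(n_reps = 4), p)
    te <- estimateSizeFactors(sim$te)
    res <- testStrainInteraction(te)
    keep <- !res$low_expression & sim$truth$baseline_mean > 100
    pos <- sim$truth$true_te_log2fc_WT[keep] != 0
    z <- abs(res$z[keep])
    r <- rank(z)
    auc <- (mean(r[pos]) - (sum(pos) + 1) / 2) / sum(!pos)
    expect_gte(auc, 0.9)
})

test_that("a missing contrast cell or absent strain is fatal", {
    f <- .fixture(seed = 2)
    expect_error(testTEChange(f$te, strain = "nope"), "not in design")
    expect_error(testTEChange(f$te, strain = "WT", time_late = "12h"),
                 "time level")
})

test_that("permutation mode yields valid p-values under the null", {
    f <- .fixture(n_genes = 150, n_reps = 2, seed = 6,
                  frac_mrna_de = 0, frac_te_de = 0)
    res <- testTEChange(f$te, strain = "WT", p_mode = "permutation",
                        n_perm = 200)
    ok <- !res$low_expression
    expect_true(all(res$p_raw[ok] > 0 & res$p_raw[ok] <= 1))
    # roughly uniform: no gross inflation of small p-values
    expect_lt(mean(res$p_raw[ok] < 0.1), 0.25)
})
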