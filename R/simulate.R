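#' @importFrom stats rlnorm rnbinom rpois runif rnorm median setNames
NULL

# named, independent substream seeds derived from one master seed, so that
# adding a stage never perturbs another stage's draws
.substream_seeds <- function(seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                    c("counts", "sizes", "leaders", "terms"))
}

#' Build a full-factorial polysome-profiling design
#'
#' One sample per (strain, time, fraction, replicate) combination; sample
#' ids are \code{strain_time_fraction_rep}.
#'
#' @param strains,times character vectors (defaults \code{c("WT","S52A")},
#'   \code{c("0h","6h")}); \code{times} is interpreted as ordered
#'   (first = early).
#' @param n_reps replicates per cell.
#' @return design data.frame suitable for \code{\link{TranslatomeExperiment}}.
#' @export
makeDesign <- function(strains = c("WT", "S52A"), times = c("0h", "6h"),
                       n_reps = 2L) {
    g <- expand.grid(replicate = seq_len(n_reps),
                     fraction = c("total", "polysome"),
                     time = times, strain = strains,
                     stringsAsFactors = FALSE)
    g <- g[, c("strain", "time", "fraction", "replicate")]
    data.frame(sample_id = paste(g$strain, g$time, g$fraction, g$replicate,
                                 sep = "_"), g, stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defaults describe a two-strain (WT vs a non-phosphorylatable eIF2-alpha
#' mutant), two-timepoint, total/polysome design with duplicate libraries
#' (16 samples), 2,000 genes with log-normal baseline abundance, a
#' decreasing negative-binomial dispersion trend phi(mu) = a/mu + b, 10%
#' of genes carrying mRNA-level effects and 10% carrying TE effects at the
#' later timepoint, and uORF presence probabilities of 0.4 genome-wide
#' with 0.2 in the mutant-dependent up-regulated class.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per (strain, time, fraction) cell.
#' @param baseline_log_mean_mu,baseline_log_mean_sd natural-log mean and sd
#'   of the log-normal gene baseline abundance.
#' @param dispersion_a,dispersion_b NB dispersion trend phi = a/mu + b
#'   (variance = mu + phi mu^2); both 0 gives the Poisson limit.
#' @param size_factor_sd sd of log-normal per-sample library-size factors
#'   (0 = all factors 1).
#' @param frac_mrna_de,frac_te_de proportion of genes with planted mRNA /
#'   TE log2 fold changes, drawn independently per strain; either a
#'   scalar or a named vector with one entry per strain (so effects can
#'   be planted in one strain only).
#' @param frac_te_shared proportion of genes with a TE effect planted
#'   identically in every strain (a strain-independent translational
#'   program; default 0), additive with the per-strain effects.
#' @param effect_log2_sd sd of planted log2 effects (normal draws).
#' @param effect_fixed_log2 if non-NULL, planted effects are exactly this
#'   magnitude with a random sign instead of normal draws.
#' @param uorf_prob_by_class named probabilities of carrying an upstream
#'   uORF, per gene class (\code{background}, \code{wt_up}, \code{s52a_up}).
#' @param leader_len_mean mean 5' leader length (nt, Poisson).
#' @param seed master seed; named substreams for counts, size factors and
#'   leaders are derived from it.
#' @return validated parameter list of class \code{SimulationParams}.
#' @export
simulationParams <- function(n_genes = 2000L, n_reps = 2L,
                             baseline_log_mean_mu = 5, baseline_log_mean_sd = 1.5,
                             dispersion_a = 1, dispersion_b = 0.005,
                             size_factor_sd = 0.2,
                             frac_mrna_de = 0.1, frac_te_de = 0.1,
                             frac_te_shared = 0,
                             effect_log2_sd = 1,
                             effect_fixed_log2 = NULL,
                             uorf_prob_by_class = c(background = 0.4,
                                                    wt_up = 0.4,
                                                    s52a_up = 0.2),
                             leader_len_mean = 150L, seed = 1L) {
    p <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              baseline_log_mean_mu = baseline_log_mean_mu,
              baseline_log_mean_sd = baseline_log_mean_sd,
              dispersion_a = dispersion_a, dispersion_b = dispersion_b,
              size_factor_sd = size_factor_sd,
              frac_mrna_de = frac_mrna_de, frac_te_de = frac_te_de,
              frac_te_shared = frac_te_shared,
              effect_log2_sd = effect_log2_sd,
              effect_fixed_log2 = effect_fixed_log2,
              uorf_prob_by_class = uorf_prob_by_class,
              leader_len_mean = as.integer(leader_len_mean),
              seed = as.integer(seed))
    stopifnot(p$n_genes >= 1L, p$n_reps >= 1L,
              p$dispersion_a >= 0, p$dispersion_b >= 0,
              p$size_factor_sd >= 0,
              all(p$frac_mrna_de >= 0 & p$frac_mrna_de <= 1),
              all(p$frac_te_de >= 0 & p$frac_te_de <= 1),
              p$frac_te_shared >= 0, p$frac_te_shared <= 1,
              all(p$uorf_prob_by_class >= 0 & p$uorf_prob_by_class <= 1))
    class(p) <- "SimulationParams"
    p
}

#' Simulate polysome-profiling counts with planted truth
#'
#' Counts are drawn gene by sample from a negative binomial with mean
#' \eqn{s_j \mu_g 2^{m_{gs}} 2^{t_{gs}}} where \eqn{s_j} is the sample
#' size factor, \eqn{\mu_g} the gene baseline, \eqn{m_{gs}} the planted
#' mRNA log2 effect of the sample's strain (applied at the later timepoint
#' only) and \eqn{t_{gs}} the planted TE log2 effect (applied at the later
#' timepoint of the polysome fraction only), and with variance
#' \eqn{\mu + \phi \mu^2}, \eqn{\phi = a/\mu_g + b}. The first time level
#' appearing in \code{design} is the early timepoint.
#'
#' @param design full-factorial design (see \code{\link{makeDesign}}); a
#'   missing (strain, time, fraction) cell is an error.
#' @param params a \code{\link{simulationParams}} object.
#'
#' @return list with \code{te}, a \linkS4class{TranslatomeExperiment}, and
#'   \code{truth}, a data.frame of per-gene planted effects
#'   (\code{true_mrna_log2fc_*}, \code{true_te_log2fc_*}, per strain),
#'   \code{baseline_mean}, the gene's \code{uorf_class}, and a
#'   \code{has_uorf} column filled in by \code{\link{simulateLeaders}}.
#' @export
simulateCounts <- function(design, params = simulationParams()) {
    stopifnot(inherits(params, "SimulationParams"))
    strains <- unique(design$strain)
    times <- unique(design$time)
    cells <- table(design$strain, design$time, design$fraction)
    if (any(cells == 0L))
        stop("degenerate design: every (strain, time, fraction) cell needs ",
             "at least one replicate")
    seeds <- .substream_seeds(params$seed)
    n <- params$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n))

    set.seed(seeds[["counts"]])
    mu <- stats::rlnorm(n, params$baseline_log_mean_mu,
                        params$baseline_log_mean_sd)
    phi <- if (params$dispersion_a == 0 && params$dispersion_b == 0)
        rep(0, n) else params$dispersion_a / mu + params$dispersion_b
    mrna_lfc <- te_lfc <- matrix(0, n, length(strains),
                                 dimnames = list(gene_ids, strains))
    draw_effect <- function(m) {
        if (is.null(params$effect_fixed_log2))
            stats::rnorm(m, 0, params$effect_log2_sd)
        else params$effect_fixed_log2 * sample(c(-1, 1), m, replace = TRUE)
    }
    frac_for <- function(x, s) {
        if (is.null(names(x))) return(x[[1L]])
        if (!s %in% names(x))
            stop("per-strain fraction lacks an entry for strain ", s)
        x[[s]]
    }
    for (s in strains) {
        idx <- which(stats::runif(n) < frac_for(params$frac_mrna_de, s))
        mrna_lfc[idx, s] <- draw_effect(length(idx))
        idx <- which(stats::runif(n) < frac_for(params$frac_te_de, s))
        te_lfc[idx, s] <- draw_effect(length(idx))
    }
    idx <- which(stats::runif(n) < params$frac_te_shared)
    if (length(idx)) {
        eff <- draw_effect(length(idx))
        for (s in strains) te_lfc[idx, s] <- te_lfc[idx, s] + eff
    }

    set.seed(seeds[["sizes"]])
    sf <- stats::rlnorm(nrow(design), 0, params$size_factor_sd)

    late <- times[length(times)]
    k <- matrix(0L, n, nrow(design),
                dimnames = list(gene_ids, design$sample_id))
    set.seed(seeds[["counts"]] + 1L)
    for (j in seq_len(nrow(design))) {
        s <- design$strain[j]
        m <- mu * sf[j]
        if (design$time[j] == late) {
            m <- m * 2^mrna_lfc[, s]
            if (design$fraction[j] == "polysome") m <- m * 2^te_lfc[, s]
        }
        k[, j] <- if (all(phi == 0)) stats::rpois(n, m) else
            ifelse(phi == 0, stats::rpois(n, m),
                   stats::rnbinom(n, size = 1 / pmax(phi, 1e-12), mu = m))
    }

    # classes drive uORF placement: mutant-strain-dependent up-regulation
    # (second strain) gets its own class, WT-dependent another
    cls <- rep("background", n)
    if (length(strains) >= 1L) cls[te_lfc[, 1L] > 0] <- "wt_up"
    if (length(strains) >= 2L) cls[te_lfc[, 2L] > 0] <- "s52a_up"

    truth <- data.frame(gene_id = gene_ids, baseline_mean = mu,
                        uorf_class = cls, has_uorf = NA,
                        stringsAsFactors = FALSE)
    for (s in strains) {
        truth[[paste0("true_mrna_log2fc_", s)]] <- mrna_lfc[, s]
        truth[[paste0("true_te_log2fc_", s)]] <- te_lfc[, s]
    }
    list(te = TranslatomeExperiment(k, design), truth = truth)
}

.rand_dna <- function(n) {
    if (n == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate 5' leader sequences with controlled uORF content
#'
#' For each gene, draws a random-composition leader of Poisson-distributed
#' length. With the probability of the gene's class
#' (\code{params$uorf_prob_by_class}), an intact fully upstream uORF (ATG,
#' zero or more in-frame non-stop codons, in-frame stop, all before the
#' CDS start) is planted at a random in-bounds position; otherwise every
#' accidental fully upstream uORF is disrupted by mutating its start
#' codon, so the gene has none. \code{truth$has_uorf} is set from a scan
#' of the final sequence.
#'
#' @param truth truth table from \code{\link{simulateCounts}} (needs
#'   \code{gene_id} and \code{uorf_class}).
#' @param params a \code{\link{simulationParams}} object; leader draws use
#'   a seed substream independent of the count draws.
#' @param max_retries redraws allowed for a leader too short to host the
#'   requested uORF before failing.
#'
#' @return list with \code{leaders}, a named
#'   \link[Biostrings]{DNAStringSet}, and \code{truth} with
#'   \code{has_uorf} filled in.
#' @export
simulateLeaders <- function(truth, params = simulationParams(),
                            max_retries = 50L) {
    stopifnot(inherits(params, "SimulationParams"))
    probs <- params$uorf_prob_by_class
    missing_cls <- setdiff(unique(truth$uorf_class), names(probs))
    if (length(missing_cls))
        stop("uorf_prob_by_class lacks classes: ",
             paste(missing_cls, collapse = ", "))
    seeds <- .substream_seeds(params$seed)
    set.seed(seeds[["leaders"]])
    stops <- c("TAA", "TAG", "TGA")
    b <- c("A", "C", "G", "T")
    all_codons <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
                        paste0, collapse = "")
    non_stop <- setdiff(all_codons, stops)
    n <- nrow(truth)
    leaders <- character(n)
    has <- logical(n)
    for (i in seq_len(n)) {
        plant <- stats::runif(1) < probs[[truth$uorf_class[i]]]
        if (plant) {
            len <- 0L
            for (try in seq_len(max_retries)) {
                len <- stats::rpois(1, params$leader_len_mean)
                if (len >= 6L) break
            }
            if (len < 6L)
                stop("leader too short to host a uORF for gene ",
                     truth$gene_id[i], " after ", max_retries, " redraws")
            seq <- .rand_dna(len)
            m <- sample.int(min(2L, len %/% 3L - 2L) + 1L, 1L) - 1L
            orf <- paste0("ATG",
                          if (m > 0) paste(sample(non_stop, m, replace = TRUE),
                                           collapse = "") else "",
                          sample(stops, 1L))
            start <- sample.int(len - nchar(orf) + 1L, 1L)
            substr(seq, start, start + nchar(orf) - 1L) <- orf
        } else {
            seq <- .rand_dna(stats::rpois(1, params$leader_len_mean))
            repeat {
                rec <- scanUorfs(seq)
                up <- rec[rec$kind == "upstream", , drop = FALSE]
                if (!nrow(up)) break
                # knock out the start codon of the first offender; A -> C
                # can neither create an ATG nor a stop codon elsewhere
                substr(seq, up$start[1L] + 1L, up$start[1L] + 1L) <- "C"
            }
        }
        leaders[i] <- seq
        rec <- scanUorfs(seq)
        has[i] <- geneHasUorf(rec, mode = "upstream_only")
    }
    truth$has_uorf <- has
    out <- Biostrings::DNAStringSet(leaders)
    names(out) <- truth$gene_id
    list(leaders = out, truth = truth)
}

#' Simulate a gene-to-term map anchored to the planted truth
#'
#' Builds a term map usable for over-representation analysis of simulated
#' runs: one term per planted regulation class (\code{planted_wt_up},
#' \code{planted_s52a_up}, when non-empty) holding exactly the genes of
#' that class, plus random terms drawn uniformly from all genes.
#'
#' @param truth truth table from \code{\link{simulateCounts}}.
#' @param params a \code{\link{simulationParams}} object (supplies the
#'   seed substream).
#' @param n_random_terms number of random terms (default 20).
#' @param term_size genes per random term (default 30).
#' @return named list of gene-id vectors with a \code{term_name}
#'   attribute, as from \code{\link{readTermMap}}.
#' @export
simulateTermMap <- function(truth, params = simulationParams(),
                            n_random_terms = 20L, term_size = 30L) {
    seeds <- .substream_seeds(params$seed)
    set.seed(seeds[["terms"]])
    terms <- list()
    for (cls in c("wt_up", "s52a_up")) {
        g <- truth$gene_id[truth$uorf_class == cls]
        if (length(g)) terms[[paste0("planted_", cls)]] <- g
    }
    for (i in seq_len(n_random_terms)) {
        terms[[sprintf("RND%03d", i)]] <-
            sample(truth$gene_id, min(term_size, nrow(truth)))
    }
    attr(terms, "term_name") <- stats::setNames(names(terms), names(terms))
    terms
}
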