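#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml as.yaml
#' @importFrom tools md5sum
#' @importFrom utils packageVersion modifyList combn
NULL

.write_tsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Default pipeline configuration
#'
#' Returns the full configuration list \code{\link{runPipeline}} consumes,
#' with every default filled in. In \code{simulate} mode the inputs are
#' generated by the package's simulator; in \code{input} mode paths to a
#' counts TSV, sample sheet, leader FASTA + annotation and a term map must
#' be supplied.
#'
#' @param ... overrides, as \code{name = value} pairs; simulation
#'   parameters live under \code{sim} (a list passed to
#'   \code{\link{simulationParams}}).
#' @return named list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        mode = "simulate",           # "simulate" or "input"
        counts = NULL, sample_sheet = NULL,
        leaders_fasta = NULL, leaders_annot = NULL, term_map = NULL,
        sim = list(),                # simulationParams() overrides
        seed = 1L,
        pseudocount = 0.5, min_count = 10,
        n_prior = 5, n_bins = 20,
        p_mode = "wald",
        fold_threshold = 1.5, alpha = 0.05, p_field = "p_raw",
        margin = 1,
        uorf_mode = "upstream_only",
        enrich_alpha = 0.05, min_term_size = 3L,
        strains = NULL, time_early = NULL, time_late = NULL)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
    class(cfg) <- "RunConfig"
    cfg
}

.validate_config <- function(cfg) {
    if (!cfg$mode %in% c("simulate", "input"))
        stop("mode must be 'simulate' or 'input'")
    if (cfg$mode == "input") {
        need <- c("counts", "sample_sheet", "leaders_fasta", "leaders_annot")
        for (key in need) {
            if (is.null(cfg[[key]]))
                stop("input mode requires config key '", key, "'")
            if (!file.exists(cfg[[key]]))
                stop("input file does not exist: ", cfg[[key]],
                     " (config key '", key, "')")
        }
        if (!is.null(cfg$term_map) && !file.exists(cfg$term_map))
            stop("input file does not exist: ", cfg$term_map,
                 " (config key 'term_map')")
    }
    invisible(cfg)
}

#' Run the full translational-control pipeline
#'
#' Executes, in order: data acquisition (simulation with planted truth, or
#' reading user files), median-of-ratios normalization, TE computation,
#' per-strain TE-change tests, the strain-interaction test, threshold
#' classification and set intersection, scatter/correlation summaries,
#' uORF scanning with proportion tests of the up-regulated sets against
#' the annotation-wide frequency, and term over-representation with an
#' A-versus-B comparison. Every stage writes its TSV into \code{outdir}
#' and a \code{manifest.json} records the configuration, seed, package
#' version and an md5 checksum of every output, so two runs with one
#' config are byte-identical. A stage failure leaves a \code{FAILED}
#' marker naming the stage and aborts.
#'
#' @param config a \code{\link{pipelineConfig}} list (or path to a YAML
#'   file of the same keys).
#' @param outdir output directory (created if needed).
#'
#' @return the manifest, invisibly (list with \code{files}: named md5
#'   checksums).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("run")) {
    if (is.character(config))
        config <- do.call(pipelineConfig, yaml::read_yaml(config))
    .validate_config(config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- "validate"
    files <- character()
    emit <- function(x, name) {
        files[[name]] <<- .write_tsv(x, file.path(outdir, name))
    }
    on_fail <- function(e) {
        writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    }
    tryCatch({
        stage <- "acquire"
        truth <- NULL
        if (config$mode == "simulate") {
            params <- do.call(simulationParams,
                              utils::modifyList(list(seed = config$seed),
                                                config$sim))
            sim <- simulateCounts(makeDesign(n_reps = params$n_reps), params)
            te <- sim$te
            led <- simulateLeaders(sim$truth, params)
            leaders <- led$leaders
            truth <- led$truth
            terms <- simulateTermMap(truth, params)
            emit(data.frame(gene_id = rownames(counts(te)), counts(te),
                            check.names = FALSE), "counts.tsv")
            emit(design(te), "sample_sheet.tsv")
            emit(truth, "truth.tsv")
            writeLeaders(leaders, file.path(outdir, "leaders.fasta"),
                         file.path(outdir, "leaders_annot.tsv"))
            files[["leaders.fasta"]] <- file.path(outdir, "leaders.fasta")
            files[["leaders_annot.tsv"]] <- file.path(outdir,
                                                      "leaders_annot.tsv")
        } else {
            dsn <- readSampleSheet(config$sample_sheet)
            te <- readCounts(config$counts, dsn)
            leaders <- readLeaders(config$leaders_fasta, config$leaders_annot)
            terms <- if (!is.null(config$term_map))
                readTermMap(config$term_map) else NULL
        }
        d <- design(te)
        strains <- if (is.null(config$strains)) unique(d$strain)[1:2]
                   else config$strains

        stage <- "normalize"
        te <- estimateSizeFactors(te)
        emit(data.frame(sample_id = colnames(te),
                        size_factor = unname(sizeFactors(te))),
             "size_factors.tsv")

        stage <- "te"
        te_tab <- computeTE(te, pseudocount = config$pseudocount,
                            min_count = config$min_count,
                            time_early = config$time_early,
                            time_late = config$time_late)
        emit(te_tab, "te_table.tsv")

        stage <- "te-test"
        tests <- lapply(strains, function(s)
            testTEChange(te, strain = s, pseudocount = config$pseudocount,
                         min_count = config$min_count,
                         time_early = config$time_early,
                         time_late = config$time_late,
                         n_prior = config$n_prior, n_bins = config$n_bins,
                         p_mode = config$p_mode))
        names(tests) <- strains
        for (s in strains)
            emit(tests[[s]], paste0("te_test_", s, ".tsv"))
        inter <- testStrainInteraction(te, strains = strains,
                                       pseudocount = config$pseudocount,
                                       min_count = config$min_count,
                                       time_early = config$time_early,
                                       time_late = config$time_late,
                                       n_prior = config$n_prior,
                                       n_bins = config$n_bins)
        emit(inter, "te_interaction.tsv")

        stage <- "classify"
        calls <- lapply(tests, classifyGenes,
                        fold_threshold = config$fold_threshold,
                        alpha = config$alpha, p_field = config$p_field)
        for (s in strains)
            emit(calls[[s]], paste0("gene_calls_", s, ".tsv"))
        isect <- intersectSets(calls[[1L]], calls[[2L]],
                               margin = config$margin)
        emit(isect$summary, "set_summary.tsv")
        emit(data.frame(gene_id = isect$genes$up_both,
                        excess_in_a = isect$genes$up_both %in%
                            isect$genes$excess_in_a),
             "up_both_genes.tsv")

        stage <- "correlate"
        ok <- !te_tab$low_expression
        cors <- rbind(
            cbind(contrast = paste0("mrna_vs_te_", strains[1L]),
                  fitScatter(te_tab[[paste0("log2_mrna_change_", strains[1L])]][ok],
                             te_tab[[paste0("log2_te_change_", strains[1L])]][ok])),
            cbind(contrast = paste0("mrna_vs_te_", strains[2L]),
                  fitScatter(te_tab[[paste0("log2_mrna_change_", strains[2L])]][ok],
                             te_tab[[paste0("log2_te_change_", strains[2L])]][ok])),
            cbind(contrast = "te_strain1_vs_strain2",
                  fitScatter(te_tab[[paste0("log2_te_change_", strains[1L])]][ok],
                             te_tab[[paste0("log2_te_change_", strains[2L])]][ok])))
        both <- te_tab$gene_id %in% isect$genes$up_both
        if (sum(both) >= 3L)
            cors <- rbind(cors,
                cbind(contrast = "te_strain1_vs_strain2_up_both",
                      fitScatter(te_tab[[paste0("log2_te_change_", strains[1L])]][both],
                                 te_tab[[paste0("log2_te_change_", strains[2L])]][both])))
        emit(cors, "correlations.tsv")

        stage <- "uorf"
        usum <- uorfGeneSummary(leaders, mode = config$uorf_mode)
        emit(usum, "uorf_genes.tsv")
        p0 <- mean(usum$has_uorf)
        utests <- do.call(rbind, lapply(strains, function(s) {
            set <- intersect(calls[[s]]$gene_id[calls[[s]]$class == "up"],
                             usum$gene_id)
            if (length(set) == 0L || p0 <= 0 || p0 >= 1) return(NULL)
            k <- sum(usum$has_uorf[match(set, usum$gene_id)])
            cbind(set = paste0("up_", s),
                  uorfProportionTest(k, length(set), p0))
        }))
        if (!is.null(utests)) emit(utests, "uorf_tests.tsv")

        stage <- "enrich"
        if (!is.null(terms)) {
            universe <- te_tab$gene_id[!te_tab$low_expression]
            enr <- lapply(strains, function(s) {
                set <- intersect(calls[[s]]$gene_id[calls[[s]]$class == "up"],
                                 universe)
                if (!length(set)) return(NULL)
                enrichTerms(set, universe, terms,
                            alpha = config$enrich_alpha,
                            min_term_size = config$min_term_size)
            })
            names(enr) <- strains
            for (s in strains)
                if (!is.null(enr[[s]]))
                    emit(enr[[s]], paste0("enrichment_", s, ".tsv"))
            if (!any(vapply(enr, is.null, logical(1))))
                emit(compareEnrichments(enr[[1L]], enr[[2L]],
                                        alpha = config$enrich_alpha),
                     "enrichment_compare.tsv")
        }

        stage <- "manifest"
        cfg_path <- file.path(outdir, "config.yaml")
        writeLines(yaml::as.yaml(unclass(config)), cfg_path)
        manifest <- list(
            package = "polysomeTE",
            version = as.character(utils::packageVersion("polysomeTE")),
            seed = config$seed,
            config_md5 = unname(tools::md5sum(cfg_path)),
            files = as.list(tools::md5sum(unlist(files))))
        names(manifest$files) <- basename(names(manifest$files))
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        invisible(manifest)
    }, error = on_fail)
}
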