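#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom BiocGenerics counts sizeFactors sizeFactors<- estimateSizeFactors design
NULL

.FRACTIONS <- c("total", "polysome")

#' Container for a polysome-profiling experiment
#'
#' A \code{TranslatomeExperiment} extends
#' \linkS4class{SummarizedExperiment} and holds one \code{"counts"} assay of
#' non-negative integer read counts (genes x samples) together with the
#' experimental design in \code{colData}: columns \code{strain},
#' \code{time}, \code{fraction} (\code{"total"} or \code{"polysome"}) and
#' \code{replicate}. Per-sample size factors, once estimated, live in
#' \code{colData(x)$sizeFactor}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#' @aliases TranslatomeExperiment-class
#' @exportClass TranslatomeExperiment
setClass("TranslatomeExperiment", contains = "SummarizedExperiment")

setValidity("TranslatomeExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- SummarizedExperiment::assay(object, "counts")
        if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(k != round(k))) msg <- c(msg, "counts must be integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain", "time", "fraction", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("design columns missing: ",
                             paste(miss, collapse = ", ")))
    else {
        if (!all(cd$fraction %in% .FRACTIONS))
            msg <- c(msg, "fraction must be 'total' or 'polysome'")
        if (any(duplicated(rownames(cd))) || is.null(rownames(cd)))
            msg <- c(msg, "sample_ids (colnames) must be unique and non-NULL")
        if (any(cd$replicate < 1) || any(cd$replicate != round(cd$replicate)))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene_ids (rownames) must be unique and non-NULL")
    if (length(msg)) msg else TRUE
})

#' Construct a TranslatomeExperiment
#'
#' @param counts integer matrix of read counts, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param design \code{data.frame} or \code{DataFrame} with one row per
#'   sample and columns \code{sample_id}, \code{strain}, \code{time},
#'   \code{fraction}, \code{replicate}. Columns of \code{counts} are
#'   reordered to match \code{design$sample_id}.
#'
#' @return A \linkS4class{TranslatomeExperiment}.
#' @examples
#' d <- data.frame(sample_id = c("s1", "s2"), strain = "WT", time = "0h",
#'                 fraction = c("total", "polysome"), replicate = 1L)
#' k <- matrix(c(5L, 8L, 7L, 2L), 2, dimnames = list(c("g1", "g2"), d$sample_id))
#' te <- TranslatomeExperiment(k, d)
#' counts(te)
#' @export
TranslatomeExperiment <- function(counts, design) {
    design <- as.data.frame(design)
    need <- c("sample_id", "strain", "time", "fraction", "replicate")
    miss <- setdiff(need, colnames(design))
    if (length(miss))
        stop("design is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(design$sample_id))
        stop("duplicate sample_id in design")
    absent <- setdiff(design$sample_id, colnames(counts))
    if (length(absent))
        stop("samples in design absent from counts: ",
             paste(absent, collapse = ", "))
    counts <- counts[, design$sample_id, drop = FALSE]
    storage.mode(counts) <- "integer"
    cd <- S4Vectors::DataFrame(design[, setdiff(colnames(design), "sample_id"),
                                      drop = FALSE],
                               row.names = design$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("TranslatomeExperiment", se)
}

#' @describeIn TranslatomeExperiment raw count matrix accessor
#' @param object,x a \code{TranslatomeExperiment}
#' @export
setMethod("counts", "TranslatomeExperiment", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' @describeIn TranslatomeExperiment experimental design as a data.frame
#'   with a \code{sample_id} column
#' @export
setMethod("design", "TranslatomeExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    data.frame(sample_id = rownames(cd),
               as.data.frame(cd)[, c("strain", "time", "fraction", "replicate")],
               row.names = NULL)
})

#' @describeIn TranslatomeExperiment per-sample size factors (NULL until
#'   \code{estimateSizeFactors} has been called)
#' @export
setMethod("sizeFactors", "TranslatomeExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"sizeFactor" %in% colnames(cd)) return(NULL)
    stats::setNames(cd$sizeFactor, rownames(cd))
})

#' @describeIn TranslatomeExperiment set size factors
#' @param value named numeric vector of positive factors, one per sample
#' @export
setReplaceMethod("sizeFactors", "TranslatomeExperiment", function(object, value) {
    if (!is.null(names(value)))
        value <- value[colnames(object)]
    if (any(!is.finite(value)) || any(value <= 0))
        stop("size factors must be positive and finite")
    SummarizedExperiment::colData(object)$sizeFactor <- unname(value)
    object
})

setMethod("show", "TranslatomeExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("class: TranslatomeExperiment\n")
    cat("dim:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("strains:", paste(unique(cd$strain), collapse = ", "), "\n")
    cat("times:", paste(unique(cd$time), collapse = ", "), "\n")
    cat("fractions:", paste(unique(cd$fraction), collapse = ", "), "\n")
    cat("size factors:",
        if ("sizeFactor" %in% colnames(cd)) "estimated" else "not estimated",
        "\n")
})
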