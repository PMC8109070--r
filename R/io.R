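#' @importFrom Biostrings readBStringSet writeXStringSet DNAStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read a gene-by-sample count matrix
#'
#' Reads a TSV whose header row holds sample ids and whose first column
#' holds gene ids, checks it against a sample sheet, and returns a
#' \linkS4class{TranslatomeExperiment} with columns in design order.
#'
#' @param path path to the counts TSV.
#' @param design data.frame with columns \code{sample_id}, \code{strain},
#'   \code{time}, \code{fraction}, \code{replicate} (see
#'   \code{\link{readSampleSheet}}).
#'
#' @return A \linkS4class{TranslatomeExperiment}.
#' @export
readCounts <- function(path, design) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    gene_ids <- tab[[1L]]
    if (anyDuplicated(gene_ids))
        stop("duplicate gene_id in ", path, ": ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    missing_cols <- setdiff(design$sample_id, colnames(mat))
    if (length(missing_cols))
        stop("sample column(s) missing from ", path, ": ",
             paste(missing_cols, collapse = ", "))
    num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                   dimnames = dimnames(mat)))
    bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-integer or negative count at gene '", gene_ids[bad[1, 1]],
             "', sample '", colnames(mat)[bad[1, 2]], "': ",
             mat[bad[1, 1], bad[1, 2]])
    storage.mode(num) <- "integer"
    rownames(num) <- gene_ids
    TranslatomeExperiment(num, design)
}

#' Write a count matrix as TSV
#'
#' Inverse of \code{\link{readCounts}}: first column \code{gene_id}, one
#' column per sample.
#'
#' @param x a \code{TranslatomeExperiment} or count matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path) {
    k <- if (is(x, "TranslatomeExperiment")) counts(x) else x
    out <- data.frame(gene_id = rownames(k), k, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' TSV or CSV (by extension) with columns \code{sample_id}, \code{strain},
#' \code{time}, \code{fraction}, \code{replicate}.
#'
#' @param path path to the sample sheet.
#' @return data.frame in file order.
#' @export
readSampleSheet <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    d <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("sample_id", "strain", "time", "fraction", "replicate")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample_id in sample sheet")
    bad <- setdiff(unique(d$fraction), c("total", "polysome"))
    if (length(bad))
        stop("invalid fraction value(s): ", paste(bad, collapse = ", "))
    d$replicate <- as.integer(d$replicate)
    d
}

#' Write a sample sheet as TSV
#' @param design data.frame as returned by \code{\link{readSampleSheet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(design, path) {
    utils::write.table(design, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.parse_cds_tsv <- function(annot_path) {
    first <- readLines(annot_path, n = 1L)
    fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
    has_header <- length(fields) >= 2L &&
        is.na(suppressWarnings(as.numeric(fields[2L])))
    tab <- utils::read.delim(annot_path, header = has_header,
                             stringsAsFactors = FALSE)
    data.frame(gene_id = as.character(tab[[1L]]),
               cds_start = as.integer(tab[[2L]]))
}

.parse_cds_gff3 <- function(annot_path) {
    lines <- readLines(annot_path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) >= 8L && x[3L] == "CDS", logical(1))
    f <- f[keep]
    if (!length(f)) stop("no CDS features found in ", annot_path)
    tx <- vapply(f, `[`, character(1), 1L)
    strand <- vapply(f, `[`, character(1), 7L)
    if (any(strand != "+"))
        stop("only '+'-strand transcript-coordinate CDS records are ",
             "supported; offending transcript(s): ",
             paste(unique(tx[strand != "+"]), collapse = ", "))
    if (anyDuplicated(tx))
        stop("multi-exon (multiple CDS rows) transcripts are not supported: ",
             paste(unique(tx[duplicated(tx)]), collapse = ", "))
    data.frame(gene_id = tx,
               cds_start = as.integer(vapply(f, `[`, character(1), 4L)))
}

#' Read 5' leader sequences
#'
#' Extracts, for every annotated transcript, the 5' leader: the sequence
#' strictly upstream of the annotated CDS start. Input is a transcript
#' FASTA plus either a GFF3 (transcript coordinates, 1-based inclusive,
#' '+' strand, single CDS row per transcript) or a two-column TSV
#' (\code{gene_id}, \code{cds_start_1based}). Sequences are uppercased and
#' RNA is converted to DNA (U to T); letters outside A/C/G/T/N are fatal.
#'
#' @param fasta_path transcript FASTA.
#' @param annot_path GFF3 (extension \code{.gff}/\code{.gff3}) or TSV.
#'
#' @return Named \link[Biostrings]{DNAStringSet} of leaders, one per
#'   annotated transcript; a leader may have width 0 (CDS starts at
#'   position 1). The CDS start offset equals the leader width.
#' @export
readLeaders <- function(fasta_path, annot_path) {
    # read as raw strings: readDNAStringSet would silently drop RNA 'U's
    # instead of letting us convert them
    seqs <- Biostrings::readBStringSet(fasta_path)
    # keep only the first whitespace-delimited token of each FASTA header
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ann <- if (grepl("\\.gff3?$", annot_path, ignore.case = TRUE))
        .parse_cds_gff3(annot_path) else .parse_cds_tsv(annot_path)
    if (anyDuplicated(ann$gene_id))
        stop("duplicate transcript in annotation: ",
             paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
    absent <- setdiff(ann$gene_id, names(seqs))
    if (length(absent))
        stop("transcript(s) in annotation but absent from FASTA: ",
             paste(absent, collapse = ", "))
    seqs <- seqs[ann$gene_id]
    # start == length + 1 marks a leader-only record (whole sequence is
    # the 5' leader), as written by writeLeaders()
    too_far <- ann$cds_start > Biostrings::width(seqs) + 1L | ann$cds_start < 1L
    if (any(too_far))
        stop("CDS start outside sequence for: ",
             paste(ann$gene_id[too_far], collapse = ", "))
    chars <- toupper(as.character(seqs))
    chars <- chartr("U", "T", chars)
    leaders <- substr(chars, 1L, ann$cds_start - 1L)
    bad <- grepl("[^ACGTN]", leaders)
    if (any(bad))
        stop("leader contains letters outside A/C/G/T/N for: ",
             paste(ann$gene_id[bad], collapse = ", "))
    out <- Biostrings::DNAStringSet(leaders)
    names(out) <- ann$gene_id
    out
}

#' Write leaders as FASTA plus CDS-start TSV
#'
#' Writes each leader as a FASTA record and an annotation TSV with
#' \code{cds_start_1based = width + 1}, so that
#' \code{readLeaders(fasta, tsv)} round-trips to the same set.
#'
#' @param leaders named \code{DNAStringSet} of leader sequences.
#' @param fasta_path,annot_path output paths.
#' @return \code{fasta_path}, invisibly.
#' @export
writeLeaders <- function(leaders, fasta_path, annot_path) {
    Biostrings::writeXStringSet(leaders, fasta_path)
    ann <- data.frame(gene_id = names(leaders),
                      cds_start_1based = Biostrings::width(leaders) + 1L)
    utils::write.table(ann, annot_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(fasta_path)
}

#' Read a gene-to-term map
#'
#' Accepts GMT (term id, description, then member genes, tab-separated) or
#' a headerless two-column TSV of (gene, term) pairs. Member genes are
#' deduplicated per term; terms with no genes are dropped with a warning.
#'
#' @param path GMT (detected by any line having 3+ fields or a
#'   \code{.gmt} extension) or two-column TSV.
#'
#' @return Named list of unique gene-id character vectors, one element per
#'   term; \code{attr(x, "term_name")} carries the term descriptions.
#' @export
readTermMap <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty term map: ", path)
    f <- strsplit(lines, "\t", fixed = TRUE)
    is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
        any(lengths(f) >= 3L)
    if (is_gmt) {
        ids <- vapply(f, `[`, character(1), 1L)
        descs <- vapply(f, function(x) if (length(x) >= 2L) x[2L] else x[1L],
                        character(1))
        genes <- lapply(f, function(x) unique(x[-c(1L, 2L)]))
    } else {
        g <- vapply(f, `[`, character(1), 1L)
        t <- vapply(f, `[`, character(1), 2L)
        ids <- unique(t)
        descs <- ids
        genes <- lapply(ids, function(term) unique(g[t == term]))
    }
    if (anyDuplicated(ids))
        stop("duplicate term id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    empty <- lengths(genes) == 0L
    if (any(empty)) {
        warning("dropping term(s) with no genes: ",
                paste(ids[empty], collapse = ", "))
        ids <- ids[!empty]; descs <- descs[!empty]; genes <- genes[!empty]
    }
    names(genes) <- ids
    attr(genes, "term_name") <- stats::setNames(descs, ids)
    genes
}
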