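test_that("count TSVs round-trip and are validated against the design", {
    d <- data.frame(sample_id = c("s1", "s2"), strain = "WT", time = "0h",
                    fraction = c("total", "polysome"), replicate = 1L)
    k <- matrix(c(3L, 0L, 12L, 7L, 1L, 9L), nrow = 3,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
    te <- TranslatomeExperiment(k, d)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCounts(te, path)
    back <- readCounts(path, d)
    expect_identical(counts(back), counts(te))
    expect_identical(design(back), design(te))

    # design sample absent from the file -> error naming the sample
    d2 <- rbind(d, data.frame(sample_id = "s3", strain = "WT", time = "0h",
                              fraction = "total", replicate = 2L))
    expect_error(readCounts(path, d2), "s3")

    # negative cell -> error naming gene and sample
    bad <- read.delim(path, check.names = FALSE, colClasses = "character")
    bad[2, "s2"] <- "-1"
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCounts(path2, d), "gB.*s2")

    # non-integer cell
    bad[2, "s2"] <- "3.5"
    write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCounts(path2, d), "gB.*s2")

    # duplicate gene id
    dup <- rbind(bad[1, ], bad)
    dup[2, "s2"] <- "1"
    write.table(dup, path2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCounts(path2, d), "duplicate gene_id")
})

test_that("count round trip is the identity on random fixtures", {
    set.seed(42)
    for (i in 1:10) {
        n <- sample(3:40, 1)
        m <- sample(2:8, 1)
        d <- makeDesign(strains = "WT", times = "0h", n_reps = m)[seq_len(m), ]
        k <- matrix(rpois(n * m, 50), n,
                    dimnames = list(sprintf("g%02d", 1:n), d$sample_id))
        storage.mode(k) <- "integer"
        te <- TranslatomeExperiment(k, d)
        p <- withr::local_tempfile(fileext = ".tsv")
        writeCounts(te, p)
        expect_identical(counts(readCounts(p, d)), k)
    }
})

test_that("leader extraction takes the sequence strictly before the CDS", {
    fa <- withr::local_tempfile(fileext = ".fa")
    ann <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(">tx1", "CCATGAAATAACCATGGGG",
                 ">tx2", "ATGCCC",
                 ">tx3 extra header text", "ccauggg"), fa)
    writeLines(c("gene_id\tcds_start_1based",
                 "tx1\t14", "tx2\t1", "tx3\t6"), ann)
    led <- readLeaders(fa, ann)
    expect_identical(as.character(led[["tx1"]]), "CCATGAAATAACC")
    expect_identical(nchar(as.character(led[["tx1"]])), 13L)
    # CDS at position 1 -> empty leader, record retained
    expect_identical(as.character(led[["tx2"]]), "")
    # lowercase RNA normalized to uppercase DNA (U inside the leader)
    expect_identical(as.character(led[["tx3"]]), "CCATG")

    # annotated transcript missing from the FASTA
    writeLines(c("gene_id\tcds_start_1based", "nope\t3"), ann)
    expect_error(readLeaders(fa, ann), "nope")
    # CDS start beyond the sequence
    writeLines(c("gene_id\tcds_start_1based", "tx2\t99"), ann)
    expect_error(readLeaders(fa, ann), "outside")
})

test_that("GFF3 CDS annotation is accepted; minus strand and multi-exon are not", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">tx1", "CCATGAAATAACCATGGGG"), fa)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "tx1\tsrc\tCDS\t14\t19\t.\t+\t0\tID=cds1"), gff)
    led <- readLeaders(fa, gff)
    expect_identical(as.character(led[["tx1"]]), "CCATGAAATAACC")

    writeLines(c("tx1\tsrc\tCDS\t14\t19\t.\t-\t0\tID=cds1"), gff)
    expect_error(readLeaders(fa, gff), "strand")
    writeLines(c("tx1\tsrc\tCDS\t4\t9\t.\t+\t0\tID=a",
                 "tx1\tsrc\tCDS\t14\t19\t.\t+\t0\tID=b"), gff)
    expect_error(readLeaders(fa, gff), "multi-exon|supported")
})

test_that("leader round trip and brute-force substring extraction agree", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(1:10, 1)
        seqs <- vapply(seq_len(n), function(j) random_dna(sample(10:80, 1)),
                       character(1))
        starts <- vapply(seqs, function(s) sample(seq_len(nchar(s)), 1), 1L)
        ids <- sprintf("t%02d", seq_len(n))
        fa <- withr::local_tempfile(fileext = ".fa")
        ann <- withr::local_tempfile(fileext = ".tsv")
        writeLines(as.vector(rbind(paste0(">", ids), seqs)), fa)
        writeLines(c("gene_id\tcds_start",
                     paste(ids, starts, sep = "\t")), ann)
        led <- readLeaders(fa, ann)
        expect_identical(as.character(led),
                         setNames(substr(seqs, 1, starts - 1), ids))
        # write -> read round trip on the leader set itself
        fa2 <- withr::local_tempfile(fileext = ".fa")
        ann2 <- withr::local_tempfile(fileext = ".tsv")
        writeLeaders(led, fa2, ann2)
        expect_identical(as.character(readLeaders(fa2, ann2)),
                         as.character(led))
    }
})

test_that("term maps parse from GMT and pair TSV to identical structures", {
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("T1\tdesc one\tg1\tg2", "T2\tdesc two\tg2\tg3\tg3"), gmt)
    tm <- readTermMap(gmt)
    expect_named(tm, c("T1", "T2"))
    expect_setequal(tm$T1, c("g1", "g2"))
    expect_setequal(tm$T2, c("g2", "g3"))  # duplicate g3 collapsed
    expect_identical(unname(attr(tm, "term_name")["T1"]), "desc one")

    # pair TSV with duplicates dedups
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("g1\tT1", "g1\tT1", "g2\tT1", "g2\tT2", "g3\tT2"), tsv)
    tm2 <- readTermMap(tsv)
    expect_setequal(tm2$T1, c("g1", "g2"))

    # same data in both formats -> identical term maps
    writeLines(c("T1\tT1\tg1\tg2", "T2\tT2\tg2\tg3"), gmt)
    tm3 <- readTermMap(gmt)
    expect_identical(lapply(tm3, sort), lapply(tm2, sort))

    # empty term dropped with a warning
    writeLines(c("T1\td\tg1", "T0\td"), gmt)
    expect_warning(tm4 <- readTermMap(gmt), "T0")
    expect_named(tm4, "T1")
})

test_that("the experiment container enforces its invariants", {
    d <- makeDesign(n_reps = 1L)
    k <- matrix(1L, 4, nrow(d),
                dimnames = list(paste0("g", 1:4), d$sample_id))
    expect_s4_class(TranslatomeExperiment(k, d), "TranslatomeExperiment")
    d_bad <- d; d_bad$fraction[1] <- "ribosome"
    expect_error(TranslatomeExperiment(k, d_bad), "fraction")
    k_bad <- k; k_bad[1, 1] <- -1L
    expect_error(TranslatomeExperiment(k_bad, d), "non-negative")
    expect_error(TranslatomeExperiment(k, d[, -1]), "sample_id")
})
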