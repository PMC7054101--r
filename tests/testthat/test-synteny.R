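# Rule-based synteny classification of acyltransferase candidate loci.

test_that("each generated layout classifies to its generating class", {
    expected <- c(rhlAB_operon = "rhlA_glycolipid_operon",
                  rhlA_transporter = "rhlA_transporter_synteny",
                  phaG_context = "phaG",
                  isolated = "unsupported")
    for (kind in names(expected)) {
        res <- classifyLocus(generateNeighborhood(kind))
        expect_identical(res$classification, unname(expected[kind]), info = kind)
        expect_length(res$rule, 1L)   # exactly one rule fires
        expect_true(nzchar(res$trace))
    }
})

test_that("rhlB on the opposite strand does not satisfy the operon rule", {
    ft <- data.frame(id = c("rhlA", "rhlB"),
                     label = c("rhlA_candidate", "rhlB"),
                     strand = c("+", "-"), ordinal = 1:2)
    res <- classifyLocus(geneNeighborhood(ft))
    expect_identical(res$classification, "unsupported")
    # same strand fires rule 1
    ft$strand <- c("+", "+")
    expect_identical(classifyLocus(geneNeighborhood(ft))$classification,
                     "rhlA_glycolipid_operon")
})

test_that("an rhlB anywhere in the window blocks the transporter rule", {
    ft <- data.frame(id = c("rhlA", "tpt", "rhlB"),
                     label = c("rhlA_candidate", "transporter", "rhlB"),
                     strand = c("+", "+", "-"), ordinal = 1:3)
    expect_identical(classifyLocus(geneNeighborhood(ft))$classification,
                     "unsupported")
})

test_that("candidate multiplicity is validated", {
    ft <- data.frame(id = c("a", "b"), label = c("other", "other"),
                     strand = c("+", "+"), ordinal = 1:2)
    expect_error(geneNeighborhood(ft), "exactly one rhlA_candidate")
    ft2 <- data.frame(id = c("a", "b"), label = rep("rhlA_candidate", 2),
                      strand = c("+", "+"), ordinal = 1:2)
    expect_error(geneNeighborhood(ft2), "exactly one rhlA_candidate")
})

test_that("widening the window never flips an operon call to phaG", {
    for (kind in c("rhlAB_operon", "rhlA_transporter", "phaG_context")) {
        c5 <- classifyLocus(generateNeighborhood(kind, window = 5L))$classification
        c10 <- classifyLocus(generateNeighborhood(kind, window = 10L))$classification
        if (c5 == "rhlA_glycolipid_operon")
            expect_identical(c10, "rhlA_glycolipid_operon")
        expect_identical(c5, c10)
    }
})

test_that("GFF3 round trips preserve the layout and its classification", {
    gff <- tempfile(fileext = ".gff3")
    generateNeighborhood("phaG_context", gffPath = gff)
    nb <- readNeighborhood(gff, candidateId = "phaG")
    expect_identical(classifyLocus(nb)$classification, "phaG")
    ft <- features(nb)
    cand <- ft$ordinal[ft$label == "rhlA_candidate"]
    expect_identical(sum(ft$ordinal < cand), 4L)          # four upstream genes
    expect_identical(ft$label[ft$ordinal > cand], "tRNA") # tRNA downstream

    gff2 <- tempfile(fileext = ".gff3")
    generateNeighborhood("rhlAB_operon", gffPath = gff2)
    nb2 <- readNeighborhood(gff2, candidateId = "rhlA")
    expect_true(all(c("rhlB", "rhlR", "rhlI") %in% features(nb2)$label))
    expect_identical(classifyLocus(nb2)$classification, "rhlA_glycolipid_operon")
})

test_that("TSV parsing is equivalent to GFF parsing of the same locus", {
    gff <- tempfile(fileext = ".gff3")
    generateNeighborhood("rhlA_transporter", gffPath = gff)
    fromGff <- readNeighborhood(gff, candidateId = "rhlA")
    tsv <- tempfile(fileext = ".tsv")
    write.table(data.frame(id = c("geneL1", "rhlA", "tpt", "geneR1"),
                           product = c("conserved protein", "HAA synthase candidate",
                                       "putative transporter", "conserved protein"),
                           strand = c("+", "+", "+", "-"),
                           ordinal = 1:4),
                tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    fromTsv <- readNeighborhood(tsv, candidateId = "rhlA")
    expect_identical(features(fromGff)[, c("id", "label", "strand", "ordinal")],
                     features(fromTsv)[, c("id", "label", "strand", "ordinal")])
    expect_identical(classifyLocus(fromTsv)$classification, "rhlA_transporter_synteny")
})

test_that("unmappable products become 'other' with a warning; missing candidates error", {
    tsv <- tempfile(fileext = ".tsv")
    write.table(data.frame(id = c("x", "cand"),
                           product = c("frobnicator subunit", "acyltransferase"),
                           strand = c("+", "+"), ordinal = 1:2),
                tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_warning(nb <- readNeighborhood(tsv, candidateId = "cand"), "frobnicator")
    expect_identical(features(nb)$label, c("other", "rhlA_candidate"))
    expect_error(suppressWarnings(readNeighborhood(tsv, candidateId = "nope")),
                 "not found")
})
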