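mkHits <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(qseqid = r[[1L]], sseqid = r[[2L]], pident = 90,
                   length = 100, mismatch = 5, gapopen = 0,
                   qstart = 1, qend = 100, sstart = 1, send = 100,
                   evalue = r[[3L]],
                   bitscore = if (length(r) > 3L) r[[4L]] else 200,
                   stringsAsFactors = FALSE)))
}

test_that("longest transcript wins, ties break to the smallest id", {
    tx <- data.frame(gene = c("g1", "g1"),
                     transcript = c("t1", "t2"),
                     length = c(300L, 450L))
    expect_equal(selectLongestTranscript(tx), c(g1 = "t2"))
    tie <- data.frame(gene = c("g1", "g1"),
                      transcript = c("t2", "t1"),
                      length = c(300L, 300L))
    expect_equal(selectLongestTranscript(tie), c(g1 = "t1"))
    one <- data.frame(gene = "g1", transcript = "t1", length = 10L)
    expect_equal(selectLongestTranscript(one), c(g1 = "t1"))
    expect_error(selectLongestTranscript(
        data.frame(gene = "g1", transcript = "t1", length = 0L)),
        "positive")
})

test_that("best hits respect the inclusive e-value cutoff", {
    expect_equal(bestHits(mkHits(list("q1", "s1", 1e-10))),
                 c(q1 = "s1"))
    ## above the cutoff: discarded
    expect_length(bestHits(mkHits(list("q1", "s1", 1e-3))), 0L)
    ## exactly at the cutoff: kept (<= is inclusive)
    expect_equal(bestHits(mkHits(list("q1", "s1", 1e-5))),
                 c(q1 = "s1"))
})

test_that("best-hit tie-break cascade ends at the lexicographic subject", {
    expect_equal(bestHits(mkHits(list("q1", "s2", 1e-40, 200),
                                 list("q1", "s1", 1e-40, 200))),
                 c(q1 = "s1"))
    ## bitscore dominates evalue
    expect_equal(bestHits(mkHits(list("q1", "s2", 1e-50, 100),
                                 list("q1", "s1", 1e-40, 300))),
                 c(q1 = "s1"))
    ## HSP rows for one (q, s) collapse to the best before selection
    expect_equal(bestHits(mkHits(list("q1", "s1", 1e-40, 100),
                                 list("q1", "s1", 1e-45, 250),
                                 list("q1", "s2", 1e-45, 200))),
                 c(q1 = "s1"))
})

test_that("reciprocity is required and yields a partial matching", {
    expect_equal(reciprocalBestHits(c(a1 = "b1"), c(b1 = "a1")),
                 data.frame(gene_a = "a1", gene_b = "b1"))
    expect_equal(nrow(reciprocalBestHits(c(a1 = "b1"),
                                         c(b1 = "a2"))), 0L)
    rb <- reciprocalBestHits(c(a1 = "b1", a2 = "b2"),
                             c(b1 = "a1", b2 = "a1"))
    expect_equal(rb, data.frame(gene_a = "a1", gene_b = "b1"))
    ## brute-force reciprocity predicate over all name pairs
    fwd <- c(a1 = "b2", a2 = "b1", a3 = "b3")
    rev <- c(b1 = "a2", b2 = "a3", b3 = "a3")
    got <- reciprocalBestHits(fwd, rev)
    want <- list()
    for (a in names(fwd)) for (b in names(rev))
        if (fwd[[a]] == b && rev[[b]] == a)
            want[[length(want) + 1L]] <- c(a, b)
    expect_equal(nrow(got), length(want))
    for (w in want)
        expect_true(any(got$gene_a == w[1L] & got$gene_b == w[2L]))
    expect_false(anyDuplicated(c(got$gene_a)) > 0 ||
                 anyDuplicated(c(got$gene_b)) > 0)
})

test_that("evidence intersection keeps only agreeing pairs", {
    p1 <- data.frame(gene_a = "a1", gene_b = "b1")
    expect_equal(intersectEvidence(p1, p1)$evidence, "both")
    p2 <- data.frame(gene_a = "a1", gene_b = "b2")
    expect_equal(nrow(intersectEvidence(p1, p2)), 0L)
    expect_equal(nrow(intersectEvidence(p1[0L, ], p1)), 0L)
    ## symmetric and a subset of each input
    big <- data.frame(gene_a = c("a1", "a2", "a3"),
                      gene_b = c("b1", "b2", "b3"))
    sml <- data.frame(gene_a = c("a2", "a9"), gene_b = c("b2", "b9"))
    i1 <- intersectEvidence(big, sml)
    i2 <- intersectEvidence(sml, big)
    expect_equal(i1[c("gene_a", "gene_b")], i2[c("gene_a", "gene_b")])
    expect_true(all(paste(i1$gene_a, i1$gene_b) %in%
                    paste(big$gene_a, big$gene_b)))
})

test_that("raising the e-value cutoff never removes best-hit pairs", {
    set.seed(31)
    hits <- mkHits(list("q1", "s1", 1e-30, 300),
                   list("q1", "s2", 1e-8, 150),
                   list("q2", "s2", 1e-6, 90),
                   list("q3", "s3", 1e-4, 60),
                   list("q4", "s1", 1e-12, 220))
    prev <- character(0)
    for (cut in c(1e-10, 1e-6, 1e-5, 1e-3, 1)) {
        bh <- bestHits(hits, evalueCutoff = cut)
        expect_true(all(prev %in% names(bh)))
        prev <- names(bh)
    }
})

test_that("BLAST tabular reader flags malformed rows with line numbers", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("q1", "s1", 90, 100, 5, 0, 1, 100, 1, 100,
                         "1e-20", 200), collapse = "\t"),
                 paste(c("q2", "s2", 90, 100, 5, 0, 1, 100, 1, 100,
                         "not-a-number", 200), collapse = "\t")), f)
    expect_error(readBlastTab(f), "line 2")
    unlink(f)
})

test_that("transcript pairs lift to genes before intersection", {
    p <- data.frame(gene_a = c("SPA_G0001.T1", "SPA_G0001.T2"),
                    gene_b = c("SPB_G0002.T1", "SPB_G0002.T1"))
    lifted <- liftTranscripts(p)
    expect_equal(lifted,
                 data.frame(gene_a = "SPA_G0001", gene_b = "SPB_G0002"))
    map <- c(x1 = "gA", x2 = "gA", y1 = "gB")
    p2 <- data.frame(gene_a = c("x1", "x2"), gene_b = c("y1", "y1"))
    expect_equal(nrow(liftTranscripts(p2, map)), 1L)
})

test_that("within-species input is ignored with a warning", {
    p <- data.frame(gene_a = "a1", gene_b = "a2")
    expect_warning(out <- canonicalPairs(p, "S1", "S1"),
                   "within-species")
    expect_equal(nrow(out), 0L)
})

test_that("the manifest pipeline recovers planted pairs exactly", {
    spec <- scenarioSpec(seed = 73)
    dir <- file.path(tempdir(), "sim-orth")
    sim <- simulateScenario(spec, dir = dir)
    pairs <- rbbhPipeline(file.path(dir, "manifest.tsv"), dir = dir)
    key <- function(p) sort(paste(p$species_a, p$gene_a,
                                  p$species_b, p$gene_b))
    expect_equal(key(pairs), key(sim$planted$truthPairs))
    unlink(dir, recursive = TRUE)
})
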