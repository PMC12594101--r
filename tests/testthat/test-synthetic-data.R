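test_that("simulated genomes respect bounds, uniqueness and determinism", {
    ann <- makeGenome(1, 10, seed = 1)
    g <- genes(ann)
    expect_length(g, 10L)
    expect_false(anyDuplicated(g$symbol) > 0)
    sl <- GenomeInfoDb::seqlengths(g)
    expect_true(all(GenomicRanges::start(g) >= 1))
    expect_true(all(GenomicRanges::end(g) <=
                    sl[as.character(GenomicRanges::seqnames(g))]))
    cen <- centromeres(ann)
    expect_length(cen, 1L)
    expect_true(GenomicRanges::end(cen) <= sl[[1L]])
    # gene intervals do not overlap
    expect_true(all(GenomicRanges::countOverlaps(g, g) == 1L))
    expect_identical(makeGenome(1, 10, seed = 1), ann)
    expect_false(identical(makeGenome(1, 10, seed = 2), ann))
})

test_that("rpkm zero-inflation matches its configured weight", {
    ann <- makeGenome(2, 50, seed = 7, zeroInflation = 0.2)
    frac <- mean(genes(ann)$rpkm < 0.1)
    expect_lt(abs(frac - 0.2), 0.1)
    ann2 <- makeGenome(2, 200, seed = 7, zeroInflation = 0.5)
    expect_lt(abs(mean(genes(ann2)$rpkm < 0.1) - 0.5), 0.1)
})

test_that("impossible gene packing is a configuration error", {
    expect_error(makeGenome(1, 100, seed = 1, chromosomeLength = 5000),
                 "packing")
})

test_that("library generation counts guides and controls correctly", {
    ann <- makeGenome(1, 10, seed = 1)
    lib <- makeLibrary(ann, 4, 100, seed = 1)
    expect_equal(nGuides(lib), 140L)
    gd <- guides(lib)
    expect_equal(sum(gd$isControl), 100L)
    expect_false(anyDuplicated(gd$sequence) > 0)
    expect_false(anyDuplicated(gd$sgrna) > 0)
    expect_true(all(nchar(gd$sequence) == 20L))
    noCtrl <- makeLibrary(ann, 4, 0, seed = 1)
    expect_equal(sum(guides(noCtrl)$isControl), 0L)
    expect_identical(makeLibrary(ann, 4, 100, seed = 1), lib)
})

test_that("true networks flag artifacts only inside the centromere span", {
    ann <- makeGenome(2, 100, seed = 5)
    reporter <- genes(ann)$symbol[150]
    tr <- makeTrueNetwork(ann, reporter, 5, 5, seed = 5)
    expect_equal(sum(tr$label == "activator"), 5L)
    expect_equal(sum(tr$label == "repressor"), 5L)
    expect_true(all(tr$effect[tr$label == "activator"] < 0))
    expect_true(all(tr$effect[tr$label == "repressor"] > 0))
    expect_true(all(tr$effect[tr$label %in% c("null", "artifact")] == 0))
    span <- ReporterScreen:::centromereSpan(ann, reporter)
    g <- genes(ann)
    inSpan <- g$symbol[IRanges::overlapsAny(g, span)]
    expect_true(all(tr$gene[tr$artifact] %in% inSpan))
    expect_error(makeTrueNetwork(ann, "NOPE", 2, 2), "not in annotation")
})

test_that("per-bin counts sum to the configured read depth", {
    m <- SummarizedExperiment::assay(screenCounts(tinySim$sim), "counts")
    expect_true(all(colSums(m) == tinySim$cfg$readsPerBin))
    expect_true(all(m >= 0))
})

test_that("a null screen is symmetric between bins", {
    lib <- tinySim$lib
    nullTruth <- data.frame(gene = genes(tinySim$ann)$symbol, effect = 0,
                            artifact = FALSE, penetrance = 0)
    sim <- suppressWarnings(simulateScreen(lib, nullTruth,
        screenConfig(replicates = 4, cellsPerReplicate = 6e4,
                     readsPerBin = 5e4, seed = 7)))
    ss <- sgrnaScores(screenCounts(sim))
    # mean log2 low/high ratio centred at zero, no directional drift
    expect_lt(abs(mean(ss$score)), 0.05)
    expect_gt(mean(ss$score > 0), 0.4)
    expect_lt(mean(ss$score > 0), 0.6)
})

test_that("a strong activator's guides enrich in the low bin", {
    ann <- tinySim$ann
    reporter <- tinySim$reporter
    tr <- data.frame(gene = genes(ann)$symbol, effect = 0,
                     artifact = FALSE, penetrance = 0)
    act <- genes(ann)$symbol[10]
    tr$effect[tr$gene == act] <- -2  # knockout halves expression twice
    sim <- suppressWarnings(simulateScreen(tinySim$lib, tr,
        screenConfig(replicates = 8, cellsPerReplicate = 5e4,
                     readsPerBin = 3e4, seed = 11)))
    ss <- sgrnaScores(screenCounts(sim))
    actScores <- ss$score[!is.na(ss$gene) & ss$gene == act]
    expect_length(actScores, 4L)
    expect_true(all(actScores > 0))  # low/high ratio > 1 on log2 scale
})

test_that("detection frequency is monotone in effect size", {
    ann <- makeGenome(1, 100, seed = 21)
    lib <- makeLibrary(ann, 4, 50, seed = 22)
    sym <- genes(ann)$symbol
    planted <- list(`0.5` = sym[1:6], `1` = sym[11:16], `2` = sym[21:26])
    tr <- data.frame(gene = sym, effect = 0, artifact = FALSE,
                     penetrance = 0)
    for (e in names(planted))
        tr$effect[tr$gene %in% planted[[e]]] <- -as.numeric(e)
    sim <- suppressWarnings(simulateScreen(lib, tr,
        screenConfig(replicates = 4, cellsPerReplicate = 2e5,
                     readsPerBin = 1e5, seed = 23)))
    gs <- geneRRA(sgrnaScores(screenCounts(sim)),
                  rraConfig(nPermutations = 2000, seed = 24))
    det <- vapply(planted, function(gg)
        sum(gs$posFdr[gs$gene %in% gg] < 0.05), integer(1L))
    expect_true(det[["0.5"]] <= det[["1"]])
    expect_true(det[["1"]] <= det[["2"]])
    expect_gt(det[["2"]], 3L)
})

test_that("simulation warns when sorted cells underrepresent the library", {
    expect_warning(
        simulateScreen(tinySim$lib, tinySim$truth,
            screenConfig(replicates = 1, cellsPerReplicate = 2e4,
                         readsPerBin = 1e4, seed = 1)),
        "representation loss")
})

test_that("emitted reads follow the amplicon structure and conserve counts", {
    sim <- tinySim$sim
    reads <- emitReads(sim, seed = 1)
    m <- SummarizedExperiment::assay(screenCounts(sim), "counts")
    expect_length(reads, sum(m))
    expect_true(all(Biostrings::width(reads) == 75L))
    # sample rep1_low is assigned primer F01: stagger t, index AAGTAGAG
    gd <- guides(tinySim$lib)
    g1 <- gd$sgrna[1L]
    expected <- toupper(paste0("t", "AAGTAGAG",
                               "TCTTGTGGAAAGGACGAAACACCG",
                               gd$sequence[1L]))
    got <- sum(startsWith(as.character(reads), expected))
    expect_equal(got, unname(m[g1, "rep1_low"]))

    empty <- screenCounts(sim)
    SummarizedExperiment::assay(empty, "counts")[] <- 0L
    expect_length(emitReads(empty), 0L)
})

test_that("read emission errors when the read cannot span the guide", {
    expect_error(emitReads(tinySim$sim, readLength = 50L),
                 "stagger\\+index\\+Template1\\+20")
})

test_that("screen simulation is deterministic under a fixed seed", {
    cfg <- screenConfig(replicates = 2, cellsPerReplicate = 3e4,
                        readsPerBin = 1e4, seed = 31)
    a <- suppressWarnings(simulateScreen(tinySim$lib, tinySim$truth, cfg))
    b <- suppressWarnings(simulateScreen(tinySim$lib, tinySim$truth, cfg))
    expect_identical(SummarizedExperiment::assay(screenCounts(a)),
                     SummarizedExperiment::assay(screenCounts(b)))
})
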