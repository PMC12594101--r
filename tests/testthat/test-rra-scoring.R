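test_that("median-of-ratios size factors behave under scaling", {
    set.seed(42)
    base <- matrix(rnbinom(600, mu = 200, size = 5) + 1L, ncol = 2)
    sc <- countsFromMatrix(cbind(base[, 1], base[, 1]),
                           gene = paste0("G", seq_len(nrow(base))),
                           isControl = rep(FALSE, nrow(base)))
    n <- normalizeCounts(sc)
    sf <- SummarizedExperiment::colData(n)$sizeFactor
    expect_equal(unname(sf[1]), unname(sf[2]))
    expect_identical(SummarizedExperiment::assay(n, "normalized")[, 1],
                     SummarizedExperiment::assay(n, "normalized")[, 2])

    doubled <- countsFromMatrix(cbind(base[, 1], 2L * base[, 1]),
                                gene = paste0("G", seq_len(nrow(base))),
                                isControl = rep(FALSE, nrow(base)))
    nd <- normalizeCounts(doubled)
    sfd <- SummarizedExperiment::colData(nd)$sizeFactor
    expect_equal(unname(sfd[2] / sfd[1]), 2)
    nm <- SummarizedExperiment::assay(nd, "normalized")
    expect_equal(unname(nm[, 1]), unname(nm[, 2]))
})

test_that("size factors match an independent median-of-ratios oracle", {
    set.seed(7)
    m <- matrix(rpois(4 * 300, lambda = 150) + 1L, ncol = 4)
    sc <- countsFromMatrix(m, gene = paste0("G", seq_len(nrow(m))),
                           isControl = rep(FALSE, nrow(m)))
    sf <- SummarizedExperiment::colData(normalizeCounts(sc))$sizeFactor
    # brute force, written out longhand
    geo <- apply(m, 1, function(x) exp(mean(log(x))))
    brute <- vapply(seq_len(ncol(m)),
                    function(j) median(m[, j] / geo), numeric(1))
    expect_equal(unname(sf), brute)
    # DESeq2's estimator as an external cross-check (all-positive matrix)
    ds <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(sf), unname(ds), tolerance = 1e-6)
})

test_that("normalization falls back to totals and rejects empty samples", {
    m <- matrix(c(10L, 0L, 5L, 0L, 20L, 0L, 10L, 0L), ncol = 2)
    sc <- countsFromMatrix(m, gene = paste0("G", 1:4),
                           isControl = rep(FALSE, 4))
    sf <- SummarizedExperiment::colData(normalizeCounts(sc))$sizeFactor
    tot <- colSums(m)
    expect_equal(unname(sf), unname(tot / mean(tot)))
    m0 <- m; m0[, 2] <- 0L
    sc0 <- countsFromMatrix(m0, gene = paste0("G", 1:4),
                            isControl = rep(FALSE, 4))
    expect_error(normalizeCounts(sc0), "zero total")
})

test_that("sgRNA scores: zeros for balanced guides, ranks and control p", {
    nG <- 20L
    low <- matrix(c(rep(100L, nG)), ncol = 1)
    m <- cbind(rep1_low = rep(100L, nG), rep1_high = rep(100L, nG),
               rep2_low = rep(100L, nG), rep2_high = rep(100L, nG))
    sc <- countsFromMatrix(m, gene = c(paste0("G", 1:15), rep(NA, 5)),
                           isControl = c(rep(FALSE, 15), rep(TRUE, 5)),
                           replicate = c(1L, 1L, 2L, 2L),
                           bin = c("low", "high", "low", "high"))
    ss <- sgrnaScores(sc)
    expect_true(all(ss$score == 0))
    # one guide strictly most low-enriched -> pos percentile rank 1/n
    m2 <- m; m2[1L, c(1L, 3L)] <- 400L
    sc2 <- countsFromMatrix(m2, gene = c(paste0("G", 1:15), rep(NA, 5)),
                            isControl = c(rep(FALSE, 15), rep(TRUE, 5)),
                            replicate = c(1L, 1L, 2L, 2L),
                            bin = c("low", "high", "low", "high"))
    ss2 <- sgrnaScores(sc2)
    expect_equal(ss2$posRank[1L], 1 / nG)
    expect_equal(ss2$negRank[1L], 1)
})

test_that("a control at the control median has empirical p near 0.5", {
    nC <- 1001L
    low <- as.integer(seq(50L, 1050L))          # distinct ratios
    m <- cbind(rep1_low = low, rep1_high = rep(500L, nC))
    sc <- countsFromMatrix(m, gene = rep(NA_character_, nC),
                           isControl = rep(TRUE, nC),
                           replicate = c(1L, 1L), bin = c("low", "high"))
    ss <- sgrnaScores(sc)
    med <- which(rank(ss$score, ties.method = "first") == 501L)
    expected <- (1 + sum(ss$score >= ss$score[med])) / (1 + nC)
    expect_equal(ss$posP[med], expected)
    expect_lt(abs(ss$posP[med] - 0.5), 0.01)
})

test_that("scoring requires control guides", {
    m <- cbind(rep1_low = c(10L, 20L), rep1_high = c(10L, 20L),
               rep2_low = c(10L, 20L), rep2_high = c(10L, 20L))
    sc <- countsFromMatrix(m, gene = c("G1", "G2"),
                           isControl = c(FALSE, FALSE),
                           replicate = c(1L, 1L, 2L, 2L),
                           bin = c("low", "high", "low", "high"))
    expect_error(sgrnaScores(sc), "control sgRNAs")
})

test_that("rho reduces to the rank for one selected guide and to 1 for none", {
    ss <- data.frame(sgrna = paste0("s", 1:5),
                     gene = c("A", rep("Z", 4)),
                     isControl = FALSE,
                     score = c(5, 4, 3, 2, 1),
                     posP = c(0.01, rep(0.5, 4)),
                     negP = rep(0.99, 5),
                     posRank = c(0.2, 0.4, 0.6, 0.8, 1.0),
                     negRank = c(1.0, 0.8, 0.6, 0.4, 0.2))
    gs <- geneRRA(ss, rraConfig(alpha = 0.05, nPermutations = 200, seed = 1))
    # Beta(1, 1) CDF identity: single selected guide at rank r -> rho = r
    expect_equal(gs$posScore[gs$gene == "A"], 0.2)
    # Z has no guide below alpha -> rho 1, permutation p 1
    expect_equal(gs$posScore[gs$gene == "Z"], 1)
    expect_equal(gs$posP[gs$gene == "Z"], 1)
    expect_equal(gs$posGood[gs$gene == "Z"], 0L)
})

test_that("alpha-RRA matches an exhaustive enumeration on a 3-gene toy", {
    # 6 guides, 2 per gene; ranks fixed; all guides pass alpha
    ranks <- c(1, 2, 3, 4, 5, 6) / 6
    gene <- c("A", "A", "B", "B", "C", "C")
    ss <- data.frame(sgrna = paste0("s", 1:6), gene = gene,
                     isControl = FALSE, score = rev(seq_len(6)),
                     posP = 0.01, negP = 0.99,
                     posRank = ranks, negRank = rev(ranks))
    nPerm <- 20000L
    gs <- geneRRA(ss, rraConfig(alpha = 0.05, nPermutations = nPerm,
                                seed = 99))
    # exact rho from the brute-force order-statistic definition
    for (g in c("A", "B", "C")) {
        i <- gene == g
        expect_equal(gs$posScore[gs$gene == g],
                     bruteRho(ranks[i], rep(0.01, 2), 0.05))
    }
    # exhaustive permutation null: all C(6,2) rank pairs
    combos <- combn(6L, 2L)
    rhoNull <- apply(combos, 2L, function(ix)
        bruteRho(ranks[ix], rep(0.01, 2), 0.05))
    for (g in c("A", "B", "C")) {
        rho <- gs$posScore[gs$gene == g]
        exact <- mean(rhoNull <= rho)
        expect_lt(abs(gs$posP[gs$gene == g] - exact), 0.02)
    }
})

test_that("rho is monotone: improving a selected rank never raises rho", {
    set.seed(5)
    for (i in 1:50) {
        m <- sample(2:6, 1)
        r <- sort(runif(m))
        p <- runif(m, 0, 0.04)        # all selected
        rho <- bruteRho(r, p, 0.05)
        j <- sample(m, 1)
        r2 <- r; r2[j] <- r2[j] * runif(1)
        expect_lte(bruteRho(r2, p, 0.05), rho)
        # same property through the package path
        ss <- data.frame(sgrna = paste0("s", seq_len(m)), gene = "A",
                         isControl = FALSE, score = rev(seq_len(m)),
                         posP = p, negP = 0.99, posRank = r,
                         negRank = rev(r))
        gs <- geneRRA(ss, rraConfig(alpha = 0.05, nPermutations = 100,
                                    seed = 1))
        expect_equal(gs$posScore, rho)
    }
})

test_that("permutation p respects its lower bound exactly", {
    nPerm <- 500L
    ss <- data.frame(sgrna = paste0("s", 1:40),
                     gene = c(rep("HIT", 4), rep(paste0("G", 1:9),
                                                 each = 4)),
                     isControl = FALSE, score = seq(40, 1),
                     posP = c(rep(1e-4, 4), rep(0.6, 36)),
                     negP = 0.99,
                     posRank = seq_len(40) / 40,
                     negRank = rev(seq_len(40)) / 40)
    gs <- geneRRA(ss, rraConfig(alpha = 0.05, nPermutations = nPerm,
                                seed = 3))
    expect_equal(gs$posP[gs$gene == "HIT"], 1 / (nPerm + 1))
    expect_true(all(gs$posP >= 1 / (nPerm + 1)))
    expect_true(all(gs$negP >= 1 / (nPerm + 1)))
})

test_that("null gene p-values are uniform without selection truncation", {
    ann <- makeGenome(1, 300, seed = 51)
    lib <- makeLibrary(ann, 4, 100, seed = 52)
    nullTruth <- data.frame(gene = genes(ann)$symbol, effect = 0,
                            artifact = FALSE, penetrance = 0)
    sim <- suppressWarnings(simulateScreen(lib, nullTruth,
        screenConfig(replicates = 4, cellsPerReplicate = 3e5,
                     readsPerBin = 1e5, seed = 53)))
    ss <- sgrnaScores(screenCounts(sim))
    gsFree <- geneRRA(ss, rraConfig(alpha = 1, nPermutations = 4000,
                                    seed = 54))
    ks <- suppressWarnings(ks.test(gsFree$posP, "punif"))
    expect_gt(ks$p.value, 0.01)
    # and with selection at the default alpha the extreme tail stays empty
    gsSel <- geneRRA(ss, rraConfig(alpha = 0.05, nPermutations = 4000,
                                   seed = 55))
    expect_lte(mean(gsSel$posP < 1e-3), 0.005)
    expect_lte(mean(gsSel$negP < 1e-3), 0.005)
})

test_that("score tables export losslessly in the fixed column order", {
    gs <- data.frame(gene = c("B", "A"),
                     posScore = c(1e-5, 0.2), posP = c(1e-4, 0.3),
                     posFdr = c(2e-4, 0.5), posGood = c(4L, 1L),
                     negScore = c(0.9, 0.4), negP = c(0.95, 0.5),
                     negFdr = c(0.95, 0.7), negGood = c(0L, 2L),
                     stringsAsFactors = FALSE)
    f <- tempfile(fileext = ".tsv")
    exportScores(gs, f)
    header <- strsplit(readLines(f, n = 1L), "\t")[[1L]]
    expect_identical(header, c("gene", "pos.score", "neg.score", "pos.p",
                               "neg.p", "pos.fdr", "neg.fdr",
                               "pos.goodsgrna", "neg.goodsgrna"))
    back <- readScores(f)
    expect_equal(back$gene, c("B", "A"))  # sorted by min(pos, neg)
    expect_equal(back[order(back$gene), -1],
                 gs[order(gs$gene), names(back)[-1]],
                 ignore_attr = TRUE)
    # empty table -> header-only file
    f2 <- tempfile(fileext = ".tsv")
    exportScores(gs[0, ], f2)
    expect_length(readLines(f2), 1L)
})
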