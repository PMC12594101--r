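test_that("overlap matrices count shared regulators symmetrically", {
    a <- hitTableFrom("S1", activators = c("R1", "R2", "R3"),
                      repressors = c("Q1", "Q2"))
    b <- hitTableFrom("S2", activators = c("R1", "R2", "R3"),
                      repressors = c("Q1", "Q2"))
    c_ <- hitTableFrom("S3", activators = c("X1", "X2"),
                       repressors = "Y1")
    om <- overlapMatrices(list(a, b, c_))
    expect_equal(om$activator["S1", "S2"], 3L)
    expect_equal(om$activator["S1", "S1"], 3L)   # diagonal = hit count
    expect_equal(om$jaccardActivator["S1", "S2"], 1)
    expect_equal(om$activator["S1", "S3"], 0L)   # disjoint
    expect_equal(om$jaccardActivator["S1", "S3"], 0)
    expect_identical(om$repressor, t(om$repressor))
    expect_true(all(om$jaccardRepressor >= 0 & om$jaccardRepressor <= 1))
    # off-diagonals never exceed either diagonal
    d <- diag(om$activator)
    expect_true(all(om$activator <= pmin(outer(d, d, pmin),
                                         outer(d, d, pmax))))
})

test_that("matrix-product overlaps agree with explicit set intersection", {
    set.seed(3)
    tabs <- lapply(1:6, function(i) {
        hitTableFrom(paste0("S", i),
            activators = paste0("R", sample.int(40, sample(5:20, 1))),
            repressors = paste0("Q", sample.int(40, sample(5:20, 1))))
    })
    om <- overlapMatrices(tabs)
    for (i in 1:6) for (j in 1:6) {
        ai <- hits(tabs[[i]]); aj <- hits(tabs[[j]])
        sa <- length(intersect(ai$gene[ai$sense == "activator"],
                               aj$gene[aj$sense == "activator"]))
        expect_equal(unname(om$activator[i, j]), sa)
        sr <- length(intersect(ai$gene[ai$sense == "repressor"],
                               aj$gene[aj$sense == "repressor"]))
        expect_equal(unname(om$repressor[i, j]), sr)
    }
})

test_that("screens cluster into the planted activator/repressor groups", {
    tabs <- plantedTables()
    cl <- clusterScreens(overlapMatrices(unname(tabs)))
    asn <- cl$assignment
    gA <- asn$group[startsWith(asn$screen, "gA")]
    gB <- asn$group[startsWith(asn$screen, "gB")]
    expect_true(all(gA == "1"))  # activator-sharing block is group 1
    expect_true(all(gB == "2"))
    expect_gt(cl$silhouette, 0.2)
})

test_that("group recovery is invariant to screen order and noise-tolerant", {
    tabs <- plantedTables()
    base <- clusterScreens(overlapMatrices(unname(tabs)))$assignment
    perm <- clusterScreens(overlapMatrices(unname(tabs[c(3, 8, 1, 10, 2,
                                                         7, 5, 9, 4, 6)])))
    pa <- perm$assignment
    expect_equal(base$group[match(pa$screen, base$screen)], pa$group)
    noisy <- plantedTables(flip = c(2L, 8L), seed = 11)
    na <- clusterScreens(overlapMatrices(unname(noisy)))$assignment
    agree <- mean(na$group == base$group[match(na$screen, base$screen)])
    expect_gte(agree, 0.9)
})

test_that("identical screens cannot be partitioned and are unassigned", {
    same <- lapply(1:4, function(i)
        hitTableFrom(paste0("S", i), activators = c("R1", "R2"),
                     repressors = "Q1"))
    cl <- clusterScreens(overlapMatrices(same))
    expect_true(all(cl$assignment$group == "unassigned"))
    expect_error(clusterScreens(overlapMatrices(same[1:2])), "at least 3")
})

test_that("shared regulators over 2-4 screens give consistent Venn regions", {
    t1 <- hitTableFrom("S1", activators = paste0("R", 1:5))
    t2 <- hitTableFrom("S2", activators = paste0("R", 1:5))
    sh <- sharedRegulators(list(t1, t2), c("S1", "S2"), "activator")
    expect_length(sh$shared, 5L)
    t3 <- hitTableFrom("S3", activators = paste0("R", 3:8))
    t4 <- hitTableFrom("S4", activators = character())
    sh4 <- sharedRegulators(list(t1, t2, t3, t4),
                            c("S1", "S2", "S3", "S4"), "activator")
    expect_length(sh4$shared, 0L)
    union_ <- length(unique(c(paste0("R", 1:5), paste0("R", 3:8))))
    expect_equal(sum(sh4$regions), union_)
    sh3 <- sharedRegulators(list(t1, t2, t3), c("S1", "S3"), "activator")
    expect_equal(sort(sh3$shared), paste0("R", 3:5))
    expect_error(sharedRegulators(list(t1, t2), c("S1", "NOPE")),
                 "unknown screen")
    expect_error(sharedRegulators(list(t1, t2), "S1"), "between 2 and 4")
})

test_that("condition-specific regulators subtract the untreated union", {
    tr1 <- hitTableFrom("R_T1", activators = c("FKBP1A", "NAE1", "COMMON"))
    tr2 <- hitTableFrom("R_T2", activators = c("FKBP1A", "NAE1", "COMMON",
                                               "EXTRA"))
    tr3 <- hitTableFrom("R_T3", activators = c("FKBP1A", "NAE1", "COMMON"))
    un1 <- hitTableFrom("U1", activators = c("COMMON", "OTHER"))
    un2 <- hitTableFrom("U2", repressors = "NAE1")
    res <- conditionSpecificRegulators(list(tr1, tr2, tr3),
                                       list(un1, un2))
    expect_setequal(res$common, c("FKBP1A", "NAE1", "COMMON"))
    expect_setequal(res$specific, "FKBP1A")
    # sense-restricted: NAE1 untreated hit is a repressor only
    resAct <- conditionSpecificRegulators(list(tr1, tr2, tr3),
                                          list(un1, un2),
                                          sense = "activator")
    expect_setequal(resAct$specific, c("FKBP1A", "NAE1"))
    same <- conditionSpecificRegulators(list(tr1), list(tr1))
    expect_length(same$specific, 0L)
})

test_that("class composition fractions are coherent", {
    t1 <- hitTableFrom("S1", activators = c("R1", "R2", "R3"),
                       repressors = c("Q1", "Q2"))
    mapAll <- data.frame(gene = c("R1", "R2", "R3", "Q1", "Q2"),
                         class = "ribosome")
    cd <- classDistribution(list(t1), mapAll)
    expect_true(all(cd$fraction == 1))
    expect_equal(sum(cd$count[cd$sense == "activator"]), 3L)
    mapNone <- data.frame(gene = character(), class = character())
    cdEmpty <- classDistribution(list(t1), mapNone)
    expect_true(nrow(cdEmpty) == 0L || all(cdEmpty$fraction == 0))
    mapHalf <- data.frame(gene = c("R1", "Q1", "Q2"),
                          class = c("ribosome", "ribosome", "cycle"))
    cdH <- classDistribution(list(t1), mapHalf)
    expect_true(all(cdH$fraction >= 0 & cdH$fraction <= 1))
    expect_equal(cdH$fraction[cdH$sense == "activator" &
                              cdH$class == "ribosome"], 1 / 3)
    repTot <- sum(cdH$count[cdH$sense == "repressor"])
    expect_equal(repTot, 2L)  # mapped repressors across classes
})
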