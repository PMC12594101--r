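# Fixtures are built in code; nothing is read from disk.

# Annotation with explicit coordinates, for filter tests.
annotationFromTable <- function(chromLen, geneDf, cenDf) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(chromLen),
                                seqlengths = unname(chromLen))
    g <- GenomicRanges::GRanges(geneDf$chrom,
                                IRanges::IRanges(geneDf$start, geneDf$end),
                                seqinfo = si)
    g$symbol <- geneDf$symbol
    g$rpkm <- if (is.null(geneDf$rpkm)) rep(1, nrow(geneDf)) else geneDf$rpkm
    cen <- GenomicRanges::GRanges(cenDf$chrom,
                                  IRanges::IRanges(cenDf$start, cenDf$end),
                                  seqinfo = si)
    new("GenomeAnnotation", genes = g, centromeres = cen)
}

# Minimal hit table from activator / repressor gene vectors.
hitTableFrom <- function(screen, activators = character(),
                         repressors = character(), score = 1e-4) {
    h <- rbind(
        data.frame(gene = activators,
                   sense = rep("activator", length(activators)),
                   score = rep(score, length(activators)),
                   fdr = rep(score, length(activators)),
                   stringsAsFactors = FALSE),
        data.frame(gene = repressors,
                   sense = rep("repressor", length(repressors)),
                   score = rep(score, length(repressors)),
                   fdr = rep(score, length(repressors)),
                   stringsAsFactors = FALSE))
    new("HitTable", screen = screen, hits = h,
        removed = data.frame(gene = character(), sense = character(),
                             score = numeric(), reason = character(),
                             stringsAsFactors = FALSE),
        cutoff = 1e-3)
}

# ScreenCounts straight from a matrix (rows auto-named sg001...).
countsFromMatrix <- function(m, gene, isControl, replicate = NULL,
                             bin = NULL, sequence = NULL) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("sg%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
    gd <- data.frame(sgrna = rownames(m), gene = gene,
                     isControl = isControl, stringsAsFactors = FALSE)
    if (!is.null(sequence)) gd$sequence <- sequence
    cd <- S4Vectors::DataFrame(
        sample = colnames(m),
        replicate = if (is.null(replicate)) NA_integer_ else replicate,
        bin = if (is.null(bin)) NA_character_ else bin,
        row.names = colnames(m))
    ReporterScreen:::newScreenCounts(m, gd, cd)
}

# Independent brute-force alpha-RRA rho, written against the definition
# rather than the package internals: sorted ranks, Beta order statistics.
bruteRho <- function(ranks, pvals, alpha) {
    ord <- order(ranks)
    r <- ranks[ord]
    sel <- pvals[ord] < alpha
    if (!any(sel)) return(1)
    m <- length(r)
    vals <- c()
    for (k in seq_len(m))
        if (sel[k]) vals <- c(vals, pbeta(r[k], k, m - k + 1))
    min(vals)
}

# Ten screens with a planted two-block structure: block A screens share
# activators, block B screens share repressors.
plantedTables <- function(flip = integer(), seed = 7, nA = 30L, nB = 30L) {
    set.seed(seed)
    sharedAct <- paste0("A", 1:nA)
    sharedRep <- paste0("B", 1:nB)
    tabs <- list()
    for (i in 1:5) tabs[[paste0("gA", i)]] <- hitTableFrom(
        paste0("gA", i),
        activators = c(sharedAct, paste0("uA", i, "_", 1:5)),
        repressors = paste0("uR", i, "_", 1:8))
    for (i in 1:5) tabs[[paste0("gB", i)]] <- hitTableFrom(
        paste0("gB", i),
        activators = paste0("vA", i, "_", 1:8),
        repressors = c(sharedRep, paste0("vR", i, "_", 1:5)))
    for (i in flip) {  # label noise: thin a screen's shared set
        nm <- names(tabs)[i]
        h <- hits(tabs[[nm]])
        drop <- sample(which(h$gene %in% c(sharedAct, sharedRep)),
                       ceiling(nA * 0.3))
        tabs[[nm]]@hits <- h[-drop, ]
    }
    tabs
}

# A small simulated screen shared by several tests.
tinySim <- local({
    ann <- makeGenome(1, 50, seed = 101)
    lib <- makeLibrary(ann, 4, 20, seed = 102)
    reporter <- genes(ann)$symbol[40]
    tr <- makeTrueNetwork(ann, reporter, 3, 3, effectSize = 2,
                          seed = 103)
    cfg <- screenConfig(replicates = 3, cellsPerReplicate = 6e4,
                        readsPerBin = 3e4, seed = 104)
    sim <- suppressWarnings(simulateScreen(lib, tr, cfg,
                                           reporterGene = reporter))
    list(ann = ann, lib = lib, reporter = reporter, truth = tr,
         cfg = cfg, sim = sim)
})
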