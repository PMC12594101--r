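#' Screen simulation parameters
#'
#' Bundles the experimental-design parameters of a sorted-bin reporter
#' screen. Defaults mirror the screening protocol (6 replicates, MOI 0.3,
#' bottom/top 5\% tails) at desk scale: cell and read numbers are scaled
#' down from the ~60 million sorted cells and ~9 million tail cells per
#' replicate of a production screen.
#'
#' @param replicates sorted replicates (>= 1; default 6).
#' @param moi multiplicity of infection (> 0; recorded for provenance --
#'   the cell model assumes exactly one guide per infected, selected
#'   cell, which MOI 0.3 plus selection makes a good approximation).
#' @param sortFraction fraction of cells sorted into each tail
#'   (0 < f < 0.5; default 0.05).
#' @param cellsPerReplicate infected cells entering the sort per
#'   replicate.
#' @param readsPerBin sequencing reads per sorted bin.
#' @param reporterMeanlog,reporterSdlog natural-log parameters of the
#'   log-normal baseline reporter intensity.
#' @param libraryDispersion Dirichlet concentration scale controlling
#'   plasmid-library skew of guide frequencies.
#' @param seed optional RNG seed for the whole simulation.
#' @return A classed list of validated parameters.
#' @examples
#' screenConfig(replicates = 3, cellsPerReplicate = 1e5)
#' @export
screenConfig <- function(replicates = 6L, moi = 0.3, sortFraction = 0.05,
                         cellsPerReplicate = 2e6, readsPerBin = 2e5,
                         reporterMeanlog = log(1000), reporterSdlog = 0.5,
                         libraryDispersion = 300, seed = NULL) {
    stopIfNot(replicates >= 1L, "replicates must be >= 1")
    stopIfNot(moi > 0, "MOI must be > 0")
    stopIfNot(sortFraction > 0 && sortFraction < 0.5,
              "sortFraction must be in (0, 0.5)")
    stopIfNot(cellsPerReplicate >= 1, "cellsPerReplicate must be >= 1")
    stopIfNot(readsPerBin >= 1, "readsPerBin must be >= 1")
    structure(list(replicates = as.integer(replicates), moi = moi,
                   sortFraction = sortFraction,
                   cellsPerReplicate = as.integer(cellsPerReplicate),
                   readsPerBin = as.integer(readsPerBin),
                   reporterMeanlog = reporterMeanlog,
                   reporterSdlog = reporterSdlog,
                   libraryDispersion = libraryDispersion, seed = seed),
              class = "ScreenConfig")
}

#' Plant a ground-truth regulatory structure for one reporter
#'
#' Assigns log2 knockout effects on the reporter to randomly chosen
#' regulator genes and flags centromere-proximal artifact genes. The
#' sign convention follows the screen readout: \code{effect} is the
#' log2 fold-change of reporter expression when the gene is knocked out,
#' so activators carry \emph{negative} effects (knockout lowers the
#' reporter, guides enrich in the low bin) and repressors positive ones.
#' Artifact genes model Cas9-induced loss of the knock-in reporter
#' allele: they lie between the centromere and the reporter locus and,
#' with probability \code{penetrance} per cell, abolish the reporter
#' signal entirely.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param reporterGene symbol of the knock-in reporter gene.
#' @param nActivators,nRepressors numbers of true regulators to plant.
#' @param effectSize magnitude(s) of planted log2 effects, recycled over
#'   regulators of each sense.
#' @param nArtifacts number of artifact genes to flag, drawn from genes
#'   lying in the centromere-to-reporter span (default: all of them).
#' @param penetrance per-cell probability of reporter loss for artifact
#'   genes.
#' @param seed optional RNG seed.
#' @return data.frame with one row per annotated gene: \code{gene},
#'   \code{effect}, \code{artifact}, \code{penetrance}, \code{label}.
#' @examples
#' ann <- makeGenome(2, 100, seed = 1)
#' tr <- makeTrueNetwork(ann, genes(ann)$symbol[150], 5, 5, seed = 1)
#' table(tr$label)
#' @export
makeTrueNetwork <- function(annotation, reporterGene, nActivators = 20L,
                            nRepressors = 20L, effectSize = 2,
                            nArtifacts = NULL, penetrance = 0.3,
                            seed = NULL) {
    g <- genes(annotation)
    stopIfNot(reporterGene %in% g$symbol,
              "reporter gene not in annotation: ", reporterGene)
    span <- centromereSpan(annotation, reporterGene)
    inSpan <- g$symbol[IRanges::overlapsAny(g, span)]
    inSpan <- setdiff(inSpan, reporterGene)
    withSeed(seed, {
        pool <- setdiff(g$symbol, c(inSpan, reporterGene))
        stopIfNot(length(pool) >= nActivators + nRepressors,
                  "not enough genes outside the artifact span")
        reg <- sample(pool, nActivators + nRepressors)
        act <- reg[seq_len(nActivators)]
        rep_ <- reg[nActivators + seq_len(nRepressors)]
        art <- if (is.null(nArtifacts)) inSpan
               else sample(inSpan, min(nArtifacts, length(inSpan)))
        eff <- stats::setNames(numeric(length(g)), g$symbol)
        eff[act] <- -rep_len(effectSize, nActivators)
        eff[rep_] <- rep_len(effectSize, nRepressors)
        label <- rep("null", length(g))
        names(label) <- g$symbol
        label[act] <- "activator"
        label[rep_] <- "repressor"
        label[art] <- "artifact"
        data.frame(gene = g$symbol, effect = unname(eff),
                   artifact = g$symbol %in% art,
                   penetrance = ifelse(g$symbol %in% art, penetrance, 0),
                   label = unname(label), stringsAsFactors = FALSE)
    })
}

#' Simulate a FACS-sorted CRISPR reporter screen
#'
#' Cell-level generative model: each cell carries exactly one guide
#' (frequencies drawn once per screen from a Dirichlet perturbation of
#' uniform to mimic plasmid-library skew); its reporter intensity is
#' log-normal, multiplied by \code{2^effect} of the guide's target gene;
#' artifact-gene cells lose the reporter entirely with the gene's
#' penetrance. Per replicate, the bottom and top \code{sortFraction}
#' tails of the reporter distribution are sorted and each sorted bin is
#' sequenced as a multinomial draw of \code{readsPerBin} reads over the
#' guide frequencies within that bin.
#'
#' @param library an \linkS4class{SgRNALibrary}.
#' @param truth ground-truth effect table from
#'   \code{\link{makeTrueNetwork}} (or any data.frame with \code{gene},
#'   \code{effect}, \code{artifact}, \code{penetrance}).
#' @param config a \code{\link{screenConfig}}.
#' @param reporterGene optional reporter symbol, stored as metadata.
#' @return A \linkS4class{SimulatedScreen}.
#' @examples
#' ann <- makeGenome(1, 50, seed = 1)
#' lib <- makeLibrary(ann, 4, 20, seed = 1)
#' tr <- makeTrueNetwork(ann, genes(ann)$symbol[40], 3, 3, seed = 1)
#' sim <- simulateScreen(lib, tr, screenConfig(replicates = 2,
#'     cellsPerReplicate = 5e4, readsPerBin = 2e4, seed = 1))
#' sim
#' @export
simulateScreen <- function(library, truth, config = screenConfig(),
                           reporterGene = NULL) {
    gd <- guides(library)
    n <- nrow(gd)
    stopIfNot(all(is.finite(truth$effect)), "effect sizes must be finite")
    idx <- match(gd$gene, truth$gene)
    eff <- ifelse(is.na(idx), 0, truth$effect[idx])
    art <- !is.na(idx) & truth$artifact[idx]
    pen <- ifelse(is.na(idx), 0, truth$penetrance[idx])
    R <- config$replicates
    withSeed(config$seed, {
        p <- rdirichlet1(config$libraryDispersion * stats::runif(n))
        N <- config$cellsPerReplicate
        k <- as.integer(floor(config$sortFraction * N))
        stopIfNot(k >= 1L, "sortFraction * cellsPerReplicate < 1")
        if (k < 10L * n)
            warning("fewer sorted cells per bin (", k, ") than 10x ",
                    "library size (", 10L * n, "): representation loss")
        mat <- matrix(0L, nrow = n, ncol = 2L * R)
        for (r in seq_len(R)) {
            cellsPerGuide <- stats::rmultinom(1L, N, p)[, 1L]
            guideOf <- rep.int(seq_len(n), cellsPerGuide)
            lr <- stats::rnorm(N,
                mean = config$reporterMeanlog + log(2) * eff[guideOf],
                sd = config$reporterSdlog)
            ai <- which(art[guideOf])
            if (length(ai)) {
                lost <- ai[stats::runif(length(ai)) < pen[guideOf[ai]]]
                lr[lost] <- -Inf
            }
            ord <- order(lr)
            lowTab <- tabulate(guideOf[ord[seq_len(k)]], nbins = n)
            highTab <- tabulate(guideOf[ord[(N - k + 1L):N]], nbins = n)
            mat[, 2L * r - 1L] <-
                stats::rmultinom(1L, config$readsPerBin, lowTab)[, 1L]
            mat[, 2L * r] <-
                stats::rmultinom(1L, config$readsPerBin, highTab)[, 1L]
        }
        colData <- S4Vectors::DataFrame(
            sample = paste0("rep", rep(seq_len(R), each = 2L), "_",
                            rep(c("low", "high"), R)),
            replicate = rep(seq_len(R), each = 2L),
            bin = rep(c("low", "high"), R))
        rownames(colData) <- colData$sample
        colnames(mat) <- colData$sample
        rownames(mat) <- gd$sgrna
        sc <- newScreenCounts(mat, gd, colData)
        S4Vectors::metadata(sc)$reporterGene <- reporterGene
        if (!"label" %in% names(truth))
            truth$label <- ifelse(truth$artifact, "artifact",
                ifelse(truth$effect < 0, "activator",
                       ifelse(truth$effect > 0, "repressor", "null")))
        new("SimulatedScreen", counts = sc, truth = truth,
            config = unclass(config))
    })
}

# Assemble a ScreenCounts from a count matrix and a guide table.
newScreenCounts <- function(mat, gd, colData) {
    rd <- S4Vectors::DataFrame(gene = gd$gene, isControl = gd$isControl,
                               row.names = gd$sgrna)
    if (!is.null(gd$sequence)) rd$sequence <- gd$sequence
    new("ScreenCounts", SummarizedExperiment(
        assays = list(counts = mat), rowData = rd, colData = colData))
}

#' Emit amplicon reads for a simulated screen
#'
#' Converts a sorted-bin count table into single-end amplicon reads with
#' the fixed structure stagger + 8-nt index + Template1 + sgRNA + prefix
#' of Template2, truncated to \code{readLength} (default 75 nt). One read
#' is emitted per count, so the read set and count table are mutually
#' recoverable (see \code{\link{countReads}}).
#'
#' @param counts a \linkS4class{ScreenCounts} (rowData must carry
#'   \code{sequence}) or a \linkS4class{SimulatedScreen}.
#' @param primerSet a \linkS4class{PrimerSet}.
#' @param layout primer-to-sample layout (data.frame with \code{primer},
#'   \code{sample}); default \code{\link{defaultSampleLayout}} sized to
#'   the replicates present.
#' @param path optional FASTQ output path.
#' @param readLength read truncation length; must cover stagger + index +
#'   Template1 + 20 for every primer used.
#' @param errorRate uniform per-base substitution probability (default 0).
#' @param seed optional RNG seed (used only if \code{errorRate > 0}).
#' @return A named \link[Biostrings]{DNAStringSet} of reads (invisibly if
#'   \code{path} is given).
#' @export
emitReads <- function(counts, primerSet = defaultPrimers(), layout = NULL,
                      path = NULL, readLength = 75L, errorRate = 0,
                      seed = NULL) {
    if (is(counts, "SimulatedScreen")) counts <- screenCounts(counts)
    rd <- rowData(counts)
    stopIfNot(!is.null(rd$sequence),
              "rowData(counts)$sequence is required to emit reads")
    if (is.null(layout)) {
        reps <- max(1L, max(colData(counts)$replicate, na.rm = TRUE))
        layout <- defaultSampleLayout(reps, primerSet)
    }
    p <- primers(primerSet)
    mat <- assay(counts, "counts")
    allReads <- character(0)
    for (j in seq_len(ncol(mat))) {
        smp <- colnames(mat)[j]
        pr <- layout$primer[match(smp, layout$sample)]
        stopIfNot(!is.na(pr), "no primer assigned to sample ", smp)
        i <- match(pr, p$name)
        prefix <- toupper(paste0(p$stagger[i], p$index[i]))
        minLen <- nchar(prefix) + nchar(primerSet@template1) + 20L
        if (readLength < minLen)
            stop("readLength ", readLength, " < stagger+index+Template1+20",
                 " (", minLen, ") for primer ", pr)
        full <- substr(paste0(prefix, primerSet@template1, rd$sequence,
                              primerSet@template2), 1L, readLength)
        cnt <- mat[, j]
        if (any(cnt > 0))
            allReads <- c(allReads, rep(full[cnt > 0], cnt[cnt > 0]))
    }
    if (errorRate > 0 && length(allReads))
        allReads <- withSeed(seed, mutateReads(allReads, errorRate))
    reads <- Biostrings::DNAStringSet(allReads)
    if (length(reads))
        names(reads) <- sprintf("read_%07d", seq_along(reads))
    if (!is.null(path)) {
        qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
        Biostrings::writeXStringSet(reads, path, format = "fastq",
                                    qualities = qual)
        return(invisible(reads))
    }
    reads
}

# Uniform substitution errors: each base mutates with prob `rate` to one
# of the three other nucleotides.
mutateReads <- function(reads, rate) {
    nmut <- stats::rbinom(length(reads), nchar(reads), rate)
    hit <- which(nmut > 0)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(nchar(reads[i]), nmut[i])
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        for (pp in pos)
            ch[pp] <- sample(setdiff(bases, ch[pp]), 1L)
        reads[i] <- paste0(ch, collapse = "")
    }
    reads
}
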