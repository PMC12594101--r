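#' Simulate a genome annotation
#'
#' Generates a compact genome with non-overlapping gene bodies, one
#' centromere interval per chromosome, and per-gene expression (rpkm)
#' drawn from a two-component mixture: with probability
#' \code{zeroInflation} a transcriptionally inactive draw (uniform on
#' [0, 0.1)), otherwise a log-normal active component. The inactive tail
#' gives the rpkm < 0.1 hit filter realistic work.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param genesPerChromosome genes placed on each chromosome.
#' @param seed optional RNG seed for reproducibility.
#' @param chromosomeLength chromosome length in bp; by default sized so
#'   genes (mean spacing \code{slotLength}) fit comfortably.
#' @param slotLength spacing budget per gene in bp; genes occupy a random
#'   40--90\% of their slot.
#' @param zeroInflation probability a gene is transcriptionally inactive.
#' @return A \linkS4class{GenomeAnnotation}.
#' @examples
#' ann <- makeGenome(2, 50, seed = 1)
#' head(genes(ann))
#' @export
makeGenome <- function(nChromosomes, genesPerChromosome, seed = NULL,
                       chromosomeLength = NULL, slotLength = 20000L,
                       zeroInflation = 0.2) {
    stopIfNot(nChromosomes >= 1L, "nChromosomes must be >= 1")
    stopIfNot(genesPerChromosome >= 1L, "genesPerChromosome must be >= 1")
    autoLen <- is.null(chromosomeLength)
    if (autoLen)
        chromosomeLength <- as.integer(genesPerChromosome) * slotLength +
            2L * slotLength
    if (genesPerChromosome * 1000 > chromosomeLength)
        stop("impossible packing: ", genesPerChromosome,
             " genes do not fit in ", chromosomeLength, " bp")
    withSeed(seed, {
        chrom <- paste0("chr", seq_len(nChromosomes))
        slot <- chromosomeLength %/% (genesPerChromosome + 1L)
        gl <- vector("list", nChromosomes)
        for (i in seq_len(nChromosomes)) {
            slotStart <- slot * (seq_len(genesPerChromosome) - 1L) + 1L
            gw <- pmax(500L, as.integer(round(
                slot * stats::runif(genesPerChromosome, 0.4, 0.9))))
            off <- as.integer(floor(stats::runif(genesPerChromosome) *
                                    pmax(1L, slot - gw)))
            gl[[i]] <- GRanges(chrom[i],
                IRanges(start = slotStart + off,
                        width = pmin(gw, slot - off)),
                strand = sample(c("+", "-"), genesPerChromosome, TRUE))
        }
        g <- suppressWarnings(do.call(c, gl))
        n <- length(g)
        g$symbol <- sprintf("G%s_%04d",
                            rep(sub("^chr", "", chrom),
                                each = genesPerChromosome),
                            rep(seq_len(genesPerChromosome), nChromosomes))
        inactive <- stats::runif(n) < zeroInflation
        rpkm <- exp(stats::rnorm(n, log(10), 1.5))
        rpkm[inactive] <- stats::runif(sum(inactive), 0, 0.1)
        g$rpkm <- rpkm
        # centromere: ~4% of the chromosome somewhere in the middle third
        cenW <- as.integer(round(chromosomeLength * 0.04))
        cenS <- as.integer(round(chromosomeLength *
                                 stats::runif(nChromosomes, 0.35, 0.6)))
        cen <- GRanges(chrom, IRanges(start = cenS, width = cenW))
        si <- Seqinfo(seqnames = chrom,
                      seqlengths = rep(chromosomeLength, nChromosomes))
        GenomeInfoDb::seqlevels(g) <- chrom
        GenomeInfoDb::seqinfo(g) <- si
        GenomeInfoDb::seqlevels(cen) <- chrom
        GenomeInfoDb::seqinfo(cen) <- si
        new("GenomeAnnotation", genes = g, centromeres = cen)
    })
}

#' Read / write a genome annotation as BED-like text files
#'
#' Genes are stored as BED6 (name = symbol) with rpkm in a companion
#' expression TSV; centromeres as BED3; chromosome lengths in a
#' \code{chrom.sizes} two-column file (UCSC convention).
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param dir directory to write to / read from.
#' @return \code{writeAnnotation} returns the directory invisibly;
#'   \code{readAnnotation} returns a \linkS4class{GenomeAnnotation}.
#' @export
writeAnnotation <- function(annotation, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- genes(annotation)
    bed <- data.frame(chrom = as.character(seqnames(g)),
                      start = start(g) - 1L, end = end(g),
                      name = g$symbol, score = 0L,
                      strand = as.character(strand(g)))
    utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    cen <- centromeres(annotation)
    cbed <- data.frame(chrom = as.character(seqnames(cen)),
                       start = start(cen) - 1L, end = end(cen))
    utils::write.table(cbed, file.path(dir, "centromeres.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    sl <- seqlengths(g)
    utils::write.table(data.frame(names(sl), unname(sl)),
                       file.path(dir, "chrom.sizes"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(expressionTable(annotation),
                       file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(dir) {
    sizes <- utils::read.table(file.path(dir, "chrom.sizes"), sep = "\t",
                               col.names = c("chrom", "length"))
    si <- Seqinfo(seqnames = sizes$chrom, seqlengths = sizes$length)
    bed <- utils::read.table(file.path(dir, "genes.bed"), sep = "\t",
        col.names = c("chrom", "start", "end", "name", "score", "strand"))
    g <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end),
                 strand = bed$strand, seqinfo = si)
    g$symbol <- bed$name
    expr <- utils::read.table(file.path(dir, "expression.tsv"),
                              header = TRUE, sep = "\t")
    g$rpkm <- expr$rpkm[match(g$symbol, expr$gene)]
    cbed <- utils::read.table(file.path(dir, "centromeres.bed"), sep = "\t",
                              col.names = c("chrom", "start", "end"))
    cen <- GRanges(cbed$chrom, IRanges(cbed$start + 1L, cbed$end),
                   seqinfo = si)
    new("GenomeAnnotation", genes = g, centromeres = cen)
}
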