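#' Simulate a Brunello-like sgRNA library
#'
#' Draws distinct random 20-nt guide sequences: \code{guidesPerGene}
#' targeting guides for every annotated gene plus \code{nControls}
#' non-targeting control guides (the empirical null used in scoring).
#'
#' @param annotation a \linkS4class{GenomeAnnotation} (or character vector
#'   of gene symbols).
#' @param guidesPerGene guides per targeting gene (default 4).
#' @param nControls number of non-targeting controls (>= 0).
#' @param seed optional RNG seed.
#' @return An \linkS4class{SgRNALibrary}.
#' @examples
#' lib <- makeLibrary(makeGenome(1, 10, seed = 1), 4, 20, seed = 1)
#' nGuides(lib)  # 10 * 4 + 20
#' @export
makeLibrary <- function(annotation, guidesPerGene = 4L, nControls = 100L,
                        seed = NULL) {
    symbols <- if (is(annotation, "GenomeAnnotation"))
        genes(annotation)$symbol else as.character(annotation)
    stopIfNot(nControls >= 0L, "nControls must be >= 0")
    stopIfNot(guidesPerGene >= 1L, "guidesPerGene must be >= 1")
    nTarget <- length(symbols) * guidesPerGene
    n <- nTarget + nControls
    if (n > 4^20 / 2)
        stop("sequence-space exhaustion: cannot draw ", n,
             " distinct 20-mers")
    withSeed(seed, {
        seqs <- randomGuideSeqs(n)
        gene <- c(rep(symbols, each = guidesPerGene),
                  rep(NA_character_, nControls))
        id <- c(paste0(rep(symbols, each = guidesPerGene), "_sg",
                       rep(seq_len(guidesPerGene), length(symbols))),
                if (nControls > 0)
                    sprintf("CONTROL_%05d", seq_len(nControls)))
        new("SgRNALibrary", guides = data.frame(
            sgrna = id, sequence = seqs, gene = gene,
            isControl = is.na(gene), stringsAsFactors = FALSE))
    })
}

# Distinct random 20-mers, redrawing collisions.
randomGuideSeqs <- function(n) {
    draw <- function(k) {
        m <- matrix(sample(c("A", "C", "G", "T"), 20L * k, replace = TRUE),
                    nrow = 20L)
        apply(m, 2L, paste0, collapse = "")
    }
    seqs <- unique(draw(n))
    tries <- 0L
    while (length(seqs) < n) {
        seqs <- unique(c(seqs, draw(n - length(seqs) + 10L)))
        tries <- tries + 1L
        if (tries > 100L) stop("sequence-space exhaustion")
    }
    seqs[seq_len(n)]
}

#' Read / write an sgRNA library as TSV
#'
#' Columns \code{sgrna}, \code{sequence}, \code{gene} (empty for
#' non-targeting controls), \code{isControl}.
#'
#' @param library an \linkS4class{SgRNALibrary}.
#' @param path TSV file path.
#' @export
writeLibrary <- function(library, path) {
    gd <- guides(library)
    gd$gene[is.na(gd$gene)] <- ""
    utils::write.table(gd, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
    gd <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(sgrna = "character",
                                           sequence = "character",
                                           gene = "character"))
    gd$gene[gd$gene == ""] <- NA_character_
    gd$isControl <- as.logical(gd$isControl)
    new("SgRNALibrary", guides = gd)
}
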