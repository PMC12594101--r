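#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData
NULL

#' Genome annotation with centromeres and expression levels
#'
#' Container for a (real or simulated) genome annotation: gene bodies as a
#' \link[GenomicRanges]{GRanges} carrying \code{symbol} and \code{rpkm}
#' metadata columns, plus one centromere interval per chromosome. The
#' centromere coordinates drive the reporter-loss artifact filter and the
#' \code{rpkm} values the inactive-gene filter.
#'
#' @slot genes GRanges of gene bodies; mcols \code{symbol} (unique) and
#'   \code{rpkm} (non-negative).
#' @slot centromeres GRanges with exactly one range per chromosome.
#' @aliases GenomeAnnotation
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    slots = c(genes = "GRanges", centromeres = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes
    cen <- object@centromeres
    msg <- character()
    sym <- g$symbol
    if (is.null(sym) || anyDuplicated(sym))
        msg <- c(msg, "gene symbols must be present and unique")
    if (is.null(g$rpkm) || any(g$rpkm < 0))
        msg <- c(msg, "rpkm must be present and non-negative")
    sl <- GenomeInfoDb::seqlengths(g)
    if (any(is.na(sl)))
        msg <- c(msg, "chromosome lengths (seqlengths) must be set")
    ok <- function(x) all(start(x) >= 1) &&
        all(end(x) <= sl[as.character(seqnames(x))])
    if (length(g) && !ok(g))
        msg <- c(msg, "gene intervals must lie within chromosome bounds")
    if (length(cen) && !ok(cen))
        msg <- c(msg, "centromere intervals must lie within chromosome bounds")
    if (anyDuplicated(as.character(seqnames(cen))))
        msg <- c(msg, "at most one centromere per chromosome")
    if (length(msg)) msg else TRUE
})

#' sgRNA library
#'
#' A Brunello-like pooled sgRNA library: up to a fixed number of 20-nt
#' guides per protein-coding gene plus non-targeting control guides used
#' as the empirical null in scoring.
#'
#' @slot guides data.frame with columns \code{sgrna} (unique id),
#'   \code{sequence} (20 nt, ACGT), \code{gene} (symbol, or \code{NA} for
#'   controls) and \code{isControl} (logical).
#' @aliases SgRNALibrary
#' @exportClass SgRNALibrary
setClass("SgRNALibrary", slots = c(guides = "data.frame"))

setValidity("SgRNALibrary", function(object) {
    gd <- object@guides
    msg <- character()
    need <- c("sgrna", "sequence", "gene", "isControl")
    if (!all(need %in% names(gd)))
        return(paste("guides must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(gd$sgrna)) msg <- c(msg, "sgRNA ids must be unique")
    if (any(nchar(gd$sequence) != 20L))
        msg <- c(msg, "sgRNA sequences must be 20 nt")
    if (any(grepl("[^ACGT]", gd$sequence)))
        msg <- c(msg, "sgRNA sequences must be over {A,C,G,T}")
    if (any(!gd$isControl & is.na(gd$gene)))
        msg <- c(msg, "targeting guides must name a gene")
    if (length(msg)) msg else TRUE
})

#' Staggered readout primer set
#'
#' The twelve staggered readout primers used to demultiplex up to twelve
#' sorted-bin samples per sequencing lane, together with the two invariant
#' amplicon template sequences. Each amplicon reads as
#' stagger + 8-nt index + Template1 + sgRNA(20 nt) + Template2.
#'
#' @slot primers data.frame with columns \code{name}, \code{stagger}
#'   (1--9 nt) and \code{index} (8 nt); (stagger, index) pairs unique.
#' @slot template1 24-nt invariant sequence preceding the guide.
#' @slot template2 invariant sequence following the guide.
#' @aliases PrimerSet
#' @exportClass PrimerSet
setClass("PrimerSet",
    slots = c(primers = "data.frame", template1 = "character",
              template2 = "character"))

setValidity("PrimerSet", function(object) {
    p <- object@primers
    msg <- character()
    if (!all(c("name", "stagger", "index") %in% names(p)))
        return("primers must have columns name, stagger, index")
    if (any(nchar(p$index) != 8L)) msg <- c(msg, "indexes must be 8 nt")
    if (any(nchar(p$stagger) < 1L | nchar(p$stagger) > 9L))
        msg <- c(msg, "staggers must be 1-9 nt")
    if (anyDuplicated(paste(toupper(p$stagger), toupper(p$index))))
        msg <- c(msg, "(stagger, index) pairs must be unique")
    if (nchar(object@template1) != 24L)
        msg <- c(msg, "template1 must be 24 nt")
    if (length(msg)) msg else TRUE
})

#' Per-sample sgRNA count container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one row per
#' library sgRNA (zeros kept) and one column per sorted-bin sample. The
#' \code{counts} assay holds raw non-negative integer counts;
#' \code{normalizeCounts} adds a \code{normalized} assay and per-sample
#' size factors. rowData carries \code{gene} and \code{isControl};
#' colData carries \code{replicate} and \code{bin} (\code{"low"}/
#' \code{"high"}).
#'
#' @aliases ScreenCounts
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        return("a 'counts' assay is required")
    m <- assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    if (!all(c("gene", "isControl") %in% names(rowData(object))))
        msg <- c(msg, "rowData must carry 'gene' and 'isControl'")
    if (length(msg)) msg else TRUE
})

#' Simulated sorted-bin screen
#'
#' Output of \code{\link{simulateScreen}}: the per-(replicate, bin) count
#' table plus the ground-truth regulatory labels used to plant the screen.
#'
#' @slot counts ScreenCounts of simulated sequencing counts.
#' @slot truth data.frame with columns \code{gene}, \code{effect} (log2
#'   fold-change of the reporter upon knockout), \code{artifact},
#'   \code{penetrance} and \code{label} (activator/repressor/null/artifact).
#' @slot config the ScreenConfig list used.
#' @aliases SimulatedScreen
#' @exportClass SimulatedScreen
setClass("SimulatedScreen",
    slots = c(counts = "ScreenCounts", truth = "data.frame",
              config = "list"))

#' Demultiplexing reference index
#'
#' The artificial amplicon reference: one record per (primer, sgRNA)
#' combination, each a full stagger + index + Template1 + sgRNA +
#' Template2 sequence named \code{"primer|gene|sgRNA"}. Writable as FASTA
#' with \code{\link{writeReference}}.
#'
#' @slot records data.frame with columns \code{name}, \code{primer},
#'   \code{gene}, \code{sgrna}, \code{sequence}.
#' @slot library the SgRNALibrary indexed.
#' @slot primers the PrimerSet used.
#' @aliases ReferenceIndex
#' @exportClass ReferenceIndex
setClass("ReferenceIndex",
    slots = c(records = "data.frame", library = "SgRNALibrary",
              primers = "PrimerSet"))

#' Per-screen hit table with removal provenance
#'
#' Hits passing the RRA score cutoff for one screen, in both senses, with
#' a complete log of genes removed by downstream filters (reason-coded),
#' so that |input| = |hits| + |removed| at every stage.
#'
#' @slot screen screen (target gene) name.
#' @slot hits data.frame: \code{gene}, \code{sense} (activator/repressor),
#'   \code{score}, \code{fdr}.
#' @slot removed data.frame: \code{gene}, \code{sense}, \code{score},
#'   \code{reason}.
#' @slot cutoff the RRA score cutoff applied.
#' @aliases HitTable
#' @exportClass HitTable
setClass("HitTable",
    slots = c(screen = "character", hits = "data.frame",
              removed = "data.frame", cutoff = "numeric"))

setValidity("HitTable", function(object) {
    h <- object@hits
    msg <- character()
    if (nrow(h)) {
        if (!all(h$sense %in% c("activator", "repressor")))
            msg <- c(msg, "sense must be activator or repressor")
        if (any(h$score >= object@cutoff))
            msg <- c(msg, "all retained scores must be below the cutoff")
        if (anyDuplicated(paste(h$gene, h$sense)))
            msg <- c(msg, "(gene, sense) must be unique within a screen")
    }
    if (length(msg)) msg else TRUE
})

#' Directed, signed, weighted regulatory network
#'
#' One edge per retained screen hit: regulator gene -> screened target
#' gene, with sense (activation/repression), the RRA score, and weight
#' -log10(score). Self-regulation (a screen detecting its own target
#' gene) is retained and flagged.
#'
#' @slot edges data.frame: \code{regulator}, \code{target}, \code{sense},
#'   \code{score}, \code{weight}, \code{selfLoop}.
#' @aliases RegulatoryNetwork
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork", slots = c(edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (nrow(e)) {
        if (anyDuplicated(paste(e$regulator, e$target, e$sense)))
            msg <- c(msg, "duplicate (regulator, target, sense) edges")
        if (!all(e$sense %in% c("activation", "repression")))
            msg <- c(msg, "sense must be activation or repression")
        if (any(abs(e$weight - (-log10(e$score))) > 1e-8))
            msg <- c(msg, "weight must equal -log10(score)")
    }
    if (length(msg)) msg else TRUE
})
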