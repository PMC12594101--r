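#' @importFrom GenomeInfoDb seqlengths seqinfo Seqinfo seqnames
NULL

#' @describeIn GenomeAnnotation-class gene bodies as GRanges
#' @param x,object a GenomeAnnotation
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))
#' @export
setMethod("genes", "GenomeAnnotation", function(x, ...) x@genes)

#' @describeIn GenomeAnnotation-class centromere intervals as GRanges
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
#' @export
setMethod("centromeres", "GenomeAnnotation", function(x) x@centromeres)

#' @describeIn GenomeAnnotation-class gene symbol / rpkm expression table
#' @export
setGeneric("expressionTable", function(x) standardGeneric("expressionTable"))
#' @export
setMethod("expressionTable", "GenomeAnnotation", function(x)
    data.frame(gene = x@genes$symbol, rpkm = x@genes$rpkm))

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", length(object@genes), "genes on",
        length(seqlengths(object@genes)), "chromosome(s)\n")
})

#' @describeIn SgRNALibrary-class guide table (sgrna, sequence, gene, isControl)
#' @param x,object an SgRNALibrary
#' @export
setGeneric("guides", function(x) standardGeneric("guides"))
#' @export
setMethod("guides", "SgRNALibrary", function(x) x@guides)

#' @describeIn SgRNALibrary-class number of guides (targeting + control)
#' @export
setGeneric("nGuides", function(x) standardGeneric("nGuides"))
#' @export
setMethod("nGuides", "SgRNALibrary", function(x) nrow(x@guides))

setMethod("show", "SgRNALibrary", function(object) {
    gd <- object@guides
    cat("SgRNALibrary:", nrow(gd), "guides (",
        sum(!gd$isControl), "targeting,", sum(gd$isControl),
        "non-targeting controls ) over",
        length(unique(gd$gene[!gd$isControl])), "genes\n")
})

#' @describeIn PrimerSet-class primer table (name, stagger, index)
#' @param x,object a PrimerSet
#' @export
setGeneric("primers", function(x) standardGeneric("primers"))
#' @export
setMethod("primers", "PrimerSet", function(x) x@primers)

setMethod("show", "PrimerSet", function(object) {
    cat("PrimerSet:", nrow(object@primers), "staggered readout primers;",
        "Template1", nchar(object@template1), "nt, Template2",
        nchar(object@template2), "nt\n")
})

setMethod("show", "ScreenCounts", function(object) {
    cat("ScreenCounts:", nrow(object), "sgRNAs x", ncol(object),
        "samples; assays:", paste(names(assays(object)), collapse = ", "),
        "\n")
})

#' @describeIn SimulatedScreen-class simulated count container
#' @param x,object a SimulatedScreen
#' @export
setGeneric("screenCounts", function(x) standardGeneric("screenCounts"))
#' @export
setMethod("screenCounts", "SimulatedScreen", function(x) x@counts)

#' @describeIn SimulatedScreen-class ground-truth gene labels
#' @export
setGeneric("screenTruth", function(x) standardGeneric("screenTruth"))
#' @export
setMethod("screenTruth", "SimulatedScreen", function(x) x@truth)

setMethod("show", "SimulatedScreen", function(object) {
    tt <- table(object@truth$label)
    cat("SimulatedScreen:", nrow(object@counts), "sgRNAs,",
        ncol(object@counts), "samples; truth:",
        paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
})

#' @describeIn ReferenceIndex-class reference record table
#' @param x,object a ReferenceIndex
#' @export
setGeneric("referenceRecords", function(x) standardGeneric("referenceRecords"))
#' @export
setMethod("referenceRecords", "ReferenceIndex", function(x) x@records)

setMethod("show", "ReferenceIndex", function(object) {
    cat("ReferenceIndex:", nrow(object@records), "records (",
        nrow(object@primers@primers), "primers x",
        nrow(object@library@guides), "sgRNAs )\n")
})

#' @describeIn HitTable-class retained hits
#' @param x,object a HitTable
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @export
setMethod("hits", "HitTable", function(x) x@hits)

#' @describeIn HitTable-class removal provenance (gene, sense, reason)
#' @export
setGeneric("removals", function(x) standardGeneric("removals"))
#' @export
setMethod("removals", "HitTable", function(x) x@removed)

#' @describeIn HitTable-class screen (target gene) name
#' @export
setGeneric("screenName", function(x) standardGeneric("screenName"))
#' @export
setMethod("screenName", "HitTable", function(x) x@screen)

setMethod("show", "HitTable", function(object) {
    h <- object@hits
    cat("HitTable [", object@screen, "]: ", nrow(h), " hits (",
        sum(h$sense == "activator"), " activators, ",
        sum(h$sense == "repressor"), " repressors); ",
        nrow(object@removed), " removed\n", sep = "")
})

#' @describeIn RegulatoryNetwork-class edge table
#' @param x,object a RegulatoryNetwork
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @export
setMethod("edges", "RegulatoryNetwork", function(x) x@edges)

setMethod("show", "RegulatoryNetwork", function(object) {
    e <- object@edges
    cat("RegulatoryNetwork:", nrow(e), "edges (",
        sum(e$sense == "activation"), "activating,",
        sum(e$sense == "repression"), "repressing ),",
        length(unique(e$regulator)), "regulators,",
        length(unique(e$target)), "targets\n")
})
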