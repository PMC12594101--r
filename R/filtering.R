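#' Select screen hits by RRA score cutoff
#'
#' Activator hits are genes whose pos (low-bin) RRA score is strictly
#' below the cutoff, repressor hits those whose neg (high-bin) score is;
#' a gene passing in both directions appears once per sense. The default
#' cutoff of 1e-3 is the validated operating point (72\% of activators
#' and 97\% of repressors confirmed by single-guide follow-up at this
#' threshold).
#'
#' @param geneScores data.frame from \code{\link{geneRRA}}.
#' @param screen screen (target gene) name.
#' @param cutoff strict upper bound on the RRA score (default 1e-3).
#' @return A \linkS4class{HitTable}.
#' @export
applyRraCutoff <- function(geneScores, screen, cutoff = 1e-3) {
    stopIfNot(cutoff > 0 && cutoff < 1, "cutoff must be in (0, 1)")
    act <- geneScores[geneScores$posScore < cutoff, ]
    rep_ <- geneScores[geneScores$negScore < cutoff, ]
    h <- rbind(
        data.frame(gene = act$gene, sense = rep("activator", nrow(act)),
                   score = act$posScore, fdr = act$posFdr,
                   stringsAsFactors = FALSE),
        data.frame(gene = rep_$gene, sense = rep("repressor", nrow(rep_)),
                   score = rep_$negScore, fdr = rep_$negFdr,
                   stringsAsFactors = FALSE))
    new("HitTable", screen = screen, hits = h,
        removed = data.frame(gene = character(), sense = character(),
                             score = numeric(), reason = character(),
                             stringsAsFactors = FALSE),
        cutoff = cutoff)
}

# Closed genomic span from the centromere boundary nearest the target
# gene to the far end of the target gene, on the target's chromosome.
centromereSpan <- function(annotation, targetGene) {
    g <- genes(annotation)
    i <- match(targetGene, g$symbol)
    if (is.na(i)) stop("target gene not in annotation: ", targetGene)
    tg <- g[i]
    chr <- as.character(seqnames(tg))
    cen <- centromeres(annotation)
    cen <- cen[as.character(seqnames(cen)) == chr]
    if (!length(cen)) stop("no centromere annotated on ", chr)
    if (start(tg) > end(cen)) {          # target on the right arm
        GRanges(chr, IRanges(end(cen), end(tg)))
    } else if (end(tg) < start(cen)) {   # target on the left arm
        GRanges(chr, IRanges(start(tg), start(cen)))
    } else {                             # target overlaps the centromere
        GRanges(chr, IRanges(min(start(cen), start(tg)),
                             max(end(cen), end(tg))))
    }
}

#' Remove centromere-proximal reporter-loss artifacts
#'
#' Cas9 cutting between the centromere and the knock-in reporter locus
#' can destabilize the chromosome arm and delete the reporter allele,
#' producing spurious low-bin "hits". This filter removes any hit whose
#' gene body overlaps the closed span from the centromere boundary
#' nearest the target gene through the far end of the target gene. Hits
#' on other chromosomes, or on the opposite side of the centromere, are
#' retained.
#'
#' @param hitTable a \linkS4class{HitTable}.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param targetGene the screen's knock-in gene symbol (defaults to the
#'   hit table's screen name).
#' @return The filtered \linkS4class{HitTable}; removals are logged with
#'   reason \code{"centromere_span"}.
#' @export
filterCentromereSpan <- function(hitTable, annotation,
                                 targetGene = screenName(hitTable)) {
    span <- centromereSpan(annotation, targetGene)
    g <- genes(annotation)
    flagged <- g$symbol[IRanges::overlapsAny(g, span)]
    h <- hits(hitTable)
    drop <- h$gene %in% flagged
    removeHits(hitTable, drop, "centromere_span")
}

#' Remove hits on transcriptionally inactive genes
#'
#' Hits whose gene has rpkm strictly below \code{minRpkm} (default 0.1)
#' are removed; a gene at exactly the threshold is retained. Genes absent
#' from the expression table are retained with a warning -- the filter
#' only acts on measured inactivity.
#'
#' @param hitTable a \linkS4class{HitTable}.
#' @param expression data.frame with columns \code{gene} and \code{rpkm}
#'   (e.g. \code{expressionTable(annotation)}).
#' @param minRpkm strict lower bound for retention (default 0.1).
#' @return The filtered \linkS4class{HitTable}; removals logged with
#'   reason \code{"inactive_rpkm"}.
#' @export
filterInactive <- function(hitTable, expression, minRpkm = 0.1) {
    h <- hits(hitTable)
    rpkm <- expression$rpkm[match(h$gene, expression$gene)]
    if (anyNA(rpkm) && nrow(h))
        warning(sum(is.na(rpkm)), " hit gene(s) absent from the ",
                "expression table; retained")
    drop <- !is.na(rpkm) & rpkm < minRpkm
    removeHits(hitTable, drop, "inactive_rpkm")
}

removeHits <- function(hitTable, drop, reason) {
    h <- hits(hitTable)
    if (any(drop)) {
        rm_ <- data.frame(gene = h$gene[drop], sense = h$sense[drop],
                          score = h$score[drop],
                          reason = rep(reason, sum(drop)),
                          stringsAsFactors = FALSE)
        hitTable@removed <- rbind(hitTable@removed, rm_)
        hitTable@hits <- h[!drop, , drop = FALSE]
        rownames(hitTable@hits) <- NULL
    }
    validObject(hitTable)
    hitTable
}

#' Classify single-guide validation outcomes
#'
#' A hit re-tested with its best guide is a true positive if the mean
#' reporter intensity relative to a non-targeting control changes by
#' more than 5\% in the expected direction: below 0.95 for activators,
#' above 1.05 for repressors; anything else is a false positive.
#'
#' @param relativeMFI positive ratio(s) of reporter mean fluorescence
#'   intensity vs non-targeting control.
#' @param expectedSense \code{"activator"} or \code{"repressor"},
#'   recycled.
#' @return character vector of \code{"true_positive"} /
#'   \code{"false_positive"}.
#' @examples
#' classifyValidation(c(0.90, 1.00, 1.06),
#'                    c("activator", "activator", "repressor"))
#' @export
classifyValidation <- function(relativeMFI, expectedSense) {
    if (any(!is.finite(relativeMFI)) || any(relativeMFI <= 0))
        stop("relativeMFI must be positive ratios")
    expectedSense <- rep_len(expectedSense, length(relativeMFI))
    stopIfNot(all(expectedSense %in% c("activator", "repressor")),
              "expectedSense must be activator or repressor")
    tp <- ifelse(expectedSense == "activator",
                 relativeMFI < 0.95, relativeMFI > 1.05)
    ifelse(tp, "true_positive", "false_positive")
}

#' Write a hit table (and its removal log) as TSV
#'
#' @param hitTable a \linkS4class{HitTable}.
#' @param path TSV path for retained hits (columns screen, gene, sense,
#'   score, fdr).
#' @param removalPath optional TSV path for the removal log.
#' @export
writeHits <- function(hitTable, path, removalPath = NULL) {
    h <- hits(hitTable)
    out <- cbind(screen = rep(screenName(hitTable), nrow(h)), h)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(removalPath)) {
        r <- removals(hitTable)
        out <- cbind(screen = rep(screenName(hitTable), nrow(r)), r)
        utils::write.table(out, removalPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
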