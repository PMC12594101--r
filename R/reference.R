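#' Build the artificial amplicon reference
#'
#' For every sgRNA and every readout primer, constructs the full expected
#' amplicon sequence stagger + index + Template1 + sgRNA + Template2 and
#' names it \code{"primer|gene|sgRNA"}. A 77,441-guide library with the
#' twelve default primers yields 929,292 records.
#'
#' @param library an \linkS4class{SgRNALibrary}.
#' @param primerSet a \linkS4class{PrimerSet}.
#' @return A \linkS4class{ReferenceIndex}.
#' @examples
#' lib <- makeLibrary(makeGenome(1, 5, seed = 1), 4, 0, seed = 1)
#' buildReference(lib)  # 20 guides x 12 primers = 240 records
#' @export
buildReference <- function(library, primerSet = defaultPrimers()) {
    gd <- guides(library)
    stopIfNot(nrow(gd) > 0L, "library must be non-empty")
    if (any(nchar(gd$sequence) != 20L))
        stop("all sgRNA sequences must be 20 nt")
    p <- primers(primerSet)
    nP <- nrow(p)
    nG <- nrow(gd)
    gene <- ifelse(gd$isControl, "CONTROL", gd$gene)
    prefix <- toupper(paste0(p$stagger, p$index))
    rec <- data.frame(
        name = paste(rep(p$name, each = nG), rep(gene, nP),
                     rep(gd$sgrna, nP), sep = "|"),
        primer = rep(p$name, each = nG),
        gene = rep(gene, nP),
        sgrna = rep(gd$sgrna, nP),
        sequence = paste0(rep(prefix, each = nG),
                          primerSet@template1,
                          rep(gd$sequence, nP),
                          primerSet@template2),
        stringsAsFactors = FALSE)
    new("ReferenceIndex", records = rec, library = library,
        primers = primerSet)
}

#' Write a reference index as FASTA
#'
#' @param reference a \linkS4class{ReferenceIndex}.
#' @param path output FASTA path.
#' @export
writeReference <- function(reference, path) {
    rec <- referenceRecords(reference)
    x <- Biostrings::DNAStringSet(rec$sequence)
    names(x) <- rec$name
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Demultiplex and count amplicon reads
#'
#' Assigns each read by fixed-position, substitution-only matching: the
#' stagger + index prefix must match exactly one primer exactly; the
#' Template1 region may carry at most \code{t1Mismatch} substitutions;
#' the 20-nt guide region must have a unique best library match within
#' \code{maxMismatch} substitutions (ties are discarded). Unassigned
#' reads are tallied with reason codes in
#' \code{metadata(result)$unassigned}. Reads shorter than the full
#' amplicon are matched on their available prefix, so 75-nt reads of the
#' longer amplicon are fully supported.
#'
#' @param reads FASTQ path, \link[Biostrings]{DNAStringSet}, or character
#'   vector of read sequences.
#' @param reference a \linkS4class{ReferenceIndex} from
#'   \code{\link{buildReference}}.
#' @param maxMismatch substitution budget in the guide region (default 2).
#' @param t1Mismatch substitution budget in the Template1 region
#'   (default 2); the stagger + index prefix always requires an exact
#'   match.
#' @param layout primer-to-sample layout (data.frame with \code{primer},
#'   \code{sample} and optionally \code{replicate}, \code{bin}); default
#'   maps all twelve primers via \code{\link{defaultSampleLayout}}.
#' @return A \linkS4class{ScreenCounts} with one column per layout sample
#'   (every library guide present, zeros kept) and unassigned-read
#'   tallies in its metadata.
#' @export
countReads <- function(reads, reference, maxMismatch = 2L,
                       t1Mismatch = 2L, layout = NULL) {
    stopIfNot(is(reference, "ReferenceIndex"),
              "reference must be a ReferenceIndex")
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    if (is(reads, "XStringSet")) reads <- as.character(reads)
    reads <- toupper(unname(reads))
    lib <- guides(reference@library)
    ps <- reference@primers
    p <- primers(ps)
    if (is.null(layout))
        layout <- defaultSampleLayout(nrow(p) %/% 2L, ps)
    samples <- layout$sample
    n <- length(reads)
    counts <- matrix(0L, nrow = nrow(lib), ncol = length(samples),
                     dimnames = list(lib$sgrna, samples))
    reasons <- c(ambiguous_index = 0L, unknown_index = 0L,
                 too_short = 0L, template_mismatch = 0L,
                 guide_no_match = 0L, guide_ambiguous = 0L)
    if (n > 0L) {
        prefixes <- primerPrefixes(ps)
        t1 <- ps@template1
        nT1 <- nchar(t1)
        hitMat <- vapply(prefixes, function(px) startsWith(reads, px),
                         logical(n))
        if (n == 1L) hitMat <- matrix(hitMat, nrow = 1L)
        nHit <- rowSums(hitMat)
        reasons["unknown_index"] <- sum(nHit == 0L)
        reasons["ambiguous_index"] <- sum(nHit > 1L)
        ok <- which(nHit == 1L)
        primerIdx <- max.col(hitMat[ok, , drop = FALSE])
        off <- nchar(prefixes)[primerIdx]
        len <- nchar(reads[ok])
        short <- len < off + nT1 + 20L
        reasons["too_short"] <- sum(short)
        ok <- ok[!short]
        primerIdx <- primerIdx[!short]
        off <- off[!short]
        if (length(ok)) {
            t1seen <- substr(reads[ok], off + 1L, off + nT1)
            t1ok <- t1seen == t1
            if (t1Mismatch > 0L && any(!t1ok)) {
                chk <- which(!t1ok)
                t1ok[chk] <- hammingTo(t1, t1seen[chk]) <= t1Mismatch
            }
            reasons["template_mismatch"] <- sum(!t1ok)
            ok <- ok[t1ok]
            primerIdx <- primerIdx[t1ok]
            off <- off[t1ok]
        }
        if (length(ok)) {
            gseen <- substr(reads[ok], off + nT1 + 1L, off + nT1 + 20L)
            gIdx <- match(gseen, lib$sequence)
            if (maxMismatch > 0L && anyNA(gIdx)) {
                libMat <- charMatrix(lib$sequence, 20L)
                miss <- which(is.na(gIdx))
                uq <- unique(gseen[miss])
                res <- vapply(uq, function(q) {
                    d <- mismatchToAll(q, libMat)
                    b <- min(d)
                    if (b > maxMismatch) return(c(NA_integer_, 0L))
                    w <- which(d == b)
                    if (length(w) > 1L) c(NA_integer_, 1L)
                    else c(w, 0L)
                }, integer(2L))
                gIdx[miss] <- res[1L, match(gseen[miss], uq)]
                amb <- res[2L, match(gseen[miss], uq)] == 1L
                reasons["guide_ambiguous"] <- sum(amb)
                reasons["guide_no_match"] <- sum(is.na(gIdx[miss]) & !amb)
            } else {
                reasons["guide_no_match"] <- sum(is.na(gIdx))
            }
            keep <- !is.na(gIdx)
            sampIdx <- match(p$name[primerIdx], layout$primer)
            unk <- keep & is.na(sampIdx)
            reasons["unknown_index"] <- reasons["unknown_index"] + sum(unk)
            keep <- keep & !is.na(sampIdx)
            if (any(keep)) {
                tab <- table(factor(gIdx[keep], levels = seq_len(nrow(lib))),
                             factor(sampIdx[keep],
                                    levels = seq_along(samples)))
                counts <- counts + as.matrix(unclass(tab))
            }
        }
    }
    mode(counts) <- "integer"
    dimnames(counts) <- list(lib$sgrna, samples)
    cd <- S4Vectors::DataFrame(
        sample = samples,
        replicate = if ("replicate" %in% names(layout)) layout$replicate
                    else NA_integer_,
        bin = if ("bin" %in% names(layout)) layout$bin else NA_character_,
        primer = layout$primer, row.names = samples)
    sc <- newScreenCounts(counts, lib, cd)
    S4Vectors::metadata(sc)$unassigned <- reasons
    S4Vectors::metadata(sc)$totalReads <- n
    sc
}

#' Count-table quality summary
#'
#' Deterministic per-run summary: guides never observed, per-sample
#' totals, and the fraction of reads on non-targeting control guides.
#'
#' @param counts a \linkS4class{ScreenCounts}.
#' @return list with \code{zeroCountGuides}, \code{perSampleTotals},
#'   \code{controlFraction} (per sample) and \code{unassigned} (if the
#'   table came from \code{\link{countReads}}).
#' @export
countQC <- function(counts) {
    m <- assay(counts, "counts")
    rd <- rowData(counts)
    totals <- colSums(m)
    ctrl <- colSums(m[rd$isControl, , drop = FALSE])
    list(zeroCountGuides = rownames(m)[rowSums(m) == 0],
         perSampleTotals = totals,
         controlFraction = ifelse(totals > 0, ctrl / totals, 0),
         unassigned = S4Vectors::metadata(counts)$unassigned)
}

#' Write / read a long-format count table
#'
#' TSV with one row per (sample, sgRNA): columns \code{sample},
#' \code{gene} (\code{"CONTROL"} for non-targeting guides),
#' \code{sgrna}, \code{count} and \code{fraction} (of the sample total).
#'
#' @param counts a \linkS4class{ScreenCounts}.
#' @param path TSV path.
#' @export
writeCounts <- function(counts, path) {
    m <- assay(counts, "counts")
    rd <- rowData(counts)
    totals <- colSums(m)
    gene <- ifelse(rd$isControl, "CONTROL", rd$gene)
    long <- data.frame(
        sample = rep(colnames(m), each = nrow(m)),
        gene = rep(gene, ncol(m)),
        sgrna = rep(rownames(m), ncol(m)),
        count = as.vector(m),
        fraction = as.vector(sweep(m, 2L, pmax(totals, 1L), "/")),
        stringsAsFactors = FALSE)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = c(sample = "character",
                                             gene = "character",
                                             sgrna = "character"))
    samples <- unique(long$sample)
    sgrna <- unique(long$sgrna)
    m <- matrix(0L, nrow = length(sgrna), ncol = length(samples),
                dimnames = list(sgrna, samples))
    m[cbind(match(long$sgrna, sgrna), match(long$sample, samples))] <-
        as.integer(long$count)
    first <- long[!duplicated(long$sgrna), ]
    gd <- data.frame(sgrna = first$sgrna,
                     gene = ifelse(first$gene == "CONTROL",
                                   NA_character_, first$gene),
                     isControl = first$gene == "CONTROL",
                     stringsAsFactors = FALSE)
    mm <- regmatches(samples, regexec("^rep([0-9]+)_(low|high)$", samples))
    cd <- S4Vectors::DataFrame(
        sample = samples,
        replicate = vapply(mm, function(x)
            if (length(x)) as.integer(x[2L]) else NA_integer_, integer(1L)),
        bin = vapply(mm, function(x)
            if (length(x)) x[3L] else NA_character_, character(1L)),
        row.names = samples)
    gd <- gd[match(sgrna, gd$sgrna), ]
    newScreenCounts(m, gd, cd)
}
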