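#' Median-of-ratios count normalization
#'
#' Size factor per sample = median, over sgRNAs with positive counts in
#' every sample, of the ratio of the sgRNA's count to its geometric mean
#' across samples. If fewer than 100 such sgRNAs exist the size factors
#' fall back to total-count scaling (totals divided by their mean).
#' Normalization divides each sample by its factor, preserving
#' within-sample rank order.
#'
#' @param counts a \linkS4class{ScreenCounts} (>= 2 samples).
#' @return The same object with a \code{normalized} assay and a
#'   \code{sizeFactor} column in \code{colData}.
#' @export
normalizeCounts <- function(counts) {
    m <- assay(counts, "counts")
    stopIfNot(ncol(m) >= 2L, "need at least 2 samples")
    totals <- colSums(m)
    if (any(totals == 0)) stop("sample with zero total count: ",
        paste(colnames(m)[totals == 0], collapse = ", "))
    pos <- rowSums(m > 0) == ncol(m)
    if (sum(pos) >= 100L) {
        geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
        sf <- apply(m[pos, , drop = FALSE] / geo, 2L, stats::median)
    } else {
        sf <- totals / mean(totals)
    }
    stopIfNot(all(sf > 0), "non-positive size factor")
    assay(counts, "normalized") <- sweep(m, 2L, sf, "/")
    colData(counts)$sizeFactor <- sf
    counts
}

#' Per-sgRNA low/high enrichment scores and control-based empirical p
#'
#' The sgRNA statistic is the replicate-mean log2 ratio of normalized
#' low-bin to high-bin counts (pseudocount 0.5). Each guide receives a
#' one-sided empirical p-value against the non-targeting control guides
#' in each direction: \code{posP} (low-bin enrichment, activator
#' direction) counts controls scoring at least as high, \code{negP}
#' (high-bin enrichment, repressor direction) at most as low, with the
#' add-one rule so p is in (0, 1]. Percentile ranks over all guides are
#' computed per direction (descending score for pos, ascending for neg;
#' ties broken by sgRNA id).
#'
#' @param counts a \linkS4class{ScreenCounts}; normalized on the fly if
#'   needed.
#' @param design optional data.frame pairing samples (\code{replicate},
#'   \code{low}, \code{high}); derived from \code{colData} by default.
#' @param pseudocount added to both bins before the log ratio.
#' @return data.frame per sgRNA: \code{sgrna}, \code{gene},
#'   \code{isControl}, \code{score}, \code{posP}, \code{negP},
#'   \code{posRank}, \code{negRank} (percentile ranks in (0, 1]).
#' @export
sgrnaScores <- function(counts, design = NULL, pseudocount = 0.5) {
    if (!"normalized" %in% names(assays(counts)))
        counts <- normalizeCounts(counts)
    cd <- colData(counts)
    if (is.null(design)) {
        stopIfNot(all(c("replicate", "bin") %in% names(cd)),
                  "colData must have replicate and bin, or give a design")
        reps <- sort(unique(cd$replicate[!is.na(cd$replicate)]))
        design <- data.frame(
            replicate = reps,
            low = vapply(reps, function(r) cd$sample[
                cd$replicate == r & cd$bin == "low"][1L], character(1L)),
            high = vapply(reps, function(r) cd$sample[
                cd$replicate == r & cd$bin == "high"][1L], character(1L)))
    }
    stopIfNot(!anyNA(design$low) && !anyNA(design$high),
              "design must pair a low and a high sample per replicate")
    nm <- assay(counts, "normalized")
    lr <- vapply(seq_len(nrow(design)), function(i)
        log2((nm[, design$low[i]] + pseudocount) /
             (nm[, design$high[i]] + pseudocount)),
        numeric(nrow(nm)))
    score <- rowMeans(lr)
    rd <- rowData(counts)
    ctrl <- rd$isControl
    stopIfNot(any(ctrl), "control sgRNAs are required for the empirical null")
    cs <- sort(score[ctrl])
    nC <- length(cs)
    nGE <- nC - findInterval(score, cs, left.open = TRUE)  # controls >= s
    nLE <- findInterval(score, cs)                         # controls <= s
    posP <- (1 + nGE) / (1 + nC)
    negP <- (1 + nLE) / (1 + nC)
    n <- length(score)
    posRank <- negRank <- numeric(n)
    posRank[order(-score, rownames(nm))] <- seq_len(n) / n
    negRank[order(score, rownames(nm))] <- seq_len(n) / n
    data.frame(sgrna = rownames(nm), gene = rd$gene, isControl = ctrl,
               score = score, posP = posP, negP = negP,
               posRank = posRank, negRank = negRank,
               stringsAsFactors = FALSE)
}

#' alpha-RRA configuration
#'
#' @param alpha guide-selection threshold on the control-based empirical
#'   p-value (0 < alpha <= 1; default 0.05). Only guides with p < alpha
#'   contribute to a gene's rho; alpha = 1 disables selection.
#' @param nPermutations permutation draws for the gene p-value
#'   (>= 100; default 10000).
#' @param seed optional RNG seed for the permutation null.
#' @export
rraConfig <- function(alpha = 0.05, nPermutations = 10000L, seed = NULL) {
    stopIfNot(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
    stopIfNot(nPermutations >= 100L, "nPermutations must be >= 100")
    list(alpha = alpha, nPermutations = as.integer(nPermutations),
         seed = seed)
}

# Beta order-statistic rho for one gene: sorted percentile ranks r
# (ascending) with aligned selection flags. rho = min over selected
# positions k of P(Beta(k, m-k+1) <= r_k); 1 if nothing selected.
rhoStatistic <- function(r, selected) {
    ord <- order(r)
    r <- r[ord]
    selected <- selected[ord]
    if (!any(selected)) return(1)
    m <- length(r)
    k <- which(selected)
    min(stats::pbeta(r[k], k, m - k + 1))
}

#' Gene-level alpha-robust-rank-aggregation scores
#'
#' For each gene and direction, aggregates its guides' percentile ranks
#' with the alpha-RRA statistic: rho = min over selected guides (empirical
#' p < alpha) of the Beta(k, m-k+1) order-statistic probability of the
#' k-th smallest rank; genes with no selected guide get rho = 1. Gene
#' p-values come from a permutation null that redraws m (rank, p) pairs
#' without replacement from the observed pool, shared across genes with
#' the same guide count; BH-adjusted FDR is reported per direction. The
#' pos direction (low-bin enrichment) identifies activators, neg
#' (high-bin enrichment) repressors.
#'
#' @param scores sgRNA score table from \code{\link{sgrnaScores}}.
#' @param config an \code{\link{rraConfig}}.
#' @return data.frame per gene: \code{gene}, then per direction
#'   \code{posScore}/\code{negScore} (rho), \code{posP}/\code{negP}
#'   (permutation p, floor 1/(nPermutations+1)), \code{posFdr}/
#'   \code{negFdr}, and selected-guide counts \code{posGood}/
#'   \code{negGood}.
#' @export
geneRRA <- function(scores, config = rraConfig()) {
    targ <- scores[!scores$isControl, ]
    stopIfNot(nrow(targ) > 0L, "no targeting sgRNAs")
    stopIfNot(!anyNA(targ$gene), "every targeting sgRNA must map to a gene")
    withSeed(config$seed, {
        pos <- rraDirection(targ$gene, targ$posRank, targ$posP,
                            scores$posRank, scores$posP, config)
        neg <- rraDirection(targ$gene, targ$negRank, targ$negP,
                            scores$negRank, scores$negP, config)
        stopIfNot(identical(pos$gene, neg$gene), "direction gene mismatch")
        data.frame(gene = pos$gene,
                   posScore = pos$rho, posP = pos$p, posFdr = pos$fdr,
                   posGood = pos$good,
                   negScore = neg$rho, negP = neg$p, negFdr = neg$fdr,
                   negGood = neg$good, stringsAsFactors = FALSE)
    })
}

# One direction of alpha-RRA: observed rho per gene plus a size-class
# permutation null drawn from the pooled (rank, p) observations.
rraDirection <- function(gene, rank, p, poolRank, poolP, config) {
    sel <- p < config$alpha
    genes <- sort(unique(gene))
    byGene <- split(seq_along(gene), gene)[genes]
    rho <- vapply(byGene, function(i) rhoStatistic(rank[i], sel[i]),
                  numeric(1L))
    good <- vapply(byGene, function(i) sum(sel[i]), integer(1L))
    m <- lengths(byGene)
    nPerm <- config$nPermutations
    poolSel <- poolP < config$alpha
    nPool <- length(poolRank)
    pval <- numeric(length(genes))
    for (mm in unique(m)) {
        null <- vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(nPool, mm)
            rhoStatistic(poolRank[idx], poolSel[idx])
        }, numeric(1L))
        null <- sort(null)
        which_ <- which(m == mm)
        pval[which_] <- (1 + findInterval(rho[which_], null)) / (1 + nPerm)
    }
    data.frame(gene = genes, rho = unname(rho), p = pval,
               fdr = stats::p.adjust(pval, "BH"), good = unname(good),
               stringsAsFactors = FALSE)
}

#' Export / read gene score tables
#'
#' Lossless TSV with fixed column order \code{gene}, \code{pos.score},
#' \code{neg.score}, \code{pos.p}, \code{neg.p}, \code{pos.fdr},
#' \code{neg.fdr}, \code{pos.goodsgrna}, \code{neg.goodsgrna}, sorted by
#' the smaller of the two direction scores.
#'
#' @param geneScores data.frame from \code{\link{geneRRA}}.
#' @param path TSV path.
#' @export
exportScores <- function(geneScores, path) {
    out <- data.frame(gene = geneScores$gene,
                      pos.score = geneScores$posScore,
                      neg.score = geneScores$negScore,
                      pos.p = geneScores$posP, neg.p = geneScores$negP,
                      pos.fdr = geneScores$posFdr,
                      neg.fdr = geneScores$negFdr,
                      pos.goodsgrna = geneScores$posGood,
                      neg.goodsgrna = geneScores$negGood)
    out <- out[order(pmin(out$pos.score, out$neg.score), out$gene), ]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname exportScores
#' @export
readScores <- function(path) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(gene = "character"))
    data.frame(gene = x$gene, posScore = x$pos.score,
               posP = x$pos.p, posFdr = x$pos.fdr,
               posGood = x$pos.goodsgrna,
               negScore = x$neg.score, negP = x$neg.p,
               negFdr = x$neg.fdr, negGood = x$neg.goodsgrna,
               stringsAsFactors = FALSE)
}
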