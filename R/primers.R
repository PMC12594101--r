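#' Default staggered readout primer set
#'
#' The twelve staggered readout primers (F01--F12) used to multiplex up to
#' twelve sorted-bin samples in one sequencing lane, with the two
#' invariant amplicon templates. Each sequenced amplicon has the fixed
#' structure stagger + 8-nt index + Template1 (24 nt) + sgRNA (20 nt) +
#' Template2; the variable-length stagger provides base-composition
#' complexity across the otherwise identical template positions.
#'
#' @return A \linkS4class{PrimerSet}.
#' @examples
#' defaultPrimers()
#' @export
defaultPrimers <- function() {
    tab <- data.frame(
        name = sprintf("F%02d", 1:12),
        stagger = c("t", "at", "gat", "cgat", "tcgat", "atcgat",
                    "gatcgat", "cgatcgat", "acgatcgat", "t", "at", "gat"),
        index = c("AAGTAGAG", "ACACGATC", "CGCGCGGT", "CATGATCG",
                  "CGTTACCA", "TCCTTGGT", "AACGCATT", "ACAGGTAT",
                  "AGGTAAGG", "AACAATGG", "ACTGTATC", "AGGTCGCA"),
        stringsAsFactors = FALSE)
    new("PrimerSet",
        primers = tab,
        template1 = "TCTTGTGGAAAGGACGAAACACCG",
        template2 = paste0(
            "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGT",
            "GGCACCGAGTCGGTGCTTTTTTAAGCTTGGCGTAACTAGATCTTGAGACAAATGGCAGTA",
            "TTCATCCACAATTTTAAAAGAAAAGGGGGGATTGGGGGGTACAGTGCAGGGGAAAGAATA",
            "GTAGA"))
}

#' Default primer-to-sample layout
#'
#' Maps each readout primer to a (replicate, bin) sample: odd primers
#' carry the low-fluorescence bin and even primers the high bin of
#' successive replicates (F01 = rep1 low, F02 = rep1 high, ...).
#'
#' @param replicates number of sorted replicates (1--6 with the default
#'   12-primer set).
#' @param primerSet a \linkS4class{PrimerSet}; its primer names are used
#'   in order.
#' @return data.frame with columns \code{primer}, \code{sample},
#'   \code{replicate}, \code{bin}.
#' @examples
#' defaultSampleLayout(3)
#' @export
defaultSampleLayout <- function(replicates = 6L, primerSet = defaultPrimers()) {
    nm <- primers(primerSet)$name
    stopIfNot(replicates >= 1L && 2L * replicates <= length(nm),
              "need one primer per (replicate, bin): at most ",
              length(nm) %/% 2L, " replicates")
    rep_ <- rep(seq_len(replicates), each = 2L)
    bin <- rep(c("low", "high"), replicates)
    data.frame(primer = nm[seq_len(2L * replicates)],
               sample = paste0("rep", rep_, "_", bin),
               replicate = rep_, bin = bin, stringsAsFactors = FALSE)
}

# Full uppercase read prefix (stagger + index) per primer.
primerPrefixes <- function(primerSet) {
    p <- primers(primerSet)
    toupper(paste0(p$stagger, p$index))
}
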