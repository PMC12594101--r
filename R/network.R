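#' Assemble per-screen hit tables into a regulatory network
#'
#' One directed edge per retained hit: regulator gene -> screened target
#' gene, sense \code{"activation"} for activator hits (the gene normally
#' raises the target) and \code{"repression"} for repressor hits, with
#' the RRA score and weight -log10(score) as edge attributes. Screens
#' where a regulator is the target itself yield flagged self-loops.
#'
#' @param hitTables list of \linkS4class{HitTable}s with unique screen
#'   names.
#' @return A \linkS4class{RegulatoryNetwork}.
#' @export
buildNetwork <- function(hitTables) {
    if (is(hitTables, "HitTable")) hitTables <- list(hitTables)
    screens <- vapply(hitTables, screenName, character(1L))
    stopIfNot(!anyDuplicated(screens), "screen names must be unique")
    parts <- lapply(hitTables, function(ht) {
        h <- hits(ht)
        if (!nrow(h)) return(NULL)
        data.frame(regulator = h$gene,
                   target = rep(screenName(ht), nrow(h)),
                   sense = ifelse(h$sense == "activator",
                                  "activation", "repression"),
                   score = h$score, stringsAsFactors = FALSE)
    })
    e <- do.call(rbind, parts)
    if (is.null(e))
        e <- data.frame(regulator = character(), target = character(),
                        sense = character(), score = numeric(),
                        stringsAsFactors = FALSE)
    if (anyDuplicated(paste(e$regulator, e$target, e$sense)))
        stop("duplicate (regulator, target, sense) rows in input hits")
    e$weight <- -log10(e$score)
    e$selfLoop <- e$regulator == e$target
    rownames(e) <- NULL
    new("RegulatoryNetwork", edges = e)
}

#' Network-wide summary totals
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return list with \code{nEdges}, \code{nActivating},
#'   \code{nRepressing}, \code{nRegulators} (distinct source genes),
#'   \code{nTargets} and \code{nSelfLoops}.
#' @export
networkSummary <- function(network) {
    e <- edges(network)
    list(nEdges = nrow(e),
         nActivating = sum(e$sense == "activation"),
         nRepressing = sum(e$sense == "repression"),
         nRegulators = length(unique(e$regulator)),
         nTargets = length(unique(e$target)),
         nSelfLoops = sum(e$selfLoop))
}

#' Classify regulators by their edge senses
#'
#' Partitions regulators into activator-only, repressor-only, and
#' context-dependent (at least one activating and one repressing edge,
#' to any targets).
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return data.frame per regulator: \code{regulator}, \code{class},
#'   \code{nActivated}, \code{nRepressed} (target counts per sense) and
#'   \code{nScreens} (distinct targets, i.e. appearance count).
#' @export
classifyRegulators <- function(network) {
    e <- edges(network)
    regs <- sort(unique(e$regulator))
    byReg <- split(seq_len(nrow(e)), e$regulator)[regs]
    nAct <- vapply(byReg, function(i)
        length(unique(e$target[i][e$sense[i] == "activation"])),
        integer(1L))
    nRep <- vapply(byReg, function(i)
        length(unique(e$target[i][e$sense[i] == "repression"])),
        integer(1L))
    nScr <- vapply(byReg, function(i) length(unique(e$target[i])),
                   integer(1L))
    cls <- ifelse(nAct > 0 & nRep > 0, "context-dependent",
                  ifelse(nAct > 0, "activator-only", "repressor-only"))
    data.frame(regulator = regs, class = unname(cls),
               nActivated = unname(nAct), nRepressed = unname(nRep),
               nScreens = unname(nScr), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Rank regulators of one sense
#'
#' Orders regulators either by their best (smallest) RRA score over
#' edges of the given sense, or by appearance count (number of distinct
#' target screens of that sense, descending). Ties are broken
#' lexicographically by gene symbol for a stable ordering.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param sense \code{"activation"} or \code{"repression"}.
#' @param by \code{"best_score"} or \code{"appearance_count"}.
#' @return data.frame ordered best-first: \code{regulator},
#'   \code{bestScore}, \code{appearances}.
#' @export
rankRegulators <- function(network, sense = c("activation", "repression"),
                           by = c("best_score", "appearance_count")) {
    sense <- match.arg(sense)
    by <- match.arg(by)
    e <- edges(network)
    e <- e[e$sense == sense, , drop = FALSE]
    stopIfNot(nrow(e) > 0L, "no edges of sense ", sense)
    regs <- sort(unique(e$regulator))
    byReg <- split(e$score, e$regulator)[regs]
    best <- vapply(byReg, min, numeric(1L))
    app <- vapply(split(e$target, e$regulator)[regs],
                  function(x) length(unique(x)), integer(1L))
    out <- data.frame(regulator = regs, bestScore = unname(best),
                      appearances = unname(app), stringsAsFactors = FALSE)
    ord <- if (by == "best_score") order(out$bestScore, out$regulator)
           else order(-out$appearances, out$regulator)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export / import a regulatory network
#'
#' TSV export is lossless (all edge columns). SIF uses interaction
#' labels \code{activates} / \code{represses}; GraphML goes through
#' \pkg{igraph} with sense, score and weight as edge attributes.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param path output file path.
#' @param format \code{"tsv"}, \code{"sif"} or \code{"graphml"}.
#' @export
exportNetwork <- function(network, path,
                          format = c("tsv", "sif", "graphml")) {
    format <- match.arg(format)
    e <- edges(network)
    if (format == "tsv") {
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else if (format == "sif") {
        lab <- ifelse(e$sense == "activation", "activates", "represses")
        writeLines(paste(e$regulator, lab, e$target, sep = "\t"), path)
    } else {
        g <- igraph::graph_from_data_frame(
            e[, c("regulator", "target", "sense", "score", "weight")],
            directed = TRUE)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' @rdname exportNetwork
#' @export
importNetworkTSV <- function(path) {
    e <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(regulator = "character",
                                          target = "character",
                                          sense = "character"))
    e$selfLoop <- as.logical(e$selfLoop)
    new("RegulatoryNetwork", edges = e)
}

#' Access the paper-deposited per-screen hit tables
#'
#' The full per-screen hit tables underlying the published 47-screen
#' regulatory network are distributed as supplementary data alongside
#' the primary publication and via GEO, and are not bundled with this
#' package. This accessor exists so analyses written against it run
#' unchanged once the tables are placed under the path it reports.
#'
#' @param dir directory expected to contain one
#'   \code{<screen>_hits.tsv} per screen (columns gene, sense, score,
#'   fdr).
#' @return list of \linkS4class{HitTable}s.
#' @export
supplementaryHitTables <- function(dir = getOption(
        "ReporterScreen.supplementaryDir",
        system.file("extdata", "supplementary", package = "ReporterScreen"))) {
    files <- if (!is.null(dir) && nzchar(dir) && dir.exists(dir))
        list.files(dir, pattern = "_hits\\.tsv$", full.names = TRUE)
    else character()
    if (!length(files))
        stop("deposited per-screen hit tables are not bundled with this ",
             "package; place the published supplementary tables under ",
             "a directory with one <screen>_hits.tsv per screen and ",
             "pass it as `dir` (or set options(",
             "ReporterScreen.supplementaryDir=))")
    lapply(files, function(f) {
        h <- utils::read.table(f, header = TRUE, sep = "\t",
                               colClasses = c(gene = "character",
                                              sense = "character"))
        new("HitTable", screen = sub("_hits\\.tsv$", "", basename(f)),
            hits = h[, c("gene", "sense", "score", "fdr")],
            removed = data.frame(gene = character(), sense = character(),
                                 score = numeric(), reason = character()),
            cutoff = if (nrow(h)) max(1e-3, max(h$score) * 1.000001)
                     else 1e-3)
    })
}
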