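# Hit sets per screen and sense from hit tables or a network.
hitSets <- function(x, sense = c("activator", "repressor")) {
    sense <- match.arg(sense)
    if (is(x, "RegulatoryNetwork")) {
        e <- edges(x)
        s <- if (sense == "activator") "activation" else "repression"
        e <- e[e$sense == s, , drop = FALSE]
        split(e$regulator, factor(e$target, levels = sort(unique(edges(x)$target))))
    } else {
        stopIfNot(is.list(x) && all(vapply(x, is, logical(1L), "HitTable")),
                  "expected a RegulatoryNetwork or a list of HitTables")
        nm <- vapply(x, screenName, character(1L))
        sets <- lapply(x, function(ht) {
            h <- hits(ht)
            unique(h$gene[h$sense == sense])
        })
        names(sets) <- nm
        sets
    }
}

#' Shared-regulator overlap matrices across screens
#'
#' For each sense, entry (i, j) is the number of regulators of that
#' sense shared by screens i and j; the diagonal is each screen's hit
#' count. Companion Jaccard matrices (overlap / union) are returned for
#' scale-invariant comparison.
#'
#' @param x a \linkS4class{RegulatoryNetwork} or list of
#'   \linkS4class{HitTable}s (>= 2 screens).
#' @return list with integer matrices \code{activator},
#'   \code{repressor} and numeric \code{jaccardActivator},
#'   \code{jaccardRepressor}.
#' @export
overlapMatrices <- function(x) {
    act <- hitSets(x, "activator")
    rep_ <- hitSets(x, "repressor")
    stopIfNot(length(act) >= 2L, "need at least 2 screens")
    one <- function(sets) {
        regs <- unique(unlist(sets, use.names = FALSE))
        inc <- vapply(sets, function(s) regs %in% s,
                      logical(length(regs)))
        if (length(regs) == 0L)
            inc <- matrix(FALSE, 0L, length(sets),
                          dimnames = list(NULL, names(sets)))
        if (length(regs) == 1L)
            inc <- matrix(inc, nrow = 1L,
                          dimnames = list(NULL, names(sets)))
        ov <- crossprod(inc)
        d <- diag(ov)
        un <- outer(d, d, "+") - ov
        jac <- ifelse(un > 0, ov / un, 0)
        storage.mode(ov) <- "integer"
        list(overlap = ov, jaccard = jac)
    }
    a <- one(act)
    r <- one(rep_)
    list(activator = a$overlap, repressor = r$overlap,
         jaccardActivator = a$jaccard, jaccardRepressor = r$jaccard)
}

#' Cluster screens into the two co-regulation groups
#'
#' Average-linkage hierarchical clustering of screens on the distance
#' 1 - mean(activator Jaccard, repressor Jaccard), cut at k = 2. The
#' cluster with the higher mean within-group activator Jaccard is
#' labelled group 1 (screens sharing activators); the other group 2
#' (screens sharing repressors). The mean silhouette width of the
#' 2-split is reported so the strength of the partition is explicit.
#' Degenerate inputs (all pairwise distances zero) yield
#' \code{"unassigned"} labels.
#'
#' @param overlaps output of \code{\link{overlapMatrices}}.
#' @param k number of clusters (default 2).
#' @param linkage hclust agglomeration method (default
#'   \code{"average"}).
#' @return list: \code{assignment} (data.frame screen / group),
#'   \code{tree} (hclust), \code{silhouette} (mean width of the split).
#' @export
clusterScreens <- function(overlaps, k = 2L, linkage = "average") {
    ja <- overlaps$jaccardActivator
    jr <- overlaps$jaccardRepressor
    n <- nrow(ja)
    stopIfNot(n >= 3L, "need at least 3 screens to cluster")
    D <- 1 - (ja + jr) / 2
    diag(D) <- 0
    if (max(D) < .Machine$double.eps^0.5) {
        return(list(assignment = data.frame(
                        screen = rownames(ja),
                        group = rep("unassigned", n),
                        stringsAsFactors = FALSE),
                    tree = NULL, silhouette = NA_real_))
    }
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    cl <- stats::cutree(hc, k = k)
    withinJac <- vapply(seq_len(k), function(g) {
        i <- which(cl == g)
        if (length(i) < 2L) return(-Inf)
        m <- ja[i, i]
        mean(m[upper.tri(m)])
    }, numeric(1L))
    group1 <- which.max(withinJac)
    group <- ifelse(cl == group1, "1", "2")
    sil <- meanSilhouette(D, cl)
    list(assignment = data.frame(screen = rownames(ja), group = group,
                                 stringsAsFactors = FALSE),
         tree = hc, silhouette = sil)
}

# Mean silhouette width from a distance matrix and integer labels.
meanSilhouette <- function(D, cl) {
    n <- nrow(D)
    ks <- unique(cl)
    s <- vapply(seq_len(n), function(i) {
        own <- which(cl == cl[i])
        a <- if (length(own) > 1L) mean(D[i, setdiff(own, i)]) else 0
        b <- min(vapply(setdiff(ks, cl[i]), function(g)
            mean(D[i, cl == g]), numeric(1L)))
        if (length(own) == 1L) 0 else (b - a) / max(a, b)
    }, numeric(1L))
    mean(s)
}

#' Regulators shared by a small set of screens
#'
#' Intersection of the hit sets of the given sense across 2--4 screens,
#' plus Venn-style exclusive region counts over all membership
#' patterns.
#'
#' @param hitTables list of \linkS4class{HitTable}s (or a
#'   \linkS4class{RegulatoryNetwork}).
#' @param screens 2--4 screen names to compare.
#' @param sense \code{"activator"} or \code{"repressor"}.
#' @return list: \code{shared} (regulators in every chosen screen),
#'   \code{regions} (named exclusive-region counts, names like
#'   \code{"A&B"}), \code{membership} (regulator x screen logical
#'   data.frame).
#' @export
sharedRegulators <- function(hitTables, screens,
                             sense = c("activator", "repressor")) {
    sense <- match.arg(sense)
    stopIfNot(length(screens) >= 2L && length(screens) <= 4L,
              "choose between 2 and 4 screens")
    sets <- hitSets(hitTables, sense)
    missing <- setdiff(screens, names(sets))
    if (length(missing))
        stop("unknown screen name(s): ", paste(missing, collapse = ", "))
    sets <- sets[screens]
    regs <- sort(unique(unlist(sets, use.names = FALSE)))
    memb <- vapply(sets, function(s) regs %in% s, logical(length(regs)))
    if (length(regs) == 1L)
        memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, screens))
    if (length(regs) == 0L)
        memb <- matrix(FALSE, 0L, length(screens),
                       dimnames = list(NULL, screens))
    pat <- apply(memb, 1L, function(x)
        paste(screens[x], collapse = "&"))
    regions <- table(pat)
    shared <- regs[rowSums(memb) == length(screens)]
    list(shared = shared,
         regions = stats::setNames(as.integer(regions), names(regions)),
         membership = data.frame(regulator = regs, memb,
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE))
}

#' Condition-specific regulators
#'
#' \code{common} is the intersection of hit sets across all treated
#' screens; \code{specific} removes anything also found in any
#' untreated screen. Used to isolate regulators required only under a
#' perturbation (e.g. the mTORC1-inhibited screens).
#'
#' @param treated,untreated lists of \linkS4class{HitTable}s (>= 1
#'   each).
#' @param sense \code{"activator"}, \code{"repressor"} or \code{"any"}
#'   (gene detected in either sense; default).
#' @return list with \code{common} and \code{specific} character
#'   vectors.
#' @export
conditionSpecificRegulators <- function(treated, untreated,
        sense = c("any", "activator", "repressor")) {
    sense <- match.arg(sense)
    pull <- function(ht) {
        h <- hits(ht)
        if (sense != "any") h <- h[h$sense == sense, , drop = FALSE]
        unique(h$gene)
    }
    stopIfNot(length(treated) >= 1L && length(untreated) >= 1L,
              "need at least one hit table per condition")
    common <- sort(Reduce(intersect, lapply(treated, pull)))
    seen <- unique(unlist(lapply(untreated, pull), use.names = FALSE))
    list(common = common, specific = setdiff(common, seen))
}

#' Functional-class composition of screen hits
#'
#' Given a user-supplied gene-to-class map (functional clustering itself
#' is out of scope here), counts hits per screen, sense and class, and
#' the fraction of each screen's activators / repressors falling in
#' each class.
#'
#' @param hitTables list of \linkS4class{HitTable}s.
#' @param classMap data.frame with columns \code{gene}, \code{class}.
#' @return data.frame: \code{screen}, \code{sense}, \code{class},
#'   \code{count}, \code{fraction} (of that screen's hits of that
#'   sense; unmapped genes count toward the denominator).
#' @export
classDistribution <- function(hitTables, classMap) {
    rows <- list()
    for (ht in hitTables) {
        h <- hits(ht)
        for (sn in c("activator", "repressor")) {
            genes_ <- unique(h$gene[h$sense == sn])
            tot <- length(genes_)
            cls <- classMap$class[match(genes_, classMap$gene)]
            tab <- table(cls[!is.na(cls)])
            for (cn in sort(unique(classMap$class))) {
                cnt <- if (cn %in% names(tab)) as.integer(tab[[cn]]) else 0L
                rows[[length(rows) + 1L]] <- data.frame(
                    screen = screenName(ht), sense = sn, class = cn,
                    count = cnt,
                    fraction = if (tot > 0) cnt / tot else 0,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(screen = character(), sense = character(),
                          class = character(), count = integer(),
                          fraction = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
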