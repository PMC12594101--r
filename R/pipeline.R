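#' Run the screen-analysis pipeline end to end
#'
#' Config-driven orchestration of simulate (or load) -> normalize ->
#' score -> filter -> network -> co-regulation, writing every stage
#' output plus a manifest (file hashes, seed, versions) so a rerun with
#' the same config is bit-identical except for the manifest timestamp.
#'
#' The config is a named list (or path to a YAML file) with:
#' \describe{
#'   \item{outdir}{output directory (required).}
#'   \item{seed}{integer seed propagated to every stochastic stage.}
#'   \item{counts, screen}{to analyse an existing long-format count TSV
#'     (one screen).}
#'   \item{annotation}{directory written by
#'     \code{\link{writeAnnotation}}; enables the centromere and
#'     expression filters.}
#'   \item{simulate}{list: \code{nChromosomes}, \code{genesPerChromosome},
#'     \code{guidesPerGene}, \code{nControls}, \code{nScreens},
#'     \code{nActivators}, \code{nRepressors}, \code{effectSize},
#'     \code{penetrance}.}
#'   \item{screen_config}{arguments for \code{\link{screenConfig}}.}
#'   \item{rra}{arguments for \code{\link{rraConfig}}.}
#'   \item{filter}{\code{cutoff} (RRA score) and \code{minRpkm}.}
#' }
#'
#' @param config named list or YAML file path.
#' @return (invisibly) list with the hit tables, network, group
#'   assignment (if >= 3 screens) and the manifest.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        stopIfNot(file.exists(config), "config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    stopIfNot(!is.null(config$outdir), "config$outdir is required")
    for (p in c("counts", "annotation"))
        if (!is.null(config[[p]]) && !file.exists(config[[p]]))
            stop("configured path does not exist: ", config[[p]])
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    rra <- do.call(rraConfig, c(config$rra,
                                list(seed = seed + 500L)))
    cutoff <- if (is.null(config$filter$cutoff)) 1e-3
              else config$filter$cutoff
    minRpkm <- if (is.null(config$filter$minRpkm)) 0.1
               else config$filter$minRpkm
    written <- character()
    put <- function(f) written[[length(written) + 1L]] <<- f

    annotation <- NULL
    if (!is.null(config$annotation))
        annotation <- readAnnotation(config$annotation)

    hitTables <- list()
    if (!is.null(config$counts)) {
        counts <- readCounts(config$counts)
        screen <- config$screen
        stopIfNot(!is.null(screen), "config$screen names the target gene")
        hitTables[[screen]] <- scoreAndFilter(counts, screen, rra, cutoff,
                                              minRpkm, annotation, outdir,
                                              put)
    } else {
        sim <- config$simulate
        gpc <- if (is.null(sim$genesPerChromosome)) 25L
               else sim$genesPerChromosome
        nchr <- if (is.null(sim$nChromosomes)) 2L else sim$nChromosomes
        annotation <- makeGenome(nchr, gpc, seed = seed)
        lib <- makeLibrary(annotation,
            if (is.null(sim$guidesPerGene)) 4L else sim$guidesPerGene,
            if (is.null(sim$nControls)) 20L else sim$nControls,
            seed = seed + 1L)
        adir <- file.path(outdir, "annotation")
        writeAnnotation(annotation, adir)
        for (f in c("genes.bed", "centromeres.bed", "chrom.sizes",
                    "expression.tsv"))
            put(file.path(adir, f))
        writeLibrary(lib, file.path(outdir, "library.tsv"))
        put(file.path(outdir, "library.tsv"))
        nScreens <- if (is.null(sim$nScreens)) 1L else sim$nScreens
        sym <- genes(annotation)$symbol
        reporters <- withSeed(seed + 2L, sample(sym, nScreens))
        scfgArgs <- config$screen_config
        for (i in seq_len(nScreens)) {
            rg <- reporters[i]
            tr <- makeTrueNetwork(annotation, rg,
                nActivators = if (is.null(sim$nActivators)) 5L
                              else sim$nActivators,
                nRepressors = if (is.null(sim$nRepressors)) 5L
                              else sim$nRepressors,
                effectSize = if (is.null(sim$effectSize)) 2
                             else sim$effectSize,
                penetrance = if (is.null(sim$penetrance)) 0.3
                             else sim$penetrance,
                seed = seed + 10L + i)
            scfg <- do.call(screenConfig,
                            c(scfgArgs, list(seed = seed + 100L + i)))
            sc <- simulateScreen(lib, tr, scfg, reporterGene = rg)
            tpath <- file.path(outdir, paste0(rg, "_truth.tsv"))
            utils::write.table(screenTruth(sc), tpath, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            put(tpath)
            cpath <- file.path(outdir, paste0(rg, "_counts.tsv"))
            writeCounts(screenCounts(sc), cpath)
            put(cpath)
            hitTables[[rg]] <- scoreAndFilter(screenCounts(sc), rg, rra,
                                              cutoff, minRpkm, annotation,
                                              outdir, put)
        }
    }

    net <- buildNetwork(unname(hitTables))
    npath <- file.path(outdir, "network.tsv")
    exportNetwork(net, npath, "tsv")
    put(npath)
    groups <- NULL
    if (length(hitTables) >= 3L) {
        om <- overlapMatrices(unname(hitTables))
        groups <- clusterScreens(om)
        gpath <- file.path(outdir, "groups.tsv")
        utils::write.table(groups$assignment, gpath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        put(gpath)
    }
    spath <- file.path(outdir, "summary.json")
    jsonlite::write_json(c(networkSummary(net),
                           list(nScreens = length(hitTables))),
                         spath, auto_unbox = TRUE, pretty = TRUE)
    put(spath)
    manifest <- list(
        seed = seed,
        package = as.character(utils::packageVersion("ReporterScreen")),
        r = R.version.string,
        timestamp = format(Sys.time(), tz = "UTC"),
        files = as.list(tools::md5sum(sort(unlist(written)))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(hitTables = hitTables, network = net, groups = groups,
                   manifest = manifest))
}

# Score one screen's counts and apply the hit filters, writing stage
# outputs under `outdir`.
scoreAndFilter <- function(counts, screen, rra, cutoff, minRpkm,
                           annotation, outdir, put) {
    counts <- normalizeCounts(counts)
    gs <- geneRRA(sgrnaScores(counts), rra)
    spath <- file.path(outdir, paste0(screen, "_scores.tsv"))
    exportScores(gs, spath)
    put(spath)
    ht <- applyRraCutoff(gs, screen, cutoff)
    if (!is.null(annotation)) {
        if (screen %in% genes(annotation)$symbol)
            ht <- filterCentromereSpan(ht, annotation, screen)
        ht <- suppressWarnings(
            filterInactive(ht, expressionTable(annotation), minRpkm))
    }
    hpath <- file.path(outdir, paste0(screen, "_hits.tsv"))
    writeHits(ht, hpath,
              file.path(outdir, paste0(screen, "_removals.tsv")))
    put(hpath)
    put(file.path(outdir, paste0(screen, "_removals.tsv")))
    ht
}

#' Generate an on-disk synthetic fixture dataset
#'
#' \code{"tiny"}: 50 genes x 4 guides + 20 controls, 3 replicates,
#' small cell and read numbers -- builds in seconds for smoke tests.
#' \code{"desk"}: 2,000 genes x 4 guides + 100 controls, 6 replicates
#' at desk-scale depth. Writes the library, annotation, ground truth,
#' simulated counts and a config echo (YAML) into \code{dir}.
#'
#' @param size \code{"tiny"} or \code{"desk"}.
#' @param dir output directory.
#' @param seed RNG seed.
#' @return (invisibly) list with the generated objects and paths.
#' @export
makeFixture <- function(size = c("tiny", "desk"), dir, seed = 1L) {
    size <- match.arg(size)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prm <- switch(size,
        tiny = list(nchr = 1L, gpc = 50L, nctrl = 20L, reps = 3L,
                    cells = 5e4, reads = 2e4, nact = 3L, nrep = 3L),
        desk = list(nchr = 4L, gpc = 500L, nctrl = 100L, reps = 6L,
                    cells = 2e6, reads = 2e5, nact = 20L, nrep = 20L))
    ann <- makeGenome(prm$nchr, prm$gpc, seed = seed)
    lib <- makeLibrary(ann, 4L, prm$nctrl, seed = seed + 1L)
    reporter <- withSeed(seed + 2L,
                         sample(genes(ann)$symbol[-seq_len(5L)], 1L))
    tr <- makeTrueNetwork(ann, reporter, prm$nact, prm$nrep,
                          effectSize = 2, seed = seed + 3L)
    cfg <- screenConfig(replicates = prm$reps,
                        cellsPerReplicate = prm$cells,
                        readsPerBin = prm$reads, seed = seed + 4L)
    sim <- simulateScreen(lib, tr, cfg, reporterGene = reporter)
    writeAnnotation(ann, file.path(dir, "annotation"))
    writeLibrary(lib, file.path(dir, "library.tsv"))
    utils::write.table(screenTruth(sim), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeCounts(screenCounts(sim), file.path(dir, "counts.tsv"))
    yaml::write_yaml(list(size = size, seed = seed, reporter = reporter,
                          screen_config = unclass(cfg)[
                              setdiff(names(cfg), "seed")]),
                     file.path(dir, "config.yaml"))
    invisible(list(annotation = ann, library = lib, truth = tr,
                   screen = sim, reporter = reporter, dir = dir))
}
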