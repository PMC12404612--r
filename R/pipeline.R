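#' Default pipeline configuration
#'
#' Returns the full run configuration as a named list; fields mirror the
#' tunable parameters of each stage.  `simulate` holds [simulationSpec()]
#' arguments (used when no input paths are given); `input` may instead name
#' `counts`, `phenotype`, `annotation` and `sitecalls` files.  Stage toggles
#' live under `stages`.  Serializes cleanly to YAML via [writeRunConfig()].
#'
#' @param seed global seed; each stage derives its own seed from it.
#' @return named list (class `RunConfig`).
#' @export
defaultRunConfig <- function(seed = 1) {
    structure(list(
        seed = seed,
        input = list(counts = NULL, phenotype = NULL, annotation = NULL,
                     sitecalls = NULL),
        simulate = list(nWorms = 180, nReplicates = 5, nGenes = 400,
                        fracEnvGenes = 0.05, fracTraitGenes = 0.03,
                        effectSizeSd = 0.13),
        filters = list(scan = list(rule = "any_gt", threshold = 10),
                       strict = list(rule = "all_gt", threshold = 1)),
        alpha = 0.05,
        trait = "early_brood",
        prediction = list(nPerm = 50, nIter = 100, k = 10, alphaEnet = 0.5,
                          kMaxPcs = 30, enet = TRUE),
        enrichment = list(nRandom = 500),
        isogenicity = list(nWorms = 20, nSites = 2000, depthMean = 30,
                           errorRate = 0, minDepth = 20, minWormsCovered = 10),
        stages = list(scan = TRUE, envde = TRUE, pathdecomp = TRUE,
                      prediction = TRUE, enrichment = TRUE,
                      isogenicity = TRUE)),
        class = "RunConfig")
}

#' Read / write a run configuration
#'
#' YAML round-trip of a `RunConfig`; `readRunConfig` fills unset fields
#' from [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return `readRunConfig`: a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- unclass(defaultRunConfig())
    merge2 <- function(base, new) {
        for (k in names(new)) {
            base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
                merge2(base[[k]], new[[k]]) else new[[k]]
        }
        base
    }
    structure(merge2(base, cfg), class = "RunConfig")
}

#' @rdname readRunConfig
#' @param config a `RunConfig` list.
#' @export
writeRunConfig <- function(config, path) {
    dropNulls <- function(x) {
        if (!is.list(x)) return(x)
        x <- lapply(x, dropNulls)
        x[!vapply(x, is.null, logical(1))]
    }
    yaml::write_yaml(dropNulls(unclass(config)), path)
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' preprocess, per-gene trait scan, environment scan + variance Z-scores,
#' path decomposition and gene classification, prediction suite,
#' enrichment, isogenicity check — writing per-stage TSV/JSON outputs and a
#' `manifest.json` (stage status, seeds, file digests) under `outdir`.
#' Reruns with the same config and seed reproduce all outputs
#' bit-identically.  A stage failure halts the run with the failing stage
#' named; outputs of completed stages are preserved.
#'
#' @param config a `RunConfig` (list) or path to a YAML config.
#' @param outdir output directory (created if missing).
#' @return (invisibly) list with the in-memory results of each stage and
#'   the manifest.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = tempfile("run")) {
    if (is.character(config)) config <- readRunConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package_version = as.character(
        utils::packageVersion("wormtrait")),
        seed = config$seed, stages = list())
    results <- list()
    writeRunConfig(config, file.path(outdir, "config.yaml"))

    runStage <- function(name, enabled, fun) {
        if (!enabled) {
            manifest$stages[[name]] <<- list(status = "skipped")
            return(invisible(NULL))
        }
        res <- tryCatch(fun(), error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        manifest$stages[[name]] <<- list(status = "done")
        results[[name]] <<- res
        res
    }

    # -- data -------------------------------------------------------------
    we <- runStage("data", TRUE, function() {
        if (!is.null(config$input$counts)) {
            readWormExperiment(config$input$counts, config$input$phenotype,
                               config$input$annotation)
        } else {
            spec <- do.call(simulationSpec,
                            c(config$simulate, list(seed = config$seed)))
            simulateStudy(spec)
        }
    })
    we <- cpmNormalize(we)
    writeCounts(counts(we), file.path(outdir, "counts.tsv"))
    writePhenotype(phenotype(we), file.path(outdir, "phenotype.csv"))
    if (!is.null(groundTruth(we)))
        jsonlite::write_json(groundTruth(we),
                             file.path(outdir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)

    scanSet <- filterGenes(we, config$filters$scan$rule,
                           config$filters$scan$threshold)
    strictSet <- filterGenes(we, config$filters$strict$rule,
                             config$filters$strict$threshold)
    trait <- config$trait

    # -- trait scan -------------------------------------------------------
    scan <- runStage("scan", isTRUE(config$stages$scan), function() {
        s <- scanTraitAssociations(we, trait, scanSet, alpha = config$alpha)
        data.table::fwrite(s, file.path(outdir, "scan.tsv"), sep = "\t")
        s
    })

    # -- environment DE + variance Z ---------------------------------------
    envde <- runStage("envde", isTRUE(config$stages$envde), function() {
        e <- scanEnvironmentDE(we, strictSet, alpha = config$alpha)
        data.table::fwrite(e, file.path(outdir, "envde.tsv"), sep = "\t")
        vz <- tryCatch(varianceZscores(e), error = function(err) NULL)
        if (!is.null(vz))
            data.table::fwrite(vz, file.path(outdir, "variance_z.tsv"),
                               sep = "\t")
        list(envde = e, varz = vz)
    })

    # -- path decomposition ------------------------------------------------
    runStage("pathdecomp",
             isTRUE(config$stages$pathdecomp) && !is.null(scan),
             function() {
        sig <- scan$gene[scan$significant]
        if (length(sig) == 0) sig <- utils::head(scan$gene[order(scan$p)], 5)
        pc <- decomposeGenes(sig, we, trait)
        if (!is.null(envde)) pc <- classifyGenes(pc, envde$envde,
                                                 alpha = config$alpha)
        data.table::fwrite(pc, file.path(outdir, "path_coefficients.tsv"),
                           sep = "\t")
        pc
    })

    # -- prediction --------------------------------------------------------
    runStage("prediction", isTRUE(config$stages$prediction), function() {
        y <- phenotype(we)[[trait]]
        lt <- logTransformForPca(we, strictSet)
        pcs <- pcaScores(lt)
        kMax <- min(config$prediction$kMaxPcs, ncol(pcs$scores))
        pcCurve <- cumulativePcR2(pcs$scores, y, kMax,
                                  nPerm = config$prediction$nPerm,
                                  seed = config$seed)
        data.table::fwrite(pcCurve, file.path(outdir, "pc_r2_curve.tsv"),
                           sep = "\t")
        xm <- t(lt)
        rs <- trainTestResampling(xm, y, nIter = config$prediction$nIter,
                                  k = config$prediction$k,
                                  seed = config$seed)
        data.table::fwrite(rs$iterations,
                           file.path(outdir, "resampling.tsv"), sep = "\t")
        enet <- if (isTRUE(config$prediction$enet))
            elasticNetLoocv(xm, y, alpha = config$prediction$alphaEnet,
                            seed = config$seed)
        list(pcCurve = pcCurve, resampling = rs, enet = enet)
    })

    # -- enrichment --------------------------------------------------------
    runStage("enrichment",
             isTRUE(config$stages$enrichment) &&
                 !is.null(results$prediction) && !is.null(scan),
             function() {
        ann <- data.frame(
            gene = rownames(we),
            domain = SummarizedExperiment::rowData(we)$domain,
            tissue = SummarizedExperiment::rowData(we)$tissue)
        eff <- data.frame(gene = scan$gene, beta1 = scan$std_beta)
        anova <- tryCatch(tissueDomainAnova(eff, ann),
                          error = function(e) NULL)
        ks <- regulatedProportionTest(
            results$prediction$resampling$geneSets, strictSet$genes, ann,
            nRandom = config$enrichment$nRandom, seed = config$seed)
        wz <- if (!is.null(envde$varz))
            varianceByDomainTest(envde$varz, ann)
        out <- list(anova = anova, ks = ks, wilcoxon = wz)
        jsonlite::write_json(list(
            ks = as.list(ks$ks),
            wilcoxon_p = if (!is.null(wz)) wz$p else NA),
            file.path(outdir, "enrichment.json"), auto_unbox = TRUE)
        out
    })

    # -- isogenicity -------------------------------------------------------
    runStage("isogenicity", isTRUE(config$stages$isogenicity), function() {
        iso <- config$isogenicity
        sc <- if (!is.null(config$input$sitecalls))
            readSiteCalls(config$input$sitecalls)
        else simulateSiteCalls(iso$nWorms, iso$nSites,
                               depthMean = iso$depthMean,
                               errorRate = iso$errorRate,
                               seed = config$seed)
        rep <- isogenicityCheck(sc, minDepth = iso$minDepth,
                                minWormsCovered = iso$minWormsCovered)
        jsonlite::write_json(
            rep[c("sitesConsidered", "totalObservations", "homCandidates",
                  "hetCandidates", "homRate", "hetRate")],
            file.path(outdir, "isogenicity.json"), auto_unbox = TRUE)
        rep
    })

    files <- setdiff(list.files(outdir, full.names = TRUE), "manifest.json")
    manifest$digests <- as.list(tools::md5sum(
        files[!grepl("manifest\\.json$", files)]))
    names(manifest$digests) <- basename(names(manifest$digests))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(c(results, list(manifest = manifest, outdir = outdir,
                              experiment = we)))
}
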