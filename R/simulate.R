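#' Simulation settings for a synthetic single-worm study
#'
#' Captures the study design the generator emulates: 180 individuals in five
#' biological replicates, a 2x2 historical-environment design (parental age x
#' early-life temperature), negative-binomial counts with replicate random
#' intercepts and environment effects on a gene subset, and two reproductive
#' traits built from gene-level effects plus environment, replicate and
#' residual noise (early brood with standard deviation 20.3; egg-laying onset
#' on the integer 66--74 h clock).
#'
#' @slot nWorms number of individuals (default 180).
#' @slot nReplicates number of biological replicates (default 5).
#' @slot nGenes number of genes simulated (default 1000).
#' @slot fracEnvGenes fraction of genes whose expression responds to parental
#'   age (default 0.05); a tenth as many respond to temperature, mirroring the
#'   strong asymmetry between the two perturbations.
#' @slot fracTraitGenes fraction of genes with a direct standardized effect on
#'   each trait (default 0.03).
#' @slot effectSizeSd standard deviation of true standardized gene-to-trait
#'   effects (default 0.13, so the aggregate expression signal explains about
#'   half of trait variance).
#' @slot replicateSd random-intercept standard deviation, used on the log
#'   scale for expression and on the standardized latent scale for traits
#'   (default 0.1).
#' @slot nbDispersion negative-binomial dispersion theta with
#'   Var = mu + mu^2/theta (default 2).
#' @slot meanLibsize expected reads per worm (default 5.8e6).
#' @slot traitSdBrood target standard deviation of early brood (default 20.3).
#' @slot envTraitBrood standardized (age, temperature) effects on early brood;
#'   default c(0.3, 0): brood responds to parental age but not temperature.
#' @slot envTraitElo standardized (age, temperature) effects on egg-laying
#'   onset; default c(0.3, 0.2): both perturbations shift onset.
#' @slot seed integer RNG seed.
#' @seealso [simulationSpec()], [simulateStudy()]
#' @export
setClass("SimulationSpec", representation(
    nWorms = "numeric", nReplicates = "numeric", nGenes = "numeric",
    fracEnvGenes = "numeric", fracTraitGenes = "numeric",
    effectSizeSd = "numeric", replicateSd = "numeric",
    nbDispersion = "numeric", meanLibsize = "numeric",
    traitSdBrood = "numeric", envTraitBrood = "numeric",
    envTraitElo = "numeric", seed = "numeric"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    pos1 <- function(x) length(x) == 1 && is.finite(x) && x > 0
    if (!pos1(object@nWorms) || object@nWorms != round(object@nWorms))
        msg <- c(msg, "nWorms must be a positive integer")
    if (!pos1(object@nReplicates) ||
        object@nReplicates != round(object@nReplicates))
        msg <- c(msg, "nReplicates must be a positive integer")
    if (pos1(object@nWorms) && pos1(object@nReplicates) &&
        object@nWorms < 2 * object@nReplicates)
        msg <- c(msg, "need nWorms >= 2 * nReplicates to estimate replicate variance")
    if (!pos1(object@nGenes)) msg <- c(msg, "nGenes must be positive")
    for (f in c("fracEnvGenes", "fracTraitGenes")) {
        v <- slot(object, f)
        if (!(length(v) == 1 && is.finite(v) && v >= 0 && v <= 1))
            msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
    }
    if (!pos1(object@nbDispersion)) msg <- c(msg, "nbDispersion must be > 0")
    if (!pos1(object@meanLibsize)) msg <- c(msg, "meanLibsize must be > 0")
    if (!pos1(object@traitSdBrood)) msg <- c(msg, "traitSdBrood must be > 0")
    if (length(msg)) msg else TRUE
})

#' Create a SimulationSpec
#'
#' @param nWorms,nReplicates,nGenes,fracEnvGenes,fracTraitGenes,effectSizeSd
#'   see [SimulationSpec-class].
#' @param replicateSd,nbDispersion,meanLibsize,traitSdBrood,envTraitBrood,envTraitElo,seed
#'   see [SimulationSpec-class].
#' @return a validated [SimulationSpec-class].
#' @examples
#' spec <- simulationSpec(nWorms = 40, nReplicates = 4, nGenes = 100, seed = 7)
#' @export
simulationSpec <- function(nWorms = 180, nReplicates = 5, nGenes = 1000,
                           fracEnvGenes = 0.05, fracTraitGenes = 0.03,
                           effectSizeSd = 0.13, replicateSd = 0.1,
                           nbDispersion = 2, meanLibsize = 5.8e6,
                           traitSdBrood = 20.3,
                           envTraitBrood = c(0.3, 0),
                           envTraitElo = c(0.3, 0.2), seed = 1) {
    new("SimulationSpec", nWorms = nWorms, nReplicates = nReplicates,
        nGenes = nGenes, fracEnvGenes = fracEnvGenes,
        fracTraitGenes = fracTraitGenes, effectSizeSd = effectSizeSd,
        replicateSd = replicateSd, nbDispersion = nbDispersion,
        meanLibsize = meanLibsize, traitSdBrood = traitSdBrood,
        envTraitBrood = envTraitBrood, envTraitElo = envTraitElo, seed = seed)
}

#' Simulate the per-worm design table (traits unset)
#'
#' Assigns worms to biological replicates in balanced blocks and draws the
#' two binarized historical-environment factors independently as
#' Bernoulli(0.5): `parental_age` (1 = day-1 parent) and `early_temp`
#' (1 = constant 20 degrees C).
#'
#' @param spec a [SimulationSpec-class].
#' @return data.frame with columns `worm_id`, `replicate`, `parental_age`,
#'   `early_temp`, `elo_hours` (NA), `early_brood` (NA).
#' @examples
#' head(simulateDesign(simulationSpec(nWorms = 20, nReplicates = 2)))
#' @export
simulateDesign <- function(spec) {
    validObject(spec)
    n <- spec@nWorms
    R <- spec@nReplicates
    set.seed(.stageSeed(spec@seed, 1L))
    # balanced within +/- 1: first (n mod R) replicates get the extra worm
    sizes <- rep(n %/% R, R) + c(rep(1L, n %% R), rep(0L, R - n %% R))
    data.frame(
        worm_id = sprintf("worm_%03d", seq_len(n)),
        replicate = rep(seq_len(R), times = sizes),
        parental_age = stats::rbinom(n, 1, 0.5),
        early_temp = stats::rbinom(n, 1, 0.5),
        elo_hours = NA_integer_,
        early_brood = NA_integer_,
        stringsAsFactors = FALSE)
}

#' Simulate a single-worm count matrix
#'
#' Counts for gene g in worm i are negative binomial with
#' log-mean = baseline_g + bAge_g * age_i + bTemp_g * temp_i + u_rep(i) +
#' log(target_i / meanLibsize), dispersion theta = `nbDispersion`
#' (Var = mu + mu^2/theta).  Gene baselines follow a log-normal abundance
#' profile; target library sizes are log-normal around `meanLibsize`.  The
#' realized column sums are recorded as the library sizes of the returned
#' object, so library-size conservation holds by construction.
#'
#' @param design design table from [simulateDesign()].
#' @param spec a [SimulationSpec-class].
#' @param bAge,bTemp optional named numeric vectors (names = gene ids)
#'   overriding the drawn log-scale environment effects for those genes;
#'   useful for planting effects of known size.
#' @return a [WormExperiment-class] whose `metadata()$truth` records the true
#'   environment effects on expression, the replicate intercepts and the
#'   environment-responsive gene lists.
#' @export
simulateExpression <- function(design, spec, bAge = NULL, bTemp = NULL) {
    validObject(spec)
    stopifnot(all(c("replicate", "parental_age", "early_temp") %in%
                  colnames(design)))
    n <- nrow(design)
    G <- spec@nGenes
    set.seed(.stageSeed(spec@seed, 2L))
    genes <- sprintf("gene_%04d", seq_len(G))

    # relative abundance profile: broad log-normal, normalized to sum 1
    ab <- exp(stats::rnorm(G, mean = 0, sd = 1.6))
    ab <- ab / sum(ab)
    baseline <- log(ab)
    if (any(!is.finite(baseline))) stop("non-finite gene baselines")

    nAge <- round(spec@fracEnvGenes * G)
    nTemp <- round(spec@fracEnvGenes * G / 10)
    ageGenes <- if (nAge > 0) sample(genes, nAge) else character()
    tempGenes <- if (nTemp > 0) sample(setdiff(genes, ageGenes), nTemp)
                 else character()
    bAgeV <- stats::setNames(numeric(G), genes)
    bTempV <- stats::setNames(numeric(G), genes)
    bAgeV[ageGenes] <- stats::rnorm(nAge, 0, log(1.5))
    bTempV[tempGenes] <- stats::rnorm(nTemp, 0, log(1.5))
    if (!is.null(bAge)) {
        stopifnot(all(names(bAge) %in% genes))
        bAgeV[names(bAge)] <- bAge
        ageGenes <- names(bAgeV)[bAgeV != 0]
    }
    if (!is.null(bTemp)) {
        stopifnot(all(names(bTemp) %in% genes))
        bTempV[names(bTemp)] <- bTemp
        tempGenes <- names(bTempV)[bTempV != 0]
    }
    bAge <- bAgeV
    bTemp <- bTempV

    R <- max(design$replicate)
    uRep <- stats::rnorm(R, 0, spec@replicateSd)
    target <- exp(stats::rnorm(n, log(spec@meanLibsize), 0.35))

    logOffset <- log(target / spec@meanLibsize) + uRep[design$replicate]
    # log-mean matrix genes x worms
    eta <- baseline + log(spec@meanLibsize) +
        outer(bAge, design$parental_age) + outer(bTemp, design$early_temp)
    eta <- sweep(eta, 2, logOffset, "+")
    mu <- exp(eta)
    cts <- matrix(stats::rnbinom(G * n, size = spec@nbDispersion, mu = mu),
                  nrow = G, dimnames = list(genes, design$worm_id))

    truth <- list(
        envExprAge = bAge, envExprTemp = bTemp,
        envGenesAge = sort(ageGenes), envGenesTemp = sort(tempGenes),
        replicateIntercepts = uRep, targetLibsizes = target)
    WormExperiment(cts, design, truth = truth)
}

#' Simulate the two reproductive traits from expression
#'
#' Traits are generated from the same causal structure the path decomposition
#' fits: a standardized latent
#' trait = sum over causal genes of beta_g * z(CPM_g) + standardized
#' environment effects + replicate intercept + Gaussian noise, with the noise
#' variance chosen so the latent has unit variance in expectation.  Early
#' brood is the latent rescaled to `traitSdBrood`, shifted to a realistic
#' mean and rounded to non-negative integers; egg-laying onset is an affine
#' map of its latent onto the integer 66--74 h observation clock.
#'
#' @param expr a [WormExperiment-class] from [simulateExpression()].
#' @param spec a [SimulationSpec-class].
#' @param causalBrood,causalElo optional named numeric vectors of true
#'   standardized effects (names = gene ids); drawn from the spec when NULL.
#' @return the `WormExperiment` with `elo_hours` and `early_brood` filled in
#'   and the causal effects appended to the ground truth.
#' @export
simulateTraits <- function(expr, spec, causalBrood = NULL, causalElo = NULL) {
    validObject(spec)
    we <- cpmNormalize(expr)
    cpm <- cpmValues(we)
    genes <- rownames(cpm)
    design <- phenotype(we)
    n <- ncol(cpm)
    set.seed(.stageSeed(spec@seed, 3L))

    # causal genes are drawn from the expressed pool (mean CPM > 10):
    # trait-associated genes in this kind of study pass the expression
    # filters, and near-silent genes have degenerate z-scores
    expressed <- genes[rowMeans(cpm) > 10]
    if (length(expressed) == 0) expressed <- genes
    drawBetas <- function() {
        k <- min(round(spec@fracTraitGenes * length(genes)),
                 length(expressed))
        if (k == 0) return(stats::setNames(numeric(0), character(0)))
        g <- sample(expressed, k)
        stats::setNames(stats::rnorm(k, 0, spec@effectSizeSd), g)
    }
    if (is.null(causalBrood)) causalBrood <- drawBetas()
    if (is.null(causalElo)) causalElo <- drawBetas()
    if (!all(names(causalBrood) %in% genes) ||
        !all(names(causalElo) %in% genes))
        stop("causal gene absent from the expression matrix")

    zsafe <- function(x) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    latent <- function(betas, envBeta) {
        sig <- rep(0, n)
        for (g in names(betas)) sig <- sig + betas[[g]] * zsafe(cpm[g, ])
        sig <- sig + envBeta[1] * zsafe(design$parental_age) +
                     envBeta[2] * zsafe(design$early_temp)
        uj <- stats::rnorm(max(design$replicate), 0, spec@replicateSd)
        sig <- sig + uj[design$replicate]
        s2 <- max(0.05, 1 - sum(betas^2) - sum(envBeta^2) - spec@replicateSd^2)
        sig + stats::rnorm(n, 0, sqrt(s2))
    }
    lb <- latent(causalBrood, spec@envTraitBrood)
    le <- latent(causalElo, spec@envTraitElo)

    zb <- if (stats::sd(lb) > 0) (lb - mean(lb)) / stats::sd(lb) else lb
    brood <- pmax(0L, as.integer(round(110 + spec@traitSdBrood * zb)))
    ze <- if (stats::sd(le) > 0) (le - mean(le)) / stats::sd(le) else le
    elo <- as.integer(pmin(74, pmax(66, round(70 + 1.8 * ze))))

    cd <- SummarizedExperiment::colData(we)
    cd$early_brood <- brood
    cd$elo_hours <- elo
    SummarizedExperiment::colData(we) <- cd
    md <- S4Vectors::metadata(we)
    md$truth$causalBrood <- causalBrood
    md$truth$causalElo <- causalElo
    S4Vectors::metadata(we) <- md
    we
}

#' Simulate a per-site, per-worm base-count (pileup-like) table
#'
#' Per worm x site, depth is Poisson(`depthMean`); each read reports the
#' worm's true allele at the site (hom ref, a planted hom alt, or a planted
#' het at expected allele fraction 0.5) and is miscalled to a uniformly
#' chosen other base with probability `errorRate`.
#'
#' @param nWorms,nSites dimensions of the table.
#' @param depthMean mean sequencing depth per site.
#' @param errorRate per-read miscall probability, in [0, 0.1].
#' @param homSites,hetSites optional data.frames with columns `pos` and
#'   `worm` (integer worm index) marking planted homozygous-alternative and
#'   heterozygous sites.
#' @param homRate,hetRate alternatively, per-observation planting rates;
#'   planted positions are drawn at random.
#' @param seed integer RNG seed.
#' @return a `data.table` with columns worm_id, chrom, pos, depth, A, C, G, T,
#'   with attribute `"planted"` recording the planted variants.
#' @export
simulateSiteCalls <- function(nWorms, nSites, depthMean = 30, errorRate = 0,
                              homSites = NULL, hetSites = NULL,
                              homRate = 0, hetRate = 0, seed = 1) {
    stopifnot(errorRate >= 0, errorRate <= 0.1, depthMean > 0)
    set.seed(.stageSeed(seed, 4L))
    bases <- c("A", "C", "G", "T")
    refIdx <- sample.int(4, nSites, replace = TRUE)

    N <- nWorms * nSites
    worm <- rep(seq_len(nWorms), each = nSites)
    pos <- rep(seq_len(nSites), times = nWorms)

    pickPlanted <- function(df, rate) {
        if (!is.null(df)) return(df)
        k <- stats::rbinom(1, N, rate)
        if (k == 0) return(data.frame(pos = integer(), worm = integer()))
        i <- sample.int(N, k)
        data.frame(pos = (i - 1L) %% nSites + 1L,
                   worm = (i - 1L) %/% nSites + 1L)
    }
    homSites <- pickPlanted(homSites, homRate)
    hetSites <- pickPlanted(hetSites, hetRate)

    # genotype per observation: 0 = hom ref, 1 = hom alt, 2 = het ref/alt
    geno <- integer(N)
    obsIdx <- function(df) (df$worm - 1L) * nSites + df$pos
    geno[obsIdx(homSites)] <- 1L
    geno[obsIdx(hetSites)] <- 2L
    altIdx <- (refIdx %% 4L) + 1L       # deterministic alt base per site
    ref <- refIdx[pos]
    alt <- altIdx[pos]

    depth <- stats::rpois(N, depthMean)
    refReads <- depth
    altReads <- integer(N)
    het <- geno == 2L
    if (any(het)) {
        altReads[het] <- stats::rbinom(sum(het), depth[het], 0.5)
        refReads[het] <- depth[het] - altReads[het]
    }
    hom <- geno == 1L
    if (any(hom)) {
        altReads[hom] <- depth[hom]
        refReads[hom] <- 0L
    }
    # accumulate base counts as four vectors; each true read is miscalled to
    # one of the three other bases (uniformly) with probability errorRate
    cnt <- list(integer(N), integer(N), integer(N), integer(N))
    addReads <- function(nReads, baseIdx) {
        if (errorRate > 0) {
            nerr <- stats::rbinom(N, nReads, errorRate)
            good <- nReads - nerr
            e1 <- stats::rbinom(N, nerr, 1 / 3)
            e2 <- stats::rbinom(N, nerr - e1, 1 / 2)
            err <- list(e1, e2, nerr - e1 - e2)
        } else {
            good <- nReads
        }
        for (b in seq_len(4)) {
            sel <- (baseIdx == b)
            cnt[[b]] <<- cnt[[b]] + good * sel
            if (errorRate > 0) {
                o <- setdiff(seq_len(4), b)
                for (j in 1:3)
                    cnt[[o[j]]] <<- cnt[[o[j]]] + err[[j]] * sel
            }
        }
    }
    addReads(refReads, ref)
    addReads(altReads, alt)

    wormLabels <- sprintf("worm_%03d", seq_len(nWorms))
    out <- list(
        worm_id = wormLabels[worm],
        chrom = rep("I", N), pos = pos, depth = depth,
        A = cnt[[1]], C = cnt[[2]], G = cnt[[3]], T = cnt[[4]])
    data.table::setDT(out)
    planted <- list(
        hom = data.frame(pos = homSites$pos, worm = homSites$worm,
                         ref = bases[refIdx[homSites$pos]],
                         alt = bases[altIdx[homSites$pos]]),
        het = data.frame(pos = hetSites$pos, worm = hetSites$worm,
                         ref = bases[refIdx[hetSites$pos]],
                         alt = bases[altIdx[hetSites$pos]]))
    data.table::setattr(out, "planted", planted)
    out[]
}

#' Simulate a chromatin-domain / tissue annotation table
#'
#' Stands in for the published H3K27me3/H3K36me3 domain classification:
#' each gene is labeled `regulated` with probability `pRegulated`, otherwise
#' `active` (with a small `other` remainder), and `germline` with probability
#' `pGermline`, otherwise `soma`/`other`.  This synthetic table only mimics
#' the marginal label frequencies, not any biological coupling to expression.
#'
#' @param genes character vector of gene ids.
#' @param pRegulated probability a gene sits in a regulated (H3K27me3) domain.
#' @param pGermline probability a gene is germline-expressed.
#' @param pOther probability of the `other` label on each axis (default 0.1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `gene`, `domain`, `tissue`.
#' @export
simulateChromatinAnnotation <- function(genes, pRegulated = 0.35,
                                        pGermline = 0.4, pOther = 0.1,
                                        seed = 1) {
    stopifnot(pRegulated >= 0, pRegulated <= 1,
              pGermline >= 0, pGermline <= 1, pOther >= 0, pOther <= 1)
    set.seed(.stageSeed(seed, 5L))
    G <- length(genes)
    domain <- ifelse(stats::runif(G) < pRegulated, "regulated", "active")
    domain[stats::runif(G) < pOther] <- "other"
    if (pRegulated == 1) domain <- rep("regulated", G)
    tissue <- ifelse(stats::runif(G) < pGermline, "germline", "soma")
    tissue[stats::runif(G) < pOther] <- "other"
    data.frame(gene = genes, domain = domain, tissue = tissue,
               stringsAsFactors = FALSE)
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulateDesign()], [simulateExpression()],
#' [simulateTraits()] and [simulateChromatinAnnotation()], and attaching the
#' annotation to `rowData`.
#'
#' @param spec a [SimulationSpec-class].
#' @return a trait-filled, annotated [WormExperiment-class].
#' @examples
#' we <- simulateStudy(simulationSpec(nWorms = 30, nReplicates = 3,
#'                                    nGenes = 60, seed = 3))
#' @export
simulateStudy <- function(spec = simulationSpec()) {
    design <- simulateDesign(spec)
    we <- simulateExpression(design, spec)
    we <- simulateTraits(we, spec)
    ann <- simulateChromatinAnnotation(rownames(we), seed = spec@seed)
    rd <- SummarizedExperiment::rowData(we)
    rd$domain <- ann$domain
    rd$tissue <- ann$tissue
    SummarizedExperiment::rowData(we) <- rd
    we
}

# deterministic fan-out of a user seed into per-stage seeds (kept < 2^31)
.stageSeed <- function(seed, stage) {
    (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(stage)
}
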