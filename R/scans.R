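#' Per-gene trait-association scan
#'
#' For every gene in `geneSet`, fits the random-intercept LMM
#' `trait = b0 + b1 * expression + u_replicate + e` ([fitLmm()]) and tests
#' `b1` with a Wald t-test.  Genes are flagged significant under a
#' Bonferroni-corrected family-wise level `alpha` over the scanned gene
#' count, i.e. at nominal threshold `alpha / G` (for the study-scale family
#' of 8824 genes and alpha 0.05 this is 5.67e-6).
#'
#' @param x a CPM-normalized [WormExperiment-class].
#' @param trait `"early_brood"` or `"elo_hours"` (or any numeric colData
#'   column).
#' @param geneSet character vector or `GeneSetFilter`; defaults to all genes.
#' @param alpha family-wise significance level (default 0.05).
#' @param predictor `"cpm"` (default, the expression level as modelled) or
#'   `"logcpm"` (log2(CPM + 0.5)).
#' @param dfMethod passed to [fitLmm()].
#' @return data.frame of `GeneScanResult` rows: gene, estimate (raw slope),
#'   std_beta (slope * sd(x)/sd(y)), se, t, p, significant (p < alpha/G),
#'   sign (+1/-1), plus attributes `nominalThreshold` and `skipped`.
#' @export
scanTraitAssociations <- function(x, trait = c("early_brood", "elo_hours"),
                                  geneSet = NULL, alpha = 0.05,
                                  predictor = c("cpm", "logcpm"),
                                  dfMethod = "residual") {
    trait <- if (is.character(trait)) match.arg(trait, colnames(
        SummarizedExperiment::colData(x)), several.ok = FALSE) else trait
    predictor <- match.arg(predictor)
    ph <- phenotype(x)
    y <- ph[[trait]]
    if (any(is.na(y))) stop("trait '", trait, "' has missing values")
    if (inherits(geneSet, "GeneSetFilter")) geneSet <- geneSet$genes
    if (is.null(geneSet)) geneSet <- rownames(x)
    cpm <- cpmValues(x)[geneSet, , drop = FALSE]
    if (predictor == "logcpm") cpm <- log2(cpm + 0.5)
    gi <- as.integer(factor(ph$replicate))
    G <- max(gi)
    n <- length(y)
    nGenes <- length(geneSet)
    thr <- bonferroniThreshold(alpha, nGenes)
    df <- max(1, n - 2 - G)
    sdy <- stats::sd(y)

    sdx <- apply(cpm, 1, stats::sd)
    skipped <- geneSet[sdx == 0]
    use <- sdx > 0
    est <- se <- pv <- rep(NA_real_, nGenes)
    if (any(use)) {
        f <- .scanRanIntAll(y, cpm[use, , drop = FALSE], gi)
        est[use] <- f$slope
        se[use] <- f$se
        tv <- f$slope / f$se
        pv[use] <- if (identical(dfMethod, "normal"))
            2 * stats::pnorm(-abs(tv)) else 2 * stats::pt(-abs(tv), df)
    }
    ok <- !is.na(pv) & is.finite(est) & is.finite(se)
    res <- data.frame(
        gene = geneSet[ok], estimate = est[ok],
        std_beta = est[ok] * sdx[ok] / sdy, se = se[ok],
        t = est[ok] / se[ok], p = pv[ok],
        significant = pv[ok] < thr,
        sign = ifelse(est[ok] >= 0, 1L, -1L),
        stringsAsFactors = FALSE)
    attr(res, "nominalThreshold") <- thr
    attr(res, "alpha") <- alpha
    attr(res, "trait") <- trait
    attr(res, "skipped") <- skipped
    res
}

#' Per-gene negative-binomial environment scan
#'
#' For every gene in `geneSet`, fits a negative-binomial mixed model to the
#' raw counts with fixed effects parental age and early-life temperature, a
#' biological-replicate random intercept, a log library-size offset, and a
#' log link (via [glmmTMB::glmmTMB()], family `nbinom2`).  Each factor is
#' flagged under a Bonferroni correction over the scanned gene count.  The
#' residual ("unexplained") variance of each fit is recorded on the log10
#' scale — `var(log10((y + 0.5) / (mu_hat + 0.5)))` — for use by
#' [varianceZscores()].
#'
#' @param x a CPM-normalized [WormExperiment-class] (raw counts are used for
#'   fitting; CPM only for the reported mean expression level).
#' @param geneSet character vector or `GeneSetFilter` (typically the strict
#'   all-libraries CPM > 1 set); defaults to all genes.
#' @param alpha family-wise significance level.
#' @param offset logical; include the log library-size offset (default TRUE).
#' @return data.frame of `EnvDEResult` rows: gene, age_coef, age_p, temp_coef,
#'   temp_p, dispersion, unexplained_var, mean_cpm, sig_age, sig_temp,
#'   converged; attribute `skipped` lists non-converged genes.
#' @export
scanEnvironmentDE <- function(x, geneSet = NULL, alpha = 0.05, offset = TRUE) {
    if (inherits(geneSet, "GeneSetFilter")) geneSet <- geneSet$genes
    if (is.null(geneSet)) geneSet <- rownames(x)
    ph <- phenotype(x)
    cts <- counts(x)[geneSet, , drop = FALSE]
    cpm <- cpmValues(x)[geneSet, , drop = FALSE]
    off <- if (offset) log(libSizes(x)) else rep(0, ncol(x))
    dat <- data.frame(age = ph$parental_age, temp = ph$early_temp,
                      rep = factor(ph$replicate), off = off)
    nGenes <- length(geneSet)
    thr <- bonferroniThreshold(alpha, nGenes)

    one <- function(j) {
        yj <- cts[j, ]
        if (stats::var(yj) == 0) {
            # degenerate: no variation to model
            return(list(age_coef = 0, age_p = 1, temp_coef = 0, temp_p = 1,
                        dispersion = Inf, unexplained_var = 0,
                        converged = TRUE))
        }
        dat$y <- yj
        fit <- tryCatch(suppressWarnings(glmmTMB::glmmTMB(
            y ~ age + temp + (1 | rep) + offset(off),
            data = dat, family = glmmTMB::nbinom2())),
            error = function(e) NULL)
        if (is.null(fit) || !is.finite(stats::logLik(fit)))
            return(NULL)
        sm <- summary(fit)$coefficients$cond
        mu <- stats::fitted(fit)
        r <- log10((yj + 0.5) / (mu + 0.5))
        list(age_coef = sm["age", "Estimate"],
             age_p = sm["age", "Pr(>|z|)"],
             temp_coef = sm["temp", "Estimate"],
             temp_p = sm["temp", "Pr(>|z|)"],
             dispersion = stats::sigma(fit),
             unexplained_var = stats::var(r),
             converged = TRUE)
    }
    fits <- lapply(seq_len(nGenes), one)
    ok <- !vapply(fits, is.null, logical(1))
    skipped <- geneSet[!ok]
    fits <- fits[ok]
    res <- data.frame(
        gene = geneSet[ok],
        age_coef = vapply(fits, `[[`, numeric(1), "age_coef"),
        age_p = vapply(fits, `[[`, numeric(1), "age_p"),
        temp_coef = vapply(fits, `[[`, numeric(1), "temp_coef"),
        temp_p = vapply(fits, `[[`, numeric(1), "temp_p"),
        dispersion = vapply(fits, `[[`, numeric(1), "dispersion"),
        unexplained_var = vapply(fits, `[[`, numeric(1), "unexplained_var"),
        mean_cpm = rowMeans(cpm)[ok],
        stringsAsFactors = FALSE)
    res$sig_age <- res$age_p < thr
    res$sig_temp <- res$temp_p < thr
    attr(res, "nominalThreshold") <- thr
    attr(res, "skipped") <- skipped
    res
}

#' Variance Z-scores relative to the mean-variance trend
#'
#' Unexplained (residual) variance rises with expression level, so raw
#' variances cannot be compared across genes.  A loess curve of
#' log10(unexplained variance) on log10(mean CPM) models the trend, and each
#' gene's Z-score is its residual from the curve divided by the residual
#' standard deviation: genes far above the curve are unusually variable for
#' their expression level.
#'
#' @param envDE data.frame from [scanEnvironmentDE()] (needs
#'   `unexplained_var` and `mean_cpm`).
#' @param span loess span (default 0.75), `degree` 2.
#' @param degree loess polynomial degree.
#' @return data.frame: gene, log_mean_cpm, log_unexplained_var, fitted, z;
#'   genes with non-positive variance are excluded (attribute `excluded`).
#' @export
varianceZscores <- function(envDE, span = 0.75, degree = 2) {
    keep <- is.finite(envDE$unexplained_var) & envDE$unexplained_var > 0 &
        envDE$mean_cpm > 0
    excluded <- envDE$gene[!keep]
    d <- envDE[keep, ]
    if (nrow(d) < 50)
        stop("need at least 50 genes with positive unexplained variance")
    lx <- log10(d$mean_cpm)
    ly <- log10(d$unexplained_var)
    lo <- stats::loess(ly ~ lx, span = span, degree = degree)
    res <- ly - stats::fitted(lo)
    res <- res - mean(res)           # z-scores have mean zero by definition
    s <- stats::sd(res)
    z <- if (s > 1e-8 * max(1, stats::sd(ly))) res / s else rep(0, length(res))
    out <- data.frame(gene = d$gene, log_mean_cpm = lx,
                      log_unexplained_var = ly, fitted = stats::fitted(lo),
                      z = z, stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    out
}

#' RNAi knockdown effect test on early brood
#'
#' Mirrors the feeding-RNAi analysis: a random-intercept LMM of brood on
#' RNAi treatment (dummy-coded against the empty-vector control) with
#' biological replicate as the random effect; one contrast per treatment.
#' Treatments with fewer than 3 observations are excluded.
#'
#' @param brood numeric early-brood vector.
#' @param treatment character/factor RNAi treatment labels.
#' @param replicates biological replicate labels.
#' @param control control label (default `"ev"`, empty vector).
#' @return data.frame: treatment, estimate (difference from control), se, df,
#'   t, p; attribute `excluded` lists dropped treatments.
#' @export
rnaiEffectTest <- function(brood, treatment, replicates, control = "ev") {
    treatment <- as.character(treatment)
    if (!control %in% treatment) stop("control label '", control,
                                      "' not present")
    tab <- table(treatment)
    excluded <- names(tab)[tab < 3]
    keep <- !treatment %in% excluded
    brood <- brood[keep]; treatment <- treatment[keep]
    replicates <- replicates[keep]
    f <- stats::relevel(factor(treatment), ref = control)
    X <- stats::model.matrix(~f)
    colnames(X) <- sub("^f", "", colnames(X))
    fit <- fitLmm(brood, X, replicates)
    co <- fit$coefficients[-1, , drop = FALSE]
    out <- data.frame(treatment = co$term, estimate = co$estimate,
                      se = co$se, df = co$df, t = co$t, p = co$p,
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    attr(out, "fit") <- fit
    out
}
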