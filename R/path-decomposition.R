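#' Standardized-beta path decomposition for one gene
#'
#' Separates the total expression-to-trait effect from the part that
#' survives adjustment for historical environment by fitting three
#' random-intercept LMMs (replicate random intercept throughout):
#'
#' * Model 1: `trait = b0 + b1 * expression + u_j + e` — `beta1` is the
#'   total standardized effect of expression on the trait.
#' * Model 2: `trait = b0 + b2 * expression + b3 * age + b4 * temp + u_j + e`
#'   — `beta2` is the expression effect after controlling for parental age
#'   and early-life temperature (the "noise" component), `beta3`/`beta4` the
#'   direct environment effects on the trait.
#' * Expression model: `expression = b0 + b5 * age + b6 * temp + u_j + e`
#'   — `beta5`/`beta6` are the environment effects on expression.
#'
#' Every coefficient is standardized as `b * sd(x) / sd(y)` using sample
#' standard deviations, so a 1 SD change in the predictor corresponds to a
#' `beta` SD change in the response; the binary environment indicators are
#' standardized by their sample SDs too, making `beta3`--`beta6` comparable
#' across genes.  P-values come from the unstandardized fits.  Intercepts
#' are fitted but not reported.
#'
#' @param gene gene id.
#' @param x a CPM-normalized [WormExperiment-class] with traits.
#' @param trait `"early_brood"` or `"elo_hours"`.
#' @param predictor `"cpm"` or `"logcpm"`, as in [scanTraitAssociations()].
#' @return one-row data.frame: gene, beta1, p1, beta2, p2, beta3, p3, beta4,
#'   p4, beta5, p5, beta6, p6, degenerate (TRUE when a predictor is
#'   constant, in which case its betas are NA).
#' @export
decomposeGene <- function(gene, x, trait = c("early_brood", "elo_hours"),
                          predictor = c("cpm", "logcpm")) {
    trait <- match.arg(trait)
    predictor <- match.arg(predictor)
    if (!gene %in% rownames(x)) stop("gene '", gene, "' not in matrix")
    ph <- phenotype(x)
    y <- ph[[trait]]
    expr <- cpmValues(x)[gene, ]
    if (predictor == "logcpm") expr <- log2(expr + 0.5)
    age <- ph$parental_age
    temp <- ph$early_temp
    reps <- ph$replicate
    sds <- c(y = stats::sd(y), expr = stats::sd(expr),
             age = stats::sd(age), temp = stats::sd(temp))
    degenerate <- any(sds[c("expr", "age", "temp")] == 0) || sds["y"] == 0

    std <- function(b, sx, sy) if (is.na(b) || sx == 0 || sy == 0) NA_real_
                               else b * sx / sy
    get <- function(fit, term) {
        i <- match(term, fit$coefficients$term)
        if (is.null(fit) || is.na(i))
            return(c(b = NA_real_, p = NA_real_))
        c(b = fit$coefficients$estimate[i], p = fit$coefficients$p[i])
    }
    # constant predictors are dropped from the designs (their betas are NA)
    envCols <- list(age = age, temp = temp)
    envCols <- envCols[vapply(envCols, function(v) stats::sd(v) > 0,
                              logical(1))]
    m1 <- fitLmm(y, cbind(1, expr = expr), reps)
    m2 <- fitLmm(y, do.call(cbind, c(list(1, expr = expr), envCols)), reps)
    m3 <- if (length(envCols))
        fitLmm(expr, do.call(cbind, c(list(1), envCols)), reps) else NULL
    c1 <- get(m1, "expr"); c2 <- get(m2, "expr")
    c3 <- get(m2, "age");  c4 <- get(m2, "temp")
    c5 <- get(m3, "age");  c6 <- get(m3, "temp")
    data.frame(
        gene = gene,
        beta1 = std(c1["b"], sds["expr"], sds["y"]), p1 = unname(c1["p"]),
        beta2 = std(c2["b"], sds["expr"], sds["y"]), p2 = unname(c2["p"]),
        beta3 = std(c3["b"], sds["age"], sds["y"]),  p3 = unname(c3["p"]),
        beta4 = std(c4["b"], sds["temp"], sds["y"]), p4 = unname(c4["p"]),
        beta5 = std(c5["b"], sds["age"], sds["expr"]), p5 = unname(c5["p"]),
        beta6 = std(c6["b"], sds["temp"], sds["expr"]), p6 = unname(c6["p"]),
        degenerate = degenerate,
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Path decomposition over a gene set
#'
#' Applies [decomposeGene()] to each gene (typically the trait-significant
#' set from [scanTraitAssociations()]).  Genes whose expression is constant
#' are skipped.
#'
#' @inheritParams decomposeGene
#' @param genes character vector of gene ids.
#' @return data.frame with one row per gene (see [decomposeGene()]).
#' @export
decomposeGenes <- function(genes, x, trait = c("early_brood", "elo_hours"),
                           predictor = c("cpm", "logcpm")) {
    trait <- match.arg(trait)
    predictor <- match.arg(predictor)
    out <- do.call(rbind, lapply(genes, function(g)
        tryCatch(decomposeGene(g, x, trait, predictor),
                 error = function(e) NULL)))
    out
}

#' Classify genes into noise / parental-age / both groups
#'
#' Within the trait-significant set, genes are grouped by whether the
#' environment-adjusted expression effect (`beta2`) is significant and
#' whether parental age significantly affects their expression (from the
#' negative-binomial environment scan):
#'
#' * `noise`: `beta2` significant, parental-age DE not significant —
#'   expression noise independent of historical environment drives the
#'   association;
#' * `parental_age`: `beta2` not significant, parental-age DE significant —
#'   the association is routed through parental age;
#' * `both`: both significant; `neither`: neither.
#'
#' `beta2` significance is Bonferroni-corrected over the classified set
#' (the trait-significant genes) by default, or over `beta2Family` tests if
#' given; parental-age significance uses the `sig_age` flag already computed
#' by [scanEnvironmentDE()].  Genes missing from the environment scan are
#' labelled `neither` with a warning.
#'
#' @param pathCoefs data.frame from [decomposeGenes()].
#' @param envDE data.frame from [scanEnvironmentDE()].
#' @param alpha family-wise level for `beta2` (default 0.05).
#' @param beta2Family number of tests in the `beta2` family; defaults to
#'   `nrow(pathCoefs)`.
#' @return `pathCoefs` with added logical columns `sig_beta2`, `sig_age` and
#'   a `group` factor in \{noise, parental_age, both, neither\}.
#' @export
classifyGenes <- function(pathCoefs, envDE, alpha = 0.05,
                          beta2Family = NULL) {
    if (is.null(beta2Family)) beta2Family <- nrow(pathCoefs)
    thr <- bonferroniThreshold(alpha, beta2Family)
    sigB2 <- !is.na(pathCoefs$p2) & pathCoefs$p2 < thr
    i <- match(pathCoefs$gene, envDE$gene)
    sigAge <- envDE$sig_age[i]
    if (anyNA(sigAge)) {
        warning(sum(is.na(sigAge)),
                " gene(s) missing from the environment scan; labelled 'neither'")
        sigAge[is.na(sigAge)] <- FALSE
    }
    group <- ifelse(sigB2 & sigAge, "both",
             ifelse(sigB2, "noise",
             ifelse(sigAge, "parental_age", "neither")))
    pathCoefs$sig_beta2 <- sigB2
    pathCoefs$sig_age <- sigAge
    pathCoefs$group <- factor(group,
        levels = c("noise", "parental_age", "both", "neither"))
    pathCoefs
}

#' Convert a standardized effect to trait units
#'
#' A standardized beta times the trait's standard deviation gives the trait
#' change per 1 SD of expression: for early brood (SD 20.3) a beta of 0.39
#' is about 7.9 progeny and 0.26 about 5.3 progeny — roughly five to eight
#' progeny in the first day of egg-laying.
#'
#' @param beta standardized effect(s).
#' @param traitSd trait standard deviation (> 0).
#' @return `beta * traitSd`.
#' @examples
#' effectInTraitUnits(c(0.39, 0.26), 20.3)
#' @export
effectInTraitUnits <- function(beta, traitSd) {
    stopifnot(traitSd > 0)
    beta * traitSd
}
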