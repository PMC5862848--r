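# Feature counting and moderated-t enrichment analysis of probe vs control.
#
# The counting unit is the "feature": a distinct (peptide sequence,
# modification state, charge) triple observed in one sample. Counts are
# log2-CPM transformed with precision weights from the fitted
# mean-variance trend, then tested per protein with an empirical-Bayes
# moderated t-test; p-values are Benjamini-Hochberg adjusted.

#' Count features per protein and sample
#'
#' Features are unique peptide forms with a particular charge state:
#' distinct (sequence, modification set, charge) triples, counted per
#' protein per sample.
#'
#' @param psms data.frame with `protein_id`, `sequence`, `mods`, `charge`,
#'   `sample_id`, `condition`, `replicate`.
#' @return A `SummarizedExperiment` of protein x sample feature counts
#'   with `condition` and `replicate` in `colData`.
#' @export
countFeatures <- function(psms) {
    need <- c("protein_id", "sequence", "charge", "sample_id")
    stopifnot(all(need %in% names(psms)))
    mods <- if ("mods" %in% names(psms)) psms$mods else ""
    feat <- unique(data.frame(protein_id = psms$protein_id,
        sample_id = psms$sample_id,
        form = paste(psms$sequence, mods, psms$charge)))
    counts <- table(factor(feat$protein_id), factor(feat$sample_id))
    counts <- matrix(as.integer(counts), nrow = nrow(counts),
        dimnames = dimnames(counts))
    meta <- unique(psms[, intersect(c("sample_id", "condition",
        "replicate"), names(psms)), drop = FALSE])
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    featureCountMatrix(counts,
        condition = if ("condition" %in% names(meta)) meta$condition else
            rep(NA_character_, ncol(counts)),
        replicate = if ("replicate" %in% names(meta)) meta$replicate else
            rep(NA_character_, ncol(counts)))
}

#' Build a feature-count matrix
#'
#' @param counts integer matrix, proteins x samples.
#' @param condition per-sample condition labels (e.g. probe vs control).
#' @param replicate per-sample biological-replicate labels.
#' @return A `SummarizedExperiment` with assay `counts`.
#' @export
featureCountMatrix <- function(counts, condition, replicate) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    stopifnot(length(condition) == ncol(counts),
        length(replicate) == ncol(counts))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(condition = condition,
            replicate = replicate,
            row.names = colnames(counts)))
}

#' Discard sparsely observed proteins
#'
#' Proteins with fewer than `minTotal` features summed over all samples
#' carry too little information for the mean-variance trend and are
#' removed (default: fewer than three features in total).
#'
#' @param x SummarizedExperiment or counts matrix.
#' @param minTotal minimum row total retained.
#' @return Filtered object of the same class.
#' @export
filterMinFeatures <- function(x, minTotal = 3L) {
    stopifnot(minTotal >= 0)
    counts <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
    keep <- rowSums(counts) >= minTotal
    x[keep, , drop = FALSE]
}

# two-column design (intercept + condition indicator) from a condition
# factor; the control-like level is the reference
.conditionDesign <- function(condition) {
    condition <- as.character(condition)
    lev <- sort(unique(condition))
    if (length(lev) != 2L)
        stop("exactly two conditions required, got: ",
            paste(lev, collapse = ", "))
    ref <- if ("control" %in% lev) "control" else lev[1L]
    alt <- setdiff(lev, ref)
    if (min(table(condition)) < 2L)
        stop("each condition needs at least two samples")
    design <- cbind(`(Intercept)` = 1, ind = as.numeric(condition == alt))
    colnames(design)[2L] <- alt
    design
}

#' Precision-weighted log-count transform
#'
#' Transforms counts to log2 counts-per-million,
#' y = log2((c + 0.5) / (N + 1) * 1e6) with N the sample library size,
#' fits a per-protein linear model on the design, and estimates the
#' mean-variance trend by robust lowess of sqrt(residual sd) against
#' average log2 count. Each observation receives the precision weight
#' (predicted sqrt-sd at its fitted log-count)^-4, so downstream linear
#' modelling can treat the log-counts as approximately
#' variance-stabilized. Residual sd is floored at 1e-8 so proteins with
#' identical counts across samples do not degenerate the trend fit.
#'
#' @param x SummarizedExperiment (with `condition` in colData) or counts
#'   matrix.
#' @param design model matrix; defaults to intercept + condition when `x`
#'   is a SummarizedExperiment.
#' @param span lowess span for the trend (default 0.5).
#' @return list of class `"VoomTransform"`: `y` (log2-CPM), `weights`,
#'   `design`, `libSize`, `trend` (lowess points), `zeroVariance`
#'   (logical per protein).
#' @export
voomTransform <- function(x, design = NULL, span = 0.5) {
    counts <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (is.null(design)) {
        if (!is(x, "SummarizedExperiment"))
            stop("'design' required for a bare matrix")
        design <- .conditionDesign(SummarizedExperiment::colData(x)$condition)
    }
    n <- ncol(counts)
    p <- ncol(design)
    if (nrow(counts) < 2L) stop("need at least two proteins")
    if (n - p < 1L) stop("no residual degrees of freedom")
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("sample with empty library")
    y <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
    qrX <- qr(design)
    coef <- t(qr.coef(qrX, t(y)))
    res <- y - coef %*% t(design)
    sigma <- sqrt(rowSums(res^2) / (n - p))
    zeroVar <- sigma < 1e-8
    sigma[zeroVar] <- 1e-8
    amean <- rowMeans(y)
    sx <- amean + mean(log2(lib + 1)) - log2(1e6)
    sy <- sqrt(sigma)
    l <- stats::lowess(sx, sy, f = span)
    f <- stats::approxfun(l, rule = 2, ties = list("ordered", mean))
    fittedY <- coef %*% t(design)
    fittedLogCount <- t(t(fittedY) + log2(lib + 1)) - log2(1e6)
    w <- 1 / f(fittedLogCount)^4
    dim(w) <- dim(y)
    dimnames(w) <- dimnames(y)
    structure(list(y = y, weights = w, design = design, libSize = lib,
        trend = l, zeroVariance = zeroVar), class = "VoomTransform")
}

# Newton inversion of the trigamma function (solve trigamma(x) = y)
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (-dif / x < 1e-8) break
    }
    x
}

# moment-match the log residual variances to estimate the prior degrees
# of freedom d0 and prior variance s0^2 of the scaled-F variance model
.estimatePrior <- function(s2, df) {
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        warning("residual variances nearly equal; using the ",
            "common-variance limit (infinite prior df)")
        d0 <- Inf
        s02 <- exp(emean)
    }
    list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-tests
#'
#' Fits a weighted least-squares model per protein using the precision
#' weights, shrinks the residual variances toward a common prior by
#' empirical Bayes (prior df and variance estimated by moment-matching
#' the log residual variances via digamma/trigamma equations), and tests
#' the condition coefficient with a t-statistic on the augmented degrees
#' of freedom d0 + d.
#'
#' @param vt a [voomTransform()] result.
#' @param coef column of the design to test (default 2, the condition
#'   indicator).
#' @param priorDf optional fixed prior degrees of freedom overriding the
#'   empirical-Bayes estimate: 0 gives the ordinary per-protein weighted
#'   t-test, `Inf` the common-variance limit.
#' @param priorVar optional fixed prior variance (estimated when NULL).
#' @return data.frame of class `"ModeratedFit"` with one row per protein:
#'   `log2FC`, `s2` (residual variance), `s2_post` (posterior variance),
#'   `t`, `p`, `df_total`, `zero_variance`. Attributes `d0` and `s02`
#'   hold the prior.
#' @export
moderatedT <- function(vt, coef = 2L, priorDf = NULL, priorVar = NULL) {
    stopifnot(inherits(vt, "VoomTransform"))
    X <- vt$design
    n <- ncol(vt$y)
    p <- ncol(X)
    df <- n - p
    if (df < 1L) stop("no residual degrees of freedom")
    m <- nrow(vt$y)
    beta <- numeric(m); s2 <- numeric(m); u <- numeric(m)
    for (i in seq_len(m)) {
        w <- vt$weights[i, ]
        sw <- sqrt(w)
        Xw <- X * sw
        yw <- vt$y[i, ] * sw
        qrX <- qr(Xw)
        b <- qr.coef(qrX, yw)
        r <- yw - Xw %*% b
        beta[i] <- b[coef]
        s2[i] <- sum(r^2) / df
        XtX <- crossprod(Xw)
        u[i] <- sqrt(chol2inv(chol(XtX))[coef, coef])
    }
    zeroVar <- s2 < 1e-16
    if (all(zeroVar))
        stop("all residual variances are zero; cannot moderate")
    if (is.null(priorDf) || is.null(priorVar)) {
        prior <- if (is.null(priorDf) || priorDf > 0)
            .estimatePrior(pmax(s2, 1e-16), df) else
            list(d0 = 0, s02 = NA_real_)
        d0 <- if (is.null(priorDf)) prior$d0 else priorDf
        s02 <- if (is.null(priorVar)) prior$s02 else priorVar
    } else {
        d0 <- priorDf
        s02 <- priorVar
    }
    s2post <- if (!is.finite(d0)) rep(s02, m)
        else if (d0 == 0) s2
        else (d0 * s02 + df * s2) / (d0 + df)
    tstat <- beta / (u * sqrt(s2post))
    dfTotal <- min(d0 + df, m * df)
    pval <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    out <- data.frame(protein = rownames(vt$y), log2FC = beta, s2 = s2,
        s2_post = s2post, t = tstat, p = pval, df_total = dfTotal,
        zero_variance = vt$zeroVariance, stringsAsFactors = FALSE)
    attr(out, "d0") <- d0
    attr(out, "s02") <- s02
    class(out) <- c("ModeratedFit", "data.frame")
    out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p p-values in (0, 1].
#' @return q-values (step-up BH with monotonicity enforcement).
#' @export
bhAdjust <- function(p) {
    if (any(p <= 0 | p > 1 | is.na(p)))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Full enrichment analysis of a feature-count experiment
#'
#' Filters sparse proteins, applies the precision-weighted transform,
#' runs moderated t-tests of probe vs control, and BH-adjusts the
#' p-values.
#'
#' @param se SummarizedExperiment from [countFeatures()] /
#'   [featureCountMatrix()].
#' @param minTotal minimum total features per protein (default 3).
#' @return data.frame with `protein`, `log2FC`, `t`, `p`, `q`,
#'   `mean_feature_count`.
#' @export
enrichmentAnalysis <- function(se, minTotal = 3L) {
    se <- filterMinFeatures(se, minTotal)
    vt <- voomTransform(se)
    fit <- moderatedT(vt)
    counts <- SummarizedExperiment::assay(se, "counts")
    data.frame(protein = fit$protein, log2FC = fit$log2FC, t = fit$t,
        p = fit$p, q = bhAdjust(fit$p),
        mean_feature_count = rowMeans(counts),
        stringsAsFactors = FALSE)
}

#' Volcano-plot table
#'
#' @param results data.frame from [enrichmentAnalysis()].
#' @return The same rows with `neg_log10_p` added, stably sorted by `q`
#'   then decreasing absolute log2 fold change.
#' @export
volcanoTable <- function(results) {
    out <- results
    out$neg_log10_p <- -log10(out$p)
    out <- out[order(out$q, -abs(out$log2FC)), , drop = FALSE]
    rownames(out) <- NULL
    out
}
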