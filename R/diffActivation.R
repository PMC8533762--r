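#' Differential-activation settings
#'
#' @param nBootstrap Bootstrap iterations over the random normal-sample
#'   assignment (50).
#' @param alpha Significance level on the combined p-value (0.05).
#' @param concordanceMin Minimum fraction of iterations agreeing with the
#'   majority fold-change sign (0.70).
#' @param logit Model activities on the logit scale (they live in (0,1));
#'   \code{FALSE} fits on the raw activity scale.
#' @param shrink Apply empirical-Bayes variance shrinkage.
#' @param combineRaw Combine the raw per-iteration p-values and BH-adjust
#'   the combined values afterwards, instead of the default (combine the
#'   per-iteration BH-adjusted p-values and compare directly to alpha).
#' @return A list of class \code{"DiffConfig"}.
#' @export
diffConfig <- function(nBootstrap = 50L, alpha = 0.05, concordanceMin = 0.70,
                       logit = TRUE, shrink = TRUE, combineRaw = FALSE) {
    stopifnot(nBootstrap >= 1L, alpha > 0, alpha < 1,
              concordanceMin > 0, concordanceMin <= 1)
    structure(list(nBootstrap = as.integer(nBootstrap), alpha = alpha,
                   concordanceMin = concordanceMin, logit = logit,
                   shrink = shrink, combineRaw = combineRaw),
              class = "DiffConfig")
}

## Invert the trigamma function by Newton iteration (monotone decreasing on
## the positive axis, so the iteration is globally convergent from the
## asymptotic start 0.5 + 1/y).
.trigammaInverse <- function(y) {
    vapply(y, function(yi) {
        if (yi > 1e7) return(1 / sqrt(yi))
        if (yi < 1e-6) return(1 / yi)
        x <- 0.5 + 1 / yi
        for (iter in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
            x <- x + dif
            if (abs(dif / x) < 1e-8) break
        }
        x
    }, 0)
}

## Empirical-Bayes estimation of the variance prior (d0, s0^2) by moment
## matching on log residual variances: log s^2 is log sigma^2 plus a
## log chi^2_d/d term with known digamma mean and trigamma variance, and the
## prior contributes a matching log inverse-chi^2_d0 term.
.estimatePrior <- function(s2, d) {
    stopifnot(all(s2 > 0))
    z <- log(s2)
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.na(evar) || evar <= 0)  # no excess dispersion: plain pooling
        return(list(d0 = Inf, s02 = mean(s2)))
    d0 <- 2 * .trigammaInverse(evar)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated two-group t-statistics for circuit activities
#'
#' Per circuit, an ordinary two-group comparison (difference of means,
#' pooled residual variance with d = n1 + n2 - 2 degrees of freedom) whose
#' residual variance is shrunk toward an empirical-Bayes prior:
#' \eqn{s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)}, with \eqn{(d_0, s_0^2)}
#' estimated by closed-form moment matching on the log residual variances.
#' The moderated t is the mean difference over its posterior standard error
#' and is referred to a t distribution with \eqn{d + d_0} degrees of
#' freedom. With \code{shrink = FALSE} (or in the \eqn{d_0 \to 0} limit)
#' this is exactly the classical pooled two-sample t-test. Activities are
#' logit-transformed before fitting by default.
#'
#' @param object An \linkS4class{ActivityDataset} or a features x samples
#'   matrix.
#' @param groups Group labels (taken from the dataset when omitted); exactly
#'   two distinct labels, each with at least two samples. The log
#'   fold change is second level minus first, in the order given by
#'   \code{comparison} (or sorted unique labels).
#' @param comparison Optional length-2 character giving reference and test
#'   group.
#' @param shrink,logit See [diffConfig()].
#' @return data.frame: circuit_id, logFC, t, p, df; the estimated prior is
#'   attached as attribute \code{"prior"} (list d0, s02).
#' @export
moderatedT <- function(object, groups = NULL, comparison = NULL,
                       shrink = TRUE, logit = TRUE) {
    a <- if (is(object, "ActivityDataset")) activityValues(object) else object
    if (is.null(groups)) {
        stopifnot(is(object, "ActivityDataset"))
        groups <- groupLabels(object)
    }
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(a))
    lv <- if (is.null(comparison)) sort(unique(groups)) else comparison
    stopifnot(length(lv) == 2L, all(groups %in% lv))
    i1 <- groups == lv[1L]; i2 <- groups == lv[2L]
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 < 2L || n2 < 2L) stop("need at least two samples per group")
    d <- n1 + n2 - 2L
    y <- if (logit) stats::qlogis(a) else a
    m1 <- rowMeans(y[, i1, drop = FALSE])
    m2 <- rowMeans(y[, i2, drop = FALSE])
    ss1 <- rowSums((y[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((y[, i2, drop = FALSE] - m2)^2)
    s2 <- (ss1 + ss2) / d
    logFC <- m2 - m1
    if (shrink) {
        if (any(s2 <= 0)) {
            floorv <- min(s2[s2 > 0], 1e-12)
            warning(sum(s2 <= 0), " zero residual variance(s) floored for ",
                    "prior estimation")
            s2 <- pmax(s2, floorv)
        }
        prior <- .estimatePrior(s2, d)
        d0 <- prior$d0
        s2post <- if (is.infinite(d0)) rep(prior$s02, length(s2))
                  else (d0 * prior$s02 + d * s2) / (d0 + d)
    } else {
        prior <- list(d0 = 0, s02 = NA_real_)
        d0 <- 0
        s2post <- s2
    }
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    tstat <- logFC / se
    # total df capped at the pooled residual df across circuits
    dfTotal <- min(d + d0, length(s2) * d)
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    out <- data.frame(circuit_id = rownames(a), logFC = logFC, t = tstat,
                      p = p, df = dfTotal, row.names = rownames(a))
    attr(out, "prior") <- prior
    attr(out, "comparison") <- lv
    out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment \code{p.adjust(p, "BH")}: monotone in the raw
#' p-values and idempotent on its own output.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Fisher's p-value combination
#'
#' \eqn{X = -2 \sum \ln p_b} referred to the upper tail of a chi-square
#' distribution with 2k degrees of freedom. Exact zeros are floored at
#' 1e-300 with a warning. Note the chi-square reference assumes independent
#' p-values; bootstrap iterations over a shared cohort are positively
#' dependent, so downstream combined values are approximate.
#'
#' @param p Numeric vector of k p-values in \[0, 1\].
#' @return Combined p-value.
#' @examples
#' fisherCombine(c(0.1, 0.1))  # X = 9.21, chi-square(4) tail ~ 0.056
#' @export
fisherCombine <- function(p) {
    stopifnot(length(p) >= 1L, all(p >= 0 & p <= 1))
    if (any(p == 0)) {
        warning("zero p-value(s) floored at 1e-300")
        p <- pmax(p, 1e-300)
    }
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

## Collapse per-iteration adjusted p-values and fold-change signs into the
## per-circuit selection summary.
.summariseBootstrap <- function(padj, sgn, logFC, tstat, config) {
    B <- ncol(padj)
    combined <- apply(padj, 1L, fisherCombine)
    up <- rowSums(sgn > 0)
    down <- rowSums(sgn < 0)
    direction <- ifelse(up >= down, "up", "down")
    concordance <- pmax(up, down) / B
    if (config$combineRaw) combined <- bhAdjust(combined)
    selected <- combined < config$alpha &
        concordance >= config$concordanceMin
    data.frame(logFC = rowMeans(logFC), t = rowMeans(tstat),
               combined_p = combined, concordance = concordance,
               direction = direction, selected = selected)
}

#' Bootstrap differential circuit activation
#'
#' Repeats the whole sample-assignment + knockdown + propagation +
#' moderated-t pipeline \code{nBootstrap} times with fresh random
#' normal-sample draws. Per circuit, the per-iteration BH-adjusted p-values
#' are pooled with [fisherCombine()], the fold-change sign concordance is
#' the fraction of iterations agreeing with the majority sign, and a
#' circuit is selected when the combined p-value is below \code{alpha} and
#' the concordance reaches \code{concordanceMin}. Direction \code{"up"}
#' means higher activity in the second group of \code{comparison}.
#'
#' A comparison against \code{"normal"} draws as many unperturbed normal
#' profiles as there are tumors in the other group (equal group sizes).
#'
#' @param cohort A \linkS4class{GeneStatusMatrix}.
#' @param expr Raw genes x samples normal-tissue expression matrix.
#' @param graphs List of \linkS4class{PathwayGraph} or \linkS4class{Circuit}
#'   objects.
#' @param comparison Length-2 character: reference then test group, e.g.
#'   \code{c("nevogenic", "CSD")} or \code{c("normal", "CSD")}.
#' @param config A [diffConfig()].
#' @param kdConfig A [knockdownConfig()].
#' @param lofGenes Optional LoF gene set.
#' @param seed Integer seed; the whole bootstrap consumes one RNG stream.
#' @return data.frame, one row per circuit: circuit_id, pathway_id, logFC
#'   (mean over iterations), t (mean), combined_p, concordance, direction,
#'   selected. Attribute \code{"note"} records the approximate nature of
#'   the chi-square reference under bootstrap dependence.
#' @export
bootstrapDiff <- function(cohort, expr, graphs,
                          comparison = c("nevogenic", "CSD"),
                          config = diffConfig(),
                          kdConfig = knockdownConfig(), lofGenes = NULL,
                          seed = NULL) {
    stopifnot(length(comparison) == 2L)
    circuits <- if (length(graphs) && is(graphs[[1L]], "Circuit")) graphs
                else unlist(lapply(graphs, decomposeCircuits))
    if (!length(circuits)) stop("no circuits to test")
    realGroups <- setdiff(comparison, "normal")
    nNormal <- if ("normal" %in% comparison) {
        grp <- as.character(patientInfo(cohort)$group)
        sum(grp %in% realGroups)
    } else 0L
    B <- config$nBootstrap
    nC <- length(circuits)
    padj <- sgn <- lfc <- tst <- matrix(NA_real_, nC, B)
    withSeed(seed, {
        for (b in seq_len(B)) {
            ds <- buildGroupDataset(cohort, expr, circuits,
                                    groups = realGroups, nNormal = nNormal,
                                    config = kdConfig, lofGenes = lofGenes,
                                    seed = NULL)
            mt <- moderatedT(ds, comparison = comparison,
                             shrink = config$shrink, logit = config$logit)
            padj[, b] <- bhAdjust(mt$p)
            sgn[, b] <- sign(mt$logFC)
            lfc[, b] <- mt$logFC
            tst[, b] <- mt$t
        }
    })
    res <- .summariseBootstrap(padj, sgn, lfc, tst, config)
    out <- cbind(data.frame(circuit_id = vapply(circuits, slot, "", "circuitId"),
                            pathway_id = vapply(circuits, slot, "", "pathwayId")),
                 res)
    rownames(out) <- out$circuit_id
    attr(out, "note") <- paste("combined p-values use a chi-square reference",
                               "that is approximate under bootstrap",
                               "dependence (shared cohort)")
    attr(out, "comparison") <- comparison
    out
}
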