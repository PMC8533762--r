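#' Two-sided exact association test for a 2x2 table
#'
#' Tests mutation-by-group association in a 2x2 table laid out as rows
#' mutated/wild-type, columns nevogenic/CSD. The two-sided p-value uses the
#' probability-mass convention (sum of hypergeometric probabilities of all
#' tables with the observed margins no more probable than the observed one),
#' as computed by \code{stats::fisher.test}; the odds ratio is the sample
#' cross-product ratio \eqn{ad/bc}, not the conditional MLE. A table with an
#' empty margin carries no information and returns p = 1 flagged degenerate.
#' A chi-square variant (\code{stats::chisq.test}, no continuity correction)
#' is available behind \code{test = "chisq"}.
#'
#' @param a,b Mutated and wild-type counts in the nevogenic group.
#' @param c,d Mutated and wild-type counts in the CSD group.
#' @param test \code{"fisher"} (default) or \code{"chisq"}.
#' @return One-row data.frame: p_value, odds_ratio, test, degenerate.
#' @examples
#' fisherExact2x2(1, 81, 4, 33)  # GNA11-like table, p ~ 0.032
#' @export
fisherExact2x2 <- function(a, b, c, d, test = c("fisher", "chisq")) {
    test <- match.arg(test)
    x <- c(a, b, c, d)
    stopifnot(length(x) == 4L, all(x >= 0), all(x == round(x)))
    m <- matrix(as.integer(x), 2L, 2L,
                dimnames = list(status = c("mutated", "WT"),
                                group = c("nevogenic", "CSD")))
    degenerate <- any(rowSums(m) == 0L) || any(colSums(m) == 0L)
    orr <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c)
    p <- if (degenerate) 1 else if (test == "fisher")
        stats::fisher.test(m)$p.value
    else
        suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    data.frame(p_value = p, odds_ratio = orr,
               test = if (test == "fisher") "fisher.exact.two.sided"
                      else "chi.square",
               degenerate = degenerate)
}

#' Per-gene mutation prevalence by etiopathogenic group
#'
#' For each gene: mutated counts and percentages overall and within each
#' group, denominators restricted to informative (non-NA) tumors, plus the
#' two-sided exact p-value for the group comparison. Percentages are rounded
#' half-up to one decimal, the table's display convention.
#'
#' @param object A \linkS4class{GeneStatusMatrix} whose patient metadata has
#'   a \code{group} column, or a status matrix with \code{groups} supplied.
#' @param groups Optional group labels (values \code{"nevogenic"} /
#'   \code{"CSD"}), overriding the metadata.
#' @param test Passed to [fisherExact2x2()].
#' @return data.frame, one row per gene: n_mut, pct, n_inf, and the same
#'   within each group, with p_value.
#' @export
prevalenceTable <- function(object, groups = NULL, test = "fisher") {
    m <- if (is(object, "GeneStatusMatrix")) mutationStatus(object) else object
    if (is.null(groups)) {
        stopifnot(is(object, "GeneStatusMatrix"),
                  "group" %in% colnames(patientInfo(object)))
        groups <- patientInfo(object)$group
    }
    stopifnot(length(groups) == nrow(m))
    isNev <- groups == "nevogenic"
    isCsd <- groups == "CSD"
    one <- function(g) {
        x <- m[, g]
        inf <- !is.na(x)
        nm <- sum(x == 1L, na.rm = TRUE)
        nmN <- sum(x == 1L & isNev, na.rm = TRUE)
        nmC <- sum(x == 1L & isCsd, na.rm = TRUE)
        niN <- sum(inf & isNev); niC <- sum(inf & isCsd)
        tst <- fisherExact2x2(nmN, niN - nmN, nmC, niC - nmC, test = test)
        data.frame(gene = g, n_mut = nm, n_inf = sum(inf),
                   pct = roundHalfUp(100 * nm / sum(inf)),
                   n_mut_nev = nmN, n_inf_nev = niN,
                   pct_nev = roundHalfUp(100 * nmN / niN),
                   n_mut_csd = nmC, n_inf_csd = niC,
                   pct_csd = roundHalfUp(100 * nmC / niC),
                   p_value = tst$p_value, odds_ratio = tst$odds_ratio)
    }
    out <- do.call(rbind, lapply(colnames(m), one))
    rownames(out) <- out$gene
    out
}

#' Long, display-shaped prevalence table
#'
#' Two rows per gene (Mutated / WT) with reconciled percentages (the WT
#' percentage is 100 minus the rounded mutated percentage, so each pair sums
#' to exactly 100.0 after rounding) and formatted p-values.
#'
#' @inheritParams prevalenceTable
#' @return data.frame: gene, status, n, pct, n_nev, pct_nev, n_csd, pct_csd,
#'   p_value.
#' @export
prevalenceTableLong <- function(object, groups = NULL, test = "fisher") {
    w <- prevalenceTable(object, groups = groups, test = test)
    rows <- lapply(seq_len(nrow(w)), function(i) {
        x <- w[i, ]
        data.frame(gene = x$gene, status = c("Mutated", "WT"),
                   n = c(x$n_mut, x$n_inf - x$n_mut),
                   pct = c(x$pct, 100 - x$pct),
                   n_nev = c(x$n_mut_nev, x$n_inf_nev - x$n_mut_nev),
                   pct_nev = c(x$pct_nev, 100 - x$pct_nev),
                   n_csd = c(x$n_mut_csd, x$n_inf_csd - x$n_mut_csd),
                   pct_csd = c(x$pct_csd, 100 - x$pct_csd),
                   p_value = c(formatPValue(x$p_value), ""))
    })
    do.call(rbind, rows)
}

.glmBinomial <- function(y, X) {
    df <- data.frame(.y = y, X, check.names = FALSE)
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                control = stats::glm.control(epsilon = 1e-8,
                                                             maxit = 50L)))
}

.separationCut <- 15

#' Univariate logistic regression of group on gene status
#'
#' Maximum-likelihood fit of logit P(CSD) = b0 + b1 x, reporting the odds
#' ratio exp(b1) and its Wald p-value. Complete or quasi-complete separation
#' (diverging coefficient, |b1| > 15, or non-convergence) is detected and
#' flagged instead of reporting a spurious estimate.
#'
#' @param y Group labels: a factor/character vector (second level, or
#'   \code{"CSD"}, is the event) or a 0/1 vector.
#' @param x Binary (or numeric) predictor.
#' @return One-row data.frame: estimate, odds_ratio, p_value, separation.
#' @export
logisticUnivariate <- function(y, x) {
    yb <- .binaryResponse(y)
    stopifnot(length(unique(yb)) == 2L)
    fit <- .glmBinomial(yb, data.frame(x = x))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || abs(co["x", "Estimate"]) > .separationCut
    if (sep)
        return(data.frame(estimate = NA_real_, odds_ratio = NA_real_,
                          p_value = NA_real_, separation = TRUE))
    data.frame(estimate = co["x", "Estimate"],
               odds_ratio = exp(co["x", "Estimate"]),
               p_value = co["x", "Pr(>|z|)"], separation = FALSE)
}

.binaryResponse <- function(y) {
    if (is.numeric(y) || is.logical(y)) {
        stopifnot(all(y %in% c(0, 1)))
        return(as.integer(y))
    }
    y <- as.character(y)
    lv <- if (all(y %in% c("nevogenic", "CSD"))) c("nevogenic", "CSD")
          else sort(unique(y))
    stopifnot(length(lv) == 2L)
    as.integer(y == lv[2L])
}

#' Adjusted (joint) logistic regression over several genes
#'
#' Joint maximum-likelihood fit of group on all supplied columns, reporting
#' per-gene adjusted odds ratios and Wald p-values. Duplicated or collinear
#' columns raise an error naming the offending columns; per-coefficient
#' separation is flagged as in [logisticUnivariate()].
#'
#' @param y Group labels (see [logisticUnivariate()]).
#' @param X Matrix or data.frame of predictor columns.
#' @return data.frame, one row per predictor: estimate, odds_ratio, p_value,
#'   separation.
#' @export
logisticAdjusted <- function(y, X) {
    X <- as.data.frame(X)
    stopifnot(ncol(X) >= 1L)
    yb <- .binaryResponse(y)
    dup <- duplicated(as.list(X))
    if (any(dup))
        stop("duplicated predictor column(s): ",
             paste(names(X)[dup], collapse = ", "))
    mm <- cbind(1, as.matrix(X))
    qrd <- qr(mm)
    if (qrd$rank < ncol(mm)) {
        bad <- colnames(mm)[qrd$pivot[-seq_len(qrd$rank)]]
        stop("collinear predictor column(s): ", paste(bad, collapse = ", "))
    }
    fit <- .glmBinomial(yb, X)
    co <- summary(fit)$coefficients
    terms <- rownames(co)[-1L]
    est <- co[terms, "Estimate"]
    sep <- !fit$converged | abs(est) > .separationCut
    out <- data.frame(term = names(X),
                      estimate = ifelse(sep, NA_real_, est),
                      odds_ratio = ifelse(sep, NA_real_, exp(est)),
                      p_value = ifelse(sep, NA_real_, co[terms, "Pr(>|z|)"]),
                      separation = sep, row.names = NULL)
    out
}
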