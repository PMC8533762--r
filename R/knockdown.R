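#' In-silico knockdown settings
#'
#' A knockdown multiplies a mutated gene's raw expression by \code{factor}
#' (0.01 by default, i.e. a 100-fold loss of expression). By default every
#' mutated panel gene in a profile is knocked down, treating all retained
#' pathogenic mutations as loss of function; \code{lofOnly = TRUE} restricts
#' the perturbation to genes flagged as LoF.
#'
#' @param factor Multiplier in (0, 1]; 1 is a degenerate no-op config.
#' @param lofOnly Restrict knockdowns to LoF-flagged genes.
#' @return A list of class \code{"KnockdownConfig"}.
#' @export
knockdownConfig <- function(factor = 0.01, lofOnly = FALSE) {
    stopifnot(is.numeric(factor), length(factor) == 1L,
              factor > 0, factor <= 1)
    structure(list(factor = factor, lofOnly = lofOnly),
              class = "KnockdownConfig")
}

#' Apply an in-silico knockdown to an expression profile
#'
#' Multiplies the expression of each mutated gene by the knockdown factor,
#' leaving all other genes untouched. Operates on the raw (pre-rescaling)
#' scale.
#'
#' @param expr Named numeric vector (one sample's raw expression).
#' @param mutatedGenes Character vector of genes mutated in the profile.
#' @param config A [knockdownConfig()].
#' @param lofGenes With \code{lofOnly}, the genes whose mutations are LoF.
#' @return The perturbed expression vector.
#' @examples
#' applyKnockdown(c(NF1 = 10, BRAF = 5), "NF1")
#' @export
applyKnockdown <- function(expr, mutatedGenes, config = knockdownConfig(),
                           lofGenes = NULL) {
    if (config$lofOnly) mutatedGenes <- intersect(mutatedGenes, lofGenes)
    if (!length(mutatedGenes)) return(expr)
    missing <- setdiff(mutatedGenes, names(expr))
    if (length(missing))
        stop("mutated gene(s) absent from the expression profile: ",
             paste(missing, collapse = ", "))
    expr[mutatedGenes] <- expr[mutatedGenes] * config$factor
    expr
}

#' Assemble a group-labelled circuit-activity dataset
#'
#' One pipeline pass: for each tumor in the requested groups, one
#' normal-tissue sample is drawn (with replacement) from the expression
#' matrix and the tumor's mutated genes are knocked down on it; optionally
#' \code{nNormal} additional unperturbed normal draws are appended with
#' group label \code{"normal"}. The assembled perturbed matrix is then
#' rank-rescaled jointly (perturbation first, rescaling second — order
#' matters) and propagated through every circuit.
#'
#' @param cohort A \linkS4class{GeneStatusMatrix} with a \code{group}
#'   metadata column.
#' @param expr Raw genes x samples normal-tissue expression matrix; must
#'   contain every panel gene that can be knocked down.
#' @param graphs List of \linkS4class{PathwayGraph} or \linkS4class{Circuit}
#'   objects.
#' @param groups Which etiopathogenic groups to include.
#' @param nNormal Number of unperturbed normal profiles to append.
#' @param config A [knockdownConfig()].
#' @param lofGenes Optional LoF gene set (used when \code{config$lofOnly}).
#' @param seed Optional seed; with \code{NULL} the current RNG stream is
#'   consumed (used by the bootstrap).
#' @return An \linkS4class{ActivityDataset}.
#' @export
buildGroupDataset <- function(cohort, expr, graphs,
                              groups = c("nevogenic", "CSD"), nNormal = 0L,
                              config = knockdownConfig(), lofGenes = NULL,
                              seed = NULL) {
    stopifnot(is(cohort, "GeneStatusMatrix"), ncol(expr) >= 1L)
    grp <- as.character(patientInfo(cohort)$group)
    keep <- grp %in% groups
    if (!any(keep) && nNormal == 0L)
        stop("no tumors in the requested group(s) and nNormal = 0")
    status <- mutationStatus(cohort)[keep, , drop = FALSE]
    labels <- grp[keep]
    withSeed(seed, {
        nTum <- nrow(status)
        draw <- sample.int(ncol(expr), nTum + nNormal, replace = TRUE)
        cols <- lapply(seq_len(nTum), function(i) {
            mut <- colnames(status)[which(status[i, ] == 1L)]
            applyKnockdown(expr[, draw[i]], mut, config, lofGenes)
        })
        if (nNormal > 0L)
            cols <- c(cols, lapply(nTum + seq_len(nNormal),
                                   function(i) expr[, draw[i]]))
        perturbed <- do.call(cbind, cols)
        colnames(perturbed) <- make.unique(
            c(rownames(status), rep("normal", nNormal)), sep = "_")
        rescaled <- rankRescale(perturbed)
        activityMatrix(graphs, rescaled,
                       c(labels, rep("normal", nNormal)))
    })
}
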