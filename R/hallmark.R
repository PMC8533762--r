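#' The canonical cancer-hallmark vocabulary
#'
#' Reference names of the ten acquired capabilities of tumors used as the
#' default annotation vocabulary; hallmark names elsewhere in the package are
#' free strings.
#'
#' @format Character vector of ten hallmark names.
#' @export
cancerHallmarks <- c("sustaining proliferative signaling",
                     "evading growth suppressors",
                     "resisting cell death",
                     "enabling replicative immortality",
                     "inducing angiogenesis",
                     "activating invasion and metastasis",
                     "genome instability and mutation",
                     "tumor-promoting inflammation",
                     "deregulating cellular energetics",
                     "avoiding immune destruction")

#' Hallmark annotation settings
#'
#' Text-mining hallmark scores are thresholded at 0.18, the ninetieth
#' percentile of the score distribution in the reference data; with
#' \code{percentile = TRUE} the threshold is recomputed as the 90th
#' percentile of the supplied scores (for synthetic score tables whose scale
#' differs).
#'
#' @param threshold Fixed score threshold (strictly exceeded to annotate).
#' @param percentile Recompute the threshold as the 90th percentile.
#' @return A list of class \code{"HallmarkConfig"}.
#' @export
hallmarkConfig <- function(threshold = 0.18, percentile = FALSE) {
    stopifnot(threshold >= 0)
    structure(list(threshold = threshold, percentile = percentile),
              class = "HallmarkConfig")
}

.checkScoreTable <- function(scores) {
    stopifnot(all(c("circuit_id", "hallmark", "score") %in% names(scores)))
    if (nrow(scores)) {
        stopifnot(all(is.finite(scores$score)), all(scores$score >= 0))
        if (anyDuplicated(scores[, c("circuit_id", "hallmark")]))
            stop("duplicated (circuit_id, hallmark) rows in the score table")
    }
    invisible(scores)
}

#' Threshold hallmark annotation scores
#'
#' Keeps (circuit, hallmark) rows whose score strictly exceeds the
#' threshold (a score exactly at the threshold is excluded) and returns the
#' circuit-to-hallmark annotation map.
#'
#' @param scores data.frame with columns circuit_id, hallmark, score
#'   (unique (circuit, hallmark) keys, finite non-negative scores).
#' @param config A [hallmarkConfig()].
#' @return Named list mapping circuit ids to character vectors of hallmark
#'   names; the threshold actually used is in attribute
#'   \code{"threshold"}.
#' @export
thresholdAnnotations <- function(scores, config = hallmarkConfig()) {
    .checkScoreTable(scores)
    thr <- if (config$percentile)
        stats::quantile(scores$score, 0.9, names = FALSE)
    else config$threshold
    kept <- scores[scores$score > thr, , drop = FALSE]
    out <- lapply(split(as.character(kept$hallmark), kept$circuit_id), unique)
    attr(out, "threshold") <- thr
    out
}

#' Per-hallmark dysregulated-circuit counts and ratios
#'
#' For each group and hallmark: the number of selected (significantly
#' dysregulated) circuits annotated to the hallmark, the total number of
#' annotated circuits, and two ratios — over the annotated circuits
#' (\code{ratio}) and over the group's selected circuits
#' (\code{ratio_selected}); the radar-plot table.
#'
#' @param selected Named list: group -> character vector of selected circuit
#'   ids.
#' @param annotations Circuit-to-hallmark map from [thresholdAnnotations()].
#' @return data.frame: hallmark, group, count, annotated, ratio,
#'   ratio_selected.
#' @export
hallmarkCounts <- function(selected, annotations) {
    stopifnot(is.list(selected), !is.null(names(selected)))
    hallmarks <- sort(unique(unlist(annotations)))
    annTot <- vapply(hallmarks, function(h)
        sum(vapply(annotations, function(a) h %in% a, TRUE)), 0L)
    rows <- lapply(names(selected), function(g) {
        sel <- selected[[g]]
        cnt <- vapply(hallmarks, function(h)
            sum(vapply(sel, function(cc)
                h %in% annotations[[cc]], TRUE)), 0L)
        data.frame(hallmark = hallmarks, group = g, count = cnt,
                   annotated = annTot,
                   ratio = ifelse(annTot > 0, cnt / annTot, 0),
                   ratio_selected = if (length(sel)) cnt / length(sel) else 0,
                   row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Pathway-level combined significance
#'
#' Fisher-combines the per-circuit p-values of each pathway's independent
#' circuits into one pathway-level dysregulation p-value.
#'
#' @param p Numeric vector of per-circuit p-values.
#' @param pathwayIds Pathway identifier per circuit.
#' @return data.frame: pathway_id, n_circuits, combined_p.
#' @export
pathwayCombine <- function(p, pathwayIds) {
    stopifnot(length(p) == length(pathwayIds))
    sp <- split(p, pathwayIds)
    data.frame(pathway_id = names(sp),
               n_circuits = lengths(sp),
               combined_p = vapply(sp, fisherCombine, 0),
               row.names = NULL)
}

#' Hallmark enrichment along a circuit ranking
#'
#' Logistic regression of hallmark membership on a per-circuit ranking
#' statistic (the moderated t against normal tissue): the Wald p-value of
#' the slope measures whether hallmark circuits concentrate at one end of
#' the ranking. Separation (all members beyond all non-members) is flagged
#' rather than fitted.
#'
#' @param stat Numeric ranking statistic, one value per circuit.
#' @param membership Logical vector: circuit belongs to the hallmark set.
#' @return One-row data.frame: slope, p_value, separation.
#' @export
hallmarkEnrichment <- function(stat, membership) {
    stopifnot(length(stat) == length(membership), is.logical(membership))
    if (all(membership) || !any(membership))
        stop("need at least one member and one non-member circuit")
    fit <- .glmBinomial(as.integer(membership), data.frame(stat = stat))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || abs(co["stat", "Estimate"]) > .separationCut
    if (sep)
        return(data.frame(slope = NA_real_, p_value = NA_real_,
                          separation = TRUE))
    data.frame(slope = co["stat", "Estimate"],
               p_value = co["stat", "Pr(>|z|)"], separation = FALSE)
}

#' Hallmark enrichment table over all hallmarks
#'
#' Runs [hallmarkEnrichment()] for every hallmark in the annotation map;
#' hallmarks covering none or all of the ranked circuits are reported as NA
#' with a warning.
#'
#' @param stat Named numeric ranking statistic (names = circuit ids).
#' @param annotations Circuit-to-hallmark map from [thresholdAnnotations()].
#' @return data.frame: hallmark, n_member, slope, p_value, separation.
#' @export
hallmarkEnrichmentTable <- function(stat, annotations) {
    stopifnot(!is.null(names(stat)))
    hallmarks <- sort(unique(unlist(annotations)))
    rows <- lapply(hallmarks, function(h) {
        member <- vapply(names(stat), function(cc)
            h %in% annotations[[cc]], TRUE)
        if (all(member) || !any(member)) {
            warning("hallmark '", h, "' covers none or all circuits; ",
                    "enrichment not estimable")
            return(data.frame(hallmark = h, n_member = sum(member),
                              slope = NA_real_, p_value = NA_real_,
                              separation = NA))
        }
        cbind(data.frame(hallmark = h, n_member = sum(member)),
              hallmarkEnrichment(stat, member))
    })
    do.call(rbind, rows)
}
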