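#' Cohort-layer report
#'
#' Prevalence and association tables for a classified cohort: the per-gene
#' prevalence table with exact group-comparison p-values, the molecular
#' subtype partition (with the overlap labels that elude the four-subtype
#' classification), univariate logistic regressions of group on each
#' mutated gene, and a joint (adjusted) model over the genes univariately
#' associated at p < 0.05.
#'
#' @param cohort A \linkS4class{GeneStatusMatrix} with group metadata.
#' @param rules [classificationRules()].
#' @param test Association test for the prevalence table.
#' @param outDir Optional directory for TSV exports.
#' @return List: prevalence, prevalence_long, subtypes (with
#'   \code{"eluded"} attribute), univariate, adjusted.
#' @export
runCohortReport <- function(cohort, rules = classificationRules(),
                            test = "fisher", outDir = NULL) {
    stopifnot(is(cohort, "GeneStatusMatrix"),
              nrow(mutationStatus(cohort)) > 0)
    prev <- prevalenceTable(cohort, test = test)
    prevLong <- prevalenceTableLong(cohort, test = test)
    sub <- subtypeTable(classifySubtype(cohort, rules))
    grp <- patientInfo(cohort)$group
    m <- mutationStatus(cohort)
    use <- colnames(m)[colSums(m == 1L, na.rm = TRUE) > 0]
    uni <- do.call(rbind, lapply(use, function(g) {
        keep <- !is.na(m[, g])
        cbind(data.frame(gene = g),
              logisticUnivariate(grp[keep], m[keep, g]))
    }))
    sig <- uni$gene[!uni$separation & !is.na(uni$p_value) &
                        uni$p_value < 0.05]
    adj <- NULL
    if (length(sig) >= 2L) {
        X <- m[, sig, drop = FALSE]
        keep <- stats::complete.cases(X)
        adj <- tryCatch(logisticAdjusted(grp[keep], X[keep, , drop = FALSE]),
                        error = function(e) {
                            warning("adjusted model not fitted: ",
                                    conditionMessage(e))
                            NULL
                        })
    }
    out <- list(prevalence = prev, prevalence_long = prevLong,
                subtypes = sub, univariate = uni, adjusted = adj)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(prevLong, file.path(outDir, "prevalence.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sub, file.path(outDir, "subtypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(uni, file.path(outDir, "logistic_univariate.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(adj))
            utils::write.table(adj,
                               file.path(outDir, "logistic_adjusted.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}

#' Mechanistic-layer pipeline
#'
#' Runs the full in-silico knockdown analysis for the three comparisons
#' (CSD vs nevogenic, CSD vs normal tissue, nevogenic vs normal tissue):
#' bootstrap differential circuit activation, hallmark annotation of the
#' selected circuits, per-hallmark count/ratio radar table, pathway-level
#' combined significance, and hallmark enrichment along the
#' moderated-t ranking of each group-vs-normal comparison. Comparison
#' seeds are derived from \code{seed} by fixed offsets, so a full run is
#' reproducible bit for bit.
#'
#' @param cohort A \linkS4class{GeneStatusMatrix}.
#' @param expr Raw normal-tissue expression matrix.
#' @param graphs List of \linkS4class{PathwayGraph} objects.
#' @param hallmarkScores Score table (circuit_id, hallmark, score).
#' @param config [diffConfig()].
#' @param kdConfig [knockdownConfig()].
#' @param hmConfig [hallmarkConfig()].
#' @param seed Integer master seed.
#' @param outDir Optional directory for TSV exports and a run log.
#' @return List: diff (per-comparison result tables), selected (circuit ids
#'   per group), counts (hallmark radar table), pathway (per-comparison
#'   pathway-level p), enrichment (per group vs normal), annotations,
#'   summary (selected/up/down counts per comparison).
#' @export
runMechanistic <- function(cohort, expr, graphs, hallmarkScores,
                           config = diffConfig(),
                           kdConfig = knockdownConfig(),
                           hmConfig = hallmarkConfig(), seed = 1L,
                           outDir = NULL) {
    comparisons <- list(csd_vs_nev = c("nevogenic", "CSD"),
                        csd_vs_normal = c("normal", "CSD"),
                        nev_vs_normal = c("normal", "nevogenic"))
    circuits <- unlist(lapply(graphs, decomposeCircuits))
    diffs <- list()
    for (i in seq_along(comparisons))
        diffs[[names(comparisons)[i]]] <- bootstrapDiff(
            cohort, expr, circuits, comparison = comparisons[[i]],
            config = config, kdConfig = kdConfig, seed = seed + i)
    annotations <- thresholdAnnotations(hallmarkScores, hmConfig)
    selected <- list(
        nevogenic = diffs$nev_vs_normal$circuit_id[diffs$nev_vs_normal$selected],
        CSD = diffs$csd_vs_normal$circuit_id[diffs$csd_vs_normal$selected])
    counts <- hallmarkCounts(selected, annotations)
    pathway <- lapply(diffs, function(d)
        pathwayCombine(d$combined_p, d$pathway_id))
    enrichment <- list(
        nevogenic = hallmarkEnrichmentTable(
            stats::setNames(diffs$nev_vs_normal$t,
                            diffs$nev_vs_normal$circuit_id), annotations),
        CSD = hallmarkEnrichmentTable(
            stats::setNames(diffs$csd_vs_normal$t,
                            diffs$csd_vs_normal$circuit_id), annotations))
    summary <- do.call(rbind, lapply(names(diffs), function(nm) {
        d <- diffs[[nm]]
        data.frame(comparison = nm, n_circuits = nrow(d),
                   n_selected = sum(d$selected),
                   n_up = sum(d$selected & d$direction == "up"),
                   n_down = sum(d$selected & d$direction == "down"))
    }))
    out <- list(diff = diffs, selected = selected, counts = counts,
                pathway = pathway, enrichment = enrichment,
                annotations = annotations, summary = summary)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(diffs))
            utils::write.table(diffs[[nm]],
                               file.path(outDir, paste0("diff_", nm, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(counts, file.path(outDir, "hallmark_radar.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(summary, file.path(outDir, "summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(c(paste("seed:", seed),
                     paste("nBootstrap:", config$nBootstrap),
                     paste("alpha:", config$alpha),
                     paste("concordanceMin:", config$concordanceMin),
                     paste("knockdownFactor:", kdConfig$factor),
                     paste("hallmarkThreshold:",
                           attr(annotations, "threshold")),
                     paste("run:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
                   file.path(outDir, "run_log.txt"))
    }
    out
}
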