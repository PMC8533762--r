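#' Default per-group gene mutation probabilities
#'
#' Bernoulli mutation probabilities per gene and etiopathogenic group,
#' calibrated to the reference-cohort prevalences (counts over informative
#' group sizes), e.g. NF1 0.073 nevogenic / 0.378 CSD, BRAF 0.561 / 0.378,
#' ROS1 0.049 / 0.270.
#'
#' @return Matrix genes x c("nevogenic", "CSD") of probabilities.
#' @export
defaultMutationProbs <- function() {
    m <- melanomaMarginals()
    p <- cbind(nevogenic = m$nev / (82 - m$na_nev),
               CSD = m$csd / (37 - m$na_csd))
    rownames(p) <- m$gene
    p
}

#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators. The defaults mirror
#' the reference study conditions: 82 nevogenic and 37 CSD tumors with
#' mutation probabilities calibrated to the published prevalences, 40
#' normal-tissue expression profiles, and five random signalling pathway
#' DAGs of eight nodes.
#'
#' @param seed Master seed.
#' @param nNevogenic,nCsd Group sizes.
#' @param geneMutProbs Genes x groups probability matrix (columns
#'   nevogenic, CSD).
#' @param nPathways,nodesPerPathway Random pathway DAG dimensions.
#' @param inhibitionProb Probability that an extra parent edge is
#'   inhibitory.
#' @param nNormalSamples Normal-tissue expression profiles to simulate.
#' @param plantedEffects Optional data.frame (gene, group, prob) forcing a
#'   gene's mutation probability within a group — the handle for planting
#'   known knockdown effects.
#' @return A list of class \code{"SyntheticScenario"}.
#' @export
syntheticScenario <- function(seed = 1L, nNevogenic = 82L, nCsd = 37L,
                              geneMutProbs = defaultMutationProbs(),
                              nPathways = 5L, nodesPerPathway = 8L,
                              inhibitionProb = 0.2, nNormalSamples = 40L,
                              plantedEffects = NULL) {
    stopifnot(nNevogenic >= 2L, nCsd >= 2L,
              all(geneMutProbs >= 0 & geneMutProbs <= 1),
              all(c("nevogenic", "CSD") %in% colnames(geneMutProbs)))
    if (!is.null(plantedEffects)) {
        stopifnot(all(c("gene", "group", "prob") %in% names(plantedEffects)))
        for (i in seq_len(nrow(plantedEffects))) {
            g <- plantedEffects$gene[i]
            if (!g %in% rownames(geneMutProbs)) {
                geneMutProbs <- rbind(geneMutProbs, 0)
                rownames(geneMutProbs)[nrow(geneMutProbs)] <- g
            }
            geneMutProbs[g, plantedEffects$group[i]] <- plantedEffects$prob[i]
        }
    }
    structure(list(seed = seed, nNevogenic = nNevogenic, nCsd = nCsd,
                   geneMutProbs = geneMutProbs, nPathways = nPathways,
                   nodesPerPathway = nodesPerPathway,
                   inhibitionProb = inhibitionProb,
                   nNormalSamples = nNormalSamples),
              class = "SyntheticScenario")
}

#' Simulate a mutational cohort
#'
#' Independent per-gene Bernoulli draws with group-specific probabilities
#' (the reference data give only marginals, so no co-occurrence structure is
#' modelled), with nevus counts and elastosis grades consistent with each
#' group's classification rule.
#'
#' @param scenario A [syntheticScenario()].
#' @param seed Seed override (defaults to the scenario's).
#' @return A \linkS4class{GeneStatusMatrix}.
#' @export
simCohort <- function(scenario, seed = scenario$seed) {
    pr <- scenario$geneMutProbs
    nN <- scenario$nNevogenic; nC <- scenario$nCsd
    withSeed(seed, {
        status <- rbind(
            matrix(stats::rbinom(nN * nrow(pr), 1L, rep(pr[, "nevogenic"],
                                 each = nN)), nN),
            matrix(stats::rbinom(nC * nrow(pr), 1L, rep(pr[, "CSD"],
                                 each = nC)), nC))
        dimnames(status) <- list(sprintf("SIM%03d", seq_len(nN + nC)),
                                 rownames(pr))
        pd <- data.frame(
            tumor_id = rownames(status),
            nevus_count = c(sample(51:150, nN, replace = TRUE),
                            sample(0:19, nC, replace = TRUE)),
            elastosis_grade = c(rep("0", nN),
                                sample(c("2-", "2", "2+", "3-", "3", "3+"),
                                       nC, replace = TRUE)),
            group = rep(c("nevogenic", "CSD"), c(nN, nC)),
            row.names = rownames(status))
        geneStatusMatrix(status = status, patientData = pd,
                         genes = rownames(pr))
    })
}

#' Simulate normal-tissue expression
#'
#' Log-normal expression with gene-specific log-means (uniform on
#' \code{meanlogRange}) and common log-sd, emulating the right-skewed,
#' strictly positive abundance distribution of bulk normal-tissue
#' transcriptomes.
#'
#' @param genes Character vector of gene names (rows).
#' @param nSamples Number of profiles (columns).
#' @param seed Integer seed.
#' @param meanlogRange,sdlog Log-normal parameters.
#' @return Genes x samples matrix of positive values.
#' @export
simExpression <- function(genes, nSamples, seed = 1L,
                          meanlogRange = c(2, 8), sdlog = 0.5) {
    withSeed(seed, {
        mu <- stats::runif(length(genes), meanlogRange[1L], meanlogRange[2L])
        m <- matrix(stats::rlnorm(length(genes) * max(nSamples, 0L),
                                  meanlog = rep(mu, nSamples), sdlog = sdlog),
                    nrow = length(genes),
                    dimnames = list(genes,
                        if (nSamples > 0) sprintf("N%03d", seq_len(nSamples))))
        m
    })
}

#' Simulate random signalling pathway DAGs
#'
#' Each pathway is a layered random DAG: nodes are ordered, every
#' non-initial node receives one guaranteed activating parent among its
#' predecessors (so signal can always flow) plus optional extra parents that
#' are inhibitory with probability \code{inhibitionProb}. Node genes are
#' drawn without replacement per pathway from \code{geneUniverse} when
#' given, otherwise synthesised as \code{"<pathway>_G<i>"}. The emitted
#' ground-truth circuit list (one circuit per reachable effector) matches
#' [decomposeCircuits()] by construction.
#'
#' @param nPathways,nNodes Dimensions.
#' @param inhibitionProb Probability of an inhibitory extra edge.
#' @param geneUniverse Optional pool of gene symbols to assign to nodes.
#' @param extraParentProb Probability of each possible extra parent edge.
#' @param seed Integer seed.
#' @return List with elements \code{graphs} (list of
#'   \linkS4class{PathwayGraph}) and \code{truth} (data.frame pathway_id,
#'   effector, circuit_id).
#' @export
simPathways <- function(nPathways = 5L, nNodes = 8L, inhibitionProb = 0.2,
                        geneUniverse = NULL, extraParentProb = 0.15,
                        seed = 1L) {
    stopifnot(nNodes >= 2L)
    withSeed(seed, {
        graphs <- lapply(seq_len(nPathways), function(k) {
            pid <- sprintf("PW%02d", k)
            nodes <- sprintf("%s_N%02d", pid, seq_len(nNodes))
            from <- character(); to <- character(); sgn <- character()
            for (i in 2:nNodes) {
                main <- sample.int(i - 1L, 1L)
                from <- c(from, nodes[main]); to <- c(to, nodes[i])
                sgn <- c(sgn, "activation")
                extra <- setdiff(seq_len(i - 1L), main)
                extra <- extra[stats::runif(length(extra)) < extraParentProb]
                for (j in extra) {
                    from <- c(from, nodes[j]); to <- c(to, nodes[i])
                    sgn <- c(sgn, if (stats::runif(1) < inhibitionProb)
                        "inhibition" else "activation")
                }
            }
            genes <- if (is.null(geneUniverse))
                sprintf("%s_G%02d", pid, seq_len(nNodes))
            else sample(geneUniverse, nNodes)
            pathwayGraph(pid, data.frame(from = from, to = to, sign = sgn),
                         nodeGenes = stats::setNames(as.list(genes), nodes))
        })
        truth <- do.call(rbind, lapply(graphs, function(g)
            data.frame(pathway_id = g@pathwayId,
                       effector = sort(g@effectors),
                       circuit_id = paste(g@pathwayId, sort(g@effectors),
                                          sep = ":"))))
        list(graphs = graphs, truth = truth)
    })
}

#' Simulate a hallmark score table
#'
#' Exponential scores (heavy right tail) for every (circuit, hallmark)
#' pair; the default rate log(10)/0.18 puts 10 percent of the mass above
#' the 0.18 annotation threshold, so the fixed-threshold and
#' 90th-percentile modes agree in expectation.
#'
#' @param circuitIds Character vector of circuit ids.
#' @param hallmarks Hallmark vocabulary (default the canonical ten).
#' @param rate Exponential rate.
#' @param seed Integer seed.
#' @return data.frame circuit_id, hallmark, score with unique keys.
#' @export
simHallmarkScores <- function(circuitIds, hallmarks = cancerHallmarks,
                              rate = log(10) / 0.18, seed = 1L) {
    grid <- expand.grid(circuit_id = circuitIds, hallmark = hallmarks,
                        stringsAsFactors = FALSE)
    withSeed(seed, {
        grid$score <- stats::rexp(nrow(grid), rate = rate)
        grid
    })
}

#' Generate and write a complete synthetic run directory
#'
#' Materialises every pipeline input for a scenario: \code{cohort.tsv},
#' \code{expr.tsv}, \code{pathways.sif}, \code{node_map.tsv},
#' \code{hallmarks.tsv} and \code{truth.tsv} (ground-truth circuit list).
#' The expression matrix covers the union of the pathway genes and every
#' mutable panel gene. Sub-generators use seeds derived from the scenario
#' seed by small fixed offsets.
#'
#' @param scenario A [syntheticScenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the generated objects.
#' @export
writeScenario <- function(scenario, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    obj <- simulateScenario(scenario)
    writeCohortTable(obj$cohort, file.path(dir, "cohort.tsv"))
    ex <- data.frame(gene = rownames(obj$expr), obj$expr,
                     check.names = FALSE)
    utils::write.table(ex, file.path(dir, "expr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writePathways(obj$graphs, file.path(dir, "pathways.sif"),
                  file.path(dir, "node_map.tsv"))
    utils::write.table(obj$hallmarkScores, file.path(dir, "hallmarks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(obj$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(obj)
}

#' Generate all synthetic inputs for a scenario in memory
#'
#' @param scenario A [syntheticScenario()].
#' @return List: cohort, expr, graphs, truth, hallmarkScores.
#' @export
simulateScenario <- function(scenario) {
    s <- scenario$seed
    cohort <- simCohort(scenario, seed = s)
    pw <- simPathways(scenario$nPathways, scenario$nodesPerPathway,
                      scenario$inhibitionProb, seed = s + 1L)
    genes <- union(unique(unlist(lapply(pw$graphs, slot, "nodeGenes"))),
                   rownames(scenario$geneMutProbs))
    expr <- simExpression(genes, scenario$nNormalSamples, seed = s + 2L)
    hs <- simHallmarkScores(pw$truth$circuit_id, seed = s + 3L)
    list(cohort = cohort, expr = expr, graphs = pw$graphs,
         truth = pw$truth, hallmarkScores = hs)
}
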