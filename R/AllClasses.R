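#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setOldClass("igraph")

#' GeneStatusMatrix: per-tumor binary mutation status
#'
#' Binary (0/1/NA) mutation status of each tumor over the sequencing panel
#' genes plus the TERT promoter, together with per-patient metadata
#' (nevus count, solar-elastosis grade, etiopathogenic group). The matrix is
#' the backbone of molecular subtype classification and of the prevalence /
#' association tables.
#'
#' @slot status Integer matrix, tumors x genes, entries 0, 1 or NA
#'   (1 = at least one retained pathogenic-class variant).
#' @slot patientData A \linkS4class{DataFrame} with one row per tumor,
#'   rownames matching the status matrix; expected columns
#'   \code{nevus_count}, \code{elastosis_grade} and \code{group}.
#'
#' @seealso [geneStatusMatrix()], [classifySubtype()], [prevalenceTable()]
#' @export
setClass("GeneStatusMatrix",
    representation(status = "matrix", patientData = "DataFrame"))

setValidity("GeneStatusMatrix", function(object) {
    s <- object@status
    msg <- character()
    if ((nrow(s) > 0 && is.null(rownames(s))) ||
        (ncol(s) > 0 && is.null(colnames(s))))
        msg <- c(msg, "status matrix must have tumor rownames and gene colnames")
    bad <- !(s %in% c(0L, 1L, NA))
    if (any(bad))
        msg <- c(msg, "status entries must be 0, 1 or NA")
    if (nrow(object@patientData) != nrow(s))
        msg <- c(msg, "patientData must have one row per tumor")
    if (nrow(s) > 0 &&
        !identical(rownames(object@patientData), rownames(s)))
        msg <- c(msg, "patientData rownames must match status rownames")
    if (length(msg)) msg else TRUE
})

#' PathwayGraph: a signed, directed signalling pathway
#'
#' A directed acyclic graph whose edges carry an \code{"activation"} or
#' \code{"inhibition"} sign. Receptor nodes (no incoming edges) inject signal;
#' effector nodes (no outgoing edges) report the functional output of the
#' pathway. Each node maps to one or more genes whose (rescaled) expression
#' sets the node's capacity to transmit signal.
#'
#' @slot pathwayId Character scalar identifier.
#' @slot graph An \pkg{igraph} DAG with edge attribute \code{sign}.
#' @slot nodeGenes Named list, one character vector of gene symbols per node.
#' @slot receptors,effectors Character vectors of node names.
#'
#' @seealso [pathwayGraph()], [parsePathways()], [decomposeCircuits()]
#' @export
setClass("PathwayGraph",
    representation(pathwayId = "character", graph = "igraph",
                   nodeGenes = "list", receptors = "character",
                   effectors = "character"))

setValidity("PathwayGraph", function(object) {
    g <- object@graph
    msg <- character()
    if (!igraph::is_dag(g))
        msg <- c(msg, "pathway graph must be acyclic")
    nm <- igraph::V(g)$name
    if (igraph::ecount(g) > 0) {
        sgn <- igraph::E(g)$sign
        if (is.null(sgn) || !all(sgn %in% c("activation", "inhibition")))
            msg <- c(msg, "edge signs must be 'activation' or 'inhibition'")
    }
    if (!all(names(object@nodeGenes) %in% nm) ||
        !all(nm %in% names(object@nodeGenes)))
        msg <- c(msg, "nodeGenes must name every graph node")
    if (any(lengths(object@nodeGenes) < 1L))
        msg <- c(msg, "every node needs at least one gene")
    if (!all(object@receptors %in% nm) || !all(object@effectors %in% nm))
        msg <- c(msg, "receptors/effectors must be graph nodes")
    if (length(msg)) msg else TRUE
})

#' Circuit: the receptor-to-effector sub-DAG of one effector
#'
#' The sub-network of a \linkS4class{PathwayGraph} made of every node and edge
#' lying on some receptor-to-effector path for a single effector node. Its
#' propagated signal at the effector is the circuit activity. Topological
#' order and per-node activator/inhibitor parent lists are precomputed at
#' construction so that propagation is a single pass.
#'
#' @slot circuitId Character, \code{"<pathwayId>:<effector>"}.
#' @slot pathwayId,effector Character scalars.
#' @slot graph igraph sub-DAG.
#' @slot nodeGenes Named list of gene vectors for circuit nodes.
#' @slot topoOrder Character vector of nodes in topological order.
#' @slot activators,inhibitors Named lists: incoming activator/inhibitor
#'   parents per node.
#'
#' @seealso [decomposeCircuits()], [circuitActivity()]
#' @export
setClass("Circuit",
    representation(circuitId = "character", pathwayId = "character",
                   effector = "character", graph = "igraph",
                   nodeGenes = "list", topoOrder = "character",
                   activators = "list", inhibitors = "list"))

#' ActivityDataset: circuits x samples activity matrix
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"activity"} assay
#' of propagated circuit activities in the open unit interval, per-sample
#' group labels in \code{colData} and circuit/pathway annotation in
#' \code{rowData}. The circuit objects used to compute it are kept in
#' \code{metadata()$circuits} for reuse.
#'
#' @seealso [activityMatrix()], [buildGroupDataset()], [moderatedT()]
#' @export
setClass("ActivityDataset", contains = "SummarizedExperiment")

setValidity("ActivityDataset", function(object) {
    msg <- character()
    if (!"activity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "needs an 'activity' assay")
    else {
        a <- SummarizedExperiment::assay(object, "activity")
        if (any(!is.finite(a)) || any(a <= 0) || any(a >= 1))
            msg <- c(msg, "activities must lie strictly inside (0, 1)")
    }
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData needs a 'group' column")
    if (length(msg)) msg else TRUE
})
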