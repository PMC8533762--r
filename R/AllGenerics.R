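#' @rdname GeneStatusMatrix-class
#' @param object A \linkS4class{GeneStatusMatrix}.
#' @export
setGeneric("mutationStatus", function(object) standardGeneric("mutationStatus"))

#' @rdname GeneStatusMatrix-class
#' @export
setGeneric("patientInfo", function(object) standardGeneric("patientInfo"))

#' @rdname GeneStatusMatrix-class
#' @export
setGeneric("panelGenes", function(object) standardGeneric("panelGenes"))

#' @rdname GeneStatusMatrix-class
#' @export
setGeneric("tumorIds", function(object) standardGeneric("tumorIds"))

#' Decompose a pathway graph into effector circuits
#'
#' One circuit per effector node: the sub-DAG of every simple
#' receptor-to-effector path. Effectors unreachable from any receptor are
#' skipped with a warning. Circuits are returned ordered by effector name.
#'
#' @param object A \linkS4class{PathwayGraph}.
#' @return A list of \linkS4class{Circuit} objects.
#' @examples
#' g <- pathwayGraph("toy", data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                     sign = "activation"))
#' decomposeCircuits(g)
#' @export
setGeneric("decomposeCircuits",
           function(object) standardGeneric("decomposeCircuits"))

#' @rdname ActivityDataset-class
#' @param object An \linkS4class{ActivityDataset}.
#' @export
setGeneric("activityValues", function(object) standardGeneric("activityValues"))

#' @rdname ActivityDataset-class
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))
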