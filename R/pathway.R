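.edgeSigns <- c("activation", "inhibition")

.describeCycle <- function(g) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1L)]
    loops <- igraph::which_loop(g)
    if (any(loops))
        cyc <- union(cyc, igraph::tail_of(g, igraph::E(g)[loops])$name)
    paste(sort(cyc), collapse = " -> ")
}

#' Construct a signed pathway DAG
#'
#' Builds a \linkS4class{PathwayGraph} from an edge table. Receptors and
#' effectors are inferred from degree (in-degree 0 / out-degree 0) unless
#' overridden by explicit annotations in \code{nodes}. Cyclic topologies are
#' rejected with an error listing the nodes on a cycle: circuit activities
#' are defined by a single topological pass, so feedback motifs are out of
#' contract.
#'
#' @param pathwayId Identifier.
#' @param edges data.frame with columns from, to, sign
#'   ("activation"/"inhibition").
#' @param nodes Optional data.frame with column \code{node} and optional
#'   logical columns \code{is_receptor}, \code{is_effector} (overriding
#'   degree inference) — also the way to declare isolated nodes.
#' @param nodeGenes Optional named list mapping nodes to gene symbols;
#'   defaults to each node name being its own gene.
#' @return A \linkS4class{PathwayGraph}.
#' @examples
#' pathwayGraph("mapk", data.frame(from = c("EGFR", "RAS"),
#'                                 to = c("RAS", "ERK"),
#'                                 sign = "activation"))
#' @export
pathwayGraph <- function(pathwayId, edges, nodes = NULL, nodeGenes = NULL) {
    stopifnot(is.character(pathwayId), length(pathwayId) == 1L)
    if (nrow(edges)) {
        stopifnot(all(c("from", "to", "sign") %in% names(edges)))
        badSign <- !(edges$sign %in% .edgeSigns)
        if (any(badSign))
            stop("unknown edge relation(s): ",
                 paste(unique(edges$sign[badSign]), collapse = ", "),
                 " (expected 'activation' or 'inhibition')")
    }
    vnames <- unique(c(edges$from, edges$to,
                       if (!is.null(nodes)) as.character(nodes$node)))
    g <- igraph::graph_from_data_frame(
        edges[, c("from", "to", "sign"), drop = FALSE],
        directed = TRUE, vertices = data.frame(name = vnames))
    if (!igraph::is_dag(g))
        stop("pathway '", pathwayId, "' contains a cycle: ",
             .describeCycle(g))
    recep <- vnames[igraph::degree(g, mode = "in") == 0L]
    effec <- vnames[igraph::degree(g, mode = "out") == 0L]
    if (!is.null(nodes)) {
        if ("is_receptor" %in% names(nodes) && any(nodes$is_receptor))
            recep <- as.character(nodes$node[as.logical(nodes$is_receptor)])
        if ("is_effector" %in% names(nodes) && any(nodes$is_effector))
            effec <- as.character(nodes$node[as.logical(nodes$is_effector)])
    }
    if (is.null(nodeGenes))
        nodeGenes <- as.list(stats::setNames(vnames, vnames))
    else {
        missing <- setdiff(vnames, names(nodeGenes))
        nodeGenes[missing] <- as.list(missing)
        nodeGenes <- nodeGenes[vnames]
    }
    new("PathwayGraph", pathwayId = pathwayId, graph = g,
        nodeGenes = nodeGenes, receptors = recep, effectors = effec)
}

setMethod("show", "PathwayGraph", function(object) {
    cat("PathwayGraph '", object@pathwayId, "': ",
        igraph::vcount(object@graph), " nodes, ",
        igraph::ecount(object@graph), " edges; ",
        length(object@receptors), " receptor(s), ",
        length(object@effectors), " effector(s)\n", sep = "")
})

#' Parse pathway graphs from SIF and node-map files
#'
#' The SIF file has one edge per line (\code{source<TAB>relation<TAB>target},
#' relation \code{activation} or \code{inhibition}); the node map is a
#' tab-separated table with columns \code{node_id}, \code{gene},
#' \code{pathway_id} (several rows per node give multi-gene nodes) and
#' optional \code{is_receptor} / \code{is_effector} annotation columns.
#' Node identifiers must be unique across pathways; edges may not join
#' nodes of different pathways.
#'
#' @param sifPath,nodeMapPath File paths.
#' @return Named list of \linkS4class{PathwayGraph} objects.
#' @seealso [writePathways()] for the inverse.
#' @export
parsePathways <- function(sifPath, nodeMapPath) {
    stopifnot(file.exists(sifPath), file.exists(nodeMapPath))
    nodeMap <- utils::read.delim(nodeMapPath, colClasses = "character")
    stopifnot(all(c("node_id", "gene", "pathway_id") %in% names(nodeMap)))
    sif <- if (file.size(sifPath) > 0)
        utils::read.delim(sifPath, header = FALSE,
                          col.names = c("from", "sign", "to"),
                          colClasses = "character")
    else data.frame(from = character(), sign = character(), to = character())
    badSign <- !(sif$sign %in% .edgeSigns)
    if (any(badSign))
        stop("unknown edge relation(s) in SIF: ",
             paste(unique(sif$sign[badSign]), collapse = ", "))
    pwOf <- tapply(nodeMap$pathway_id, nodeMap$node_id,
                   function(p) unique(p))
    if (any(lengths(pwOf) > 1L))
        stop("node(s) mapped to several pathways: ",
             paste(names(pwOf)[lengths(pwOf) > 1L], collapse = ", "))
    unknown <- setdiff(unique(c(sif$from, sif$to)), names(pwOf))
    if (length(unknown))
        stop("SIF node(s) absent from the node map: ",
             paste(unknown, collapse = ", "))
    cross <- unlist(pwOf[sif$from]) != unlist(pwOf[sif$to])
    if (length(cross) && any(cross))
        stop("edge(s) joining nodes of different pathways")
    out <- lapply(split(nodeMap, nodeMap$pathway_id), function(nm) {
        nodes <- unique(nm$node_id)
        edges <- sif[sif$from %in% nodes, , drop = FALSE]
        genes <- split(nm$gene, nm$node_id)[nodes]
        nodeDf <- data.frame(node = nodes)
        for (col in c("is_receptor", "is_effector"))
            if (col %in% names(nm))
                nodeDf[[col]] <- as.logical(
                    nm[[col]][match(nodes, nm$node_id)])
        pathwayGraph(nm$pathway_id[1L],
                     edges[, c("from", "to", "sign")],
                     nodes = nodeDf, nodeGenes = genes)
    })
    out[order(names(out))]
}

#' Write pathway graphs to SIF and node-map files
#'
#' @param graphs List of \linkS4class{PathwayGraph} objects.
#' @param sifPath,nodeMapPath Output file paths.
#' @return Invisibly, the two paths.
#' @export
writePathways <- function(graphs, sifPath, nodeMapPath) {
    ed <- do.call(rbind, lapply(graphs, function(g) {
        e <- igraph::as_data_frame(g@graph, what = "edges")
        if (nrow(e)) data.frame(from = e$from, sign = e$sign, to = e$to)
        else NULL
    }))
    if (is.null(ed)) ed <- data.frame(from = character(), sign = character(),
                                      to = character())
    utils::write.table(ed, sifPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    nm <- do.call(rbind, lapply(graphs, function(g) {
        nodes <- igraph::V(g@graph)$name
        do.call(rbind, lapply(nodes, function(n)
            data.frame(node_id = n, gene = g@nodeGenes[[n]],
                       pathway_id = g@pathwayId,
                       is_receptor = n %in% g@receptors,
                       is_effector = n %in% g@effectors)))
    }))
    utils::write.table(nm, nodeMapPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(sifPath, nodeMapPath))
}

#' @rdname decomposeCircuits
#' @export
setMethod("decomposeCircuits", "PathwayGraph", function(object) {
    g <- object@graph
    fromRec <- unique(unlist(lapply(object@receptors, function(r)
        igraph::subcomponent(g, r, mode = "out")$name)))
    circuits <- list()
    for (e in sort(object@effectors)) {
        if (igraph::degree(g, e, mode = "all") == 0L) {
            warning("node '", e, "' of pathway '", object@pathwayId,
                    "' is isolated; no circuit built")
            next
        }
        toEff <- igraph::subcomponent(g, e, mode = "in")$name
        nodes <- intersect(toEff, fromRec)
        if (!length(intersect(nodes, object@receptors)) || !(e %in% nodes)) {
            warning("effector '", e, "' of pathway '", object@pathwayId,
                    "' is unreachable from any receptor; circuit skipped")
            next
        }
        sub <- igraph::induced_subgraph(g, nodes)
        topo <- igraph::topo_sort(sub, mode = "out")$name
        acts <- inhs <- stats::setNames(vector("list", length(topo)), topo)
        for (n in topo) {
            ie <- igraph::incident(sub, n, mode = "in")
            if (length(ie)) {
                from <- igraph::tail_of(sub, ie)$name
                sgn <- igraph::edge_attr(sub, "sign", ie)
                acts[[n]] <- from[sgn == "activation"]
                inhs[[n]] <- from[sgn == "inhibition"]
            } else {
                acts[[n]] <- character()
                inhs[[n]] <- character()
            }
        }
        circuits[[length(circuits) + 1L]] <- new("Circuit",
            circuitId = paste(object@pathwayId, e, sep = ":"),
            pathwayId = object@pathwayId, effector = e, graph = sub,
            nodeGenes = object@nodeGenes[topo], topoOrder = topo,
            activators = acts, inhibitors = inhs)
    }
    circuits
})

setMethod("show", "Circuit", function(object) {
    cat("Circuit '", object@circuitId, "': ", length(object@topoOrder),
        " nodes, effector '", object@effector, "'\n", sep = "")
})

#' Rank-rescale an expression matrix to the open unit interval
#'
#' Replaces each entry by rank/(N + 1), with ties averaged. By default N is
#' the number of entries of the whole matrix (one joint ranking), so every
#' value lands strictly inside (0, 1) and the transform is invariant to any
#' monotone transform of the input. Per-gene ranking (each row ranked
#' against itself) is available behind \code{perGene = TRUE}.
#'
#' @param x Numeric matrix with finite entries (no NA; imputation is out of
#'   scope).
#' @param perGene Rank within rows instead of the whole matrix.
#' @return Matrix of the same shape with entries in (0, 1).
#' @examples
#' rankRescale(matrix(1:4, 2))  # ranks 1..4 over N = 4 -> k/5
#' @export
rankRescale <- function(x, perGene = FALSE) {
    stopifnot(is.matrix(x))
    if (anyNA(x)) stop("NA entries are not allowed (no imputation)")
    if (any(!is.finite(x))) stop("non-finite entries are not allowed")
    if (perGene) {
        out <- t(apply(x, 1L, function(r)
            rank(r, ties.method = "average") / (length(r) + 1)))
        dimnames(out) <- dimnames(x)
        return(out)
    }
    out <- x
    out[] <- rank(x, ties.method = "average") / (length(x) + 1)
    out
}

#' Node signal capacities from rescaled expression
#'
#' A node's capacity is the arithmetic mean of its member genes' rescaled
#' expression values.
#'
#' @param circuit A \linkS4class{Circuit} (or \linkS4class{PathwayGraph}).
#' @param expr Rescaled genes x samples matrix (or named vector for a single
#'   sample).
#' @return Nodes x samples matrix of values in (0, 1).
#' @export
nodeValues <- function(circuit, expr) {
    if (is.null(dim(expr))) expr <- cbind(sample = expr)
    genes <- circuit@nodeGenes
    nodes <- if (is(circuit, "Circuit")) circuit@topoOrder else names(genes)
    missing <- setdiff(unique(unlist(genes[nodes])), rownames(expr))
    if (length(missing))
        stop("gene(s) absent from the expression matrix: ",
             paste(missing, collapse = ", "))
    out <- matrix(0, length(nodes), ncol(expr),
                  dimnames = list(nodes, colnames(expr)))
    for (n in nodes) {
        rows <- expr[genes[[n]], , drop = FALSE]
        out[n, ] <- colMeans(rows)
    }
    out
}

.activityEps <- 1e-12

#' Propagate signal through a circuit
#'
#' Topological-order recursion: a receptor transmits its own capacity; any
#' other node transmits \eqn{v(n) (1 - \prod_a (1 - S(a))) \prod_i (1 - S(i))}
#' over its activator parents \eqn{a} and inhibitor parents \eqn{i}. The
#' circuit activity is the signal at the effector, clipped into the open
#' unit interval by 1e-12. On a pure activation chain this reduces to the
#' product of the node capacities along the chain.
#'
#' @param circuit A \linkS4class{Circuit}.
#' @param expr Rescaled genes x samples matrix (or single-sample named
#'   vector).
#' @return Numeric vector of activities, one per sample.
#' @export
circuitActivity <- function(circuit, expr) {
    v <- nodeValues(circuit, expr)
    S <- v
    for (n in circuit@topoOrder) {
        acts <- circuit@activators[[n]]
        inhs <- circuit@inhibitors[[n]]
        if (!length(acts) && !length(inhs)) next  # receptor: S = v
        actTerm <- if (length(acts)) {
            prodComp <- rep(1, ncol(v))
            for (a in acts) prodComp <- prodComp * (1 - S[a, ])
            1 - prodComp
        } else 0
        inhTerm <- rep(1, ncol(v))
        for (i in inhs) inhTerm <- inhTerm * (1 - S[i, ])
        S[n, ] <- v[n, ] * actTerm * inhTerm
    }
    stats::setNames(pmin(pmax(S[circuit@effector, ], .activityEps),
                         1 - .activityEps), colnames(v))
}

#' Compute the circuits x samples activity matrix
#'
#' Decomposes every pathway into effector circuits and propagates each
#' sample's rescaled expression through each circuit.
#'
#' @param graphs List of \linkS4class{PathwayGraph} objects, or a
#'   pre-decomposed list of \linkS4class{Circuit} objects.
#' @param expr Rescaled genes x samples matrix.
#' @param groups Per-sample group labels.
#' @return An \linkS4class{ActivityDataset}; the circuit objects are kept in
#'   \code{metadata()$circuits}.
#' @export
activityMatrix <- function(graphs, expr, groups) {
    circuits <- if (length(graphs) && is(graphs[[1L]], "Circuit")) graphs
                else unlist(lapply(graphs, decomposeCircuits))
    if (!length(circuits))
        stop("no circuits: pathway list is empty or all effectors unreachable")
    stopifnot(length(groups) == ncol(expr))
    act <- do.call(rbind, lapply(circuits, circuitActivity, expr = expr))
    rownames(act) <- vapply(circuits, slot, "", "circuitId")
    colnames(act) <- colnames(expr)
    rd <- DataFrame(circuit_id = rownames(act),
                    pathway_id = vapply(circuits, slot, "", "pathwayId"),
                    effector = vapply(circuits, slot, "", "effector"),
                    row.names = rownames(act))
    se <- SummarizedExperiment(assays = list(activity = act),
                               colData = DataFrame(group = as.character(groups),
                                                   row.names = colnames(act)),
                               rowData = rd)
    ads <- new("ActivityDataset", se)
    metadata(ads)$circuits <- circuits
    ads
}

#' @rdname ActivityDataset-class
#' @export
setMethod("activityValues", "ActivityDataset",
          function(object) SummarizedExperiment::assay(object, "activity"))

#' @rdname ActivityDataset-class
#' @export
setMethod("groupLabels", "ActivityDataset",
          function(object) SummarizedExperiment::colData(object)$group)
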