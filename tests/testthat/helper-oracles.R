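# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher exact p by brute-force hypergeometric enumeration over all
# tables with the observed margins (probability-mass convention, relative
# tolerance 1e-7). Layout: a = mut/nev, b = wt/nev, c = mut/csd, d = wt/csd.
fisherEnumOracle <- function(a, b, c, d) {
    nNev <- a + b
    nCsd <- c + d
    rowMut <- a + c
    lo <- max(0L, rowMut - nCsd)
    hi <- min(rowMut, nNev)
    probs <- dhyper(lo:hi, nNev, nCsd, rowMut)
    pobs <- dhyper(a, nNev, nCsd, rowMut)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up by hand.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, m * p[o] / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# All nodes on any simple receptor->effector path, by recursive DFS over an
# edge table (independent of the igraph reachability implementation).
pathNodesOracle <- function(edges, receptors, effector) {
    adj <- split(as.character(edges$to), as.character(edges$from))
    found <- character()
    walk <- function(node, path) {
        if (node == effector) {
            found <<- union(found, path)
            return(invisible())
        }
        for (nxt in adj[[node]])
            if (!nxt %in% path) walk(nxt, c(path, nxt))
    }
    for (r in receptors) walk(r, r)
    sort(found)
}

# Hand evaluation of the propagation recursion on an arbitrary small DAG,
# written as a direct recursive definition (memoised top-down, no topological
# sort) to stay independent of the package's bottom-up pass.
propagateOracle <- function(edges, values, effector) {
    memo <- new.env()
    signal <- function(node) {
        if (!is.null(memo[[node]])) return(memo[[node]])
        inc <- edges[edges$to == node, , drop = FALSE]
        s <- if (nrow(inc) == 0) values[[node]] else {
            acts <- inc$from[inc$sign == "activation"]
            inhs <- inc$from[inc$sign == "inhibition"]
            act <- if (length(acts))
                1 - prod(vapply(acts, function(a) 1 - signal(a), 0))
            else 0
            inh <- prod(vapply(inhs, function(i) 1 - signal(i), 0))
            values[[node]] * act * inh
        }
        memo[[node]] <- s
        s
    }
    min(max(signal(effector), 1e-12), 1 - 1e-12)
}

# Random DAG edge table on n nodes (node i only feeds higher-numbered nodes);
# every non-source node gets at least one activating parent.
randomDagEdges <- function(n, pExtra = 0.3, pInhibit = 0.25) {
    from <- to <- sgn <- character()
    for (i in 2:n) {
        main <- sample.int(i - 1L, 1L)
        from <- c(from, paste0("n", main)); to <- c(to, paste0("n", i))
        sgn <- c(sgn, "activation")
        extra <- setdiff(seq_len(i - 1L), main)
        extra <- extra[runif(length(extra)) < pExtra]
        for (j in extra) {
            from <- c(from, paste0("n", j)); to <- c(to, paste0("n", i))
            sgn <- c(sgn, if (runif(1) < pInhibit) "inhibition"
                     else "activation")
        }
    }
    data.frame(from = from, to = to, sign = sgn)
}

# A four-node pathway with an inhibitory receptor on the effector; the
# inhibitor node carries NF1, so NF1 knockdowns raise the effector activity.
inhibitorPathway <- function() {
    pathwayGraph("mapk",
                 data.frame(from = c("R", "M", "I"), to = c("M", "E", "E"),
                            sign = c("activation", "activation",
                                     "inhibition")),
                 nodeGenes = list(R = "GR", M = "GM", E = "GE", I = "NF1"))
}

# Tiny two-group cohort mutating only `gene` with the given per-group
# probabilities.
tinyCohort <- function(gene = "NF1", pNev = 0, pCsd = 0.9, n = 10L,
                       seed = 1L) {
    simCohort(syntheticScenario(
        seed = seed, nNevogenic = n, nCsd = n,
        geneMutProbs = matrix(c(pNev, pCsd), 1, 2,
                              dimnames = list(gene,
                                              c("nevogenic", "CSD")))))
}
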