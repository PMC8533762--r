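test_that("pathway parsing validates relations, cycles and node maps", {
    sif <- withr::local_tempfile(fileext = ".sif")
    map <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("A\tactivation\tB", "B\tactivation\tC"), sif)
    writeLines(c("node_id\tgene\tpathway_id",
                 "A\tGA\tp1", "B\tGB\tp1", "C\tGC\tp1"), map)
    graphs <- parsePathways(sif, map)
    expect_length(graphs, 1)
    expect_equal(graphs$p1@receptors, "A")
    expect_equal(graphs$p1@effectors, "C")
    expect_length(decomposeCircuits(graphs$p1), 1)

    writeLines(c("A\tbinding\tB"), sif)
    expect_error(parsePathways(sif, map), "binding")
    writeLines(c("A\tactivation\tB", "B\tactivation\tA"), sif)
    expect_error(parsePathways(sif, map), "cycle")
    writeLines(c("A\tactivation\tZ"), sif)
    expect_error(parsePathways(sif, map), "absent from the node map")
})

test_that("pathway graphs round-trip through SIF + node map", {
    pw <- simPathways(nPathways = 3, nNodes = 7, seed = 21)
    sif <- withr::local_tempfile(fileext = ".sif")
    map <- withr::local_tempfile(fileext = ".tsv")
    writePathways(pw$graphs, sif, map)
    back <- parsePathways(sif, map)
    for (g in pw$graphs) {
        b <- back[[g@pathwayId]]
        expect_setequal(igraph::V(b@graph)$name, igraph::V(g@graph)$name)
        expect_equal(sort(b@effectors), sort(g@effectors))
        expect_equal(b@nodeGenes[order(names(b@nodeGenes))],
                     g@nodeGenes[order(names(g@nodeGenes))])
    }
})

test_that("circuit decomposition matches a DFS path-enumeration oracle", {
    # diamond: one effector, all four nodes on some path
    dia <- pathwayGraph("dia", data.frame(
        from = c("A", "A", "B", "C"), to = c("B", "C", "D", "D"),
        sign = "activation"))
    cc <- decomposeCircuits(dia)
    expect_length(cc, 1)
    expect_setequal(cc[[1]]@topoOrder, c("A", "B", "C", "D"))
    # two effectors -> two circuits, ordered by effector id
    two <- pathwayGraph("two", data.frame(
        from = c("A", "A"), to = c("C", "B"), sign = "activation"))
    cc2 <- decomposeCircuits(two)
    expect_equal(vapply(cc2, slot, "", "effector"), c("B", "C"))
    # isolated effector node is skipped with a warning
    iso <- pathwayGraph("iso", data.frame(from = "A", to = "B",
                                          sign = "activation"),
                        nodes = data.frame(node = c("A", "B", "X")))
    expect_warning(cci <- decomposeCircuits(iso), "isolated")
    expect_length(cci, 1)
    # random DAGs up to 12 nodes against the brute-force enumerator
    set.seed(31)
    for (i in 1:25) {
        n <- sample(3:12, 1)
        edges <- randomDagEdges(n)
        g <- pathwayGraph("rnd", edges)
        cc <- decomposeCircuits(g)
        for (circ in cc)
            expect_equal(sort(circ@topoOrder),
                         pathNodesOracle(edges, g@receptors, circ@effector))
    }
})

test_that("rank rescaling maps to (0,1), averages ties, ignores monotone scale", {
    x <- matrix(c(1, 3, 2, 4), 2)
    expect_equal(rankRescale(x), matrix(c(0.2, 0.6, 0.4, 0.8), 2))
    expect_true(all(rankRescale(matrix(5, 3, 3)) == 0.5))
    y <- matrix(rlnorm(30), 5)
    expect_equal(rankRescale(y), rankRescale(log(y)))
    expect_true(all(rankRescale(y) > 0 & rankRescale(y) < 1))
    expect_error(rankRescale(matrix(c(1, NA), 1)), "NA")
    # per-gene mode ranks each row against itself
    pg <- rankRescale(matrix(c(10, 20, 30, 1, 2, 3), 2, byrow = TRUE),
                      perGene = TRUE)
    expect_equal(pg[1, ], pg[2, ])
})

test_that("node values average member genes and demand presence", {
    g <- pathwayGraph("m", data.frame(from = "A", to = "B",
                                      sign = "activation"),
                      nodeGenes = list(A = c("g1", "g2"), B = "g3"))
    cc <- decomposeCircuits(g)[[1]]
    expr <- matrix(c(0.2, 0.8, 0.7), 3, 1, dimnames = list(c("g1", "g2", "g3"),
                                                           "s1"))
    nv <- nodeValues(cc, expr)
    expect_equal(nv["A", "s1"], 0.5)
    expect_equal(nv["B", "s1"], 0.7)
    expect_error(nodeValues(cc, expr[1:2, , drop = FALSE]), "g3")
})

test_that("propagation matches hand evaluation and the recursive oracle", {
    chain <- pathwayGraph("ch", data.frame(from = "A", to = "B",
                                           sign = "activation"))
    cc <- decomposeCircuits(chain)[[1]]
    expr <- cbind(s = c(A = 0.5, B = 1 - 1e-9))
    expect_equal(unname(circuitActivity(cc, expr)["s"]), 0.5,
                 tolerance = 1e-6)
    # pure chains give the product of node values
    chain3 <- pathwayGraph("c3", data.frame(from = c("A", "B"),
                                            to = c("B", "C"),
                                            sign = "activation"))
    cc3 <- decomposeCircuits(chain3)[[1]]
    v <- c(A = 0.3, B = 0.6, C = 0.9)
    expect_equal(unname(circuitActivity(cc3, cbind(s = v))["s"]),
                 prod(v), tolerance = 1e-12)
    # a zero-capacity node on the only path annihilates the signal
    v0 <- c(A = 0.3, B = 0, C = 0.9)
    expect_equal(unname(circuitActivity(cc3, cbind(s = v0))["s"]), 1e-12)
    # saturation is clipped into the open interval
    v1 <- c(A = 1, B = 1, C = 1)
    expect_equal(unname(circuitActivity(cc3, cbind(s = v1))["s"]), 1 - 1e-12)
    # random DAGs against the memoised recursive oracle
    set.seed(13)
    for (i in 1:25) {
        n <- sample(3:12, 1)
        edges <- randomDagEdges(n)
        g <- pathwayGraph("rnd", edges)
        vals <- setNames(runif(n), paste0("n", seq_len(n)))
        for (circ in decomposeCircuits(g)) {
            sub <- igraph::as_data_frame(circ@graph, what = "edges")
            got <- circuitActivity(circ, cbind(s = vals))
            expect_equal(unname(got["s"]),
                         propagateOracle(sub, as.list(vals), circ@effector),
                         tolerance = 1e-12)
        }
    }
})

test_that("activity is monotone in activator values and antitone in inhibitors", {
    # sign of influence of a node on the effector: (-1)^(inhibition edges)
    # along each path; uniform parity over all paths gives a definite
    # direction, mixed parity is skipped
    pathParity <- function(edges, nd, effector) {
        parities <- integer()
        walk <- function(node, inh) {
            if (node == effector) {
                parities <<- c(parities, inh %% 2L)
                return(invisible())
            }
            out <- edges[edges$from == node, , drop = FALSE]
            for (k in seq_len(nrow(out)))
                walk(out$to[k], inh + (out$sign[k] == "inhibition"))
        }
        walk(nd, 0L)
        unique(parities)
    }
    set.seed(17)
    for (i in 1:15) {
        n <- sample(4:10, 1)
        edges <- randomDagEdges(n)
        g <- pathwayGraph("rnd", edges)
        vals <- setNames(runif(n, 0.2, 0.8), paste0("n", seq_len(n)))
        for (circ in decomposeCircuits(g)) {
            sub <- igraph::as_data_frame(circ@graph, what = "edges")
            base <- circuitActivity(circ, cbind(s = vals))[["s"]]
            for (nd in circ@topoOrder) {
                up <- vals
                up[nd] <- min(up[nd] + 0.15, 0.99)
                newAct <- circuitActivity(circ, cbind(s = up))[["s"]]
                par <- pathParity(sub, nd, circ@effector)
                if (identical(par, 0L)) {
                    expect_gte(newAct, base - 1e-12)
                } else if (identical(par, 1L)) {
                    expect_lte(newAct, base + 1e-12)
                }
            }
        }
    }
})

test_that("activity matrices carry labels, circuits and open-interval values", {
    pw <- simPathways(nPathways = 2, nNodes = 6, seed = 3)
    genes <- unique(unlist(lapply(pw$graphs, slot, "nodeGenes")))
    expr <- rankRescale(simExpression(genes, 4, seed = 4))
    ads <- activityMatrix(pw$graphs, expr, rep(c("a", "b"), 2))
    expect_s4_class(ads, "ActivityDataset")
    a <- activityValues(ads)
    expect_equal(ncol(a), 4)
    expect_equal(nrow(a), nrow(pw$truth))
    expect_true(all(a > 0 & a < 1))
    expect_equal(groupLabels(ads), rep(c("a", "b"), 2))
    # duplicate sample columns give identical activity columns
    expr2 <- expr[, c(1, 1)]
    colnames(expr2) <- c("s1", "s2")
    a2 <- activityValues(activityMatrix(pw$graphs, expr2, c("a", "a")))
    expect_equal(unname(a2[, 1]), unname(a2[, 2]))
    expect_error(activityMatrix(list(), expr, rep("a", 4)), "no circuits")
})
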