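test_that("moderated t reduces exactly to the classical t without shrinkage", {
    set.seed(1)
    a <- matrix(plogis(rnorm(60)), 6, 10,
                dimnames = list(paste0("c", 1:6), paste0("s", 1:10)))
    grp <- rep(c("g1", "g2"), each = 5)
    mt <- moderatedT(a, grp, shrink = FALSE, logit = TRUE)
    for (i in 1:6) {
        ct <- t.test(qlogis(a[i, grp == "g2"]), qlogis(a[i, grp == "g1"]),
                     var.equal = TRUE)
        expect_equal(mt$t[i], unname(ct$statistic), tolerance = 1e-12)
        expect_equal(mt$p[i], ct$p.value, tolerance = 1e-12)
        expect_equal(mt$logFC[i],
                     mean(qlogis(a[i, grp == "g2"])) -
                         mean(qlogis(a[i, grp == "g1"])),
                     tolerance = 1e-12)
    }
})

test_that("shrinkage matches the empirical-Bayes reference implementation", {
    skip_if_not_installed("limma")
    set.seed(2)
    a <- matrix(plogis(rnorm(400, sd = rep(runif(40, 0.5, 2), each = 10))),
                40, 10, dimnames = list(paste0("c", 1:40), paste0("s", 1:10)))
    grp <- rep(c("g1", "g2"), each = 5)
    mt <- moderatedT(a, grp, shrink = TRUE, logit = TRUE)
    design <- cbind(1, grp == "g2")
    fit <- limma::eBayes(limma::lmFit(qlogis(a), design))
    prior <- attr(mt, "prior")
    expect_equal(prior$d0, fit$df.prior, tolerance = 1e-6)
    expect_equal(prior$s02, fit$s2.prior, tolerance = 1e-6)
    expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("full shrinkage limit pools variances when dispersion is flat", {
    # equal residual variances across many circuits: the moment estimator
    # finds no excess dispersion, d0 = Inf and s2post = s02 for every circuit
    set.seed(3)
    base <- rnorm(10)
    a <- plogis(t(vapply(1:50, function(i) base + rnorm(10, sd = 1e-3),
                         numeric(10))))
    rownames(a) <- paste0("c", 1:50)
    mt <- moderatedT(a, rep(c("g1", "g2"), each = 5))
    prior <- attr(mt, "prior")
    if (is.infinite(prior$d0)) expect_true(is.finite(prior$s02))
    expect_true(prior$d0 > 50)  # heavy pooling at minimum
})

test_that("moderated t holds its size on null circuits", {
    set.seed(4)
    a <- matrix(plogis(rnorm(2000)), 200, 10,
                dimnames = list(paste0("c", 1:200), NULL))
    mt <- moderatedT(a, rep(c("g1", "g2"), each = 5))
    rate <- mean(mt$p < 0.05)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
    expect_error(moderatedT(a[, 1:3], c("g1", "g1", "g2")),
                 "at least two samples")
})

test_that("BH adjustment equals the hand step-up oracle and its properties", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(5)
    for (i in 1:20) {
        p <- runif(sample(1:50, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bhOracle(p), tolerance = 1e-12)
        # monotone: adjusted values never cross the raw ordering
        expect_false(is.unsorted(adj[order(p)]))
        expect_true(all(adj >= p))
    }
})

test_that("Fisher combination matches the chi-square closed form", {
    expect_equal(fisherCombine(1), 1)
    expect_equal(fisherCombine(0.3), 0.3, tolerance = 1e-12)
    expect_equal(fisherCombine(rep(1, 5)), 1)
    expect_equal(fisherCombine(c(0.1, 0.1)),
                 pchisq(-4 * log(0.1), df = 4, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(round(fisherCombine(c(0.1, 0.1)), 4), 0.0561)
    for (k in c(1, 2, 5, 50))
        expect_equal(fisherCombine(rep(0.2, k)),
                     pchisq(-2 * k * log(0.2), df = 2 * k,
                            lower.tail = FALSE), tolerance = 1e-12)
    expect_warning(out <- fisherCombine(c(0, 0.5)), "floored")
    expect_lt(out, 1e-100)
})

test_that("bootstrap summary applies the selection and concordance rules", {
    summarise <- melDivergent:::.summariseBootstrap
    B <- 50
    padj <- rbind(strong = rep(1e-6, B), null = runif(B, 0.5, 1),
                  discord = rep(1e-6, B))
    sgn <- rbind(strong = rep(1, B), null = sign(rnorm(B)),
                 discord = c(rep(1, 34), rep(-1, 16)))
    lfc <- sgn * 0.5
    res <- summarise(padj, sgn, lfc, lfc, diffConfig())
    expect_true(res["strong", "selected"])
    expect_equal(res["strong", "direction"], "up")
    expect_false(res["null", "selected"])
    # 34/50 concordance misses the 70% bar even at tiny p
    expect_equal(res["discord", "concordance"], 0.68)
    expect_false(res["discord", "selected"])
    # 35/50 = 70% exactly passes
    sgn["discord", ] <- c(rep(-1, 35), rep(1, 15))
    res2 <- summarise(padj, sgn, lfc, lfc, diffConfig())
    expect_true(res2["discord", "selected"])
    expect_equal(res2["discord", "direction"], "down")
})

test_that("bootstrap diff recovers a planted inhibitor knockdown", {
    g <- inhibitorPathway()
    expr <- simExpression(c("GR", "GM", "GE", "NF1"), 20, seed = 5)
    coh <- tinyCohort(pCsd = 0.9, n = 10, seed = 3)
    res <- bootstrapDiff(coh, expr, list(g),
                         comparison = c("nevogenic", "CSD"),
                         config = diffConfig(nBootstrap = 50), seed = 101)
    expect_true(res$selected[1])
    expect_equal(res$direction[1], "up")
    expect_gt(res$logFC[1], 0)
    # byte-identical rerun at the same seed
    res2 <- bootstrapDiff(coh, expr, list(g),
                          comparison = c("nevogenic", "CSD"),
                          config = diffConfig(nBootstrap = 50), seed = 101)
    expect_identical(res, res2)
})

test_that("bootstrap diff stays quiet on exchangeable groups", {
    pw <- simPathways(nPathways = 10, nNodes = 6, seed = 31)
    genes <- unique(unlist(lapply(pw$graphs, slot, "nodeGenes")))
    expr <- simExpression(genes, 25, seed = 32)
    coh <- tinyCohort(gene = "ZZZ_unused", pNev = 0, pCsd = 0, n = 8,
                      seed = 33)
    res <- bootstrapDiff(coh, expr, pw$graphs,
                         comparison = c("nevogenic", "CSD"),
                         config = diffConfig(nBootstrap = 25), seed = 34)
    expect_lte(mean(res$selected), 0.07)
})
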