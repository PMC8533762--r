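test_that("variant filtering keeps strictly-above-VAF pathogenic-class calls", {
    v <- data.frame(
        tumor_id = c("t1", "t1", "t2", "t2", "t3"),
        gene = c("BRAF", "NF1", "TP53", "RAC1", "TERTp"),
        vaf = c(0.04, 0.30, 0.30, 0.051, 0.05),
        pathogenicity = c("pathogenic", "benign", "likely_pathogenic",
                          "predicted_pathogenic", "pathogenic"))
    out <- filterVariants(v)
    # 0.04 fails VAF, benign fails class, 0.05 is not strictly above
    expect_equal(out$gene, c("TP53", "RAC1"))
    # order preserved and idempotent
    expect_equal(filterVariants(out)$gene, out$gene)
})

test_that("calls in unknown genes are rejected loudly, not dropped silently", {
    v <- data.frame(tumor_id = "t1", gene = c("BRAF", "MYC"),
                    vaf = c(0.3, 0.3), pathogenicity = "pathogenic")
    expect_warning(out <- filterVariants(v), "MYC")
    expect_equal(out$gene, "BRAF")
    expect_equal(attr(out, "rejected")$gene, "MYC")
    expect_error(filterVariants(transform(v, vaf = c(0.3, 1.3))), "vaf")
    expect_error(
        filterVariants(data.frame(tumor_id = "t1", gene = "BRAF", vaf = 0.3,
                                  pathogenicity = "damaging")),
        "pathogenicity")
})

test_that("etiopathogenic classification applies strict nevus/elastosis rules", {
    g <- classifyGroup(c(60, 10, 35, 50, 20, 10, 60, NA),
                       c("0", "2", "1", "0", "2", "1+", "3+", "2"))
    expect_equal(as.character(g),
                 c("nevogenic", "CSD", "unclassifiable",
                   "unclassifiable",  # nevi = 50 is not > 50
                   "unclassifiable",  # nevi = 20 is not < 20
                   "unclassifiable",  # mild elastosis never qualifies
                   "unclassifiable",  # many nevi but severe elastosis
                   "unclassifiable"))
    expect_equal(attr(g, "reason")[8], "missing_fields")
    expect_equal(attr(g, "reason")[3], "rule_not_met")
    # total and deterministic; nevogenic and CSD mutually exclusive
    grid <- expand.grid(nevi = c(0, 19, 20, 21, 50, 51, 200),
                        band = c("0", "1", "2", "3"))
    lab <- classifyGroup(grid$nevi, grid$band)
    expect_false(any(is.na(lab)))
    expect_identical(lab, classifyGroup(grid$nevi, grid$band))
})

test_that("elastosis grades collapse into the four severity bands", {
    b <- elastosisBand(c("0", "1-", "1", "1+", "2-", "2", "2+", "3-", "3",
                         "3+", "bogus", NA))
    expect_equal(as.character(b)[1:10],
                 rep(c("none", "mild", "moderate", "severe"),
                     c(1, 3, 3, 3)))
    expect_true(all(is.na(b[11:12])))
    expect_equal(as.character(elastosisBand(c(0, 2))), c("none", "moderate"))
})

test_that("subtype classification handles singles, overlaps and 3wt", {
    genes <- c("BRAF", "NRAS", "HRAS", "KRAS", "NF1")
    m <- matrix(0L, 6, 5, dimnames = list(paste0("t", 1:6), genes))
    m[2, "BRAF"] <- 1L
    m[3, "HRAS"] <- 1L
    m[4, c("BRAF", "NF1")] <- 1L
    m[5, c("BRAF", "NRAS", "NF1")] <- 1L
    m[6, "NF1"] <- 1L
    expect_equal(as.character(classifySubtype(m)),
                 c("3wt", "BRAF+", "RAS+", "BRAF+NF1+", "BRAF+RAS+NF1+",
                   "NF1+"))
    expect_error(classifySubtype(m[, -5]), "NF1")
    m[1, "BRAF"] <- NA
    expect_error(classifySubtype(m), "t1")
})

test_that("subtype labels always partition the cohort", {
    set.seed(42)
    genes <- c("BRAF", "NRAS", "HRAS", "KRAS", "NF1")
    for (rep in 1:20) {
        m <- matrix(rbinom(40L * 5L, 1L, 0.3), 40L,
                    dimnames = list(sprintf("t%02d", 1:40), genes))
        st <- classifySubtype(m)
        expect_equal(sum(table(st)), 40L)
        # marginal consistency: singles plus overlap labels recover each
        # driver marginal
        nBraf <- sum(grepl("BRAF", st))
        expect_equal(nBraf, sum(m[, "BRAF"]))
        nRas <- sum(grepl("RAS\\+", st) & !grepl("NRAS", st))
        expect_equal(nRas, sum(rowSums(m[, c("NRAS", "HRAS", "KRAS")]) > 0))
    }
})

test_that("marginal fixture reproduces supplied counts and overlaps exactly", {
    fix <- cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
                               seed = 11)
    m <- mutationStatus(fix)
    grp <- patientInfo(fix)$group
    marg <- melanomaMarginals()
    for (i in seq_len(nrow(marg))) {
        g <- marg$gene[i]
        expect_equal(sum(m[grp == "nevogenic", g] == 1L, na.rm = TRUE),
                     marg$nev[i], info = g)
        expect_equal(sum(m[grp == "CSD", g] == 1L, na.rm = TRUE),
                     marg$csd[i], info = g)
    }
    expect_equal(sum(m[, "BRAF"]), 60L)
    ras <- rowSums(m[, c("NRAS", "HRAS", "KRAS")]) > 0
    expect_equal(sum(m[, "BRAF"] & ras & !m[, "NF1"]), 3)
    expect_equal(sum(m[, "BRAF"] & m[, "NF1"] & !ras), 9)
    expect_equal(sum(ras & m[, "NF1"] & !m[, "BRAF"]), 1)
    expect_equal(sum(is.na(m[, "TERTp"])), 6L)
    # metadata is consistent with the group rule
    expect_equal(as.character(classifyGroup(patientInfo(fix)$nevus_count,
                                            patientInfo(fix)$elastosis_grade)),
                 as.character(grp))
})

test_that("marginal fixture is deterministic per seed and flags infeasibility", {
    f1 <- cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
                              seed = 5)
    f2 <- cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
                              seed = 5)
    expect_identical(mutationStatus(f1), mutationStatus(f2))
    # all-zero marginals give an all-zero matrix
    zero <- data.frame(gene = c("BRAF", "NRAS", "HRAS", "KRAS", "NF1"),
                       nev = 0L, csd = 0L)
    fz <- cohortFromMarginals(zero, NULL, nNev = 4, nCsd = 4, seed = 1)
    expect_true(all(mutationStatus(fz) == 0L))
    # overlap exceeding a marginal names the violated constraint
    small <- data.frame(gene = c("BRAF", "NRAS", "HRAS", "KRAS", "NF1"),
                        nev = c(3L, 1L, 0L, 0L, 2L),
                        csd = c(0L, 0L, 0L, 0L, 0L))
    expect_error(cohortFromMarginals(small, c("BRAF:NF1" = 5L),
                                     nNev = 10, nCsd = 10),
                 "exceed the BRAF marginal")
})

test_that("cohort tables round-trip through TSV", {
    fix <- cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
                               seed = 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCohortTable(fix, path)
    back <- readCohortTable(path)
    expect_identical(mutationStatus(back), mutationStatus(fix))
    expect_equal(as.character(patientInfo(back)$group),
                 as.character(patientInfo(fix)$group))
})

test_that("status matrices can be built from variant calls", {
    v <- data.frame(tumor_id = c("t1", "t1", "t2"),
                    gene = c("BRAF", "BRAF", "NF1"),
                    vaf = 0.3, pathogenicity = "pathogenic")
    gsm <- geneStatusMatrix(variants = v, tumors = c("t1", "t2", "t3"))
    m <- mutationStatus(gsm)
    expect_equal(m["t1", "BRAF"], 1L)  # two calls still score 1
    expect_equal(m["t2", "NF1"], 1L)
    expect_equal(sum(m), 2L)
    expect_error(geneStatusMatrix(variants = v, tumors = "t1"), "t2")
})
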