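#' Reference-cohort marginal mutation counts
#'
#' Per-gene mutated-tumor counts, by etiopathogenic group, for the reference
#' cohort of 119 cutaneous melanomas (82 nevogenic, 37 CSD) that this package
#' models. TERT-promoter status is informative in 113 tumors; the six
#' uninformative tumors are split 3/3 across groups so that the group row
#' sums match the published table.
#'
#' @return data.frame with columns gene, nev, csd, na_nev, na_csd.
#' @seealso [melanomaCohortFixture()]
#' @export
melanomaMarginals <- function() {
    df <- data.frame(
        gene = c("TP53", "NF1", "BRAF", "ROS1", "NRAS", "CDK4", "ARID2",
                 "CDKN2A", "KIT", "RB1", "PPP6C", "PTEN", "IDH1", "GNA11",
                 "GNAQ", "RAC1", "KRAS", "HRAS", "MAP2K2", "PIK3CA",
                 "PIK3R1", "TERTp"),
        nev = c(6L, 6L, 46L, 4L, 12L, 3L, 5L, 6L, 2L, 3L, 3L, 2L, 4L, 1L,
                0L, 1L, 1L, 1L, 0L, 0L, 2L, 38L),
        csd = c(7L, 14L, 14L, 10L, 4L, 1L, 6L, 3L, 3L, 2L, 1L, 1L, 2L, 4L,
                1L, 6L, 0L, 1L, 2L, 1L, 3L, 21L),
        na_nev = 0L, na_csd = 0L)
    df[df$gene == "TERTp", c("na_nev", "na_csd")] <- 3L
    df
}

#' Reference-cohort driver overlap counts
#'
#' Counts of tumors mutated in two driver classes simultaneously: 3 BRAF+RAS,
#' 9 BRAF+NF1, 1 RAS+NF1 (no triple overlap).
#'
#' @return Named integer vector.
#' @export
melanomaOverlaps <- function() {
    c("BRAF:RAS" = 3L, "BRAF:NF1" = 9L, "RAS:NF1" = 1L)
}

.rasDefault <- c("NRAS", "HRAS", "KRAS")

## Split global driver-overlap counts across the two groups so that every
## per-group driver marginal stays satisfiable; first feasible split in
## lexicographic order (deterministic). Returns a list with per-group counts
## or NULL when infeasible.
.splitOverlaps <- function(mB, mR, mN, X_BR, X_BN, X_RN, Tt, nGrp) {
    for (t1 in 0:Tt) for (br1 in 0:X_BR) for (bn1 in 0:X_BN)
        for (rn1 in 0:X_RN) {
            part <- list(c(t1, br1, bn1, rn1),
                         c(Tt - t1, X_BR - br1, X_BN - bn1, X_RN - rn1))
            ok <- TRUE
            for (g in 1:2) {
                t0 <- part[[g]][1]; br <- part[[g]][2]
                bn <- part[[g]][3]; rn <- part[[g]][4]
                sB <- mB[g] - br - bn - t0
                sR <- mR[g] - br - rn - t0
                sN <- mN[g] - bn - rn - t0
                if (sB < 0 || sR < 0 || sN < 0 ||
                    sB + sR + sN + t0 + br + bn + rn > nGrp[g]) {
                    ok <- FALSE; break
                }
            }
            if (ok) return(part)
        }
    NULL
}

#' Reconstruct a patient-level cohort from marginal counts
#'
#' Builds a driver-status fixture consistent with printed per-gene,
#' per-group mutation counts and global pairwise driver-overlap counts.
#' Overlap patients are assigned first, then single-driver patients; the
#' remaining tumors are driver wild type. RAS-family genes go to distinct
#' patients (their per-group counts sum to the RAS-mutated patient count).
#' Non-driver genes are filled group-wise by exact count, assigned to
#' randomly chosen patients independently per gene; per-gene NA counts (e.g.
#' uninformative TERT-promoter assays) are likewise drawn at random. The
#' result reproduces every supplied marginal and overlap exactly and is
#' deterministic for a fixed seed.
#'
#' @param perGene data.frame with columns gene, nev, csd and optional
#'   na_nev, na_csd (counts of missing-status tumors per group).
#' @param overlaps Named vector of pairwise driver-overlap counts with names
#'   among \code{"BRAF:RAS"}, \code{"BRAF:NF1"}, \code{"RAS:NF1"} and
#'   optionally \code{"BRAF:RAS:NF1"}.
#' @param nNev,nCsd Group sizes.
#' @param rules [classificationRules()]; supplies the RAS gene set.
#' @param seed Integer seed for the random fills.
#' @return A \linkS4class{GeneStatusMatrix} with patient metadata (nevus
#'   counts and elastosis grades consistent with each group's rule).
#' @examples
#' fix <- cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
#'                            seed = 1)
#' table(classifySubtype(fix))
#' @export
cohortFromMarginals <- function(perGene, overlaps = NULL, nNev = 82L,
                                nCsd = 37L, rules = classificationRules(),
                                seed = NULL) {
    stopifnot(all(c("gene", "nev", "csd") %in% names(perGene)))
    if (is.null(overlaps)) overlaps <- c("BRAF:RAS" = 0L)
    okNames <- c("BRAF:RAS", "BRAF:NF1", "RAS:NF1", "BRAF:RAS:NF1")
    if (!all(names(overlaps) %in% okNames))
        stop("unknown overlap name(s): ",
             paste(setdiff(names(overlaps), okNames), collapse = ", "))
    ov <- function(k) if (k %in% names(overlaps)) as.integer(overlaps[[k]]) else 0L
    X_BR <- ov("BRAF:RAS"); X_BN <- ov("BRAF:NF1")
    X_RN <- ov("RAS:NF1"); Tt <- ov("BRAF:RAS:NF1")
    if (!"na_nev" %in% names(perGene)) perGene$na_nev <- 0L
    if (!"na_csd" %in% names(perGene)) perGene$na_csd <- 0L
    rownames(perGene) <- perGene$gene
    cnt <- function(g, col) if (g %in% perGene$gene) perGene[g, col] else 0L

    rasGenes <- rules$rasGenes
    nGrp <- c(nNev, nCsd)
    mB <- c(cnt("BRAF", "nev"), cnt("BRAF", "csd"))
    mN <- c(cnt("NF1", "nev"), cnt("NF1", "csd"))
    mR <- sapply(c("nev", "csd"),
                 function(cl) sum(vapply(rasGenes, cnt, 0L, col = cl)))

    if (X_BR + X_BN + Tt > sum(mB))
        stop("infeasible marginals: BRAF overlaps (", X_BR + X_BN + Tt,
             ") exceed the BRAF marginal (", sum(mB), ")")
    if (X_BR + X_RN + Tt > sum(mR))
        stop("infeasible marginals: RAS overlaps (", X_BR + X_RN + Tt,
             ") exceed the RAS marginal (", sum(mR), ")")
    if (X_BN + X_RN + Tt > sum(mN))
        stop("infeasible marginals: NF1 overlaps (", X_BN + X_RN + Tt,
             ") exceed the NF1 marginal (", sum(mN), ")")
    for (g in seq_len(nrow(perGene)))
        if (perGene$nev[g] + perGene$na_nev[g] > nNev ||
            perGene$csd[g] + perGene$na_csd[g] > nCsd)
            stop("infeasible marginals: ", perGene$gene[g],
                 " counts exceed a group size")

    split <- .splitOverlaps(mB, mR, mN, X_BR, X_BN, X_RN, Tt, nGrp)
    if (is.null(split))
        stop("infeasible marginals: driver overlap counts cannot be placed ",
             "within the per-group driver marginals")

    genes <- perGene$gene
    tumors <- sprintf("MEL%03d", seq_len(nNev + nCsd))
    status <- matrix(0L, length(tumors), length(genes),
                     dimnames = list(tumors, genes))
    groupIdx <- list(seq_len(nNev), nNev + seq_len(nCsd))

    for (g in 1:2) {
        idx <- groupIdx[[g]]
        t0 <- split[[g]][1]; br <- split[[g]][2]
        bn <- split[[g]][3]; rn <- split[[g]][4]
        sB <- mB[g] - br - bn - t0
        sR <- mR[g] - br - rn - t0
        sN <- mN[g] - bn - rn - t0
        cln <- c("nev", "csd")[g]
        rasSeq <- rep(rasGenes, times = vapply(rasGenes, cnt, 0L, col = cln))
        p <- 0L; rp <- 0L
        take <- function(k) { out <- idx[p + seq_len(k)]; p <<- p + k; out }
        takeRas <- function(k) { out <- rasSeq[rp + seq_len(k)]; rp <<- rp + k; out }
        i <- take(t0)
        status[i, "BRAF"] <- 1L; status[i, "NF1"] <- 1L
        status[cbind(i, match(takeRas(t0), genes))] <- 1L
        i <- take(br)
        status[i, "BRAF"] <- 1L
        status[cbind(i, match(takeRas(br), genes))] <- 1L
        i <- take(bn)
        status[i, "BRAF"] <- 1L; status[i, "NF1"] <- 1L
        i <- take(rn)
        status[i, "NF1"] <- 1L
        status[cbind(i, match(takeRas(rn), genes))] <- 1L
        status[take(sB), "BRAF"] <- 1L
        i <- take(sR)
        status[cbind(i, match(takeRas(sR), genes))] <- 1L
        status[take(sN), "NF1"] <- 1L
    }

    driver <- c("BRAF", "NF1", rasGenes)
    pd <- NULL
    withSeed(seed, {
        for (g in 1:2) {
            idx <- groupIdx[[g]]
            cln <- c("nev", "csd")[g]
            naCln <- c("na_nev", "na_csd")[g]
            for (gene in setdiff(genes, driver)) {
                nNA <- perGene[gene, naCln]
                nMut <- perGene[gene, cln]
                naIdx <- if (nNA > 0) sample(idx, nNA) else integer()
                status[naIdx, gene] <- NA
                status[sample(setdiff(idx, naIdx), nMut), gene] <- 1L
            }
        }
        nevi <- c(sample(51:150, nNev, replace = TRUE),
                  sample(0:19, nCsd, replace = TRUE))
        elast <- c(rep("0", nNev),
                   sample(c("2-", "2", "2+", "3-", "3", "3+"), nCsd,
                          replace = TRUE))
        pd <- data.frame(tumor_id = tumors, nevus_count = nevi,
                          elastosis_grade = elast,
                          group = rep(c("nevogenic", "CSD"), c(nNev, nCsd)),
                          row.names = tumors)
    })

    ## self-check: the fixture must reproduce every supplied count exactly
    for (g in 1:2) {
        idx <- groupIdx[[g]]
        got <- colSums(status[idx, , drop = FALSE] == 1L, na.rm = TRUE)
        want <- perGene[[c("nev", "csd")[g]]]
        stopifnot(identical(as.integer(got), as.integer(want)))
    }
    stopifnot(sum(status[, "BRAF"] & rowSums(status[, rasGenes, drop = FALSE]) > 0 &
                  !status[, "NF1"]) == X_BR,
              sum(status[, "BRAF"] & status[, "NF1"] &
                  rowSums(status[, rasGenes, drop = FALSE]) == 0) == X_BN)

    geneStatusMatrix(status = status, patientData = pd, genes = genes)
}

#' The built-in 119-patient reference cohort fixture
#'
#' Convenience wrapper: [cohortFromMarginals()] applied to
#' [melanomaMarginals()] and [melanomaOverlaps()] with group sizes 82
#' (nevogenic) and 37 (CSD).
#'
#' @param seed Integer seed for the random non-driver fills.
#' @return A \linkS4class{GeneStatusMatrix}.
#' @export
melanomaCohortFixture <- function(seed = 1L) {
    cohortFromMarginals(melanomaMarginals(), melanomaOverlaps(),
                        nNev = 82L, nCsd = 37L, seed = seed)
}
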