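#' The 21-gene melanoma sequencing panel
#'
#' Coding regions of 21 genes recurrently mutated in melanomagenesis; the TERT
#' promoter (\code{"TERTp"}, assayed separately) is carried alongside the
#' panel in status matrices but never enters subtype classification.
#'
#' @format Character vector of gene symbols.
#' @export
melanomaPanel <- c("ARID2", "BRAF", "CDK4", "CDKN2A", "GNA11", "GNAQ", "HRAS",
                   "IDH1", "KIT", "KRAS", "MAP2K2", "NF1", "NRAS", "PIK3CA",
                   "PIK3R1", "PPP6C", "PTEN", "RAC1", "RB1", "ROS1", "TP53")

.tertp <- "TERTp"
.elastosisLabels <- c("0", "1-", "1", "1+", "2-", "2", "2+", "3-", "3", "3+")
.elastosisBands <- c("none", "mild", "moderate", "severe")

#' Collapse solar-elastosis grades into severity bands
#'
#' Solar elastosis on the skin surrounding the tumor is graded on an
#' 11-degree scale spanning 0 to 3+. Grades are collapsed into four bands:
#' 0 = none, 1-/1/1+ = mild, 2-/2/2+ = moderate, 3-/3/3+ = severe.
#' Bare integers 0..3 are accepted as shorthand for 0, 1, 2, 3.
#'
#' @param grade Character (or numeric 0..3) vector of grades.
#' @return Ordered factor with levels none < mild < moderate < severe;
#'   unknown or missing grades give NA.
#' @export
elastosisBand <- function(grade) {
    g <- trimws(as.character(grade))
    base <- substr(g, 1L, 1L)
    band <- rep(NA_character_, length(g))
    known <- g %in% .elastosisLabels & base %in% c("0", "1", "2", "3")
    band[known] <- .elastosisBands[as.integer(base[known]) + 1L]
    factor(band, levels = .elastosisBands, ordered = TRUE)
}

#' Etiopathogenic classification rules
#'
#' Thresholds of the two mutually exclusive etiopathogenic groups: nevogenic
#' tumors arise in patients with more than \code{nevogenicMinNevi} melanocytic
#' nevi and no solar elastosis; chronic sun damage (CSD) tumors in patients
#' with fewer than \code{csdMaxNevi} nevi and at least
#' \code{csdMinElastosis} elastosis. Boundary counts (exactly 50 or 20 nevi)
#' satisfy neither strict inequality and are unclassifiable.
#'
#' @param nevogenicMinNevi Exclusive lower nevus bound for nevogenic (50).
#' @param csdMaxNevi Exclusive upper nevus bound for CSD (20).
#' @param csdMinElastosis Minimum elastosis band for CSD ("moderate").
#' @param rasGenes RAS-family genes pooled into the RAS+ subtype.
#' @return A list of class \code{"ClassificationRules"}.
#' @export
classificationRules <- function(nevogenicMinNevi = 50L, csdMaxNevi = 20L,
                                csdMinElastosis = "moderate",
                                rasGenes = c("NRAS", "HRAS", "KRAS")) {
    stopifnot(nevogenicMinNevi > csdMaxNevi,
              csdMinElastosis %in% .elastosisBands)
    structure(list(nevogenicMinNevi = nevogenicMinNevi,
                   csdMaxNevi = csdMaxNevi,
                   csdMinElastosis = csdMinElastosis,
                   rasGenes = rasGenes),
              class = "ClassificationRules")
}

#' Classify patients into etiopathogenic groups
#'
#' Applies the divergent-pathway rule: nevogenic iff nevus count strictly
#' above the nevogenic threshold and no elastosis; CSD iff nevus count
#' strictly below the CSD threshold and moderate-to-severe elastosis;
#' everything else (including missing fields) is unclassifiable.
#'
#' @param nevusCount Integer vector of total melanocytic nevus counts.
#' @param elastosis Elastosis grades (see [elastosisBand()]) or an already
#'   banded factor.
#' @param rules A [classificationRules()] list.
#' @return Factor with levels nevogenic, CSD, unclassifiable and an attribute
#'   \code{"reason"} coding why a patient was unclassifiable
#'   (\code{"missing_fields"} or \code{"rule_not_met"}).
#' @examples
#' classifyGroup(c(60, 10, 35), c("0", "2", "1"))
#' @export
classifyGroup <- function(nevusCount, elastosis, rules = classificationRules()) {
    band <- if (is.factor(elastosis) && all(levels(elastosis) == .elastosisBands))
        elastosis else elastosisBand(elastosis)
    n <- length(nevusCount)
    stopifnot(length(band) == n)
    minBand <- match(rules$csdMinElastosis, .elastosisBands)
    out <- rep("unclassifiable", n)
    reason <- rep(NA_character_, n)
    missing <- is.na(nevusCount) | is.na(band)
    reason[missing] <- "missing_fields"
    nev <- !missing & nevusCount > rules$nevogenicMinNevi & band == "none"
    csd <- !missing & nevusCount < rules$csdMaxNevi &
        as.integer(band) >= minBand
    out[nev] <- "nevogenic"
    out[csd] <- "CSD"
    reason[!missing & !nev & !csd] <- "rule_not_met"
    structure(factor(out, levels = c("nevogenic", "CSD", "unclassifiable")),
              reason = reason)
}

.subtypeLevels <- c("BRAF+", "RAS+", "NF1+", "3wt", "BRAF+RAS+", "BRAF+NF1+",
                    "RAS+NF1+", "BRAF+RAS+NF1+")
.overlapLevels <- c("BRAF+RAS+", "BRAF+NF1+", "RAS+NF1+", "BRAF+RAS+NF1+")

#' Classify tumors into molecular subtypes
#'
#' Mutually exclusive driver subtypes: BRAF+ (BRAF mutated), RAS+ (any of the
#' RAS-family genes), NF1+ (NF1), 3wt (none of the three). Tumors mutated in
#' more than one driver class get a concatenated overlap label
#' (e.g. \code{"BRAF+NF1+"}) and count as having eluded the four-subtype
#' classification.
#'
#' @param status A \linkS4class{GeneStatusMatrix} or a binary status matrix
#'   with at least the BRAF, NRAS, HRAS, KRAS and NF1 columns.
#' @param rules A [classificationRules()] list (for the RAS gene set).
#' @return Factor of subtype labels, one per tumor.
#' @examples
#' m <- matrix(0L, 2, 5, dimnames = list(c("t1", "t2"),
#'             c("BRAF", "NRAS", "HRAS", "KRAS", "NF1")))
#' m["t1", "BRAF"] <- 1L
#' classifySubtype(m)
#' @export
classifySubtype <- function(status, rules = classificationRules()) {
    m <- if (is(status, "GeneStatusMatrix")) mutationStatus(status) else status
    need <- c("BRAF", rules$rasGenes, "NF1")
    miss <- setdiff(need, colnames(m))
    if (length(miss))
        stop("status matrix lacks required driver column(s): ",
             paste(miss, collapse = ", "))
    drv <- m[, need, drop = FALSE]
    if (anyNA(drv))
        stop("NA driver status for tumor(s): ",
             paste(rownames(m)[rowSums(is.na(drv)) > 0], collapse = ", "))
    braf <- m[, "BRAF"] == 1L
    ras <- rowSums(m[, rules$rasGenes, drop = FALSE] == 1L) > 0L
    nf1 <- m[, "NF1"] == 1L
    lab <- paste0(ifelse(braf, "BRAF+", ""), ifelse(ras, "RAS+", ""),
                  ifelse(nf1, "NF1+", ""))
    lab[lab == ""] <- "3wt"
    factor(lab, levels = .subtypeLevels)
}

#' Tabulate molecular subtypes
#'
#' Counts and within-cohort percentages per subtype label, with the overlap
#' labels summarised in an \code{"eluded"} attribute (tumors excluded from
#' the four mutually exclusive subtypes).
#'
#' @param subtypes Factor from [classifySubtype()].
#' @return data.frame with columns subtype, n, pct.
#' @export
subtypeTable <- function(subtypes) {
    n <- table(subtypes)
    out <- data.frame(subtype = names(n), n = as.integer(n),
                      pct = roundHalfUp(100 * as.integer(n) / length(subtypes)),
                      row.names = NULL)
    attr(out, "eluded") <- sum(out$n[out$subtype %in% .overlapLevels])
    out
}

#' Variant retention filter settings
#'
#' Variants are retained when their allele frequency strictly exceeds
#' \code{minVaf} and their pathogenicity class is one of the retained classes
#' (pathogenic, likely pathogenic, predicted pathogenic by default).
#'
#' @param minVaf Exclusive lower VAF bound, default 0.05.
#' @param retainedPathogenicity Character vector of retained classes.
#' @return A list of class \code{"VariantFilterConfig"}.
#' @export
variantFilterConfig <- function(minVaf = 0.05,
                                retainedPathogenicity = c("pathogenic",
                                    "likely_pathogenic",
                                    "predicted_pathogenic")) {
    stopifnot(minVaf > 0, minVaf < 1, length(retainedPathogenicity) >= 1)
    structure(list(minVaf = minVaf,
                   retainedPathogenicity = retainedPathogenicity),
              class = "VariantFilterConfig")
}

.pathogenicityClasses <- c("pathogenic", "likely_pathogenic",
                           "predicted_pathogenic", "benign", "vus")

#' Filter variant calls by allele frequency and pathogenicity
#'
#' Keeps calls with VAF strictly above the threshold and a retained
#' pathogenicity class, preserving input order. Calls in genes outside the
#' panel (or TERTp) are rejected with a warning and returned in the
#' \code{"rejected"} attribute rather than silently dropped.
#'
#' @param variants data.frame with columns \code{tumor_id}, \code{gene},
#'   \code{vaf} (fraction in \[0,1\]) and \code{pathogenicity}.
#' @param config A [variantFilterConfig()].
#' @return The retained rows, with attribute \code{"rejected"} holding any
#'   unknown-gene rows.
#' @export
filterVariants <- function(variants, config = variantFilterConfig()) {
    need <- c("tumor_id", "gene", "vaf", "pathogenicity")
    stopifnot(all(need %in% names(variants)))
    if (any(variants$vaf < 0 | variants$vaf > 1, na.rm = TRUE))
        stop("vaf must lie in [0, 1]")
    bad <- !(variants$pathogenicity %in% .pathogenicityClasses)
    if (any(bad))
        stop("unknown pathogenicity class: ",
             paste(unique(variants$pathogenicity[bad]), collapse = ", "))
    known <- variants$gene %in% c(melanomaPanel, .tertp)
    rejected <- variants[!known, , drop = FALSE]
    if (nrow(rejected))
        warning("rejected ", nrow(rejected), " call(s) in gene(s) outside ",
                "the panel: ", paste(unique(rejected$gene), collapse = ", "))
    v <- variants[known, , drop = FALSE]
    keep <- v$vaf > config$minVaf &
        v$pathogenicity %in% config$retainedPathogenicity
    out <- v[keep, , drop = FALSE]
    attr(out, "rejected") <- rejected
    out
}

#' Build a GeneStatusMatrix
#'
#' Either directly from a binary matrix plus patient metadata, or from
#' filtered variant calls (a gene is scored 1 for a tumor when at least one
#' retained call hits it).
#'
#' @param status Binary tumors x genes matrix (entries 0/1/NA), or NULL to
#'   build from \code{variants}.
#' @param patientData data.frame or DataFrame of per-tumor metadata with
#'   rownames (or a \code{tumor_id} column) matching the tumors.
#' @param variants Filtered variant data.frame (see [filterVariants()]).
#' @param tumors Tumor identifiers (required with \code{variants}; defines
#'   row order and includes tumors with no retained calls).
#' @param genes Gene columns, default panel plus TERTp.
#' @return A \linkS4class{GeneStatusMatrix}.
#' @export
geneStatusMatrix <- function(status = NULL, patientData = NULL,
                             variants = NULL, tumors = NULL,
                             genes = c(melanomaPanel, .tertp)) {
    if (is.null(status)) {
        stopifnot(!is.null(variants), !is.null(tumors))
        status <- matrix(0L, length(tumors), length(genes),
                         dimnames = list(tumors, genes))
        unknown <- setdiff(unique(variants$tumor_id), tumors)
        if (length(unknown))
            stop("variant calls for tumors absent from `tumors`: ",
                 paste(unknown, collapse = ", "))
        hit <- unique(variants[, c("tumor_id", "gene")])
        status[cbind(match(hit$tumor_id, tumors),
                     match(hit$gene, genes))] <- 1L
    }
    storage.mode(status) <- "integer"
    if (is.null(patientData))
        patientData <- DataFrame(row.names = rownames(status))
    else {
        patientData <- as(patientData, "DataFrame")
        if (is.null(rownames(patientData)) && "tumor_id" %in% colnames(patientData))
            rownames(patientData) <- patientData$tumor_id
        patientData <- patientData[rownames(status), , drop = FALSE]
        rownames(patientData) <- rownames(status)
    }
    new("GeneStatusMatrix", status = status, patientData = patientData)
}

#' @rdname GeneStatusMatrix-class
#' @export
setMethod("mutationStatus", "GeneStatusMatrix", function(object) object@status)

#' @rdname GeneStatusMatrix-class
#' @export
setMethod("patientInfo", "GeneStatusMatrix", function(object) object@patientData)

#' @rdname GeneStatusMatrix-class
#' @export
setMethod("panelGenes", "GeneStatusMatrix",
          function(object) colnames(object@status))

#' @rdname GeneStatusMatrix-class
#' @export
setMethod("tumorIds", "GeneStatusMatrix",
          function(object) rownames(object@status))

setMethod("show", "GeneStatusMatrix", function(object) {
    s <- object@status
    cat("GeneStatusMatrix:", nrow(s), "tumors x", ncol(s), "genes\n")
    if ("group" %in% colnames(object@patientData)) {
        tab <- table(object@patientData$group)
        cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    cat("  mutated calls:", sum(s == 1L, na.rm = TRUE),
        "| missing entries:", sum(is.na(s)), "\n")
})

#' Read a cohort table
#'
#' Tab-separated, one row per tumor: \code{tumor_id}, \code{nevus_count},
#' \code{elastosis_grade}, optional \code{group}, then one 0/1/NA column per
#' panel gene. When \code{group} is absent it is derived with
#' [classifyGroup()].
#'
#' @param path File path.
#' @param rules [classificationRules()] used when deriving groups.
#' @return A \linkS4class{GeneStatusMatrix}.
#' @export
readCohortTable <- function(path, rules = classificationRules()) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c(elastosis_grade = "character"))
    meta <- intersect(c("tumor_id", "nevus_count", "elastosis_grade", "group"),
                      names(df))
    stopifnot(all(c("tumor_id", "nevus_count", "elastosis_grade") %in% meta))
    genes <- setdiff(names(df), meta)
    status <- as.matrix(df[, genes, drop = FALSE])
    rownames(status) <- df$tumor_id
    pd <- df[, meta, drop = FALSE]
    if (!"group" %in% names(pd))
        pd$group <- as.character(classifyGroup(pd$nevus_count,
                                               pd$elastosis_grade, rules))
    geneStatusMatrix(status = status, patientData = pd, genes = genes)
}

#' Write a cohort table
#'
#' Inverse of [readCohortTable()].
#'
#' @param object A \linkS4class{GeneStatusMatrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohortTable <- function(object, path) {
    pd <- as.data.frame(patientInfo(object))
    df <- cbind(data.frame(tumor_id = tumorIds(object)), pd,
                as.data.frame(mutationStatus(object)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a variant table
#'
#' Tab-separated columns \code{tumor_id}, \code{gene}, \code{vaf},
#' \code{pathogenicity}.
#'
#' @param path File path.
#' @return data.frame of variant calls.
#' @export
readVariantTable <- function(path) {
    df <- utils::read.delim(path)
    stopifnot(all(c("tumor_id", "gene", "vaf", "pathogenicity") %in% names(df)))
    df
}
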