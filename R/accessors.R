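#' Accessors for GenotypePanel
#'
#' \code{dosage} returns the markers x lines alt-allele dosage matrix
#' (0/1/2/NA); \code{lineGroups} the named vector of FP group labels;
#' \code{markerRanges} the marker \link[GenomicRanges]{GRanges};
#' \code{markerMaf} the per-marker minor allele frequency computed from
#' allele counts (a heterozygote contributes one copy of each allele,
#' missing calls are excluded); \code{markerMissingRate} the per-marker
#' fraction of missing calls.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param value for the replacement form, a character vector of group
#'   labels, either unnamed (in column order) or named by line id.
#' @return See individual descriptions.
#' @name GenotypePanel-accessors
#' @aliases dosage lineGroups lineGroups<- markerRanges
NULL

#' @rdname GenotypePanel-accessors
#' @export
setMethod("dosage", "GenotypePanel", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("lineGroups", "GenotypePanel", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' @rdname GenotypePanel-accessors
#' @export
setReplaceMethod("lineGroups", "GenotypePanel", function(x, value) {
    if (!is.null(names(value))) {
        miss <- setdiff(colnames(x), names(value))
        if (length(miss))
            stop("no group label for line(s): ", paste(miss, collapse = ", "))
        value <- value[colnames(x)]
    } else if (length(value) != ncol(x)) {
        stop("need one group label per line")
    }
    SummarizedExperiment::colData(x)$group <- unname(as.character(value))
    methods::validObject(x)
    x
})

#' @rdname GenotypePanel-accessors
#' @export
setMethod("markerRanges", "GenotypePanel", function(x)
    SummarizedExperiment::rowRanges(x))

#' @rdname GenotypePanel-accessors
#' @export
markerMaf <- function(x) {
    d <- dosage(x)
    alt <- rowSums(d, na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(d))
    p <- ifelse(tot > 0, alt / tot, NA_real_)
    pmin(p, 1 - p)
}

#' @rdname GenotypePanel-accessors
#' @export
markerMissingRate <- function(x) rowMeans(is.na(dosage(x)))

#' Attach group membership from a table
#'
#' Assigns FP group labels (and optionally co-ancestry membership
#' fractions) to panel lines from a membership table, as produced by a
#' model-based structure analysis or pedigree records. Lines absent from
#' the table keep their current label.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param table a \code{data.frame} with columns \code{line_id},
#'   \code{group} and optionally \code{membership}.
#' @param minMembership lines whose membership falls below this fraction
#'   are labeled "unassigned" (panel inclusion in the source study required
#'   co-ancestor membership above 0.5).
#' @return The panel with updated line metadata.
#' @export
assignGroups <- function(x, table, minMembership = 0.5) {
    stopifnot(all(c("line_id", "group") %in% colnames(table)))
    idx <- match(colnames(x), table$line_id)
    cd <- SummarizedExperiment::colData(x)
    hit <- !is.na(idx)
    cd$group[hit] <- as.character(table$group[idx[hit]])
    if ("membership" %in% colnames(table)) {
        cd$membership[hit] <- as.numeric(table$membership[idx[hit]])
        low <- hit & !is.na(cd$membership) & cd$membership < minMembership
        cd$group[low] <- "unassigned"
    }
    SummarizedExperiment::colData(x) <- cd
    methods::validObject(x)
    x
}

setMethod("show", "GenotypePanel", function(object) {
    cat(sprintf("GenotypePanel: %d markers x %d lines\n",
                nrow(object), ncol(object)))
    tab <- table(lineGroups(object))
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
    cat("  chromosomes:",
        paste(GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(object)),
              collapse = ", "), "\n")
    cat(sprintf("  missing calls: %.2f%%\n",
                100 * mean(is.na(dosage(object)))))
    invisible(object)
})

#' Accessors for DiversityProfile
#'
#' \code{gdValues} returns the per-marker gene diversity values (named by
#' marker id); \code{chromStats} the per-chromosome summary table with the
#' segment-calling threshold.
#'
#' @param x a \linkS4class{DiversityProfile}.
#' @name DiversityProfile-accessors
#' @aliases gdValues chromStats
NULL

#' @rdname DiversityProfile-accessors
#' @export
setMethod("gdValues", "DiversityProfile", function(x) {
    gd <- S4Vectors::mcols(x@markers)$gd
    names(gd) <- names(x@markers)
    gd
})

#' @rdname DiversityProfile-accessors
#' @export
setMethod("chromStats", "DiversityProfile", function(x) x@chromStats)

setMethod("show", "DiversityProfile", function(object) {
    gd <- S4Vectors::mcols(object@markers)$gd
    cat(sprintf("DiversityProfile for group '%s' (%d lines)\n",
                object@group, object@nLines))
    cat(sprintf("  %d markers, %d with defined GD, %d tag loci (GD = 0)\n",
                length(object@markers), sum(!is.na(gd)),
                sum(!is.na(gd) & gd == 0)))
    cat(sprintf("  mean GD %.4f over %d chromosomes\n",
                mean(gd, na.rm = TRUE), nrow(object@chromStats)))
    invisible(object)
})

setMethod("show", "VennPartition", function(object) {
    cc <- vennCounts(object)
    cat(sprintf("VennPartition of %d union intervals across groups: %s\n",
                length(object@intervals),
                paste(object@groups, collapse = ", ")))
    cat("  totals:  ", paste(sprintf("%s=%d", names(cc$total), cc$total),
                             collapse = ", "), "\n")
    cat("  specific:", paste(sprintf("%s=%d", names(cc$specific),
                                     cc$specific), collapse = ", "), "\n")
    cat(sprintf("  common to all %d groups: %d\n", length(object@groups),
                cc$common_all))
    invisible(object)
})
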