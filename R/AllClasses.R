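#' GenotypePanel: a SNP panel of inbred lines
#'
#' An S4 container for a biallelic SNP genotype panel, extending
#' \linkS4class{RangedSummarizedExperiment}. Rows are markers (a
#' \link[GenomicRanges]{GRanges} of single-bp physical positions on the
#' reference build, with metadata columns \code{ref}, \code{alt} and
#' \code{ambiguous}), columns are inbred lines (colData columns \code{group}
#' and \code{membership}), and the single assay \code{"dosage"} stores
#' alt-allele dosage codes 0 (hom-ref), 1 (het), 2 (hom-alt) or \code{NA}
#' (missing). Markers are kept sorted by (chromosome, position); duplicated
#' positions are not allowed.
#'
#' Coordinates are 1-based inclusive throughout the package (GFF
#' convention); only the BED export converts to 0-based half-open.
#'
#' @seealso [readGenotypes()], [filterSnps()], [harmonizePanels()]
#' @aliases GenotypePanel
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.validGenotypePanel <- function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0, 1, 2)))
            msg <- c(msg, "dosage codes must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
        msg <- c(msg, "marker metadata must contain 'ref' and 'alt'")
    else {
        if (any(mc$ref == mc$alt, na.rm = TRUE))
            msg <- c(msg, "ref and alt alleles must differ")
        nt <- c("A", "C", "G", "T")
        if (!all(c(mc$ref, mc$alt) %in% nt))
            msg <- c(msg, "alleles must be single nucleotides A/C/G/T")
    }
    if (length(rr)) {
        key <- paste(as.character(GenomicRanges::seqnames(rr)),
                     GenomicRanges::start(rr))
        if (anyDuplicated(key))
            msg <- c(msg, sprintf("duplicated (chrom, pos): %s",
                                  paste(unique(key[duplicated(key)]),
                                        collapse = ", ")))
        if (any(GenomicRanges::start(rr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        o <- order(match(as.character(GenomicRanges::seqnames(rr)),
                         chromLevels(GenomicRanges::seqnames(rr))),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "markers must be sorted by (chrom, pos)")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("group", "membership") %in% colnames(cd)))
        msg <- c(msg, "line metadata must contain 'group' and 'membership'")
    else {
        mem <- cd$membership
        if (any(!is.na(mem) & (mem < 0 | mem > 1)))
            msg <- c(msg, "membership must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
}

setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param dosage integer/numeric matrix, markers x lines, values 0/1/2/NA.
#'   Row names are marker ids, column names line ids.
#' @param chrom,pos chromosome label and 1-based bp position per marker.
#' @param ref,alt single-nucleotide allele codes per marker.
#' @param group optional FP group label per line (default "unassigned").
#' @param membership optional co-ancestry membership fraction per line.
#' @return A \linkS4class{GenotypePanel} with markers sorted by
#'   (chromosome, position).
#' @examples
#' gp <- GenotypePanel(matrix(c(0, 2, 0, 2), 2, 2,
#'                            dimnames = list(c("m1", "m2"), c("L1", "L2"))),
#'                     chrom = c("1", "1"), pos = c(100L, 200L),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' dosage(gp)
#' @export
GenotypePanel <- function(dosage, chrom, pos, ref, alt,
                          group = NULL, membership = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("L", seq_len(ncol(dosage)))
    chrom <- rep_len(as.character(chrom), nrow(dosage))
    lev <- chromLevels(chrom)
    o <- order(match(chrom, lev), pos)
    rr <- GenomicRanges::GRanges(
        seqnames = factor(chrom[o], levels = lev),
        ranges = IRanges::IRanges(start = as.integer(pos)[o], width = 1L),
        ref = as.character(ref)[o], alt = as.character(alt)[o],
        ambiguous = FALSE)
    names(rr) <- rownames(dosage)[o]
    if (is.null(group)) group <- rep("unassigned", ncol(dosage))
    if (is.null(membership)) membership <- rep(NA_real_, ncol(dosage))
    cd <- S4Vectors::DataFrame(group = as.character(group),
                               membership = as.numeric(membership),
                               row.names = colnames(dosage))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage[o, , drop = FALSE]),
        rowRanges = rr, colData = cd)
    methods::new("GenotypePanel", se)
}

#' DiversityProfile: per-marker gene diversity of one FP group
#'
#' Holds Nei gene diversity (GD, expected heterozygosity
#' \eqn{1 - \sum \hat p^2}) for every marker, computed over the lines of a
#' single foundation-parent group, together with per-chromosome mean,
#' sample SD and the segment-calling threshold
#' \eqn{\bar{GD}_{chr} - 0.5\, SD_{chr}}.
#'
#' @slot group the FP group label.
#' @slot markers \link[GenomicRanges]{GRanges} of markers with metadata
#'   columns \code{gd} (NA when fewer than \code{minCalls} lines had calls)
#'   and \code{n_calls} (non-missing lines at the marker).
#' @slot chromStats per-chromosome \code{data.frame} with columns
#'   \code{chrom}, \code{n_markers}, \code{mean_gd}, \code{sd_gd},
#'   \code{threshold}.
#' @slot minCalls minimum non-missing lines for a defined GD value.
#' @slot nLines number of lines in the group.
#' @seealso [geneDiversity()], [findTagLoci()], [callSegments()]
#' @exportClass DiversityProfile
setClass("DiversityProfile",
         representation(group = "character",
                        markers = "GRanges",
                        chromStats = "data.frame",
                        minCalls = "integer",
                        nLines = "integer"))

setValidity("DiversityProfile", function(object) {
    msg <- character()
    gd <- S4Vectors::mcols(object@markers)$gd
    if (is.null(gd))
        msg <- c(msg, "markers must carry a 'gd' metadata column")
    else if (any(gd < -1e-12 | gd > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "gd must lie in [0, 1]")
    if (any(object@chromStats$sd_gd < 0, na.rm = TRUE))
        msg <- c(msg, "sd_gd must be >= 0")
    if (length(object@group) != 1L)
        msg <- c(msg, "group must be a single label")
    if (length(msg)) msg else TRUE
})

#' VennPartition: group-combination classes of IBD segments
#'
#' The union interval set across the per-group IBD segment lists, with each
#' union interval labeled by the subset of groups whose segments satisfy the
#' overlap rule with it. Counting is over union intervals, so each group's
#' total equals its specific count plus its shared-class contributions.
#'
#' @slot groups the FP group labels compared.
#' @slot intervals \link[GenomicRanges]{GRanges} of union intervals with a
#'   \code{groups} \link[IRanges]{CharacterList} metadata column and an
#'   integer \code{n_groups} column.
#' @slot rule overlap rule used ("any_overlap" or "reciprocal").
#' @seealso [vennPartition()], [vennCounts()]
#' @exportClass VennPartition
setClass("VennPartition",
         representation(groups = "character",
                        intervals = "GRanges",
                        rule = "character"))

setValidity("VennPartition", function(object) {
    msg <- character()
    lab <- S4Vectors::mcols(object@intervals)$groups
    if (is.null(lab))
        msg <- c(msg, "intervals must carry a 'groups' metadata column")
    else {
        if (!all(unlist(lab) %in% object@groups))
            msg <- c(msg, "interval labels must be drawn from @groups")
        if (length(lab) && any(lengths(lab) == 0L))
            msg <- c(msg, "every union interval must belong to >= 1 group")
    }
    if (length(msg)) msg else TRUE
})
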