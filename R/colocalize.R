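## Coerce a QTN table (from callQtns) or GRanges to a point GRanges.
.qtnRanges <- function(qtns, seqlev) {
    if (methods::is(qtns, "GRanges"))
        return(qtns)
    stopifnot(all(c("marker", "chrom", "pos") %in% colnames(qtns)))
    unknown <- setdiff(unique(as.character(qtns$chrom)), seqlev)
    if (length(unknown))
        stop("QTN chromosome label(s) not on the segment frame: ",
             paste(unknown, collapse = ", "))
    gr <- GenomicRanges::GRanges(
        seqnames = factor(as.character(qtns$chrom), seqlev),
        ranges = IRanges::IRanges(start = qtns$pos, width = 1L))
    names(gr) <- qtns$marker
    S4Vectors::mcols(gr)$trait <- if ("trait" %in% colnames(qtns))
        qtns$trait else NA_character_
    gr
}

## Coerce a QTL table (BED-like, 1-based inclusive) or GRanges.
.qtlRanges <- function(qtls, seqlev) {
    if (methods::is(qtls, "GRanges"))
        return(qtls)
    stopifnot(all(c("name", "chrom", "start", "end") %in% colnames(qtls)))
    unknown <- setdiff(unique(as.character(qtls$chrom)), seqlev)
    if (length(unknown))
        stop("QTL chromosome label(s) not on the segment frame: ",
             paste(unknown, collapse = ", "))
    gr <- GenomicRanges::GRanges(
        seqnames = factor(as.character(qtls$chrom), seqlev),
        ranges = IRanges::IRanges(start = qtls$start, end = qtls$end))
    names(gr) <- qtls$name
    S4Vectors::mcols(gr)$trait <- if ("trait" %in% colnames(qtls))
        qtls$trait else NA_character_
    gr
}

#' Project QTNs and QTLs onto IBD segments
#'
#' Places GWAS QTNs (point positions) and literature QTL intervals on the
#' same physical frame as the IBD segments. A QTN supports a segment when
#' its position lies inside it (closed interval); a QTL supports a
#' segment when the intervals share at least one basepair. Segments
#' supported by both are the important candidate regions
#' (\code{support_class = "both"}); unsupported segments are omitted.
#'
#' @param segments segment \link[GenomicRanges]{GRanges} (one group or
#'   several concatenated).
#' @param qtns QTN table from [callQtns()] (passing rows are used) or a
#'   point GRanges.
#' @param qtls QTL table with columns name, trait, chrom, start, end
#'   (1-based inclusive) or a GRanges.
#' @return \code{data.frame} of supported segments: chrom, start, end,
#'   group, support_class, n_qtns, n_qtls, and comma-separated qtn/qtl
#'   ids and traits.
#' @export
projectLoci <- function(segments, qtns, qtls) {
    seqlev <- GenomeInfoDb::seqlevels(segments)
    if (!is.null(qtns) && is.data.frame(qtns) && "passes" %in% colnames(qtns))
        qtns <- qtns[qtns$passes, , drop = FALSE]
    qtnGr <- if (is.null(qtns)) GenomicRanges::GRanges() else
        .qtnRanges(qtns, seqlev)
    qtlGr <- if (is.null(qtls)) GenomicRanges::GRanges() else
        .qtlRanges(qtls, seqlev)
    hitN <- GenomicRanges::findOverlaps(segments, qtnGr)
    hitL <- GenomicRanges::findOverlaps(segments, qtlGr)
    nQtn <- GenomicRanges::countOverlaps(segments, qtnGr)
    nQtl <- GenomicRanges::countOverlaps(segments, qtlGr)
    keep <- which(nQtn > 0L | nQtl > 0L)
    collapseIds <- function(hits, gr, i, what = "names") {
        j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
        v <- if (what == "names") names(gr)[j] else
            S4Vectors::mcols(gr)$trait[j]
        paste(unique(v[!is.na(v)]), collapse = ",")
    }
    mc <- S4Vectors::mcols(segments)
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(segments))[keep],
        start = GenomicRanges::start(segments)[keep],
        end = GenomicRanges::end(segments)[keep],
        group = if ("group" %in% colnames(mc)) mc$group[keep] else NA,
        n_qtns = nQtn[keep], n_qtls = nQtl[keep],
        support_class = ifelse(nQtn[keep] > 0L & nQtl[keep] > 0L, "both",
                               ifelse(nQtn[keep] > 0L, "qtn_only",
                                      "qtl_only")),
        qtns = vapply(keep, collapseIds, character(1), hits = hitN,
                      gr = qtnGr),
        qtls = vapply(keep, collapseIds, character(1), hits = hitL,
                      gr = qtlGr),
        traits = vapply(keep, function(i) {
            tr <- c(strsplit(collapseIds(hitN, qtnGr, i, "trait"),
                             ",")[[1]],
                    strsplit(collapseIds(hitL, qtlGr, i, "trait"),
                             ",")[[1]])
            paste(sort(unique(tr[nzchar(tr)])), collapse = ",")
        }, character(1)),
        row.names = NULL)
    out
}

#' QTN/QTL clusters within supported segments
#'
#' A segment whose combined QTN + QTL feature count reaches
#' \code{minLoci} forms a cluster; clusters are reported with their
#' member features and the trait categories they span.
#'
#' @param supported output of [projectLoci()].
#' @param minLoci minimum co-segmental feature count (default 3).
#' @return Subset of \code{supported} with added \code{n_features} and
#'   \code{n_trait_categories}.
#' @export
findClusters <- function(supported, minLoci = 3L) {
    n <- supported$n_qtns + supported$n_qtls
    out <- supported[n >= minLoci, , drop = FALSE]
    out$n_features <- n[n >= minLoci]
    out$n_trait_categories <- vapply(out$traits, function(tr)
        length(strsplit(tr, ",")[[1]]), integer(1))
    rownames(out) <- NULL
    out
}

#' Candidate genes tightly linked to tag SNPs
#'
#' Within each IBD segment, annotation genes whose interval lies within
#' \code{radiusBp} of a tag SNP of the same group are reported as tightly
#' linked candidates (distance 0 when the tag falls inside the gene
#' body). The default radius of 25 kb reflects the average linkage
#' disequilibrium extent of about 30 kb in elite maize panels. Each gene
#' is reported once per segment with its nearest anchoring tag; when a
#' QTN table is supplied, the nearest in-segment QTN is attached.
#'
#' @param segments segment \link[GenomicRanges]{GRanges}.
#' @param tags tag-locus \link[GenomicRanges]{GRanges} from
#'   [findTagLoci()] (with \code{group} metadata).
#' @param annotation gene \link[GenomicRanges]{GRanges} (e.g. imported
#'   from GFF3 via \code{rtracklayer::import}, gene features only), with
#'   gene ids in \code{names} or an \code{ID} metadata column.
#' @param radiusBp linkage radius in bp.
#' @param qtns optional QTN table from [callQtns()].
#' @return \code{data.frame}: gene_id, chrom, gene_start, gene_end,
#'   strand, group, segment coords, anchor tag position, distance_bp,
#'   and nearest in-segment QTN (or NA).
#' @export
candidateGenes <- function(segments, tags, annotation, radiusBp = 25000L,
                           qtns = NULL) {
    stopifnot(radiusBp > 0)
    if (is.null(annotation) || !length(annotation))
        stop("empty gene annotation")
    genes <- annotation
    if (!is.null(S4Vectors::mcols(genes)$type))
        genes <- genes[S4Vectors::mcols(genes)$type == "gene"]
    ids <- names(genes)
    if (is.null(ids) && !is.null(S4Vectors::mcols(genes)$ID))
        ids <- S4Vectors::mcols(genes)$ID
    if (is.null(ids))
        ids <- paste0("gene", seq_along(genes))
    qtnGr <- NULL
    if (!is.null(qtns)) {
        if (is.data.frame(qtns) && "passes" %in% colnames(qtns))
            qtns <- qtns[qtns$passes, , drop = FALSE]
        qtnGr <- .qtnRanges(qtns, GenomeInfoDb::seqlevels(segments))
    }
    segTag <- GenomicRanges::findOverlaps(segments, tags)
    mcSeg <- S4Vectors::mcols(segments)
    rows <- list()
    for (i in unique(S4Vectors::queryHits(segTag))) {
        segGroup <- if ("group" %in% colnames(mcSeg)) mcSeg$group[i] else NA
        tagIdx <- S4Vectors::subjectHits(segTag)[
            S4Vectors::queryHits(segTag) == i]
        if (!is.na(segGroup) &&
            "group" %in% colnames(S4Vectors::mcols(tags)))
            tagIdx <- tagIdx[S4Vectors::mcols(tags)$group[tagIdx] ==
                             segGroup]
        if (!length(tagIdx)) next
        tagSub <- tags[tagIdx]
        dists <- as.matrix(
            outer(seq_along(genes), seq_along(tagSub),
                  function(gi, ti)
                      .pointIntervalDistance(
                          GenomicRanges::start(tagSub)[ti],
                          as.character(
                              GenomicRanges::seqnames(tagSub))[ti],
                          GenomicRanges::start(genes)[gi],
                          GenomicRanges::end(genes)[gi],
                          as.character(
                              GenomicRanges::seqnames(genes))[gi])))
        best <- apply(dists, 1L, which.min)
        bestD <- dists[cbind(seq_along(genes), best)]
        hit <- which(is.finite(bestD) & bestD <= radiusBp)
        if (!length(hit)) next
        for (g in hit) {
            qtnId <- NA_character_
            if (!is.null(qtnGr) && length(qtnGr)) {
                inSeg <- which(
                    as.character(GenomicRanges::seqnames(qtnGr)) ==
                    as.character(GenomicRanges::seqnames(segments))[i] &
                    GenomicRanges::start(qtnGr) >=
                    GenomicRanges::start(segments)[i] &
                    GenomicRanges::start(qtnGr) <=
                    GenomicRanges::end(segments)[i])
                if (length(inSeg)) {
                    dq <- abs(GenomicRanges::start(qtnGr)[inSeg] -
                              (GenomicRanges::start(genes)[g] +
                               GenomicRanges::end(genes)[g]) / 2)
                    qtnId <- names(qtnGr)[inSeg[which.min(dq)]]
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = ids[g],
                chrom = as.character(GenomicRanges::seqnames(genes))[g],
                gene_start = GenomicRanges::start(genes)[g],
                gene_end = GenomicRanges::end(genes)[g],
                strand = as.character(GenomicRanges::strand(genes))[g],
                group = segGroup,
                segment_start = GenomicRanges::start(segments)[i],
                segment_end = GenomicRanges::end(segments)[i],
                tag_pos = GenomicRanges::start(tagSub)[best[g]],
                distance_bp = bestD[g],
                qtn = qtnId)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(), chrom = character(),
                   gene_start = integer(), gene_end = integer(),
                   strand = character(), group = character(),
                   segment_start = integer(), segment_end = integer(),
                   tag_pos = integer(), distance_bp = integer(),
                   qtn = character())
    rownames(out) <- NULL
    out
}

## bp distance from a point to a closed interval on the same chromosome
## (Inf across chromosomes, 0 inside the interval).
.pointIntervalDistance <- function(pos, chrom, start, end, chrom2) {
    ifelse(chrom != chrom2, Inf,
           ifelse(pos < start, start - pos,
                  ifelse(pos > end, pos - end, 0)))
}
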