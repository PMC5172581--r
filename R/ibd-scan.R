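#' Per-group gene diversity profile
#'
#' Computes Nei gene diversity for every marker over the lines of one FP
#' group: with \eqn{\hat p} the alt-allele frequency among non-missing
#' alleles (a heterozygote contributes one copy of each allele),
#' \eqn{GD = 1 - \hat p^2 - (1-\hat p)^2}, the probability that two
#' alleles randomly chosen from the sample differ. Markers with fewer
#' than \code{minCalls} non-missing lines get a missing GD. Per
#' chromosome, the mean and sample SD (n - 1 denominator) of the defined
#' GDs are recorded together with the segment-calling threshold
#' \eqn{mean - 0.5 \times SD}.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param group an FP group label present in \code{lineGroups(x)}, or a
#'   character vector of line ids.
#' @param minCalls minimum non-missing lines for a defined GD; this guard
#'   keeps high-missingness markers from creating spurious tag loci.
#' @return A \linkS4class{DiversityProfile}.
#' @seealso [findTagLoci()], [chromosomeThreshold()], [callSegments()]
#' @export
geneDiversity <- function(x, group, minCalls = 4L) {
    groups <- lineGroups(x)
    if (length(group) == 1L && group %in% groups) {
        ids <- names(groups)[groups == group]
        label <- group
    } else {
        ids <- intersect(as.character(group), colnames(x))
        label <- if (length(group) == 1L) group else "custom"
    }
    if (length(ids) < 2L)
        stop("group must contain at least two panel lines with calls")
    d <- dosage(x)[, ids, drop = FALSE]
    alt <- rowSums(d, na.rm = TRUE)
    nCalls <- rowSums(!is.na(d))
    p <- ifelse(nCalls > 0, alt / (2 * nCalls), NA_real_)
    gd <- 1 - p^2 - (1 - p)^2
    gd[nCalls < minCalls] <- NA_real_

    rr <- markerRanges(x)
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(gd = gd,
                                                 n_calls = nCalls)
    methods::new("DiversityProfile", group = label, markers = rr,
                 chromStats = .chromStatsFromGd(
                     gd, as.character(GenomicRanges::seqnames(rr))),
                 minCalls = as.integer(minCalls),
                 nLines = length(ids))
}

## Per-chromosome mean, sample SD (n - 1) and calling threshold of the
## defined GD values.
.chromStatsFromGd <- function(gd, chrom) {
    stats <- lapply(split(gd, chrom), function(g) {
        g <- g[!is.na(g)]
        c(n = length(g),
          mean = if (length(g)) mean(g) else NA_real_,
          sd = if (length(g) >= 2L) stats::sd(g) else NA_real_)
    })
    cs <- data.frame(chrom = names(stats),
                     n_markers = vapply(stats, `[[`, numeric(1), "n"),
                     mean_gd = vapply(stats, `[[`, numeric(1), "mean"),
                     sd_gd = vapply(stats, `[[`, numeric(1), "sd"),
                     row.names = NULL)
    cs <- cs[chromOrder(cs$chrom), , drop = FALSE]
    rownames(cs) <- NULL
    cs$threshold <- cs$mean_gd - 0.5 * cs$sd_gd
    cs
}

#' Build a diversity profile from explicit per-marker GD values
#'
#' Constructs a \linkS4class{DiversityProfile} directly from a vector of
#' gene diversity values on a marker map, recomputing the per-chromosome
#' summary statistics and calling threshold exactly as [geneDiversity()]
#' does. Useful for threshold/window experiments on designed GD
#' landscapes.
#'
#' @param gd per-marker gene diversity values (NA allowed).
#' @param chrom,pos marker chromosome labels and positions.
#' @param group group label to carry.
#' @param nCalls non-missing line count per marker (defaults to
#'   \code{minCalls}, i.e. all markers pass the guard).
#' @param minCalls tag-locus call guard.
#' @return A \linkS4class{DiversityProfile}.
#' @export
diversityProfile <- function(gd, chrom, pos, group = "custom",
                             nCalls = NULL, minCalls = 4L) {
    chrom <- rep_len(as.character(chrom), length(gd))
    if (is.null(nCalls)) nCalls <- rep(as.integer(minCalls), length(gd))
    lev <- chromLevels(chrom)
    o <- order(match(chrom, lev), pos)
    rr <- GenomicRanges::GRanges(
        seqnames = factor(chrom[o], lev),
        ranges = IRanges::IRanges(start = as.integer(pos)[o], width = 1L),
        gd = gd[o], n_calls = as.integer(nCalls)[o])
    names(rr) <- sprintf("S%s_%d", chrom[o], as.integer(pos)[o])
    methods::new("DiversityProfile", group = group, markers = rr,
                 chromStats = .chromStatsFromGd(gd[o], chrom[o]),
                 minCalls = as.integer(minCalls),
                 nLines = max(nCalls))
}

#' Tag loci: monomorphic anchors of IBD candidate windows
#'
#' Returns the markers whose gene diversity is exactly zero (a single
#' observed allele) with at least \code{minCalls} non-missing lines, in
#' map order.
#'
#' @param profile a \linkS4class{DiversityProfile}.
#' @param minCalls minimum non-missing lines (defaults to the profile's
#'   guard).
#' @return A \link[GenomicRanges]{GRanges} of tag loci with \code{gd},
#'   \code{n_calls} and \code{group} metadata.
#' @export
findTagLoci <- function(profile, minCalls = profile@minCalls) {
    mc <- S4Vectors::mcols(profile@markers)
    keep <- !is.na(mc$gd) & mc$gd == 0 & mc$n_calls >= minCalls
    out <- profile@markers[keep]
    S4Vectors::mcols(out)$group <- profile@group
    out
}

## Windowed mean GD around arbitrary anchor positions, via per-chromosome
## cumulative sums. Returns mean gd, number of GD-informative markers and
## the clipped window bounds.
.windowStats <- function(profile, chrom, pos, halfWindowBp) {
    rr <- profile@markers
    mchrom <- as.character(GenomicRanges::seqnames(rr))
    mpos <- GenomicRanges::start(rr)
    gd <- S4Vectors::mcols(rr)$gd
    out <- data.frame(chrom = chrom, pos = pos, mean_gd = NA_real_,
                      n_markers = 0L, start = NA_integer_,
                      end = NA_integer_)
    for (ch in unique(chrom)) {
        sel <- mchrom == ch
        P <- mpos[sel]
        G <- gd[sel]
        csum <- c(0, cumsum(ifelse(is.na(G), 0, G)))
        cnt <- c(0L, cumsum(!is.na(G)))
        at <- which(chrom == ch)
        lo <- findInterval(pos[at] - halfWindowBp - 0.5, P) + 1L
        hi <- findInterval(pos[at] + halfWindowBp + 0.5, P)
        n <- cnt[hi + 1L] - cnt[lo]
        s <- csum[hi + 1L] - csum[lo]
        out$mean_gd[at] <- ifelse(n > 0, s / n, NA_real_)
        out$n_markers[at] <- n
        out$start[at] <- pmax(pos[at] - halfWindowBp, min(P))
        out$end[at] <- pmin(pos[at] + halfWindowBp, max(P))
    }
    out
}

#' Mean gene diversity in a tag-centered window
#'
#' Arithmetic mean of the defined GD values over all markers within
#' \code{halfWindowBp} of the anchor position on the same chromosome
#' (anchor included). The source method uses a window of 25 kb before and
#' after each tag SNP.
#'
#' @param profile a \linkS4class{DiversityProfile}.
#' @param chrom,pos anchor chromosome and position (vectorized).
#' @param halfWindowBp half-window size in bp.
#' @return Numeric vector of window mean GDs.
#' @export
windowMeanGd <- function(profile, chrom, pos, halfWindowBp = 25000L) {
    .windowStats(profile, as.character(chrom), as.numeric(pos),
                 halfWindowBp)$mean_gd
}

#' Chromosome-specific segment-calling threshold
#'
#' \code{mean_gd(chrom) - 0.5 * sd_gd(chrom)}, computed over the
#' chromosome's defined per-marker GDs within the group. A non-positive
#' threshold (very uniform chromosome) is returned with a warning: no
#' window can pass it.
#'
#' @param profile a \linkS4class{DiversityProfile}.
#' @param chrom chromosome label.
#' @return The threshold value.
#' @export
chromosomeThreshold <- function(profile, chrom) {
    cs <- profile@chromStats
    row <- cs[cs$chrom == as.character(chrom), ]
    if (nrow(row) != 1L || row$n_markers < 2L || is.na(row$sd_gd))
        stop("chromosome ", chrom,
             " has fewer than two markers with defined GD")
    thr <- row$threshold
    if (thr <= 0)
        warning("threshold for chromosome ", chrom,
                " is non-positive; no window will pass")
    thr
}

#' Call IBD segments from tag-locus windows
#'
#' For each tag locus, the candidate interval is the tag position plus and
#' minus \code{halfWindowBp}, clipped at the chromosome's marker extent.
#' A candidate is accepted when its window mean GD is strictly below the
#' chromosome threshold. Overlapping or bookended accepted windows on the
#' same chromosome are merged into one segment whose \code{mean_window_gd}
#' is the marker-weighted mean of its member windows.
#'
#' @param profile a \linkS4class{DiversityProfile}.
#' @param tags tag loci as returned by [findTagLoci()]; computed from the
#'   profile when \code{NULL}.
#' @param halfWindowBp half-window size in bp (default 25 kb).
#' @return A \link[GenomicRanges]{GRanges} of IBD segments sorted by
#'   (chrom, start), with metadata \code{group}, \code{mean_window_gd},
#'   \code{n_markers}, \code{n_tags}.
#' @export
callSegments <- function(profile, tags = NULL, halfWindowBp = 25000L) {
    if (is.null(tags))
        tags <- findTagLoci(profile)
    lev <- GenomeInfoDb::seqlevels(profile@markers)
    empty <- GenomicRanges::GRanges(seqnames = factor(character(), lev),
                                    ranges = IRanges::IRanges(),
                                    group = character(),
                                    mean_window_gd = numeric(),
                                    n_markers = integer(),
                                    n_tags = integer())
    if (!length(tags))
        return(empty)
    chrom <- as.character(GenomicRanges::seqnames(tags))
    ws <- .windowStats(profile, chrom, GenomicRanges::start(tags),
                       halfWindowBp)
    cs <- profile@chromStats
    thr <- cs$threshold[match(chrom, cs$chrom)]
    usable <- !is.na(thr) & cs$n_markers[match(chrom, cs$chrom)] >= 2L
    if (any(!usable))
        warning("tags on chromosome(s) without a defined threshold ",
                "skipped: ",
                paste(unique(chrom[!usable]), collapse = ", "))
    acc <- usable & !is.na(ws$mean_gd) & ws$mean_gd < thr
    if (!any(acc))
        return(empty)
    win <- GenomicRanges::GRanges(
        seqnames = factor(chrom[acc], lev),
        ranges = IRanges::IRanges(start = ws$start[acc], end = ws$end[acc]))
    merged <- GenomicRanges::reduce(win, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(merged)$revmap
    wMean <- ws$mean_gd[acc]
    wN <- ws$n_markers[acc]
    meanGd <- vapply(revmap, function(i)
        stats::weighted.mean(wMean[i], wN[i]), numeric(1))
    nTags <- lengths(revmap)
    hits <- GenomicRanges::countOverlaps(merged, profile@markers)
    S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
        group = profile@group, mean_window_gd = meanGd,
        n_markers = hits, n_tags = nTags)
    sort(merged)
}

#' Partition IBD segments across FP groups
#'
#' Builds the union interval set across the per-group segment lists and
#' labels each union interval with the subset of groups owning a segment
#' that satisfies the overlap rule with it. With \code{rule =
#' "any_overlap"} a single shared basepair suffices; with \code{rule =
#' "reciprocal"} a group counts only when one of its segments covers at
#' least \code{fraction} of the union interval. Class counts (specific,
#' common to k groups) are over union intervals, so per-group totals equal
#' specific plus shared contributions.
#'
#' @param segmentSets named list of per-group segment
#'   \link[GenomicRanges]{GRanges}, as from [callSegments()].
#' @param rule overlap rule.
#' @param fraction reciprocal-overlap fraction in (0, 1].
#' @return A \linkS4class{VennPartition}.
#' @export
vennPartition <- function(segmentSets, rule = c("any_overlap", "reciprocal"),
                          fraction = 0.5) {
    rule <- match.arg(rule)
    if (length(segmentSets) < 2L || is.null(names(segmentSets)) ||
        any(!nzchar(names(segmentSets))))
        stop("need a named list of >= 2 per-group segment sets")
    groups <- names(segmentSets)
    gr <- lapply(groups, function(g) {
        s <- segmentSets[[g]]
        S4Vectors::mcols(s) <- S4Vectors::DataFrame(group = g)
        s
    })
    all <- suppressWarnings(do.call(c, unname(gr)))
    if (!length(all))
        stop("all segment sets are empty")
    uni <- GenomicRanges::reduce(all)
    hits <- GenomicRanges::findOverlaps(all, uni)
    if (rule == "reciprocal") {
        ov <- GenomicRanges::pintersect(all[S4Vectors::queryHits(hits)],
                                        uni[S4Vectors::subjectHits(hits)])
        keep <- GenomicRanges::width(ov) >=
            fraction * GenomicRanges::width(uni[S4Vectors::subjectHits(hits)])
        hits <- hits[keep]
    }
    lab <- unname(splitAsListCompat(
        S4Vectors::mcols(all)$group[S4Vectors::queryHits(hits)],
        factor(S4Vectors::subjectHits(hits), levels = seq_along(uni))))
    lab <- IRanges::CharacterList(lapply(lab, function(g)
        groups[sort(match(unique(g), groups))]))
    if (any(lengths(lab) == 0L))
        stop("internal error: unlabeled union interval")
    S4Vectors::mcols(uni) <- S4Vectors::DataFrame(
        groups = lab, n_groups = lengths(lab))
    methods::new("VennPartition", groups = groups, intervals = uni,
                 rule = rule)
}

## split() wrapper kept separate for clarity on S4Vectors dispatch.
splitAsListCompat <- function(x, f) S4Vectors::split(x, f)

#' Class counts of a VennPartition
#'
#' Counts union intervals by group-combination class. \code{total[g]} is
#' the number of union intervals containing group g, \code{specific[g]}
#' those containing g alone, and \code{common} the superset counts for
#' every combination of 2 or more groups (an interval shared by three
#' groups contributes to each of its pairwise combinations, mirroring the
#' pairwise/triple/quadruple comparison cascade).
#'
#' @param x a \linkS4class{VennPartition}.
#' @return A list with \code{total}, \code{specific}, \code{common}
#'   (named by "A+B" style keys), \code{common_all} and \code{exact}
#'   (counts by exact label).
#' @export
setMethod("vennCounts", "VennPartition", function(x) {
    lab <- S4Vectors::mcols(x@intervals)$groups
    groups <- x@groups
    member <- vapply(groups, function(g)
        vapply(lab, function(l) g %in% l, logical(1)), logical(length(lab)))
    member <- matrix(member, ncol = length(groups),
                     dimnames = list(NULL, groups))
    total <- stats::setNames(as.integer(colSums(member)), groups)
    specific <- stats::setNames(
        as.integer(colSums(member & rowSums(member) == 1L)), groups)
    common <- list()
    for (k in 2:length(groups)) {
        sets <- utils::combn(groups, k, simplify = FALSE)
        for (s in sets)
            common[[paste(s, collapse = "+")]] <-
                sum(rowSums(member[, s, drop = FALSE]) == k)
    }
    exact <- table(vapply(lab, paste, character(1), collapse = "+"))
    list(total = total, specific = specific,
         common = unlist(common),
         common_all = sum(rowSums(member) == length(groups)),
         exact = exact)
})

#' Export IBD segments as BED
#'
#' Internal coordinates are 1-based inclusive; the BED file converts to
#' 0-based half-open. Columns: chrom, start, end, group, mean_window_gd,
#' n_tags.
#'
#' @param segments a segment \link[GenomicRanges]{GRanges} from
#'   [callSegments()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentsBed <- function(segments, path) {
    mc <- S4Vectors::mcols(segments)
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(segments)),
        start = GenomicRanges::start(segments) - 1L,
        end = GenomicRanges::end(segments),
        group = mc$group,
        mean_gd = signif(mc$mean_window_gd, 6),
        n_tags = mc$n_tags)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
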