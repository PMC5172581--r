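## Shared fixtures and oracles, built in code.

suppressPackageStartupMessages(library(GenomicRanges))

## Small panel straight from a dosage matrix.
toyPanel <- function(d, chrom = "1", pos = seq_len(nrow(d)) * 100,
                     ref = rep("A", nrow(d)), alt = rep("G", nrow(d)),
                     group = NULL) {
    GenotypePanel(d, chrom = chrom, pos = pos, ref = ref, alt = alt,
                  group = group)
}

## Unstructured random panel (iid markers) for oracle checks.
randomPanel <- function(nLines = 20, nMarkers = 100, missRate = 0.05,
                        seed = 1) {
    set.seed(seed)
    p <- runif(nMarkers, 0.05, 0.95)
    d <- matrix(rbinom(nMarkers * nLines, 2, rep(p, nLines)),
                nMarkers, nLines)
    d[matrix(runif(length(d)) < missRate, nMarkers, nLines)] <- NA
    dimnames(d) <- list(sprintf("m%04d", seq_len(nMarkers)),
                        sprintf("L%03d", seq_len(nLines)))
    toyPanel(d, chrom = rep(c("1", "2"), length.out = nMarkers),
             pos = ((seq_len(nMarkers) - 1L) %/% 2L + 1L) * 1000L)
}

## Test-scale study configuration for the end-to-end recovery checks:
## 4 groups x 15 lines, 8,000 markers on four 1.7 Mb chromosomes
## (0.77 markers/kb), 12 planted group-specific blocks of 40-80 kb per
## group with 60 kb guard gaps.
ciConfig <- function(seed, ...) {
    simConfig(linesPerGroup = c(B73 = 15, `207` = 15, HZS = 15,
                                Mo17 = 15),
              nMarkers = 8000L,
              chromLengthsBp = stats::setNames(rep(1.7e6, 4),
                                               as.character(1:4)),
              nSegmentsPerGroup = 12L,
              segmentSizeRange = c(40e3, 80e3),
              minSegmentGapBp = 60e3,
              backgroundGdTarget = 0.23,
              seed = seed, ...)
}

## Mid-size structured panel for association tests: 180 lines in 4 groups.
gwasConfig <- function(seed, nMarkers = 2000L, ...) {
    simConfig(linesPerGroup = c(B73 = 45, `207` = 45, HZS = 45,
                                Mo17 = 45),
              nMarkers = nMarkers,
              chromLengthsBp = c(`1` = 5e6, `2` = 5e6),
              nSegmentsPerGroup = 3L,
              segmentSizeRange = c(60e3, 100e3),
              minSegmentGapBp = 100e3,
              seed = seed, ...)
}

truthRanges <- function(truth) {
    GenomicRanges::GRanges(truth$segments$chrom,
                           IRanges::IRanges(truth$segments$start,
                                            truth$segments$end))
}

## Recovery metrics of a scan against the planted truth: per-group
## sensitivity (planted blocks intersected by called segments),
## false-called length fraction (called segments touching no planted
## block of the group), and the fraction of planted-specific length that
## the venn partition assigns to exactly the right group.
recoveryMetrics <- function(sim, segs) {
    ts <- sim$truth$segments
    tg <- truthRanges(sim$truth)
    sens <- falseLen <- numeric(0)
    for (g in sim$truth$groups) {
        own <- ts$groups == g
        sens <- c(sens, mean(GenomicRanges::countOverlaps(
            tg[own], segs[[g]]) > 0))
        fl <- segs[[g]][GenomicRanges::countOverlaps(segs[[g]],
                                                     tg[own]) == 0]
        falseLen <- c(falseLen,
                      sum(GenomicRanges::width(fl)) /
                      max(1, sum(GenomicRanges::width(segs[[g]]))))
    }
    vp <- vennPartition(segs)
    iv <- vp@intervals
    lab <- S4Vectors::mcols(iv)$groups
    okLen <- totLen <- 0
    for (i in seq_len(nrow(ts))) {
        blk <- tg[i]
        totLen <- totLen + GenomicRanges::width(blk)
        hits <- GenomicRanges::findOverlaps(blk, iv)
        for (j in S4Vectors::subjectHits(hits))
            if (identical(as.character(lab[[j]]), ts$groups[i]))
                okLen <- okLen + GenomicRanges::width(
                    GenomicRanges::pintersect(blk, iv[j]))
    }
    list(sensitivity = sens, falseLenFrac = falseLen,
         specificLenFrac = okLen / totLen, venn = vp)
}

## Brute-force per-marker gene diversity: enumerate the allele pool and
## tally, independent of the matrix algebra in geneDiversity().
gdOracle <- function(d, minCalls = 4L) {
    apply(d, 1L, function(row) {
        row <- row[!is.na(row)]
        if (length(row) < minCalls) return(NA_real_)
        alleles <- unlist(lapply(row, function(x)
            switch(as.character(x), `0` = c("r", "r"), `1` = c("r", "a"),
                   `2` = c("a", "a"))))
        f <- table(alleles) / length(alleles)
        1 - sum(f^2)
    })
}

## Basepair-resolution oracle for the venn partition: color every bp of
## the union by group membership and count maximal runs per class.
vennOracle <- function(sets, maxCoord) {
    groups <- names(sets)
    cols <- matrix(FALSE, maxCoord, length(groups),
                   dimnames = list(NULL, groups))
    for (g in groups) {
        s <- sets[[g]]
        for (k in seq_along(s)) {
            cols[GenomicRanges::start(s)[k]:GenomicRanges::end(s)[k],
                 g] <- TRUE
        }
    }
    covered <- rowSums(cols) > 0
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    iv <- cbind(starts[runs$values], ends[runs$values])
    labs <- apply(iv, 1L, function(se) {
        sub <- cols[se[1]:se[2], , drop = FALSE]
        paste(groups[colSums(sub) > 0], collapse = "+")
    })
    table(labs)
}

## One random interval set per group on a single small chromosome.
randomIntervalSets <- function(groups = c("A", "B", "C", "D"),
                               nPer = 5, maxCoord = 2000) {
    sets <- lapply(groups, function(g) {
        st <- sort(sample.int(maxCoord - 50, nPer))
        en <- pmin(st + sample(10:120, nPer, replace = TRUE), maxCoord)
        GenomicRanges::reduce(GenomicRanges::GRanges(
            "1", IRanges::IRanges(st, en)))
    })
    names(sets) <- groups
    sets[vapply(sets, length, 1L) > 0]
}

## Memoised heavy simulations shared across test files.
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(key, maker) {
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- maker()
    .simCache[[key]]
}
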