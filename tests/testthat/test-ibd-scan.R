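test_that("gene diversity equals the two-random-alleles probability", {
    ## monomorphic -> 0; balanced -> 0.5; 6:2 alleles with missing -> 0.375
    d <- rbind(m1 = c(0L, 0L, 0L, 0L, 0L),
               m2 = c(0L, 0L, 2L, 2L, 0L),
               m3 = c(0L, 0L, 0L, 2L, NA))
    colnames(d) <- paste0("L", 1:5)
    gp <- toyPanel(d, group = rep("G1", 5))
    gd <- gdValues(geneDiversity(gp, "G1", minCalls = 2L))
    expect_equal(unname(gd["m1"]), 0)
    ## m2: p = 4/10 -> 1 - .16 - .36 = .48
    expect_equal(unname(gd["m2"]), 0.48)
    ## m3: alleles 6 ref / 2 alt over 4 calls -> 1 - .75^2 - .25^2
    expect_equal(unname(gd["m3"]), 0.375)
})

test_that("gene diversity is invariant to allele swap and line order and
           respects the call guard", {
    gp <- randomPanel(nLines = 10, nMarkers = 50, missRate = 0.3, seed = 6)
    d <- dosage(gp)
    g1 <- gdValues(geneDiversity(toyPanel(d, group = rep("g", 10)), "g"))
    g2 <- gdValues(geneDiversity(toyPanel(2L - d, group = rep("g", 10)),
                                 "g"))
    expect_equal(g1, g2)
    perm <- sample(ncol(d))
    g3 <- gdValues(geneDiversity(toyPanel(d[, perm], group = rep("g", 10)),
                                 "g"))
    expect_equal(unname(g1), unname(g3))
    nCalls <- rowSums(!is.na(d))
    expect_true(all(is.na(g1[nCalls < 4])))
    expect_error(geneDiversity(gp, "absent-group"), "two panel lines")
})

test_that("tag loci are exactly the guarded monomorphic markers", {
    set.seed(30)
    d <- matrix(rbinom(50 * 8, 1, 0.5) * 2L, 50, 8,
                dimnames = list(sprintf("m%02d", 1:50), paste0("L", 1:8)))
    mono <- sample(50, 7)
    d[mono, ] <- 0L
    d[setdiff(seq_len(50), mono), 1] <- 2L   # ensure others polymorphic
    gp <- toyPanel(d, group = rep("g", 8))
    prof <- geneDiversity(gp, "g")
    tags <- findTagLoci(prof)
    ## brute force: columns with a single observed allele
    handMono <- names(which(apply(d, 1, function(r)
        length(unique(r[!is.na(r)])) == 1L)))
    expect_setequal(names(tags), handMono)
    expect_identical(length(tags), 7L)

    ## guard: a GD-0 marker with too few calls is not a tag
    d2 <- rbind(t1 = c(0L, NA, NA, NA, NA, NA, NA, NA), d)
    prof2 <- geneDiversity(toyPanel(d2, group = rep("g", 8)), "g",
                           minCalls = 4L)
    expect_false("t1" %in% names(findTagLoci(prof2)))
})

test_that("window means average the in-window GD values", {
    prof <- diversityProfile(gd = c(0, 0.1, 0.2, 0.6),
                             chrom = "1",
                             pos = c(100e3, 110e3, 120e3, 200e3))
    ## 25 kb window around the tag covers the first three markers
    expect_equal(windowMeanGd(prof, "1", 100e3), 0.1)
    ## window holding only the tag
    prof2 <- diversityProfile(gd = c(0, 0.5), chrom = "1",
                              pos = c(100e3, 200e3))
    expect_equal(windowMeanGd(prof2, "1", 100e3), 0)
})

test_that("window means equal a naive rescan on a randomized map", {
    set.seed(31)
    pos <- sort(sample.int(2e6, 400))
    gd <- runif(400); gd[sample(400, 30)] <- 0; gd[sample(400, 10)] <- NA
    prof <- diversityProfile(gd, "7", pos)
    tags <- which(!is.na(gd) & gd == 0)
    naive <- vapply(tags, function(i) {
        sel <- abs(pos - pos[i]) <= 25000 & !is.na(gd)
        mean(gd[sel])
    }, numeric(1))
    fast <- windowMeanGd(prof, rep("7", length(tags)), pos[tags])
    expect_equal(fast, naive, tolerance = 1e-12)
})

test_that("chromosome thresholds follow mean minus half the sample SD", {
    prof <- diversityProfile(gd = c(0, 0.1, 0.2, 0.3, 0.4), chrom = "1",
                             pos = (1:5) * 1e4)
    expect_equal(chromosomeThreshold(prof, "1"),
                 0.2 - 0.5 * sd(c(0, .1, .2, .3, .4)), tolerance = 1e-12)
    ## constant GDs: SD 0, threshold equals the constant
    profC <- diversityProfile(gd = rep(0.25, 6), chrom = "2",
                              pos = (1:6) * 1e4)
    expect_equal(chromosomeThreshold(profC, "2"), 0.25)
    ## against an independent two-pass computation
    set.seed(32)
    gd <- runif(500)
    profR <- diversityProfile(gd, "3", sort(sample.int(5e6, 500)))
    m <- sum(gd) / length(gd)
    s <- sqrt(sum((gd - m)^2) / (length(gd) - 1))
    expect_equal(chromosomeThreshold(profR, "3"), m - 0.5 * s,
                 tolerance = 1e-12)
    expect_error(chromosomeThreshold(prof, "9"), "fewer than two")
})

test_that("accepted windows merge when overlapping and stay apart when not", {
    ## background 0.5, threshold 0.5 - 0.5*sd; tags at 100 kb and 110 kb
    ## produce overlapping accepted windows; a tag at 400 kb is separate
    pos <- c(seq(10e3, 490e3, by = 10e3))
    gd <- rep(0.5, length(pos))
    gd[pos %in% c(100e3, 110e3, 400e3)] <- 0
    prof <- diversityProfile(gd, "1", pos)
    segs <- callSegments(prof)
    expect_identical(length(segs), 2L)
    expect_equal(start(segs)[1], 75e3)
    expect_equal(end(segs)[1], 135e3)
    expect_equal(start(segs)[2], 375e3)
    ## merged segment counts both tags
    expect_identical(S4Vectors::mcols(segs)$n_tags, c(2L, 1L))
})

test_that("segment calling is order-independent and re-checkable post hoc", {
    cs <- cachedSim("ciSim", function() {
        sim <- simulatePanel(ciConfig(101L))
        profs <- lapply(stats::setNames(nm = sim$truth$groups),
                        function(g) geneDiversity(sim$panel, g))
        segs <- lapply(profs, callSegments)
        list(sim = sim, profs = profs, segs = segs)
    })
    prof <- cs$profs[["B73"]]
    tags <- findTagLoci(prof)
    set.seed(33)
    shuffled <- callSegments(prof, tags = tags[sample(length(tags))])
    expect_identical(as.data.frame(cs$segs[["B73"]]),
                     as.data.frame(shuffled))

    ## every called segment holds >= 1 tag and beats its threshold
    segs <- cs$segs[["B73"]]
    expect_true(all(GenomicRanges::countOverlaps(segs, tags) >= 1))
    thr <- chromStats(prof)$threshold[
        match(as.character(seqnames(segs)), chromStats(prof)$chrom)]
    expect_true(all(S4Vectors::mcols(segs)$mean_window_gd < thr))
})

test_that("planted conserved blocks of 80-200 kb are recovered in a fully
           resampled background", {
    cfg <- simConfig(
        linesPerGroup = c(FP = 15, other = 2),
        nMarkers = 8000L,
        chromLengthsBp = stats::setNames(rep(2.2e6, 4),
                                         as.character(1:4)),
        nSegmentsPerGroup = 12L, segmentSizeRange = c(80e3, 200e3),
        minSegmentGapBp = 120e3, rho = 1, seed = 51L)
    ## blocks all belong to FP: background is resampled panel-wide,
    ## giving mean background GD near 0.35
    sim <- simulatePanel(cfg)
    prof <- geneDiversity(sim$panel, "FP")
    ts <- sim$truth$segments
    own <- truthRanges(sim$truth)[ts$groups == "FP"]
    gdBg <- gdValues(prof)[GenomicRanges::countOverlaps(
        prof@markers, truthRanges(sim$truth)) == 0]
    expect_gt(mean(gdBg, na.rm = TRUE), 0.30)
    segs <- callSegments(prof)
    hit <- GenomicRanges::countOverlaps(own, segs) > 0
    expect_gte(sum(hit), 11)
    false <- segs[GenomicRanges::countOverlaps(segs, own) == 0]
    expect_lt(sum(GenomicRanges::width(false)) /
              sum(GenomicRanges::width(segs)), 0.1)
})

test_that("venn partition labels toy interval sets correctly", {
    A <- GRanges("1", IRanges::IRanges(100, 200))
    B <- GRanges("1", IRanges::IRanges(150, 250))
    vp <- vennCounts(vennPartition(list(A = A, B = B)))
    expect_identical(unname(vp$total), c(1L, 1L))
    expect_identical(unname(vp$specific), c(0L, 0L))
    expect_identical(unname(vp$common["A+B"]), 1L)

    B2 <- GRanges("1", IRanges::IRanges(300, 400))
    vp2 <- vennCounts(vennPartition(list(A = A, B = B2)))
    expect_identical(unname(vp2$specific), c(1L, 1L))
    expect_identical(unname(vp2$common["A+B"]), 0L)
})

test_that("reciprocal overlap rule demands coverage of the union interval", {
    A <- GRanges("1", IRanges::IRanges(1, 1000))
    B <- GRanges("1", IRanges::IRanges(991, 1000))
    anyR <- vennCounts(vennPartition(list(A = A, B = B),
                                     rule = "any_overlap"))
    rec <- vennCounts(vennPartition(list(A = A, B = B),
                                    rule = "reciprocal", fraction = 0.5))
    expect_identical(unname(anyR$common["A+B"]), 1L)
    expect_identical(unname(rec$common["A+B"]), 0L)
    expect_identical(unname(rec$specific["A"]), 1L)
})

test_that("venn class counts match the basepair coloring oracle", {
    set.seed(34)
    for (i in 1:30) {
        sets <- randomIntervalSets(nPer = sample(2:6, 1))
        if (length(sets) < 2) next
        vp <- vennPartition(sets)
        got <- vennCounts(vp)$exact
        want <- vennOracle(sets, 2000)
        expect_identical(sort(names(got)), sort(names(want)))
        expect_identical(as.integer(got[sort(names(got))]),
                         as.integer(want[sort(names(got))]))
    }
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
    segs <- GRanges("3", IRanges::IRanges(1001, 2000))
    S4Vectors::mcols(segs) <- S4Vectors::DataFrame(
        group = "B73", mean_window_gd = 0.05, n_markers = 10L,
        n_tags = 3L)
    f <- withr::local_tempfile(fileext = ".bed")
    writeSegmentsBed(segs, f)
    bed <- utils::read.table(f, sep = "\t")
    expect_identical(bed$V2, 1000L)
    expect_identical(bed$V3, 2000L)
    expect_identical(bed$V4, "B73")
})
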