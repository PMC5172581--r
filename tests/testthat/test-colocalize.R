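mkSegs <- function(df, groups = "G1") {
    gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$group <- rep_len(groups, length(gr))
    GenomeInfoDb::seqlevels(gr) <- as.character(1:5)
    gr
}

mkQtns <- function(markers, chrom, pos, trait = "EH") {
    data.frame(trait = trait, marker = markers, chrom = chrom, pos = pos,
               effect = 1, se = 0.1, p = 1e-9, status = "tested",
               cutoff = 1e-6, passes = TRUE)
}

test_that("segments are classed by their QTN and QTL support", {
    segs <- mkSegs(data.frame(chrom = "1",
                              start = c(1, 2e5, 4e5),
                              end = c(1e5, 3e5, 5e5)))
    qtns <- mkQtns("q1", "1", 5e4)
    qtls <- data.frame(name = "yld1", trait = "EH", chrom = "1",
                       start = 4e4, end = 1.2e5)
    out <- projectLoci(segs, qtns, qtls)
    expect_identical(nrow(out), 1L)
    expect_identical(out$support_class, "both")
    expect_identical(out$qtns, "q1")
    expect_identical(out$qtls, "yld1")

    out2 <- projectLoci(segs, mkQtns("q2", "1", 2.5e5), NULL)
    expect_identical(out2$support_class, "qtn_only")
    out3 <- projectLoci(segs, NULL,
                        data.frame(name = "n1", trait = "PH", chrom = "1",
                                   start = 4.5e5, end = 6e5))
    expect_identical(out3$support_class, "qtl_only")
    expect_error(projectLoci(segs, mkQtns("qx", "12", 100), NULL),
                 "chromosome label")
})

test_that("projection matches the all-pairs interval oracle", {
    set.seed(55)
    segs <- mkSegs(data.frame(chrom = sample(as.character(1:3), 40,
                                             replace = TRUE),
                              start = s <- sample.int(9e5, 40),
                              end = s + sample.int(5e4, 40)))
    qtns <- mkQtns(sprintf("q%02d", 1:60),
                   sample(as.character(1:3), 60, replace = TRUE),
                   sample.int(1e6, 60))
    st <- sample.int(9e5, 30)
    qtls <- data.frame(name = sprintf("l%02d", 1:30), trait = "EL",
                       chrom = sample(as.character(1:3), 30,
                                      replace = TRUE),
                       start = st, end = st + sample.int(8e4, 30))
    out <- projectLoci(segs, qtns, qtls)
    for (i in seq_along(segs)) {
        ch <- as.character(seqnames(segs))[i]
        nQ <- sum(qtns$chrom == ch & qtns$pos >= start(segs)[i] &
                  qtns$pos <= end(segs)[i])
        nL <- sum(qtls$chrom == ch & qtls$start <= end(segs)[i] &
                  qtls$end >= start(segs)[i])
        row <- out[out$start == start(segs)[i] & out$chrom == ch, ]
        if (nQ + nL == 0) {
            expect_identical(nrow(row), 0L)
        } else {
            expect_identical(row$n_qtns, nQ)
            expect_identical(row$n_qtls, nL)
        }
    }
})

test_that("clusters require the configured number of co-segmental loci", {
    segs <- mkSegs(data.frame(chrom = "1", start = c(1e5, 5e5),
                              end = c(2e5, 6e5)))
    qtns <- mkQtns(c("a", "b", "c", "d"), "1",
                   c(1.1e5, 1.5e5, 1.9e5, 5.5e5),
                   trait = c("ED", "DTS", "EH/PH", "EL"))
    sup <- projectLoci(segs, qtns, NULL)
    cl <- findClusters(sup, minLoci = 3)
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$n_features, 3L)
    expect_identical(cl$n_trait_categories, 3L)
    expect_identical(nrow(findClusters(sup, minLoci = 5)), 0L)
})

test_that("candidate genes respect the tag-linkage radius", {
    segs <- mkSegs(data.frame(chrom = "1", start = 1e5, end = 2e5))
    tags <- GRanges("1", IRanges::IRanges(15e4, width = 1),
                    gd = 0, n_calls = 10L, group = "G1")
    ann <- GRanges("1", IRanges::IRanges(
        start = c(14e4, 16e4, 175e3, 21e4),
        end = c(145e3, 165e3, 185e3, 215e3)),
        strand = c("+", "-", "+", "-"))
    names(ann) <- c("inTag", "g10kb", "g25kb", "g60kb")
    ## distances from tag 150 kb: 5 kb, 10 kb, 25 kb, 60 kb
    cand <- candidateGenes(segs, tags, ann, radiusBp = 25000)
    expect_setequal(cand$gene_id, c("inTag", "g10kb", "g25kb"))
    expect_equal(cand$distance_bp[cand$gene_id == "g10kb"], 10e3)
    ## tag inside a gene: distance 0
    annIn <- GRanges("1", IRanges::IRanges(149e3, 151e3))
    names(annIn) <- "host"
    candIn <- candidateGenes(segs, tags, annIn, radiusBp = 25000)
    expect_equal(candIn$distance_bp, 0)
    ## widening the radius never loses candidates
    wide <- candidateGenes(segs, tags, ann, radiusBp = 80000)
    expect_true(all(cand$gene_id %in% wide$gene_id))
    expect_true("g60kb" %in% wide$gene_id)
    expect_error(candidateGenes(segs, tags, GRanges()), "empty")
    ## every emitted candidate re-validates the radius
    expect_true(all(cand$distance_bp <= 25000))
})

test_that("simulated annotation round-trips through GFF3 into candidates", {
    cfg <- simConfig(linesPerGroup = c(FP = 15, other = 4),
                     nMarkers = 4000L, chromLengthsBp = c(`1` = 3e6),
                     nSegmentsPerGroup = 4L,
                     segmentSizeRange = c(60e3, 90e3),
                     minSegmentGapBp = 150e3, rho = 1, seed = 71L)
    sim <- simulatePanel(cfg)
    dir <- withr::local_tempdir()
    paths <- writeAnnotation(sim$truth, cfg, dir)
    ann <- rtracklayer::import(paths["gff"])
    expect_true(all(S4Vectors::mcols(ann)$type == "gene"))
    names(ann) <- S4Vectors::mcols(ann)$ID

    prof <- geneDiversity(sim$panel, "FP")
    segs <- callSegments(prof)
    tags <- findTagLoci(prof)
    cand <- candidateGenes(segs, tags, ann, radiusBp = 25000)
    tg <- sim$truth$genes
    ## genes planted inside or 10 kb off a block are candidates; the
    ## 30 kb genes lie beyond the radius
    fpSegs <- sim$truth$segments$segment_id[
        sim$truth$segments$groups == "FP"]
    insideIds <- tg$gene_id[tg$offset_class == "inside" &
                            tg$segment_id %in% fpSegs]
    nearIds <- tg$gene_id[tg$offset_class == "near" &
                          tg$segment_id %in% fpSegs]
    farIds <- tg$gene_id[tg$offset_class == "far" &
                         tg$segment_id %in% fpSegs]
    expect_true(all(insideIds %in% cand$gene_id))
    expect_true(all(nearIds %in% cand$gene_id))
    ## every reported linkage honors the radius, so a 30 kb-offset gene
    ## can only enter anchored to a tag outside its own planted block
    expect_true(all(cand$distance_bp <= 25000))
    farRows <- cand[cand$gene_id %in% farIds, , drop = FALSE]
    if (nrow(farRows)) {
        tseg <- sim$truth$segments
        blk <- tseg[match(tg$segment_id[match(farRows$gene_id,
                                              tg$gene_id)],
                          tseg$segment_id), ]
        expect_true(all(farRows$tag_pos < blk$start |
                        farRows$tag_pos > blk$end))
    }

    ## a QTL overlapping a planted block supports its called segment
    sup <- projectLoci(segs, NULL, sim$truth$qtls)
    expect_identical(unique(sup$support_class), "qtl_only")
    expect_gt(nrow(sup), 0L)
})
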