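test_that("hapmap files round-trip through the panel container", {
    d <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 2L, 0L, 0L, NA, 1L),
                nrow = 4,
                dimnames = list(c("m1", "m2", "m3", "m4"),
                                c("L1", "L2", "L3")))
    gp <- toyPanel(d, chrom = c("1", "1", "2", "2"),
                   pos = c(100L, 900L, 150L, 400L),
                   ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
    f <- withr::local_tempfile(fileext = ".hmp.txt")
    writeGenotypes(gp, f, "hapmap")
    gp2 <- readGenotypes(f, "hapmap")
    expect_identical(dim(gp2), dim(gp))
    expect_identical(dosage(gp2), dosage(gp))
    expect_identical(names(markerRanges(gp2)), names(markerRanges(gp)))

    ## clean fixture: no missing calls survive as missing only where written
    expect_identical(sum(is.na(dosage(gp2))), 2L)
})

test_that("unknown nucleotide codes become missing calls", {
    f <- withr::local_tempfile(fileext = ".hmp.txt")
    hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                   "center", "protLSID", "assayLSID", "panelLSID",
                   "QCcode", "L1", "L2", "L3"), collapse = "\t")
    rows <- c(paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6),
                      "AA", "NN", "AG"), collapse = "\t"),
              paste(c("m2", "C/T", "1", "200", "+", rep("NA", 6),
                      "CC", "CT", "TT"), collapse = "\t"))
    writeLines(c(hdr, rows), f)
    gp <- readGenotypes(f, "hapmap")
    expect_identical(unname(dosage(gp)["m1", ]), c(0L, NA, 1L))
})

test_that("non-biallelic markers are dropped with a warning", {
    f <- withr::local_tempfile(fileext = ".hmp.txt")
    hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                   "center", "protLSID", "assayLSID", "panelLSID",
                   "QCcode", "L1", "L2"), collapse = "\t")
    rows <- c(paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6),
                      "AA", "AG"), collapse = "\t"),
              paste(c("m2", "A/G/T", "1", "200", "+", rep("NA", 6),
                      "AA", "GT"), collapse = "\t"),
              paste(c("m3", "C/T", "1", "300", "+", rep("NA", 6),
                      "CC", "TT"), collapse = "\t"),
              paste(c("m4", "G/T", "1", "400", "+", rep("NA", 6),
                      "GG", "GT"), collapse = "\t"))
    writeLines(c(hdr, rows), f)
    expect_warning(gp <- readGenotypes(f, "hapmap"), "not biallelic")
    expect_identical(nrow(gp), 3L)
    expect_false("m2" %in% rownames(dosage(gp)))
})

test_that("duplicated physical positions are a hard error naming the pair", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("marker_id,chrom,pos,ref,alt,L1,L2",
                 "m1,1,100,A,G,0,2",
                 "m2,1,100,C,T,0,1"), f)
    expect_error(readGenotypes(f, "csv"), "1:100")
})

test_that("csv round trip preserves calls, order and missing mask", {
    gp <- randomPanel(nLines = 8, nMarkers = 30, missRate = 0.1, seed = 42)
    f <- withr::local_tempfile(fileext = ".csv")
    writeGenotypes(gp, f, "csv")
    gp2 <- readGenotypes(f, "csv")
    expect_identical(dosage(gp2), dosage(gp))
    expect_identical(as.character(seqnames(markerRanges(gp2))),
                     as.character(seqnames(markerRanges(gp))))
    expect_identical(start(markerRanges(gp2)), start(markerRanges(gp)))
})

test_that("complementary allele frames are harmonized to the first panel", {
    mkP <- function(ref, alt, calls, ids)
        GenotypePanel(matrix(calls, nrow = 2,
                             dimnames = list(c("m1", "m2"), ids)),
                      chrom = "1", pos = c(100, 200), ref = ref, alt = alt)
    A <- mkP(c("A", "A"), c("G", "T"), c(0, 2, 2, 0), c("L1", "L2"))
    ## panel B reports m1 on the opposite strand: (T,C) complements (A,G)
    B <- mkP(c("T", "A"), c("C", "T"), c(0, 2, 2, 0), c("L3", "L4"))
    H <- harmonizePanels(list(A, B))
    expect_identical(unname(dosage(H)["m1", ]), c(0L, 2L, 0L, 2L))
    mc <- S4Vectors::mcols(markerRanges(H))
    expect_identical(mc["m1", "ref"], "A")
    ## A/T markers cannot be strand-resolved and are flagged
    expect_true(mc["m2", "ambiguous"])
    expect_false(mc["m1", "ambiguous"])
    expect_identical(nrow(harmonizePanels(list(A, B),
                                          dropAmbiguous = TRUE)), 1L)
})

test_that("swapped ref/alt flips dosages and bad allele pairs are dropped", {
    mkP <- function(ref, alt, calls, ids)
        GenotypePanel(matrix(calls, nrow = 2,
                             dimnames = list(c("m1", "m2"), ids)),
                      chrom = "1", pos = c(100, 200), ref = ref, alt = alt)
    A <- mkP(c("A", "A"), c("G", "C"), c(0, 2, 2, 0), c("L1", "L2"))
    B <- mkP(c("G", "A"), c("A", "T"), c(0, 1, 2, 0), c("L3", "L4"))
    expect_warning(H <- harmonizePanels(list(A, B)),
                   "neither equal nor complementary")
    ## m2 allele sets {A,C} vs {A,T} incompatible -> dropped
    expect_identical(rownames(dosage(H)), "m1")
    ## B's m1 has swapped alleles: dosages flip 0 -> 2, 2 -> 0
    expect_identical(unname(dosage(H)["m1", c("L3", "L4")]), c(2L, 0L))
})

test_that("harmonization is idempotent and disjoint panels error", {
    gp <- randomPanel(nLines = 6, nMarkers = 20, seed = 3)
    H <- harmonizePanels(list(gp, gp))
    expect_identical(dosage(H), dosage(gp))
    gp2 <- toyPanel(matrix(0L, 2, 2,
                           dimnames = list(c("x1", "x2"), c("Z1", "Z2"))),
                    chrom = "3", pos = c(5, 6))
    expect_error(harmonizePanels(list(gp, gp2)), "no markers")
})

test_that("snp filters apply strict MAF and missing-rate inequalities", {
    ## marker 1: 1 hom-alt of 10 lines -> MAF 0.10 > 0.05, retained
    ## marker 2: 2 of 10 calls missing -> rate 0.2, not < 0.2, dropped
    d <- rbind(m1 = c(2L, rep(0L, 9)),
               m2 = c(NA, NA, rep(0L, 7), 2L),
               m3 = c(rep(0L, 5), rep(2L, 5)))
    colnames(d) <- paste0("L", 1:10)
    gp <- toyPanel(d)
    kept <- filterSnps(gp, mafMin = 0.05, missMax = 0.2)
    expect_setequal(rownames(dosage(kept)), c("m1", "m3"))
    expect_error(filterSnps(gp[1:2, ], mafMin = 0.3, missMax = 0.2),
                 "no markers")
})

test_that("filtering matches hand-computed MAFs on a 20-marker fixture", {
    gp <- randomPanel(nLines = 10, nMarkers = 20, missRate = 0.15,
                      seed = 11)
    d <- dosage(gp)
    handMaf <- apply(d, 1L, function(row) {
        row <- row[!is.na(row)]
        alt <- sum(row)
        p <- alt / (2 * length(row))
        min(p, 1 - p)
    })
    handMiss <- rowMeans(is.na(d))
    expectKept <- names(which(handMaf > 0.1 & handMiss < 0.2))
    kept <- filterSnps(gp, mafMin = 0.1, missMax = 0.2)
    expect_setequal(rownames(dosage(kept)), expectKept)
    ## filtering is idempotent and yields a marker subset
    again <- filterSnps(kept, mafMin = 0.1, missMax = 0.2)
    expect_identical(dosage(again), dosage(kept))
    expect_true(all(rownames(dosage(kept)) %in% rownames(d)))
})
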