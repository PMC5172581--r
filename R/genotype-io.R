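#' Read a SNP genotype panel
#'
#' Reads a biallelic SNP panel from either a HapMap-style tab table or the
#' package's simple CSV dialect into a \linkS4class{GenotypePanel}.
#'
#' The HapMap dialect is tab-separated with the 11 standard metadata
#' columns (\code{rs#}, \code{alleles}, \code{chrom}, \code{pos},
#' \code{strand}, \code{assembly#}, \code{center}, \code{protLSID},
#' \code{assayLSID}, \code{panelLSID}, \code{QCcode}) followed by one
#' column per line, cells holding nucleotide pairs ("AA", "AG", "NN").
#' The CSV dialect has a header of \code{marker_id, chrom, pos, ref, alt}
#' followed by line ids, and calls coded 0/1/2/NA.
#'
#' Markers whose allele field or observed calls are not biallelic are
#' dropped with a warning; unknown nucleotide codes become missing calls;
#' duplicated (chrom, pos) pairs are a hard error.
#'
#' @param path path to the genotype file.
#' @param dialect "hapmap" or "csv".
#' @return A \linkS4class{GenotypePanel} sorted by (chrom, pos).
#' @seealso [writeGenotypes()], [filterSnps()], [harmonizePanels()]
#' @export
readGenotypes <- function(path, dialect = c("hapmap", "csv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (dialect == "csv") .readGenotypesCsv(path) else .readGenotypesHapmap(path)
}

.checkDupPositions <- function(chrom, pos) {
    key <- paste(chrom, pos, sep = ":")
    if (anyDuplicated(key))
        stop("duplicated (chrom, pos) pair(s): ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
}

.readGenotypesCsv <- function(path) {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    need <- c("marker_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(tab)[seq_len(5)]))
        stop("CSV dialect requires leading columns: ",
             paste(need, collapse = ", "))
    .checkDupPositions(tab$chrom, tab$pos)
    calls <- as.matrix(tab[, -seq_len(5), drop = FALSE])
    mode(calls) <- "numeric"
    bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
    if (any(bad)) {
        warning(sum(bad), " call(s) with unknown codes set to missing")
        calls[bad] <- NA
    }
    rownames(calls) <- tab$marker_id
    keepBiallelic <- tab$ref != tab$alt &
        tab$ref %in% names(WATSON_CRICK) & tab$alt %in% names(WATSON_CRICK)
    if (!all(keepBiallelic))
        warning(sum(!keepBiallelic),
                " marker(s) dropped: not biallelic A/C/G/T")
    tab <- tab[keepBiallelic, , drop = FALSE]
    calls <- calls[keepBiallelic, , drop = FALSE]
    GenotypePanel(calls, chrom = tab$chrom, pos = tab$pos,
                  ref = tab$ref, alt = tab$alt)
}

.readGenotypesHapmap <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, comment.char = "",
                             colClasses = "character", quote = "")
    if (ncol(tab) < 12L)
        stop("HapMap dialect requires 11 metadata columns plus line columns")
    meta <- tab[, seq_len(11), drop = FALSE]
    cells <- as.matrix(tab[, -seq_len(11), drop = FALSE])
    alleles <- strsplit(meta[[2]], "/", fixed = TRUE)
    biallelic <- lengths(alleles) == 2L &
        vapply(alleles, function(a)
            all(a %in% names(WATSON_CRICK)) && a[1] != a[2], logical(1))
    ref <- vapply(alleles, `[`, character(1), 1L)
    alt <- vapply(alleles, function(a) a[min(2L, length(a))], character(1))

    ## Nucleotide pair -> alt dosage; anything outside {ref, alt} is missing.
    n <- nrow(cells)
    a1 <- substr(cells, 1, 1)
    a2 <- substr(cells, 2, 2)
    score <- function(a) ifelse(a == ref, 0L, ifelse(a == alt, 1L, NA_integer_))
    d <- score(a1) + score(a2)
    ## A third observed nucleotide makes the marker effectively multiallelic;
    ## such cells are already missing, the marker itself is kept unless the
    ## allele field was non-biallelic.
    if (!all(biallelic))
        warning(sum(!biallelic),
                " marker(s) dropped: allele field not biallelic")
    dim(d) <- dim(cells)
    dimnames(d) <- list(meta[[1]], colnames(cells))
    pos <- as.integer(meta[[4]])
    .checkDupPositions(meta[[3]][biallelic], pos[biallelic])
    GenotypePanel(d[biallelic, , drop = FALSE],
                  chrom = meta[[3]][biallelic], pos = pos[biallelic],
                  ref = ref[biallelic], alt = alt[biallelic])
}

#' Write a genotype panel
#'
#' Writes a \linkS4class{GenotypePanel} in either dialect accepted by
#' [readGenotypes()]; a write/read round trip reproduces calls, marker
#' order and the missing mask exactly.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param path output file path.
#' @param dialect "hapmap" or "csv".
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path, dialect = c("hapmap", "csv")) {
    dialect <- match.arg(dialect)
    rr <- markerRanges(x)
    d <- dosage(x)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- S4Vectors::mcols(rr)$ref
    alt <- S4Vectors::mcols(rr)$alt
    if (dialect == "csv") {
        out <- data.frame(marker_id = rownames(d), chrom = chrom, pos = pos,
                          ref = ref, alt = alt, check.names = FALSE)
        out <- cbind(out, as.data.frame(d, check.names = FALSE))
        utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    } else {
        code <- function(dd)
            ifelse(is.na(dd), "NN",
                   ifelse(dd == 0L, paste0(ref, ref),
                          ifelse(dd == 2L, paste0(alt, alt),
                                 paste0(ref, alt))))
        cells <- apply(d, 2, code)
        meta <- data.frame(`rs#` = rownames(d),
                           alleles = paste(ref, alt, sep = "/"),
                           chrom = chrom, pos = pos, strand = "+",
                           `assembly#` = "RefGen", center = "NA",
                           protLSID = "NA", assayLSID = "NA",
                           panelLSID = "NA", QCcode = "NA",
                           check.names = FALSE)
        utils::write.table(cbind(meta, cells), path, sep = "\t",
                           row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' Merge genotype panels into one allele frame
#'
#' Harmonizes two or more panels genotyped on overlapping marker sets.
#' Markers are matched on identical (chrom, pos) and marker id; the merged
#' panel covers the intersection. Where a later panel's allele pair is the
#' Watson-Crick complement of the first panel's, its calls are flipped
#' into the first panel's allele frame (dosages are additionally reversed
#' when ref and alt are swapped). Strand-ambiguous A/T and C/G markers
#' cannot be disambiguated by complementation and are flagged in the
#' marker metadata (\code{ambiguous}); \code{dropAmbiguous = TRUE} removes
#' them. Matched markers whose allele sets are neither equal nor
#' complementary are dropped with a warning.
#'
#' Lines present in several panels keep the first panel's calls; the
#' number of discordant non-missing calls is reported via a message.
#'
#' @param panels a list of \linkS4class{GenotypePanel} objects (>= 2).
#' @param dropAmbiguous drop strand-ambiguous markers instead of flagging.
#' @return The merged \linkS4class{GenotypePanel}.
#' @export
harmonizePanels <- function(panels, dropAmbiguous = FALSE) {
    stopifnot(is.list(panels), length(panels) >= 2L)
    keyOf <- function(p) {
        rr <- markerRanges(p)
        paste(names(rr), as.character(GenomicRanges::seqnames(rr)),
              GenomicRanges::start(rr), sep = ":")
    }
    keys <- lapply(panels, keyOf)
    common <- Reduce(intersect, keys)
    if (!length(common))
        stop("panels share no markers (matched on id, chrom and pos)")

    ref0 <- NULL
    merged <- NULL
    conflicts <- 0L
    for (i in seq_along(panels)) {
        p <- panels[[i]]
        idx <- match(common, keys[[i]])
        rr <- markerRanges(p)[idx]
        d <- dosage(p)[idx, , drop = FALSE]
        a <- cbind(S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt)
        if (is.null(ref0)) {
            ref0 <- a
            keep <- rep(TRUE, length(common))
            merged <- d
            lines0 <- colnames(d)
        } else {
            same <- a[, 1] == ref0[, 1] & a[, 2] == ref0[, 2]
            swapped <- a[, 1] == ref0[, 2] & a[, 2] == ref0[, 1]
            compSame <- complementAllele(a[, 1]) == ref0[, 1] &
                complementAllele(a[, 2]) == ref0[, 2]
            compSwap <- complementAllele(a[, 1]) == ref0[, 2] &
                complementAllele(a[, 2]) == ref0[, 1]
            flip <- (swapped | compSwap) & !same
            bad <- !(same | swapped | compSame | compSwap)
            if (any(bad)) {
                warning(sum(bad), " matched marker(s) dropped: allele sets ",
                        "neither equal nor complementary")
                keep <- keep & !bad
            }
            d[flip, ] <- 2L - d[flip, , drop = FALSE]
            dup <- intersect(colnames(d), lines0)
            if (length(dup)) {
                both <- !is.na(merged[, dup, drop = FALSE]) &
                    !is.na(d[, dup, drop = FALSE])
                conflicts <- conflicts +
                    sum(merged[, dup, drop = FALSE][both] !=
                        d[, dup, drop = FALSE][both])
            }
            new <- setdiff(colnames(d), lines0)
            merged <- cbind(merged, d[, new, drop = FALSE])
            lines0 <- colnames(merged)
        }
    }
    if (conflicts > 0L)
        message(conflicts, " discordant duplicate-line call(s); ",
                "first panel's calls kept")
    first <- markerRanges(panels[[1]])[match(common, keys[[1]])]
    ambiguous <- ref0[, 1] == complementAllele(ref0[, 2])
    out <- GenotypePanel(merged[keep, , drop = FALSE],
                         chrom = as.character(
                             GenomicRanges::seqnames(first))[keep],
                         pos = GenomicRanges::start(first)[keep],
                         ref = ref0[keep, 1], alt = ref0[keep, 2])
    rr <- SummarizedExperiment::rowRanges(out)
    ord <- match(names(rr), rownames(merged)[keep])
    S4Vectors::mcols(rr)$ambiguous <- ambiguous[keep][ord]
    SummarizedExperiment::rowRanges(out) <- rr
    if (dropAmbiguous)
        out <- out[!S4Vectors::mcols(
            SummarizedExperiment::rowRanges(out))$ambiguous, ]
    out
}

#' Filter SNPs on minor allele frequency and missing rate
#'
#' Retains markers whose MAF strictly exceeds \code{mafMin} and whose
#' missing-call rate is strictly below \code{missMax} (the source study
#' used MAF > 0.05 and missing rate < 0.2). MAF is computed from allele
#' counts with a heterozygote contributing one copy of each allele and
#' missing calls excluded.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param mafMin minimum (exclusive) minor allele frequency, in [0, 0.5).
#' @param missMax maximum (exclusive) missing rate, in (0, 1].
#' @return The filtered \linkS4class{GenotypePanel}.
#' @export
filterSnps <- function(x, mafMin = 0.05, missMax = 0.2) {
    stopifnot(mafMin >= 0, mafMin < 0.5, missMax > 0, missMax <= 1)
    maf <- markerMaf(x)
    miss <- markerMissingRate(x)
    keep <- !is.na(maf) & maf > mafMin & miss < missMax
    if (!any(keep))
        stop("no markers pass the filters; review mafMin/missMax thresholds")
    x[keep, ]
}
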