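#' Configuration for a founder-descendant panel simulation
#'
#' Bundles every knob of the simulator. The defaults mirror the study
#' panel: four foundation-parent groups with 98/95/61/49 descendant
#' lines, about 43k mapped biallelic SNPs over ten chromosomes, twelve
#' planted group-specific conserved blocks of 80-200 kb per group, 1%
#' missing calls and 0.5% heterozygous calls.
#'
#' Descendants copy their group founder and are then resampled
#' marker-wise from the panel allele distribution with probability
#' \code{rho}, which sets the background within-group diversity;
#' \code{backgroundGdTarget} records the mean per-marker gene diversity
#' this is expected to produce outside planted segments (checked by the
#' simulator tests, not used as a control variable).
#'
#' @param linesPerGroup named integer vector of descendant counts.
#' @param nMarkers total number of SNPs.
#' @param chromLengthsBp named numeric vector of chromosome lengths.
#' @param nSegmentsPerGroup planted group-specific blocks per group
#'   (used when \code{plantedSegments} is NULL).
#' @param segmentSizeRange planted block length range in bp.
#' @param minSegmentGapBp minimum gap between planted blocks, kept large
#'   enough that called segments of different groups (block plus scan
#'   window) cannot run into each other.
#' @param plantedSegments optional explicit \code{data.frame} with
#'   columns chrom, start, end, groups (comma-separated group labels);
#'   NULL places blocks automatically.
#' @param rho per-call probability that a descendant's background marker
#'   is resampled from the panel allele distribution.
#' @param freqRange panel-level allele frequency range (uniform draw).
#' @param backgroundGdTarget expected mean background GD (declarative).
#' @param missingRate,hetRate per-call rates; heterozygous calls are
#'   never planted inside a group's own conserved blocks, which stay at
#'   gene diversity exactly zero before missingness.
#' @param qtnPlan \code{data.frame(trait, h2, marker)} of planted QTNs
#'   (variance fractions in (0,1)); \code{marker = NA} picks a
#'   polymorphic background marker at simulation time. NULL uses a
#'   default four-trait plan.
#' @param groupShifts optional list: trait -> named vector of group mean
#'   shifts.
#' @param nEnvs,nReps phenotype trial dimensions.
#' @param envSd SD of environment main effects.
#' @param noiseScale multiplier on the G-by-E and residual SDs (0 gives
#'   noiseless phenotypes).
#' @param nGenes total genes in the expression matrix (planted-segment
#'   genes plus background genes).
#' @param dePlan \code{data.frame(gene_id, group, shift)} of planted
#'   log2 expression shifts; NULL plants +2/-2 shifts on two
#'   segment-linked genes per group.
#' @param exprSd residual SD of log2 expression within a group.
#' @param nOrgans organ samples for the co-expression mode.
#' @param coexBlocks,coexBlockSize,coexR correlated gene blocks planted
#'   in the organ matrix.
#' @param seed integer seed; identical configurations give bit-identical
#'   simulations.
#' @return A list of class \code{SimConfig}.
#' @seealso [simulatePanel()], [simulatePhenotypes()],
#'   [simulateExpression()], [writeSimulation()]
#' @export
simConfig <- function(linesPerGroup = c(B73 = 98, `207` = 95, HZS = 61,
                                        Mo17 = 49),
                      nMarkers = 43252L,
                      chromLengthsBp = stats::setNames(
                          c(12, 11, 10, 10, 9, 8, 8, 7, 6, 5) * 1e6,
                          as.character(1:10)),
                      nSegmentsPerGroup = 12L,
                      segmentSizeRange = c(80e3, 200e3),
                      minSegmentGapBp = 120e3,
                      plantedSegments = NULL,
                      rho = 0.4,
                      freqRange = c(0.1, 0.9),
                      backgroundGdTarget = 0.3,
                      missingRate = 0.01,
                      hetRate = 0.005,
                      qtnPlan = NULL,
                      groupShifts = NULL,
                      nEnvs = 3L, nReps = 2L, envSd = 1, noiseScale = 1,
                      nGenes = 200L,
                      dePlan = NULL,
                      exprSd = 0.5,
                      nOrgans = 27L,
                      coexBlocks = 2L, coexBlockSize = 5L, coexR = 0.95,
                      seed = 1L) {
    stopifnot(length(linesPerGroup) >= 1L, !is.null(names(linesPerGroup)),
              nMarkers >= 1L, all(chromLengthsBp > 0),
              rho >= 0, rho <= 1, missingRate >= 0, hetRate >= 0)
    cfg <- as.list(environment())
    class(cfg) <- "SimConfig"
    cfg
}

## Place non-overlapping group-specific blocks with guaranteed gaps.
.placeSegments <- function(cfg) {
    groups <- names(cfg$linesPerGroup)
    sizes <- round(stats::runif(cfg$nSegmentsPerGroup * length(groups),
                                cfg$segmentSizeRange[1],
                                cfg$segmentSizeRange[2]))
    owner <- rep(groups, each = cfg$nSegmentsPerGroup)
    o <- sample.int(length(sizes))
    sizes <- sizes[o]
    owner <- owner[o]
    chroms <- names(cfg$chromLengthsBp)
    ## round-robin over chromosomes weighted by length
    share <- cfg$chromLengthsBp / sum(cfg$chromLengthsBp)
    alloc <- diff(c(0, round(cumsum(share) * length(sizes))))
    idx <- split(seq_along(sizes), rep(seq_along(chroms), alloc))
    rows <- list()
    for (ci in seq_along(chroms)) {
        ids <- idx[[as.character(ci)]]
        if (is.null(ids) || !length(ids)) next
        L <- cfg$chromLengthsBp[ci]
        need <- sum(sizes[ids]) + (length(ids) + 1L) * cfg$minSegmentGapBp
        if (need > L)
            stop("planted segments do not fit on chromosome ", chroms[ci],
                 "; shorten blocks or enlarge chromosomes")
        slack <- L - need
        cuts <- sort(stats::runif(length(ids), 0, slack))
        extra <- diff(c(0, cuts))
        at <- 0
        for (k in seq_along(ids)) {
            at <- at + cfg$minSegmentGapBp + extra[k]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chroms[ci], start = round(at) + 1,
                end = round(at) + sizes[ids[k]],
                groups = owner[ids[k]])
            at <- at + sizes[ids[k]]
        }
    }
    seg <- do.call(rbind, rows)
    seg <- seg[order(match(seg$chrom, chroms), seg$start), , drop = FALSE]
    seg$segment_id <- sprintf("seg%03d", seq_len(nrow(seg)))
    rownames(seg) <- NULL
    seg
}

## Gene models at controlled offsets (inside, 10 kb, 30 kb) from each
## planted block, for candidate-gene distance tests.
.placeGenes <- function(seg, cfg) {
    geneLen <- 3e3
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(seg))) {
        L <- cfg$chromLengthsBp[[seg$chrom[i]]]
        span <- seg$end[i] - seg$start[i]
        offs <- list(inside = c(seg$start[i] + round(span / 3)),
                     near = c(seg$end[i] + 10e3),
                     far = c(seg$end[i] + 30e3))
        for (cls in names(offs)) {
            st <- offs[[cls]]
            if (st + geneLen - 1 > L) next
            k <- k + 1L
            rows[[k]] <- data.frame(
                gene_id = sprintf("GENE%04d", k),
                chrom = seg$chrom[i], start = st, end = st + geneLen - 1,
                strand = if (i %% 2L) "+" else "-",
                segment_id = seg$segment_id[i], offset_class = cls)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate a founder-descendant genotype panel with planted truth
#'
#' For each group a founder haplotype is drawn (one allele per marker,
#' panel-level frequencies uniform on \code{freqRange}). Each descendant
#' copies the founder; outside planted segments every marker is
#' independently resampled from the panel allele distribution with
#' probability \code{rho}, creating background within-group diversity.
#' Inside a planted segment listing the group, descendants keep the
#' founder allele exactly, so group gene diversity there is zero before
#' missingness. Heterozygous calls (never inside a group's own planted
#' blocks) and missing calls are sprinkled at the configured rates.
#'
#' @param cfg a [simConfig()] object.
#' @return A list with \code{panel} (a \linkS4class{GenotypePanel}) and
#'   \code{truth}, the machine-readable truth set: planted segments (with
#'   group specificity), planted QTNs, the gene catalog at controlled
#'   distances from the blocks, QTL intervals and planted
#'   differential-expression genes.
#' @export
simulatePanel <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    withSeed(cfg$seed, {
        groups <- names(cfg$linesPerGroup)
        chroms <- names(cfg$chromLengthsBp)
        seg <- if (is.null(cfg$plantedSegments)) .placeSegments(cfg) else {
            s <- cfg$plantedSegments
            if (is.null(s$segment_id))
                s$segment_id <- sprintf("seg%03d", seq_len(nrow(s)))
            s
        }
        ## marker map
        share <- cfg$chromLengthsBp / sum(cfg$chromLengthsBp)
        alloc <- diff(c(0, round(cumsum(share) * cfg$nMarkers)))
        chrom <- rep(chroms, alloc)
        pos <- unlist(lapply(seq_along(chroms), function(ci)
            sort(sample.int(cfg$chromLengthsBp[ci], alloc[ci]))),
            use.names = FALSE)
        m <- length(pos)
        p <- stats::runif(m, cfg$freqRange[1], cfg$freqRange[2])

        inSeg <- function(rows) {
            hit <- rep(FALSE, m)
            for (i in rows)
                hit <- hit | (chrom == seg$chrom[i] & pos >= seg$start[i] &
                              pos <= seg$end[i])
            hit
        }
        segGroups <- strsplit(seg$groups, ",", fixed = TRUE)
        nMarkSeg <- vapply(seq_len(nrow(seg)), function(i)
            sum(inSeg(i)), integer(1))
        if (any(nMarkSeg == 0L))
            stop("planted segment(s) contain no marker: ",
                 paste(seg$segment_id[nMarkSeg == 0L], collapse = ", "))

        dosList <- list()
        groupsOf <- character()
        founders <- matrix(NA_integer_, m, length(groups),
                           dimnames = list(NULL, groups))
        for (g in groups) {
            ng <- cfg$linesPerGroup[[g]]
            founder <- stats::rbinom(m, 1L, p)
            founders[, g] <- founder
            base <- matrix(2L * founder, m, ng)
            protected <- inSeg(which(vapply(segGroups, function(x)
                g %in% x, logical(1))))
            resample <- matrix(stats::runif(m * ng) < cfg$rho, m, ng)
            resample[protected, ] <- FALSE
            if (any(resample)) {
                idx <- which(resample)
                base[idx] <- 2L * (stats::runif(length(idx)) <
                                   p[(idx - 1L) %% m + 1L])
            }
            if (cfg$hetRate > 0) {
                het <- matrix(stats::runif(m * ng) < cfg$hetRate, m, ng)
                het[protected, ] <- FALSE
                base[het] <- 1L
            }
            if (cfg$missingRate > 0)
                base[matrix(stats::runif(m * ng) < cfg$missingRate,
                            m, ng)] <- NA_integer_
            colnames(base) <- sprintf("%s_%03d", g, seq_len(ng))
            dosList[[g]] <- base
            groupsOf <- c(groupsOf, rep(g, ng))
        }
        dos <- do.call(cbind, dosList)
        rownames(dos) <- sprintf("S%s_%d", chrom, pos)
        ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
        alt <- vapply(ref, function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
        panel <- GenotypePanel(dos, chrom = chrom, pos = pos,
                               ref = ref, alt = alt,
                               group = groupsOf,
                               membership = stats::runif(ncol(dos),
                                                         0.55, 1))
        genes <- .placeGenes(seg, cfg)

        ## QTLs overlap every other planted block, plus a few background
        ## intervals in block-free space.
        traitPool <- c("DTS", "DTP", "DTT", "ASI", "EH", "PH", "EH/PH",
                       "EL", "ED", "ER", "KNPR", "KWE", "KV", "KD",
                       "10KL/10KW")
        segSel <- seq(1L, nrow(seg), by = 2L)
        qtls <- data.frame(
            name = sprintf("qtl%03d", seq_along(segSel)),
            trait = traitPool[(seq_along(segSel) - 1L) %%
                              length(traitPool) + 1L],
            chrom = seg$chrom[segSel],
            start = pmax(1, seg$start[segSel] - 20e3),
            end = pmin(cfg$chromLengthsBp[seg$chrom[segSel]],
                       seg$end[segSel] + 20e3),
            source = "synthetic")

        ## planted QTNs: explicit plan or default; NA markers resolved to
        ## polymorphic background markers (clear of planted blocks).
        plan <- cfg$qtnPlan
        if (is.null(plan))
            plan <- data.frame(trait = c("DTS", "PH", "KNPR", "ED"),
                               h2 = 0.1, marker = NA_character_)
        if (is.null(plan$marker))
            plan$marker <- NA_character_
        if (nrow(plan)) {
            stopifnot(all(plan$h2 > 0), all(plan$h2 < 1))
            ## auto-picked QTNs segregate within every group (identical
            ## founder alleles) so planted effects are not confounded
            ## with the structure covariates of the association model
            sameFounder <- apply(founders, 1L, function(f)
                length(unique(f)) == 1L)
            bg <- which(!inSeg(seq_len(nrow(seg))) & p >= 0.3 & p <= 0.7 &
                        sameFounder)
            need <- which(is.na(plan$marker))
            picks <- sample(bg, length(need))
            plan$marker[need] <- rownames(dos)[picks]
            plan$chrom <- chrom[match(plan$marker, rownames(dos))]
            plan$pos <- pos[match(plan$marker, rownames(dos))]
        }

        ## planted DE genes: two segment-linked genes per group
        de <- cfg$dePlan
        if (is.null(de)) {
            rows <- list()
            for (g in groups) {
                own <- seg$segment_id[vapply(segGroups, function(x)
                    identical(x, g), logical(1))]
                cand <- genes$gene_id[genes$segment_id %in% own &
                                      genes$offset_class == "inside"]
                if (length(cand) >= 2L)
                    rows[[g]] <- data.frame(
                        gene_id = cand[1:2], group = g, shift = c(2, -2))
            }
            de <- do.call(rbind, rows)
            rownames(de) <- NULL
        }

        truth <- structure(list(segments = seg, genes = genes,
                                qtls = qtls, qtns = plan, dePlan = de,
                                groups = groups), class = "TruthSet")
        list(panel = panel, truth = truth)
    })
}

#' Simulate multi-environment phenotypes with planted QTN effects
#'
#' Per line, the genetic value is the sum of planted QTN effects,
#' \eqn{\sum_k \beta_k d_k} with each \eqn{\beta_k} scaled so QTN k
#' explains its configured fraction of the line-mean phenotypic variance
#' (set to 1); group mean shifts, environment main effects,
#' genotype-by-environment interactions and replicate residuals are
#' added, and records are emitted in long format over
#' \code{nEnvs x nReps}.
#'
#' @param panel a \linkS4class{GenotypePanel} from [simulatePanel()].
#' @param truth the matching truth set.
#' @param cfg the [simConfig()] used.
#' @return Long-format \code{data.frame(line, env, rep, trait, value)}.
#' @export
simulatePhenotypes <- function(panel, truth, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    plan <- truth$qtns
    traits <- unique(c(plan$trait, names(cfg$groupShifts)))
    if (!length(traits))
        stop("no traits to simulate: empty QTN plan and no group shifts")
    withSeed(cfg$seed + 1000003L, {
        d <- dosage(panel)
        lines <- colnames(d)
        grp <- lineGroups(panel)
        envs <- sprintf("E%02d", seq_len(cfg$nEnvs))
        reps <- sprintf("R%d", seq_len(cfg$nReps))
        out <- list()
        for (tr in traits) {
            sub <- plan[plan$trait == tr, , drop = FALSE]
            if (sum(sub$h2) >= 1)
                stop("QTN variance fractions for trait ", tr,
                     " sum to >= 1")
            gval <- numeric(length(lines))
            for (k in seq_len(nrow(sub))) {
                dk <- d[sub$marker[k], ]
                dk[is.na(dk)] <- mean(dk, na.rm = TRUE)
                sdk <- stats::sd(dk)
                if (sdk < 1e-12)
                    stop("planted QTN marker is monomorphic: ",
                         sub$marker[k])
                gval <- gval + sqrt(sub$h2[k]) * (dk - mean(dk)) / sdk
            }
            shift <- cfg$groupShifts[[tr]]
            if (!is.null(shift))
                gval <- gval + ifelse(is.na(shift[grp]), 0, shift[grp])
            varRes <- 1 - sum(sub$h2)
            sdGe <- cfg$noiseScale * sqrt(0.4 * varRes * cfg$nEnvs)
            sdEps <- cfg$noiseScale *
                sqrt(0.6 * varRes * cfg$nEnvs * cfg$nReps)
            envEff <- stats::rnorm(cfg$nEnvs, 0, cfg$envSd)
            ge <- matrix(stats::rnorm(length(lines) * cfg$nEnvs, 0, sdGe),
                         length(lines), cfg$nEnvs)
            for (j in seq_len(cfg$nEnvs)) {
                for (r in seq_len(cfg$nReps)) {
                    eps <- stats::rnorm(length(lines), 0, sdEps)
                    out[[length(out) + 1L]] <- data.frame(
                        line = lines, env = envs[j], rep = reps[r],
                        trait = tr,
                        value = gval + envEff[j] + ge[, j] + eps)
                }
            }
        }
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        res
    })
}

#' Simulate expression matrices with planted group shifts
#'
#' \code{mode = "kernel"}: nine representative lines per FP group, gene
#' baselines \eqn{\log_2} expression ~ Normal(5, 1), planted group shifts
#' from the DE plan, residual SD \code{exprSd}; FPKM is
#' \eqn{2^{value} - 1} floored at zero. \code{mode = "organ"}: one
#' sample per organ with planted correlated gene blocks (equicorrelated
#' factor structure at \code{coexR}) for co-expression network tests.
#'
#' @param truth truth set from [simulatePanel()].
#' @param cfg the [simConfig()] used.
#' @param mode "kernel" or "organ".
#' @return A list with \code{fpkm} (genes x samples), \code{samples}
#'   metadata, \code{mode}, and for organ mode \code{blocks} (the
#'   planted co-expressed gene sets).
#' @export
simulateExpression <- function(truth, cfg, mode = c("kernel", "organ")) {
    mode <- match.arg(mode)
    stopifnot(inherits(cfg, "SimConfig"))
    geneIds <- truth$genes$gene_id
    extra <- max(0L, cfg$nGenes - length(geneIds))
    geneIds <- c(geneIds, sprintf("BGENE%04d", seq_len(extra)))
    withSeed(cfg$seed + 2000003L, {
        mu <- stats::rnorm(length(geneIds), 5, 1)
        if (mode == "kernel") {
            samples <- do.call(rbind, lapply(truth$groups, function(g)
                data.frame(sample_id = sprintf("%s_k%02d", g, 1:9),
                           group = g)))
            val <- matrix(stats::rnorm(length(geneIds) *
                                       nrow(samples), 0, cfg$exprSd),
                          length(geneIds), nrow(samples)) + mu
            de <- truth$dePlan
            if (!is.null(de) && nrow(de))
                for (i in seq_len(nrow(de))) {
                    gi <- match(de$gene_id[i], geneIds)
                    if (is.na(gi)) next
                    sel <- samples$group == de$group[i]
                    val[gi, sel] <- val[gi, sel] + de$shift[i]
                }
            blocks <- NULL
        } else {
            samples <- data.frame(
                sample_id = sprintf("organ%02d", seq_len(cfg$nOrgans)),
                group = "organ")
            val <- matrix(stats::rnorm(length(geneIds) * cfg$nOrgans),
                          length(geneIds), cfg$nOrgans) + mu
            blocks <- list()
            off <- 0L
            for (b in seq_len(cfg$coexBlocks)) {
                members <- geneIds[off + seq_len(cfg$coexBlockSize)]
                f <- stats::rnorm(cfg$nOrgans)
                for (gm in members) {
                    gi <- match(gm, geneIds)
                    val[gi, ] <- mu[gi] + sqrt(cfg$coexR) * f +
                        sqrt(1 - cfg$coexR) * stats::rnorm(cfg$nOrgans)
                }
                blocks[[b]] <- members
                off <- off + cfg$coexBlockSize
            }
        }
        fpkm <- pmax(2^val - 1, 0)
        dimnames(fpkm) <- list(geneIds, samples$sample_id)
        list(fpkm = fpkm, samples = samples, mode = mode, blocks = blocks)
    })
}

#' Write the gene annotation and QTL files of a simulation
#'
#' Emits the truth set's gene catalog as a GFF3 file (gene features,
#' 1-based inclusive coordinates) and the QTL intervals as a BED-like
#' TSV with a trait column.
#'
#' @param truth truth set from [simulatePanel()].
#' @param cfg the [simConfig()] used.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
writeAnnotation <- function(truth, cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gff <- file.path(dir, "genes.gff3")
    g <- truth$genes
    lines <- c("##gff-version 3",
               sprintf("%s\tfpibd_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id))
    writeLines(lines, gff)
    qtl <- file.path(dir, "qtl.tsv")
    utils::write.table(truth$qtls, qtl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(gff = gff, qtl = qtl))
}

#' Write a complete simulated dataset
#'
#' Runs the panel, phenotype and expression simulators for one
#' configuration and writes every pipeline input format: genotypes
#' (CSV dialect), group membership, long-format phenotypes, kernel and
#' organ expression matrices with sample metadata, gene annotation
#' (GFF3), QTL table and the truth set as JSON. Identical configurations
#' (including the seed) produce byte-identical files.
#'
#' @param cfg a [simConfig()] object.
#' @param dir output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
writeSimulation <- function(cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulatePanel(cfg)
    pheno <- simulatePhenotypes(sim$panel, sim$truth, cfg)
    kern <- simulateExpression(sim$truth, cfg, "kernel")
    org <- simulateExpression(sim$truth, cfg, "organ")
    paths <- c(
        genotypes = file.path(dir, "genotypes.csv"),
        groups = file.path(dir, "groups.csv"),
        phenotypes = file.path(dir, "phenotypes.csv"),
        expr_kernel = file.path(dir, "expression_kernel.tsv"),
        expr_kernel_samples = file.path(dir, "expression_kernel_samples.tsv"),
        expr_organ = file.path(dir, "expression_organ.tsv"),
        truth = file.path(dir, "truth.json"))
    writeGenotypes(sim$panel, paths["genotypes"], "csv")
    utils::write.csv(
        data.frame(line_id = colnames(sim$panel),
                   group = lineGroups(sim$panel),
                   membership = SummarizedExperiment::colData(
                       sim$panel)$membership),
        paths["groups"], row.names = FALSE, quote = FALSE)
    utils::write.csv(pheno, paths["phenotypes"], row.names = FALSE,
                     quote = FALSE)
    writeMat <- function(m, path) {
        out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeMat(signif(kern$fpkm, 8), paths["expr_kernel"])
    utils::write.table(kern$samples, paths["expr_kernel_samples"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeMat(signif(org$fpkm, 8), paths["expr_organ"])
    ann <- writeAnnotation(sim$truth, cfg, dir)
    tr <- sim$truth
    class(tr) <- NULL
    jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    invisible(c(paths, ann))
}
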