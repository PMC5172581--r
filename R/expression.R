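#' Log2 normalization of FPKM expression
#'
#' \code{log2(FPKM + pseudocount)}. With the default pseudocount of 1 an
#' FPKM of 0 maps to 0 and the transform is exactly invertible by
#' \code{2^x - 1}.
#'
#' @param fpkm genes x samples matrix of FPKM values (>= 0).
#' @param pseudocount added inside the log (log2 of a zero FPKM is
#'   undefined otherwise).
#' @return Matrix of the same shape.
#' @export
normalizeLog2 <- function(fpkm, pseudocount = 1) {
    fpkm <- as.matrix(fpkm)
    if (any(fpkm < 0, na.rm = TRUE))
        stop("FPKM values must be non-negative")
    log2(fpkm + pseudocount)
}

#' Differential expression between two FP groups
#'
#' Per gene, a one-way ANOVA on log2 expression between the two groups of
#' the pair (equivalent to a pooled-variance t test), with
#' \code{log2_fold_change} the difference of group means of log2 values
#' (group A minus group B). Genes with zero variance in both groups and
#' equal means get p = 1.
#'
#' @param logExpr genes x samples matrix of log2 expression (see
#'   [normalizeLog2()]).
#' @param groups character vector of group labels, one per sample column
#'   (or named by sample id).
#' @param pair length-2 character vector (A, B); fold changes are A - B.
#' @param alpha significance level for the \code{significant} flag.
#' @param fdr apply Benjamini-Hochberg correction before flagging.
#' @return \code{data.frame}: gene, pair, log2_fold_change, p_value,
#'   direction ("up" when the fold change is positive), significant.
#' @export
groupDe <- function(logExpr, groups, pair, alpha = 0.05, fdr = FALSE) {
    logExpr <- as.matrix(logExpr)
    if (!is.null(names(groups)))
        groups <- groups[colnames(logExpr)]
    stopifnot(length(groups) == ncol(logExpr), length(pair) == 2L)
    selA <- which(groups == pair[1])
    selB <- which(groups == pair[2])
    if (length(selA) < 2L || length(selB) < 2L)
        stop("need >= 2 samples per group in the pair")
    A <- logExpr[, selA, drop = FALSE]
    B <- logExpr[, selB, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- rowMeans(A); mB <- rowMeans(B)
    ssw <- rowSums((A - mA)^2) + rowSums((B - mB)^2)
    lfc <- mA - mB
    dfw <- nA + nB - 2L
    grand <- (nA * mA + nB * mB) / (nA + nB)
    ssb <- nA * (mA - grand)^2 + nB * (mB - grand)^2
    fstat <- (ssb / 1) / (ssw / dfw)
    p <- clampP(stats::pf(fstat, 1, dfw, lower.tail = FALSE))
    p[ssw < 1e-24 & ssb < 1e-24] <- 1
    padj <- if (fdr) stats::p.adjust(p, "BH") else p
    data.frame(gene = rownames(logExpr),
               pair = paste(pair, collapse = "/"),
               log2_fold_change = lfc,
               p_value = p,
               direction = ifelse(lfc > 0, "up", "down"),
               significant = padj < alpha,
               row.names = NULL)
}

#' Co-expression network edges
#'
#' Pearson correlation of log2 expression across samples (typically a
#' panel of organs) for all pairs of the requested genes; unordered pairs
#' with \code{|r| >= rMin} become edges. Genes with zero variance are
#' excluded with a warning (correlation undefined).
#'
#' @param logExpr genes x samples matrix of log2 expression.
#' @param geneSet genes to consider (default all rows).
#' @param rMin absolute-correlation edge threshold.
#' @return \code{data.frame} of edges (gene_a < gene_b lexicographically):
#'   gene_a, gene_b, r, n_samples; the per-gene edge counts are attached
#'   as the \code{degree} attribute.
#' @export
coexpressionNetwork <- function(logExpr, geneSet = rownames(logExpr),
                                rMin = 0.8) {
    logExpr <- as.matrix(logExpr)
    if (ncol(logExpr) < 3L)
        stop("need >= 3 samples to estimate correlations")
    geneSet <- intersect(geneSet, rownames(logExpr))
    m <- logExpr[geneSet, , drop = FALSE]
    v <- apply(m, 1L, stats::var)
    if (any(v < 1e-24)) {
        warning(sum(v < 1e-24),
                " constant gene(s) excluded (undefined correlation)")
        m <- m[v >= 1e-24, , drop = FALSE]
    }
    if (nrow(m) < 2L)
        return(data.frame(gene_a = character(), gene_b = character(),
                          r = numeric(), n_samples = integer()))
    cc <- stats::cor(t(m))
    idx <- which(upper.tri(cc) & abs(cc) >= rMin, arr.ind = TRUE)
    ga <- rownames(cc)[idx[, 1]]
    gb <- rownames(cc)[idx[, 2]]
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    out <- data.frame(gene_a = ga, gene_b = gb,
                      r = cc[idx], n_samples = ncol(m),
                      row.names = NULL)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    deg <- table(factor(c(out$gene_a, out$gene_b), levels = rownames(m)))
    attr(out, "degree") <- deg
    out
}
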