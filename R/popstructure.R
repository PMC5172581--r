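#' Identity-by-state genetic distance
#'
#' Computes the modified Euclidean genetic distance D = 1 - IBS between all
#' line pairs. At one locus the IBS similarity is the mean over the four
#' ordered allele pairs of the indicator "alleles identical": identical
#' homozygotes score 1, opposite homozygotes 0, and any comparison
#' involving a heterozygote 0.5. Per-pair IBS is averaged over loci
#' non-missing in both lines.
#'
#' @param x a \linkS4class{GenotypePanel} with at least two lines.
#' @return A symmetric numeric matrix of distances in [0, 1] with line ids
#'   as dimnames. Pairs sharing no non-missing locus get \code{NA} with a
#'   warning.
#' @seealso [upgmaTree()], [kinshipMatrix()]
#' @export
ibsDistance <- function(x) {
    d <- dosage(x)
    if (ncol(d) < 2L)
        stop("need at least two lines")
    ## Decompose the IBS score over indicator matrices so the pairwise sums
    ## become matrix products: s(0,0)=s(2,2)=1, s(0,2)=0, s(1,.)=0.5.
    M <- t(!is.na(d)) * 1
    A0 <- t(!is.na(d) & d == 0L) * 1
    A1 <- t(!is.na(d) & d == 1L) * 1
    A2 <- t(!is.na(d) & d == 2L) * 1
    num <- tcrossprod(A0) + tcrossprod(A2) +
        0.5 * (A1 %*% t(M) + M %*% t(A1) - tcrossprod(A1))
    den <- tcrossprod(M)
    if (any(den == 0))
        warning("line pair(s) share no non-missing locus; distance set NA")
    ibs <- ifelse(den > 0, num / den, NA_real_)
    D <- 1 - ibs
    diag(D) <- 0
    dimnames(D) <- list(colnames(d), colnames(d))
    D
}

#' UPGMA cladogram from a distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic-mean
#' cluster distances; leaves sit at height 0 and each join at half the
#' joining distance, so the cophenetic distance of the returned tree
#' reproduces an ultrametric input exactly.
#'
#' @param d a complete symmetric distance matrix (or \code{dist}).
#' @return A rooted ultrametric \link[ape]{phylo} tree.
#' @seealso [ape::write.tree()] for newick export.
#' @export
upgmaTree <- function(d) {
    m <- as.matrix(d)
    if (any(is.na(m)))
        stop("distance matrix has missing entries; drop the offending ",
             "lines before clustering")
    phangorn::upgma(stats::as.dist(m))
}

#' Principal component analysis of a panel
#'
#' Dosages are mean-imputed per marker, column-centered (plain covariance
#' PCA, no per-marker variance scaling) and decomposed by SVD. Component
#' signs are fixed so that each score vector's largest-magnitude entry is
#' positive.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param k number of components to return; truncated to the matrix rank
#'   with a warning if too large.
#' @return A list with \code{scores} (lines x k), \code{explained}
#'   (fraction of total variance per component, non-increasing) and
#'   \code{k}.
#' @export
pcaPanel <- function(x, k = 3L) {
    stopifnot(k >= 1L)
    X <- t(dosage(x)) * 1
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(X))
    if (length(idx))
        X[idx] <- mu[(idx - 1) %/% nrow(X) + 1]
    X <- sweep(X, 2L, colMeans(X))
    sv <- svd(X)
    ev <- sv$d^2
    rank <- sum(sv$d > max(sv$d) * 1e-10)
    if (k > rank) {
        warning("k exceeds matrix rank; truncated to ", rank)
        k <- rank
    }
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k, k)
    for (j in seq_len(k)) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0)
            scores[, j] <- -scores[, j]
    }
    dimnames(scores) <- list(colnames(dosage(x)), paste0("PC", seq_len(k)))
    list(scores = scores, explained = ev[seq_len(k)] / sum(ev), k = k)
}

## Mean per-marker gene diversity of a line subset, from running allele
## counts. Markers with no calls are excluded from the mean.
.meanGdFromCounts <- function(alt, n) {
    ok <- n > 0
    p <- alt[ok] / (2 * n[ok])
    mean(2 * p * (1 - p))
}

#' Select a diversity-covering subset of lines
#'
#' Greedy backward elimination: repeatedly removes the line whose removal
#' maximizes the retained diversity coverage until \code{targetN} lines
#' remain. Coverage is the ratio of mean per-marker gene diversity of the
#' subset to that of the full panel (GD being the diversity measure used
#' throughout the segment scan). Ties are broken by dropping the
#' lexicographically smallest line id.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param targetN desired subset size (2 <= targetN <= number of lines).
#' @return A list with \code{selected} (line ids) and \code{coverage}
#'   (fraction in [0, 1], possibly marginally above 1 when removing lines
#'   raises mean GD).
#' @export
selectDiverseSubset <- function(x, targetN) {
    d <- dosage(x)
    n <- ncol(d)
    stopifnot(targetN >= 2L, targetN <= n)
    alt <- rowSums(d, na.rm = TRUE)
    calls <- rowSums(!is.na(d))
    full <- .meanGdFromCounts(alt, calls)
    keep <- colnames(d)
    while (length(keep) > targetN) {
        best <- -Inf
        bestLine <- NULL
        for (l in sort(keep)) {
            dl <- d[, l]
            cov <- .meanGdFromCounts(alt - ifelse(is.na(dl), 0, dl),
                                     calls - !is.na(dl))
            if (cov > best + 1e-15) {
                best <- cov
                bestLine <- l
            }
        }
        dl <- d[, bestLine]
        alt <- alt - ifelse(is.na(dl), 0, dl)
        calls <- calls - !is.na(dl)
        keep <- setdiff(keep, bestLine)
    }
    list(selected = keep,
         coverage = .meanGdFromCounts(alt, calls) / full)
}
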