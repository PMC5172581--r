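#' Kinship matrix from panel genotypes
#'
#' \code{method = "vanraden"}: centered dosage cross-product scaled by
#' \eqn{2\sum p(1-p)} (missing dosages mean-imputed per marker).
#' \code{method = "ibs"}: pairwise identity-by-state similarity, i.e.
#' \code{1 - ibsDistance(x)}.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @param method "vanraden" or "ibs".
#' @return Symmetric lines x lines relatedness matrix.
#' @export
kinshipMatrix <- function(x, method = c("vanraden", "ibs")) {
    method <- match.arg(method)
    if (ncol(x) < 2L)
        stop("need at least two lines")
    if (method == "ibs")
        return(1 - ibsDistance(x))
    d <- t(dosage(x)) * 1
    mu <- colMeans(d, na.rm = TRUE)
    poly <- !is.nan(mu) & mu > 0 & mu < 2
    if (!any(poly))
        stop("no polymorphic markers; cannot form a kinship matrix")
    d <- d[, poly, drop = FALSE]
    mu <- mu[poly]
    idx <- which(is.na(d))
    if (length(idx))
        d[idx] <- mu[(idx - 1) %/% nrow(d) + 1]
    p <- mu / 2
    Z <- sweep(d, 2L, 2 * p)
    tcrossprod(Z) / (2 * sum(p * (1 - p)))
}

## REML estimation of the variance ratio lambda = sigma2_e / sigma2_g for
## y = X b + u + e, u ~ N(0, sigma2_g K), via the eigendecomposition of K
## and a 1-D search over log(lambda) in [-10, 10].
.remlNull <- function(y, X, K) {
    n <- length(y)
    q <- ncol(X)
    eig <- eigen(K, symmetric = TRUE)
    dvals <- pmax(eig$values, 1e-10)
    Ut <- t(eig$vectors)
    yt <- drop(Ut %*% y)
    Xt <- Ut %*% X
    ldetXX <- as.numeric(determinant(crossprod(X))$modulus)
    negll <- function(loglam) {
        lam <- exp(loglam)
        w <- 1 / (dvals + lam)
        XtW <- Xt * w
        XX <- crossprod(Xt, XtW)
        beta <- solve(XX, crossprod(XtW, yt))
        r <- yt - drop(Xt %*% beta)
        s2 <- sum(w * r^2) / (n - q)
        0.5 * ((n - q) * log(2 * pi * s2) + (n - q) +
               sum(log(dvals + lam)) +
               as.numeric(determinant(XX)$modulus) - ldetXX)
    }
    opt <- stats::optimize(negll, c(-10, 10), tol = 1e-6)
    lam <- exp(opt$minimum)
    w <- 1 / (dvals + lam)
    XtW <- Xt * w
    beta <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
    r <- yt - drop(Xt %*% beta)
    s2g <- sum(w * r^2) / (n - q)
    list(lambda = lam, sigma2_g = s2g, sigma2_e = lam * s2g,
         dvals = dvals, Ut = Ut, negll = negll, reml = -opt$objective)
}

#' Mixed-linear-model association scan
#'
#' Tests every marker for association with a per-line phenotype (typically
#' a BLUP) under \eqn{y = \mu + Q\gamma + x_s\beta_s + u + \epsilon} with
#' \eqn{u \sim N(0, \sigma^2_g K)}. The variance ratio
#' \eqn{\lambda = \sigma^2_e/\sigma^2_g} is estimated once under the null
#' by REML (P3D) and reused for every marker; each marker is then tested
#' by generalized least squares in the whitened model, with a t test on
#' the marker coefficient. With \code{kinship = NULL} (or the identity)
#' and no covariates this reduces numerically to ordinary least-squares
#' regression.
#'
#' Missing dosages are mean-imputed per marker; markers monomorphic
#' across the analyzed lines, or collinear with the covariates, are
#' skipped (NA results, flagged in \code{status}).
#'
#' @param blups per-line phenotype: a \code{data.frame} from
#'   [blupPerLine()] or a numeric vector named by line id.
#' @param x a \linkS4class{GenotypePanel}.
#' @param kinship lines x lines kinship matrix; \code{NULL} for identity.
#' @param qCovariates optional lines x c covariate matrix (e.g. PCA
#'   scores) named by line id; structure covariates in the association
#'   model.
#' @param trait trait label carried into the result.
#' @return \code{data.frame} with one row per marker: trait, marker,
#'   chrom, pos, effect (trait units per alt-allele dose), se, p, status;
#'   attributes \code{lambda}, \code{sigma2_g}, \code{sigma2_e},
#'   \code{n}.
#' @seealso [callQtns()], [kinshipMatrix()], [pcaPanel()]
#' @export
mlmAssociate <- function(blups, x, kinship = NULL, qCovariates = NULL,
                         trait = NULL) {
    if (is.data.frame(blups)) {
        if (is.null(trait) && "trait" %in% colnames(blups))
            trait <- blups$trait[1]
        y <- stats::setNames(blups$blup, blups$line_id)
    } else {
        y <- blups
    }
    if (is.null(trait)) trait <- "trait"
    ids <- intersect(colnames(x), names(y))
    if (!is.null(kinship)) ids <- intersect(ids, rownames(kinship))
    if (!is.null(qCovariates)) ids <- intersect(ids, rownames(qCovariates))
    if (length(ids) < 10L)
        stop("fewer than 10 lines shared between phenotype and genotypes")
    y <- y[ids]
    n <- length(ids)
    X <- cbind(`(Intercept)` = rep(1, n))
    if (!is.null(qCovariates))
        X <- cbind(X, as.matrix(qCovariates)[ids, , drop = FALSE])
    K <- if (is.null(kinship)) diag(n) else kinship[ids, ids]
    vc <- .remlNull(y, X, K)

    ## whiten once, then residualize phenotype and markers on covariates
    Tm <- vc$Ut / sqrt(vc$dvals + vc$lambda)
    yt <- drop(Tm %*% y)
    Xt <- Tm %*% X
    qrX <- qr(Xt)
    ry <- qr.resid(qrX, yt)

    G <- t(dosage(x)[, ids, drop = FALSE]) * 1
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    if (length(idx))
        G[idx] <- mu[(idx - 1) %/% nrow(G) + 1]
    mono <- is.nan(mu) | mu <= 0 | mu >= 2
    Gt <- Tm %*% G
    RG <- qr.resid(qrX, Gt)
    den <- colSums(RG^2)
    num <- drop(crossprod(RG, ry))
    dfree <- n - ncol(X) - 1L
    collinear <- !mono & den < 1e-10 * n
    ok <- !mono & !collinear
    beta <- ifelse(ok, num / den, NA_real_)
    rss <- pmax(sum(ry^2) - ifelse(ok, beta^2 * den, 0), 0)
    s2 <- rss / dfree
    se <- ifelse(ok, sqrt(s2 / den), NA_real_)
    tstat <- beta / se
    p <- ifelse(ok, clampP(2 * stats::pt(-abs(tstat), dfree)), NA_real_)

    rr <- markerRanges(x)
    out <- data.frame(
        trait = trait, marker = rownames(dosage(x)),
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        effect = beta, se = se, p = p,
        status = ifelse(mono, "monomorphic",
                        ifelse(collinear, "collinear", "tested")),
        row.names = NULL)
    attr(out, "lambda") <- vc$lambda
    attr(out, "sigma2_g") <- vc$sigma2_g
    attr(out, "sigma2_e") <- vc$sigma2_e
    attr(out, "n") <- n
    out
}

#' Call QTNs at the Bonferroni cutoff
#'
#' A marker passes when its p-value is strictly below \code{alpha / m}
#' (the study's cutoff: 0.05 divided by the number of markers).
#'
#' @param result association table from [mlmAssociate()].
#' @param alpha genome-wide significance level.
#' @param m number of tests; defaults to the number of tested markers.
#' @return The tested rows sorted by ascending p, with \code{cutoff} and
#'   logical \code{passes} columns.
#' @export
callQtns <- function(result, alpha = 0.05, m = NULL) {
    tested <- result[result$status == "tested" & !is.na(result$p), ,
                     drop = FALSE]
    if (is.null(m)) m <- nrow(tested)
    stopifnot(m >= 1L)
    cutoff <- alpha / m
    tested <- tested[order(tested$p), , drop = FALSE]
    tested$cutoff <- cutoff
    tested$passes <- tested$p < cutoff
    rownames(tested) <- NULL
    tested
}

#' Markers associated with multiple traits
#'
#' Groups the passing QTNs of several per-trait scans by marker and
#' reports markers significantly associated with two or more traits.
#'
#' @param qtnList list of [callQtns()] results (one per trait).
#' @return \code{data.frame} with marker, chrom, pos, n_traits and a
#'   comma-separated trait list, sorted by descending n_traits; empty when
#'   no marker is shared.
#' @export
multiTraitSummary <- function(qtnList) {
    stopifnot(length(qtnList) >= 2L)
    all <- do.call(rbind, lapply(qtnList, function(q)
        q[q$passes, c("trait", "marker", "chrom", "pos"), drop = FALSE]))
    if (is.null(all) || !nrow(all))
        return(data.frame(marker = character(), chrom = character(),
                          pos = integer(), n_traits = integer(),
                          traits = character()))
    sp <- split(all, all$marker)
    rows <- lapply(sp, function(d) {
        tr <- sort(unique(d$trait))
        data.frame(marker = d$marker[1], chrom = d$chrom[1],
                   pos = d$pos[1], n_traits = length(tr),
                   traits = paste(tr, collapse = ","))
    })
    out <- do.call(rbind, rows)
    out <- out[out$n_traits >= 2L, , drop = FALSE]
    out <- out[order(-out$n_traits, out$marker), , drop = FALSE]
    rownames(out) <- NULL
    out
}
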