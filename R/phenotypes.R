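#' Derive composite agronomic traits
#'
#' Appends the four derived traits to a long-format phenotype table,
#' computed record-wise within each (line, environment, replicate)
#' context: ASI = DTS - DTP (anthesis-silking interval, days), EH/PH =
#' EH / PH, KD = KWE / KV (kernel density, g/mL) and 10KL/10KW =
#' 10KL / 10KW. A missing operand yields a missing derived value;
#' division by zero yields missing with a warning reporting the count.
#'
#' @param pheno \code{data.frame} with columns \code{line}, \code{env},
#'   \code{rep}, \code{trait}, \code{value}.
#' @return The input with derived-trait records appended (same columns).
#' @export
deriveTraits <- function(pheno) {
    need <- c("line", "env", "rep", "trait", "value")
    stopifnot(all(need %in% colnames(pheno)))
    sep <- "\x01"
    key <- paste(pheno$line, pheno$env, pheno$rep, sep = sep)
    u <- pheno[!duplicated(key), c("line", "env", "rep"), drop = FALSE]
    ukey <- paste(u$line, u$env, u$rep, sep = sep)
    id <- match(key, ukey)
    val <- function(trait) {
        idx <- which(pheno$trait == trait)
        out <- rep(NA_real_, nrow(u))
        out[id[idx]] <- pheno$value[idx]
        out
    }
    specs <- list(
        ASI = function() val("DTS") - val("DTP"),
        `EH/PH` = function() val("EH") / val("PH"),
        KD = function() val("KWE") / val("KV"),
        `10KL/10KW` = function() val("10KL") / val("10KW"))
    divZero <- 0L
    rows <- lapply(names(specs), function(tr) {
        v <- specs[[tr]]()
        inf <- is.infinite(v) | is.nan(v)
        divZero <<- divZero + sum(inf)
        v[inf] <- NA_real_
        if (all(is.na(v)))
            return(NULL)
        data.frame(line = u$line, env = u$env, rep = u$rep,
                   trait = tr, value = v)
    })
    if (divZero > 0L)
        warning(divZero, " derived value(s) undefined (division by zero); ",
                "set to missing")
    out <- rbind(pheno[, need], do.call(rbind, rows))
    rownames(out) <- NULL
    out
}

#' Per-line BLUPs across environments
#'
#' Fits the random-effects model
#' \eqn{y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + r_{jk} + \epsilon_{ijk}}
#' by REML (genotype, environment, genotype-by-environment and replicate
#' within environment all random, following the multi-environment trial
#' model) and returns \eqn{\mu + BLUP(g_i)} per line. Terms that are
#' inestimable on the data at hand (e.g. a single replicate) are dropped
#' from the random part. As the genotypic variance approaches zero all
#' BLUPs shrink to the grand mean.
#'
#' @param pheno long-format phenotype table (see [deriveTraits()]).
#' @param trait the trait to analyze.
#' @return \code{data.frame} with \code{line_id}, \code{trait},
#'   \code{blup} and \code{n_obs}; lines without observations are omitted
#'   with a warning.
#' @export
blupPerLine <- function(pheno, trait) {
    dat <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
    if (!nrow(dat))
        stop("trait not found or has no observations: ", trait)
    dropped <- setdiff(unique(pheno$line), unique(dat$line))
    if (length(dropped))
        warning(length(dropped), " line(s) without observations omitted")
    dat$line <- factor(dat$line)
    dat$env <- factor(dat$env)
    dat$rep <- factor(dat$rep)
    if (nlevels(dat$env) < 2L || nlevels(dat$line) < 2L)
        stop("need >= 2 environments and >= 2 lines with observations")
    forms <- c(
        value ~ (1 | line) + (1 | env) + (1 | line:env) + (1 | env:rep),
        value ~ (1 | line) + (1 | env) + (1 | line:env),
        value ~ (1 | line) + (1 | env))
    if (nlevels(dat$rep) < 2L)
        forms <- forms[-1]
    fit <- NULL
    for (f in forms) {
        fit <- tryCatch(
            suppressMessages(suppressWarnings(
                lme4::lmer(f, data = dat, REML = TRUE,
                           control = lme4::lmerControl(
                               calc.derivs = FALSE,
                               check.conv.singular = "ignore")))),
            error = function(e) NULL)
        if (!is.null(fit)) break
    }
    if (is.null(fit))
        stop("BLUP model failed to fit for trait ", trait)
    mu <- unname(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit)$line
    blup <- mu + re[levels(dat$line), 1]
    nObs <- as.integer(table(dat$line)[levels(dat$line)])
    data.frame(line_id = levels(dat$line), trait = trait, blup = blup,
               n_obs = nObs, row.names = NULL)
}

## Compact letter display from a symmetric p-value matrix via
## multcomp-style insert-absorb on the significance graph.
.lettersFromP <- function(pmat, alpha) {
    g <- rownames(pmat)
    ns <- pmat >= alpha
    diag(ns) <- TRUE
    cliques <- list()
    for (i in seq_along(g)) {
        placed <- FALSE
        for (j in seq_along(cliques)) {
            if (all(ns[g[i], cliques[[j]]])) {
                cliques[[j]] <- c(cliques[[j]], g[i])
                placed <- TRUE
            }
        }
        if (!placed)
            cliques[[length(cliques) + 1L]] <- g[i]
    }
    ## absorb cliques contained in another
    keep <- rep(TRUE, length(cliques))
    for (a in seq_along(cliques))
        for (b in seq_along(cliques))
            if (a != b && keep[a] && keep[b] &&
                all(cliques[[a]] %in% cliques[[b]]))
                keep[a] <- FALSE
    cliques <- cliques[keep]
    out <- vapply(g, function(x)
        paste(letters[which(vapply(cliques, function(cl) x %in% cl,
                                   logical(1)))], collapse = ""),
        character(1))
    out
}

#' Group trait means with significance letters
#'
#' One-way ANOVA of per-line BLUPs across FP groups for each trait, with
#' all pairwise group comparisons by Tukey's HSD at \code{alpha} and a
#' compact letter display (groups sharing no letter differ
#' significantly). Degenerate traits with (near) zero within-group
#' variance fall back to exact-separation letters on distinct means.
#'
#' @param blups \code{data.frame} as returned by [blupPerLine()] (possibly
#'   several traits row-bound).
#' @param groups named character vector mapping line id to group.
#' @param alpha significance level for the letters.
#' @return \code{data.frame} with trait, group, n, mean and letter.
#' @export
groupTraitAnova <- function(blups, groups, alpha = 0.05) {
    stopifnot(!is.null(names(groups)))
    out <- list()
    for (tr in unique(blups$trait)) {
        b <- blups[blups$trait == tr, , drop = FALSE]
        grp <- factor(unname(groups[b$line_id]))
        ok <- !is.na(grp) & !is.na(b$blup)
        b <- b[ok, ]
        grp <- droplevels(grp[ok])
        means <- tapply(b$blup, grp, mean)
        ns <- tapply(b$blup, grp, length)
        if (nlevels(grp) < 2L) {
            letter <- stats::setNames("a", levels(grp))
        } else {
            if (any(ns < 2L))
                stop("each group needs >= 2 lines for trait ", tr)
            fit <- stats::aov(blup ~ grp, data = cbind(b, grp = grp))
            mse <- stats::deviance(fit) / stats::df.residual(fit)
            if (mse < 1e-12 * max(1, mean(b$blup)^2)) {
                ## zero within-variance guard: distinct means separate
                u <- sort(unique(signif(means, 12)))
                letter <- stats::setNames(
                    letters[match(signif(means, 12), u)], names(means))
            } else {
                tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
                lev <- levels(grp)
                pmat <- matrix(1, nlevels(grp), nlevels(grp),
                               dimnames = list(lev, lev))
                pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
                for (i in seq_along(pairs)) {
                    a <- pairs[[i]][1]; bb <- pairs[[i]][2]
                    pmat[a, bb] <- pmat[bb, a] <- tuk[i, "p adj"]
                }
                letter <- .lettersFromP(pmat, alpha)
            }
        }
        out[[tr]] <- data.frame(trait = tr, group = names(means),
                                n = as.integer(ns), mean = as.numeric(means),
                                letter = unname(letter[names(means)]),
                                row.names = NULL)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
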