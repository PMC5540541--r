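#' @include mutation-catalog.R
NULL

.P_FLOOR <- 1e-300

#' One-sample proportion test against a fixed expected probability
#'
#' Tests an observed success count against a fixed expected probability.
#' The default method is the exact binomial tail: for \code{side = "less"}
#' the p-value is P(X <= x), for \code{"greater"} P(X >= x), and for
#' \code{"two_sided"} the usual exact two-sided p-value. Method
#' \code{"chisq_cc"} is the continuity-corrected chi-square approximation
#' (as in \code{prop.test}), provided for parity experiments with
#' R-default workflows. Vectorized over \code{x} and \code{n}.
#'
#' The coldspot call is \code{proportionTest(n_mut, n_occ, 0.25, "less")};
#' the hotspot call is \code{proportionTest(n_mut, n_occ, 0.75,
#' "greater")}. In all-substitutions mode the inputs are \code{n_sub} and
#' \code{3 * n_occ}.
#'
#' @param x number of successes (mutated occurrences), 0 <= x <= n.
#' @param n number of trials (occurrences), n >= 1; NA is returned for
#'   n = 0 (motif absent from the unit, no test).
#' @param p0 expected probability, in (0, 1).
#' @param side \code{"less"}, \code{"greater"} or \code{"two_sided"}.
#' @param method \code{"exact_binomial"} (default) or \code{"chisq_cc"}.
#' @return numeric vector of p-values in (0, 1]; NA where n = 0.
#' @examples
#' proportionTest(0, 10, 0.25, "less")  # 0.75^10
#' @export
proportionTest <- function(x, n, p0,
                           side = c("less", "greater", "two_sided"),
                           method = c("exact_binomial", "chisq_cc")) {
    side <- match.arg(side)
    method <- match.arg(method)
    if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
        stop("'p0' must be a single probability strictly between 0 and 1")
    k <- max(length(x), length(n))
    x <- rep_len(as.numeric(x), k)
    n <- rep_len(as.numeric(n), k)
    if (any(x < 0 | x > n, na.rm = TRUE))
        stop("need 0 <= x <= n")
    p <- rep(NA_real_, k)
    has <- !is.na(n) & n >= 1
    if (method == "exact_binomial") {
        p[has] <- switch(side,
            less = stats::pbinom(x[has], n[has], p0),
            greater = stats::pbinom(x[has] - 1, n[has], p0,
                                    lower.tail = FALSE),
            two_sided = vapply(which(has), function(i)
                stats::binom.test(x[i], n[i], p = p0)$p.value, numeric(1))
        )
    } else {
        alt <- c(less = "less", greater = "greater",
                 two_sided = "two.sided")[side]
        p[has] <- vapply(which(has), function(i)
            suppressWarnings(
                stats::prop.test(x[i], n[i], p = p0, alternative = alt,
                                 correct = TRUE)$p.value),
            numeric(1))
    }
    pmin(p, 1)
}

#' Combine p-values by Fisher's method
#'
#' Computes the statistic -2 * sum(log p) and refers it to a chi-square
#' distribution with 2k degrees of freedom. For a single p-value the
#' combination is the identity. Zero p-values are clipped to 1e-300
#' (with a warning) before taking logs.
#'
#' @param p numeric vector of p-values in (0, 1], non-empty.
#' @return list with elements \code{statistic}, \code{df}, \code{p}.
#' @examples
#' fisherCombine(c(0.1, 0.1))
#' @export
fisherCombine <- function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L)
        stop("no p-values to combine (motif absent from all units)")
    if (any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    if (any(p < .P_FLOOR)) {
        warning("p-value(s) below 1e-300 clipped before log")
        p <- pmax(p, .P_FLOOR)
    }
    stat <- -2 * sum(log(p))
    df <- 2L * length(p)
    list(statistic = stat, df = df,
         p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Fisher-combined coldspot/hotspot tests for every motif
#'
#' For every canonical motif, computes one coldspot p-value (expected
#' mutation probability 0.25, one-sided below) and one hotspot p-value
#' (expected 0.75, one-sided above) per (gene, orientation) unit in which
#' the motif occurs, combines each side across units by Fisher's method,
#' and classifies the motif at the threshold \code{alpha}: coldspot when
#' the combined coldspot p-value falls below \code{alpha}, hotspot when
#' the combined hotspot p-value does, neutral when both are at or above
#' \code{alpha} (if both fall below, the smaller side wins). Motifs
#' absent from every unit are classified \code{not_observed}.
#'
#' @param tallies a \linkS4class{MotifTallies}.
#' @param mode \code{"collapsed"}: successes are occurrences with >= 1
#'   mutation out of n occurrences. \code{"all_substitutions"}: successes
#'   are distinct substitutions out of 3 x occurrences.
#' @param method proportion-test method, see [proportionTest()].
#' @param alpha classification threshold (default 0.1).
#' @param p0Cold,p0Hot expected coldspot/hotspot probabilities (defaults
#'   0.25 and 0.75).
#' @return a \linkS4class{MotifResults}.
#' @export
combineMotifs <- function(tallies,
                          mode = c("collapsed", "all_substitutions"),
                          method = c("exact_binomial", "chisq_cc"),
                          alpha = 0.1, p0Cold = 0.25, p0Hot = 0.75) {
    stopifnot(is(tallies, "MotifTallies"))
    mode <- match.arg(mode)
    method <- match.arg(method)
    occ <- nOcc(tallies)
    mut <- nMut(tallies)
    sub <- nSub(tallies)
    if (mode == "collapsed") {
        xs <- mut
        ns <- occ
    } else {
        xs <- sub
        ns <- 3L * occ
    }
    present <- occ > 0L
    xv <- xs[present]
    nv <- ns[present]
    pc <- proportionTest(xv, nv, p0Cold, side = "less", method = method)
    ph <- proportionTest(xv, nv, p0Hot, side = "greater", method = method)
    pc <- pmax(pc, .P_FLOOR)
    ph <- pmax(ph, .P_FLOOR)

    motifIdx <- factor(rep(rownames(tallies), times = ncol(tallies))[present],
                       levels = rownames(tallies))
    k <- as.integer(table(motifIdx))
    statCold <- as.numeric(rowsum(-2 * log(pc), motifIdx))
    statHot <- as.numeric(rowsum(-2 * log(ph), motifIdx))
    # rowsum drops empty groups; rebuild on full motif set
    grp <- rownames(rowsum(-2 * log(pc), motifIdx))
    sc <- stats::setNames(rep(NA_real_, nrow(tallies)), rownames(tallies))
    sh <- sc
    sc[grp] <- statCold
    sh[grp] <- statHot
    df <- 2L * k
    pCold <- ifelse(k > 0L,
                    stats::pchisq(sc, df = df, lower.tail = FALSE), NA_real_)
    pHot <- ifelse(k > 0L,
                   stats::pchisq(sh, df = df, lower.tail = FALSE), NA_real_)

    cls <- rep("neutral", nrow(tallies))
    isCold <- !is.na(pCold) & pCold < alpha
    isHot <- !is.na(pHot) & pHot < alpha
    cls[isCold] <- "coldspot"
    cls[isHot] <- "hotspot"
    both <- isCold & isHot
    cls[both] <- ifelse(pCold[both] <= pHot[both], "coldspot", "hotspot")
    cls[k == 0L] <- "not_observed"

    genesPresent <- integer(nrow(tallies))
    cd <- SummarizedExperiment::colData(tallies)
    for (g in unique(cd$geneId)) {
        gi <- cd$geneId == g
        genesPresent <- genesPresent +
            (rowSums(occ[, gi, drop = FALSE]) > 0L)
    }

    res <- S4Vectors::DataFrame(
        canonical = rownames(tallies),
        n_units = k,
        n_genes_present = genesPresent,
        n_occ = rowSums(occ),
        n_mut = rowSums(mut),
        n_sub = rowSums(sub),
        stat_cold = unname(sc),
        stat_hot = unname(sh),
        df = df,
        p_cold = unname(pCold),
        p_hot = unname(pHot),
        classification = cls,
        row.names = rownames(tallies))
    new("MotifResults", results = res, alpha = alpha, mode = mode,
        method = method)
}

#' Rank motifs by combined p-value
#'
#' Returns the top \code{m} motifs with the lowest Fisher-combined p-value
#' on the requested side, in ascending order; ties are broken by
#' lexicographic order of the canonical motif. Motifs never observed are
#' excluded.
#'
#' @param results a \linkS4class{MotifResults}.
#' @param side \code{"cold"} or \code{"hot"}.
#' @param m number of motifs to return (fewer when fewer are available).
#' @return a \linkS4class{DataFrame}, the selected rows of
#'   [resultTable()] ordered by the requested p-value.
#' @export
rankTop <- function(results, side = c("cold", "hot"), m = 20L) {
    stopifnot(is(results, "MotifResults"), m >= 1L)
    side <- match.arg(side)
    tab <- results@results
    tab <- tab[tab$classification != "not_observed", , drop = FALSE]
    p <- if (side == "cold") tab$p_cold else tab$p_hot
    o <- order(p, tab$canonical)
    tab[o[seq_len(min(m, nrow(tab)))], , drop = FALSE]
}

#' Motif class lookup from results
#'
#' @param results a \linkS4class{MotifResults}.
#' @return named character vector mapping each observed canonical motif to
#'   \code{"coldspot"}, \code{"hotspot"} or \code{"neutral"}.
#' @export
motifClassMap <- function(results) {
    tab <- results@results
    tab <- tab[tab$classification != "not_observed", , drop = FALSE]
    stats::setNames(tab$classification, tab$canonical)
}

#' Export combined results as TSV
#'
#' @param results a \linkS4class{MotifResults}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
exportResults <- function(results, path) {
    df <- as.data.frame(results@results)
    df$mode <- results@mode
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
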