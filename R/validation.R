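#' @include motif-features.R
NULL

## Distinct mutated middle positions per window, as a 0/1 vector.
.mutatedFlag <- function(windows, records) {
    if (is.null(records) || nrow(records) == 0L)
        return(rep(FALSE, nrow(windows)))
    wkey <- paste(windows$gene_id, windows$block_id, windows$middle_pos,
                  sep = "|")
    rkey <- unique(paste(records$gene_id, records$block_id,
                         records$middle_pos, sep = "|"))
    wkey %in% rkey
}

#' Class-association rates in a held-out gene
#'
#' Applies a motif class map trained on other genes to a held-out gene:
#' for each class, pools the middle-position occurrences of all member
#' motifs (both orientations) and counts how many are mutated. The pooled
#' percentage is a weighted mean of per-motif rates with occurrence
#' weights, which is how a single per-class figure arises from 20 motifs
#' of varying frequency. Classes without any occurrence are flagged
#' undefined.
#'
#' @param windows data.frame from [enumerateWindows()] for the held-out
#'   gene.
#' @param records accepted records from [readMutationTable()] for the
#'   held-out gene.
#' @param classMap named character vector, canonical motif ->
#'   \code{coldspot}/\code{hotspot}/\code{neutral} (see
#'   [motifClassMap()]).
#' @return data.frame with one row per class: \code{class},
#'   \code{n_motifs}, \code{n_occ}, \code{n_mut}, \code{pct} (100 *
#'   n_mut / n_occ, NA when undefined) and \code{pct_rounded} (nearest
#'   integer, for report display).
#' @export
classAssociation <- function(windows, records, classMap) {
    stopifnot(is.character(classMap), !is.null(names(classMap)))
    mutated <- .mutatedFlag(windows, records)
    cls <- classMap[windows$canonical]
    out <- lapply(.MOTIF_CLASSES, function(cc) {
        members <- names(classMap)[classMap == cc]
        sel <- !is.na(cls) & cls == cc
        nocc <- sum(sel)
        nmut <- sum(mutated[sel])
        data.frame(class = cc,
                   n_motifs = length(members),
                   n_occ = nocc,
                   n_mut = nmut,
                   pct = if (nocc > 0L) 100 * nmut / nocc else NA_real_,
                   pct_rounded = if (nocc > 0L)
                       as.integer(round(100 * nmut / nocc)) else NA_integer_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Per-motif occurrence/mutation breakdown in a held-out gene
#'
#' Per-motif counterpart of [classAssociation()]: for each requested
#' canonical motif, the number of middle-position occurrences in the gene
#' and how many of them are mutated. Motifs absent from the gene get a
#' 0/0 row. Class-pooled sums of this table equal the
#' [classAssociation()] output.
#'
#' @inheritParams classAssociation
#' @param motifs character vector of canonical motifs to report.
#' @return data.frame with columns \code{canonical}, \code{n_occ},
#'   \code{n_mut}, \code{pct}.
#' @export
perMotifAssociation <- function(windows, records, motifs) {
    motifs <- unique(canonicalMotif(motifs)$canonical)
    mutated <- .mutatedFlag(windows, records)
    f <- factor(windows$canonical, levels = motifs)
    nocc <- as.integer(table(f))
    nmut <- as.integer(tapply(as.integer(mutated), f, sum))
    nmut[is.na(nmut)] <- 0L
    data.frame(canonical = motifs, n_occ = nocc, n_mut = nmut,
               pct = ifelse(nocc > 0L, 100 * nmut / nocc, NA_real_),
               stringsAsFactors = FALSE)
}

#' Pool a per-motif association table
#'
#' Pools occurrence and mutation counts over the motifs of a table such
#' as [perMotifAssociation()] output (or an externally supplied per-motif
#' count table) into a single rate.
#'
#' @param tab data.frame with columns \code{n_occ} and \code{n_mut}.
#' @return list with \code{n_occ}, \code{n_mut}, \code{pct} and
#'   \code{pct_rounded}.
#' @export
poolAssociation <- function(tab) {
    stopifnot(all(c("n_occ", "n_mut") %in% colnames(tab)))
    nocc <- sum(tab$n_occ)
    nmut <- sum(tab$n_mut)
    pct <- if (nocc > 0L) 100 * nmut / nocc else NA_real_
    list(n_occ = nocc, n_mut = nmut, pct = pct,
         pct_rounded = if (nocc > 0L) as.integer(round(pct)) else
             NA_integer_)
}
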