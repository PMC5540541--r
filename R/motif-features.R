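#' @include motif-stats.R
NULL

#' Purine-tract flag for canonical motifs
#'
#' A motif carries a purine tract when it, or its reverse complement,
#' contains a run of at least \code{minLen} consecutive purines (A or G)
#' read 5' to 3'. By construction the flag is invariant under replacing a
#' motif by its reverse complement (a purine run on one strand is a
#' pyrimidine run on the other, so both strands are checked). Purine
#' tracts of length 4-5 are the hallmark of mutation coldspots.
#'
#' @param motifs character vector of 5-nt ACGT motifs.
#' @param minLen minimum run length, between 1 and 5 (default 4).
#' @return logical vector.
#' @examples
#' hasPurineTract(c("AAAGA", "TCAGA"))  # TRUE FALSE
#' @export
hasPurineTract <- function(motifs, minLen = 4L) {
    motifs <- .checkDNA(motifs, "motifs")
    if (any(nchar(motifs) != 5L))
        stop("motifs must be 5-nt strings")
    if (minLen < 1L || minLen > 5L)
        stop("'minLen' must be between 1 and 5")
    pat <- paste0("[AG]{", minLen, "}")
    grepl(pat, motifs) | grepl(pat, revComp(motifs))
}

#' Middle-position CpG flag for canonical motifs
#'
#' TRUE when a CG dinucleotide overlaps the middle (third) base of the
#' 5-mer, i.e. when the forward string contains CG at positions 2-3 or
#' 3-4. A CG at 2-3 on one strand is a CG at 3-4 on the other, so the
#' flag is strand-symmetric. Middle-position CpG marks the classical
#' deamination-driven hypermutable context seen in hotspots.
#'
#' @param motifs character vector of 5-nt ACGT motifs.
#' @return logical vector.
#' @examples
#' cpgMiddle(c("TCGCA", "CGCAG"))  # TRUE FALSE
#' @export
cpgMiddle <- function(motifs) {
    motifs <- .checkDNA(motifs, "motifs")
    if (any(nchar(motifs) != 5L))
        stop("motifs must be 5-nt strings")
    substr(motifs, 2L, 3L) == "CG" | substr(motifs, 3L, 4L) == "CG"
}

#' Purine-middle strand of a motif
#'
#' Of the two strands of a motif (the canonical 5-mer and its reverse
#' complement), returns the one with a purine (A or G) at the middle
#' position. The two middles are complementary, so exactly one strand
#' qualifies; this is the orientation used for sequence-logo and
#' substitution-spectrum summaries.
#'
#' @param motifs character vector of 5-nt ACGT motifs.
#' @return character vector of purine-middle-oriented 5-mers.
#' @examples
#' purineMiddleStrand(c("AAAGA", "CACAG"))  # "AAAGA" "CTGTG"
#' @export
purineMiddleStrand <- function(motifs) {
    motifs <- .checkDNA(motifs, "motifs")
    if (any(nchar(motifs) != 5L))
        stop("motifs must be 5-nt strings")
    rc <- revComp(motifs)
    ifelse(substr(motifs, 3L, 3L) %in% c("A", "G"), motifs, rc)
}

#' Position frequency matrix with information content
#'
#' Builds the 4 x k base-by-position count matrix of a set of
#' equal-length oriented motifs, plus the per-position information
#' content 2 - H(column) in bits against a uniform background (no
#' small-sample correction). This is the matrix underlying a sequence
#' logo.
#'
#' @param motifs non-empty character vector of equal-length ACGT strings
#'   (orient them first, e.g. with [purineMiddleStrand()]).
#' @return list with elements \code{counts} (4 x k integer matrix, rows
#'   A, C, G, T) and \code{bits} (numeric length k, each in [0, 2]).
#' @examples
#' buildPFM(c("AAAGA", "AAGAA"))$counts
#' @export
buildPFM <- function(motifs) {
    motifs <- .checkDNA(motifs, "motifs")
    if (length(motifs) == 0L)
        stop("need at least one motif")
    k <- unique(nchar(motifs))
    if (length(k) != 1L)
        stop("motifs must all have the same length")
    mat <- matrix(0L, nrow = 4L, ncol = k, dimnames = list(.BASES, NULL))
    chars <- matrix(unlist(strsplit(motifs, "")), ncol = k, byrow = TRUE)
    for (j in seq_len(k)) {
        tab <- table(factor(chars[, j], levels = .BASES))
        mat[, j] <- as.integer(tab)
    }
    freq <- sweep(mat, 2L, colSums(mat), "/")
    H <- apply(freq, 2L, function(f) {
        f <- f[f > 0]
        -sum(f * log2(f))
    })
    list(counts = mat, bits = 2 - H)
}

#' Substitution spectrum on the purine-middle strand
#'
#' Cross-tabulates middle-position substitutions after orienting every
#' occurrence to the purine-middle strand of its motif: when the window's
#' forward 5-mer is not the purine-middle strand, ref and alt are
#' complemented. The diagonal is structurally zero and the total equals
#' the number of oriented substitutions supplied.
#'
#' @param windows data.frame from [enumerateWindows()].
#' @param records accepted records from [readMutationTable()].
#' @param motifs canonical motifs to include (default: all).
#' @return 4 x 4 integer matrix, rows = reference base, columns =
#'   alternate base.
#' @export
substitutionSpectrum <- function(windows, records, motifs = NULL) {
    stopifnot(is.data.frame(windows), is.data.frame(records))
    wkey <- paste(windows$gene_id, windows$block_id, windows$middle_pos,
                  sep = "|")
    rkey <- paste(records$gene_id, records$block_id, records$middle_pos,
                  sep = "|")
    m <- match(rkey, wkey)
    if (anyNA(m))
        stop("some records do not map to a window middle")
    canon <- windows$canonical[m]
    keep <- if (is.null(motifs)) rep(TRUE, nrow(records)) else
        canon %in% motifs
    ref <- records$ref[keep]
    alt <- records$alt[keep]
    fw <- windows$forward_kmer[m][keep]
    pm <- purineMiddleStrand(canon[keep])
    flip <- fw != pm
    comp <- function(b) chartr("ACGT", "TGCA", b)
    ref[flip] <- comp(ref[flip])
    alt[flip] <- comp(alt[flip])
    out <- unclass(table(factor(ref, levels = .BASES),
                         factor(alt, levels = .BASES)))
    names(dimnames(out)) <- c("ref", "alt")
    out
}

#' Overlap between two motif lists
#'
#' Size of the set intersection after collapsing both lists to canonical
#' motifs, e.g. for comparing top-20 lists derived from two database
#' snapshots.
#'
#' @param listA,listB character vectors of 5-nt motifs (either strand).
#' @return integer, number of shared canonical motifs.
#' @examples
#' listOverlap(c("AAAGA", "ACGTA"), c("TCTTT"))  # 1
#' @export
listOverlap <- function(listA, listB) {
    a <- unique(canonicalMotif(listA)$canonical)
    b <- unique(canonicalMotif(listB)$canonical)
    length(intersect(a, b))
}

#' Packaged top-20 coldspot/hotspot motif lists
#'
#' Returns the packaged top-20 motif lists (ranked by ascending Fisher
#' combined p-value) for the requested side and database snapshot, as
#' shipped in \code{inst/extdata}.
#'
#' @param side \code{"coldspot"} or \code{"hotspot"}.
#' @param dataset \code{"2016"} (default) or \code{"2014"}.
#' @return data.frame with columns \code{rank}, \code{forward},
#'   \code{reverse}, \code{canonical}, \code{p_combined}.
#' @examples
#' head(topMotifs("coldspot", "2016"))
#' @export
topMotifs <- function(side = c("coldspot", "hotspot"),
                      dataset = c("2016", "2014")) {
    side <- match.arg(side)
    dataset <- match.arg(dataset)
    f <- system.file("extdata",
                     paste0("top20_", side, "s.tsv"),
                     package = "pentaspot", mustWork = TRUE)
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "integer",
                                            "character", "character",
                                            "numeric"))
    tab <- tab[tab$dataset == dataset, , drop = FALSE]
    tab$canonical <- canonicalMotif(tab$forward)$canonical
    rownames(tab) <- NULL
    tab[, c("rank", "forward", "reverse", "canonical", "p_combined")]
}
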