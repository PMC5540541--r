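#' @include gene-model.R
NULL

.DEFAULT_MCLASSES <- c("missense_nonsense", "splicing")

#' Read and validate a mutation table
#'
#' Reads single-nucleotide mutation records (gene, position, reference
#' base, alternate base, optional mutation class), validates them against
#' the assembled blocks, and splits them into accepted records (mapped to
#' exactly one window middle position) and rejected records with a reason
#' tag. Positions are 1-based source coordinates of the gene. Duplicate
#' (gene, position, alt) rows are dropped: a mutation database records each
#' mutation once. Records within 2 nt of a block edge can never be a
#' window middle and are tagged \code{non_middle}; records outside every
#' block are tagged \code{out_of_block}; a reference base disagreeing with
#' the sequence gives \code{ref_mismatch}.
#'
#' @param x path to a tab-separated file with header columns
#'   \code{gene_id}, \code{position}, \code{ref}, \code{alt} and optional
#'   \code{mclass}, or an equivalent data.frame.
#' @param blocks named list of \linkS4class{GenomicBlocks} (or a single
#'   object) the records are validated against.
#' @param classes mutation classes kept when an \code{mclass} column is
#'   present; default missense/nonsense and splicing.
#' @return list with elements \code{accepted} (data.frame with added
#'   \code{block_id} and \code{middle_pos}) and \code{rejected}
#'   (data.frame with a \code{reason} column).
#' @export
readMutationTable <- function(x, blocks,
                              classes = .DEFAULT_MCLASSES) {
    if (is(blocks, "GenomicBlocks"))
        blocks <- stats::setNames(list(blocks), geneId(blocks))
    if (is.character(x)) {
        x <- utils::read.table(x, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = "character")
    }
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    need <- c("gene_id", "position", "ref", "alt")
    if (!all(need %in% colnames(x)))
        stop("mutation table must have columns: ",
             paste(need, collapse = ", "))
    x$position <- suppressWarnings(as.integer(x$position))
    if (any(is.na(x$position)))
        stop("malformed mutation table: non-integer position")
    x$ref <- toupper(x$ref)
    x$alt <- toupper(x$alt)
    if (!"mclass" %in% colnames(x))
        x$mclass <- "missense_nonsense"
    x <- x[, c("gene_id", "position", "ref", "alt", "mclass")]

    reason <- rep(NA_character_, nrow(x))
    okBase <- x$ref %in% .BASES & x$alt %in% .BASES & x$ref != x$alt &
        nchar(x$ref) == 1L & nchar(x$alt) == 1L
    reason[!okBase] <- "bad_alleles"
    reason[is.na(reason) & !x$mclass %in% classes] <- "class_filtered"
    dup <- duplicated(x[, c("gene_id", "position", "alt")])
    reason[is.na(reason) & dup] <- "duplicate"

    blockId <- rep(NA_integer_, nrow(x))
    middlePos <- rep(NA_integer_, nrow(x))
    reason[is.na(reason) & !x$gene_id %in% names(blocks)] <- "unknown_gene"
    for (g in intersect(unique(x$gene_id), names(blocks))) {
        idx <- which(is.na(reason) & x$gene_id == g)
        if (!length(idx)) next
        offs <- blocks[[g]]@sourceOffsets
        w <- BiocGenerics::width(blocks[[g]]@sequences)
        seqc <- as.character(blocks[[g]]@sequences)
        pos <- x$position[idx]
        bi <- findInterval(pos, offs)
        inBlock <- bi >= 1L & pos <= offs[pmax(bi, 1L)] +
            w[pmax(bi, 1L)] - 1L
        reason[idx[!inBlock]] <- "out_of_block"
        ii <- idx[inBlock]
        bii <- bi[inBlock]
        pib <- pos[inBlock] - offs[bii] + 1L
        base <- substr(seqc[bii], pib, pib)
        bad <- base != x$ref[ii]
        reason[ii[bad]] <- "ref_mismatch"
        edge <- !bad & (pib < 3L | pib > w[bii] - 2L)
        reason[ii[edge]] <- "non_middle"
        ok <- !bad & !edge
        blockId[ii[ok]] <- bii[ok]
        middlePos[ii[ok]] <- pib[ok]
    }
    keep <- is.na(reason)
    accepted <- x[keep, , drop = FALSE]
    accepted$block_id <- blockId[keep]
    accepted$middle_pos <- middlePos[keep]
    rejected <- x[!keep, , drop = FALSE]
    rejected$reason <- reason[!keep]
    rownames(accepted) <- NULL
    rownames(rejected) <- NULL
    list(accepted = accepted, rejected = rejected)
}

#' Minimal VCF reader for SNV mutation records
#'
#' Reads SNV rows of a VCF file, interpreting CHROM as the gene id and POS
#' as the 1-based source position, and validates them like
#' [readMutationTable()]. Multi-allelic rows are expanded; non-SNV rows are
#' dropped. Requires the VariantAnnotation package.
#'
#' @inheritParams readMutationTable
#' @param path path to a VCF file.
#' @return as [readMutationTable()].
#' @export
readMutationVCF <- function(path, blocks, classes = .DEFAULT_MCLASSES) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readMutationVCF() requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    n <- lengths(alt)
    df <- data.frame(
        gene_id = rep(as.vector(GenomicRanges::seqnames(rr)), n),
        position = rep(BiocGenerics::start(rr), n),
        ref = rep(ref, n),
        alt = as.character(unlist(alt)),
        stringsAsFactors = FALSE
    )
    snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
        df$ref %in% .BASES & df$alt %in% .BASES
    readMutationTable(df[snv, , drop = FALSE], blocks, classes = classes)
}

#' Tally motif occurrences, mutations and substitutions
#'
#' Cross-tabulates windows and validated mutation records into per
#' (canonical motif, gene, orientation) counts: \code{nOcc} windows,
#' \code{nMut} windows whose middle position carries at least one
#' substitution (several substitutions at one position count as one
#' mutation), and \code{nSub} distinct substitutions summed over windows
#' (each middle can carry up to 3). Orientation is attributed from the
#' window's forward k-mer relative to the canonical motif, not from the
#' mutation record.
#'
#' @param windows data.frame from [enumerateWindows()] (one or more genes).
#' @param records accepted records from [readMutationTable()]; may have
#'   zero rows.
#' @param allMotifs when TRUE, rows cover all 512 canonical motifs so that
#'   motifs absent from every gene appear with zero occurrences (and are
#'   later reported as \code{not_observed}); default FALSE, rows are the
#'   observed motifs only.
#' @return a \linkS4class{MotifTallies}.
#' @export
tallyCounts <- function(windows, records = NULL, allMotifs = FALSE) {
    stopifnot(is.data.frame(windows), nrow(windows) > 0L)
    genes <- sort(unique(windows$gene_id))
    motifs <- if (allMotifs) allCanonicalMotifs() else
        sort(unique(windows$canonical))
    units <- expand.grid(orientation = c("forward", "reverse"),
                         geneId = genes, stringsAsFactors = FALSE)
    units <- units[, c("geneId", "orientation")]
    unitKey <- paste(units$geneId, units$orientation, sep = "|")
    fMotif <- factor(windows$canonical, levels = motifs)
    fUnit <- factor(paste(windows$gene_id, windows$orientation, sep = "|"),
                    levels = unitKey)
    occ <- unclass(table(fMotif, fUnit))

    nalts <- integer(nrow(windows))
    if (!is.null(records) && nrow(records) > 0L) {
        rkey <- paste(records$gene_id, records$block_id,
                      records$middle_pos, sep = "|")
        cnt <- table(rkey)
        wkey <- paste(windows$gene_id, windows$block_id,
                      windows$middle_pos, sep = "|")
        m <- match(wkey, names(cnt))
        nalts <- ifelse(is.na(m), 0L, as.integer(cnt[m]))
        unmapped <- setdiff(names(cnt), wkey)
        if (length(unmapped))
            warning(length(unmapped),
                    " record position(s) do not match any window middle")
    }
    mut <- .crossSum(as.integer(nalts > 0L), fMotif, fUnit)
    sub <- .crossSum(nalts, fMotif, fUnit)

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(nOcc = occ, nMut = mut, nSub = sub),
        rowData = S4Vectors::DataFrame(canonical = motifs,
                                       row.names = motifs),
        colData = S4Vectors::DataFrame(geneId = units$geneId,
                                       orientation = units$orientation,
                                       row.names = unitKey))
    new("MotifTallies", se)
}

## Sum of w within the cells of a two-way cross-classification.
.crossSum <- function(w, f1, f2) {
    out <- matrix(0L, nrow = nlevels(f1), ncol = nlevels(f2),
                  dimnames = list(levels(f1), levels(f2)))
    if (any(w != 0L)) {
        agg <- stats::xtabs(w ~ f1 + f2)
        out[rownames(agg), colnames(agg)] <- as.integer(agg)
    }
    storage.mode(out) <- "integer"
    out
}

#' Export motif tallies as a long-format TSV
#'
#' @param tallies a \linkS4class{MotifTallies}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
exportTallies <- function(tallies, path) {
    cd <- SummarizedExperiment::colData(tallies)
    long <- data.frame(
        canonical = rep(rownames(tallies), times = ncol(tallies)),
        gene_id = rep(cd$geneId, each = nrow(tallies)),
        orientation = rep(cd$orientation, each = nrow(tallies)),
        n_occ = as.vector(nOcc(tallies)),
        n_mut = as.vector(nMut(tallies)),
        n_sub = as.vector(nSub(tallies)),
        stringsAsFactors = FALSE
    )
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
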