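#' @include AllGenerics.R
NULL

.BASES <- c("A", "C", "G", "T")

## Validate a character vector of DNA strings; returns uppercased input.
.checkDNA <- function(x, what = "sequence") {
    if (!is.character(x) || any(is.na(x)))
        stop("'", what, "' must be a character vector without NA")
    x <- toupper(x)
    bad <- grepl("[^ACGT]", x)
    if (any(bad))
        stop("invalid alphabet in ", what, ": characters outside ACGT in ",
             sum(bad), " element(s), e.g. '", x[bad][1L], "'")
    x
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement, reversed. Vectorized over the input; lowercase
#' input is uppercased, characters outside ACGT raise an error.
#'
#' @param x character vector of DNA strings (any length).
#' @return character vector of reverse complements, same lengths.
#' @examples
#' revComp("AAAGA")  # "TCTTT"
#' @export
revComp <- function(x) {
    x <- .checkDNA(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical motif of 5-mers under reverse-complement collapsing
#'
#' A 5-mer and its reverse complement are the same motif read from the two
#' DNA strands; both are represented by the lexicographically smaller of
#' the pair (A < C < G < T), so the 1024 5-mers collapse into 512 canonical
#' motifs. The orientation records whether the input was the canonical
#' (\code{forward}) or the complementary (\code{reverse}) strand; no odd-
#' length k-mer equals its own reverse complement, so the orientation is
#' always well defined.
#'
#' @param kmers character vector of 5-nt ACGT strings.
#' @return data.frame with columns \code{kmer}, \code{canonical},
#'   \code{orientation}.
#' @examples
#' canonicalMotif(c("TCTTT", "AAAGA"))
#' @export
canonicalMotif <- function(kmers) {
    kmers <- .checkDNA(kmers, "kmers")
    if (any(nchar(kmers) != 5L))
        stop("all k-mers must have length 5")
    uk <- unique(kmers)
    rc <- revComp(uk)
    canon <- ifelse(uk <= rc, uk, rc)
    idx <- match(kmers, uk)
    data.frame(
        kmer = kmers,
        canonical = canon[idx],
        orientation = ifelse(kmers == canon[idx], "forward", "reverse"),
        stringsAsFactors = FALSE
    )
}

#' All canonical 5-mer motifs
#'
#' Enumerates the 1024 5-mers over ACGT and collapses them with their
#' reverse complements, yielding the 512 canonical motifs.
#'
#' @return sorted character vector of the 512 canonical 5-mers.
#' @examples
#' length(allCanonicalMotifs())  # 512
#' @export
allCanonicalMotifs <- function() {
    kmers <- Biostrings::mkAllStrings(.BASES, 5L)
    sort(unique(canonicalMotif(kmers)$canonical))
}

#' Construct a GeneStructure
#'
#' @param geneId single gene identifier.
#' @param exons an \linkS4class{IRanges}, or a 2-column matrix/data.frame of
#'   (start, end) intervals, 1-based inclusive source coordinates, sorted
#'   and non-overlapping.
#' @param flankLength intron nucleotides retained on each side of every
#'   internal exon boundary.
#' @param utrPad nucleotides retained outside the first and last exon
#'   (default 2, so the terminal coding bases can be window middles).
#' @return a \linkS4class{GeneStructure}.
#' @examples
#' GeneStructure("PAH-like", cbind(c(10, 60), c(39, 99)),
#'               flankLength = 7, utrPad = 2)
#' @export
GeneStructure <- function(geneId, exons, flankLength, utrPad = 2L) {
    if (!is(exons, "IRanges")) {
        exons <- as.matrix(as.data.frame(exons))
        exons <- IRanges(start = as.integer(exons[, 1L]),
                         end = as.integer(exons[, 2L]))
    }
    new("GeneStructure", geneId = as.character(geneId), exons = exons,
        flankLength = as.integer(flankLength), utrPad = as.integer(utrPad))
}

#' Assemble analyzed blocks of a gene
#'
#' Pads every exon with \code{flankLength} intronic nucleotides on each
#' side; at the gene's outer ends (before the first exon, after the last)
#' the pad is \code{utrPad} nucleotides instead. Padded intervals that
#' overlap or abut in source coordinates are merged into a single block so
#' no position is counted twice. Every block records per-position region
#' labels (\code{exon}, \code{utr_pad}, \code{intron_flank}).
#'
#' @param structure a \linkS4class{GeneStructure}.
#' @param sourceSeq the gene's source sequence: a single character string
#'   or \code{DNAString}; lowercase is uppercased, non-ACGT rejected.
#' @return a \linkS4class{GenomicBlocks}.
#' @examples
#' gs <- GeneStructure("g", cbind(3, 12), flankLength = 0, utrPad = 2)
#' assembleBlocks(gs, "TTACGTACGTACGTAC")
#' @export
assembleBlocks <- function(structure, sourceSeq) {
    stopifnot(is(structure, "GeneStructure"))
    sourceSeq <- .checkDNA(as.character(sourceSeq), "sourceSeq")
    if (length(sourceSeq) != 1L)
        stop("'sourceSeq' must be a single sequence")
    L <- nchar(sourceSeq)
    ex <- structure@exons
    k <- length(ex)
    if (max(BiocGenerics::end(ex)) > L)
        stop("exon coordinates extend beyond the source sequence (length ",
             L, ")")
    lpad <- rep(structure@flankLength, k)
    rpad <- rep(structure@flankLength, k)
    lpad[1L] <- structure@utrPad
    rpad[k] <- structure@utrPad
    padded <- IRanges(start = BiocGenerics::start(ex) - lpad,
                      end = BiocGenerics::end(ex) + rpad)
    if (min(BiocGenerics::start(padded)) < 1L ||
        max(BiocGenerics::end(padded)) > L)
        stop("padded exon intervals fall outside the source sequence")
    merged <- IRanges::reduce(padded)  # merges overlapping and abutting

    exonPos <- unlist(lapply(seq_len(k), function(i)
        seq.int(BiocGenerics::start(ex)[i], BiocGenerics::end(ex)[i])))
    utrPos <- integer()
    if (structure@utrPad > 0L) {
        utrPos <- c(
            seq.int(BiocGenerics::start(ex)[1L] - structure@utrPad,
                    BiocGenerics::start(ex)[1L] - 1L),
            seq.int(BiocGenerics::end(ex)[k] + 1L,
                    BiocGenerics::end(ex)[k] + structure@utrPad))
    }

    seqs <- character(length(merged))
    labs <- vector("list", length(merged))
    for (i in seq_along(merged)) {
        bs <- BiocGenerics::start(merged)[i]
        be <- BiocGenerics::end(merged)[i]
        seqs[i] <- substr(sourceSeq, bs, be)
        pos <- seq.int(bs, be)
        lab <- rep("intron_flank", length(pos))
        lab[pos %in% utrPos] <- "utr_pad"
        lab[pos %in% exonPos] <- "exon"
        labs[[i]] <- lab
    }
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- as.character(seq_along(merged))
    new("GenomicBlocks",
        geneId = structure@geneId,
        sequences = ss,
        regionLabels = IRanges::CharacterList(labs),
        sourceOffsets = BiocGenerics::start(merged))
}

#' Enumerate 5-nt windows of assembled blocks
#'
#' Slides a 5-nt window along every block; a block of length L yields
#' exactly L - 4 windows with middle positions 3 .. L - 2 (1-based within
#' the block). Windows never span two blocks, so no artificial junction
#' k-mers are created. Blocks shorter than 5 nt yield no windows (a
#' message is emitted).
#'
#' @param blocks a \linkS4class{GenomicBlocks}, or a list of them
#'   (several genes).
#' @return data.frame with columns gene_id, block_id, middle_pos,
#'   source_pos (middle position in source coordinates), forward_kmer,
#'   canonical, orientation, region_label (label of the middle position).
#' @examples
#' gs <- GeneStructure("g", cbind(3, 12), flankLength = 0, utrPad = 2)
#' nrow(enumerateWindows(assembleBlocks(gs, "TTACGTACGTACGTAC")))  # 10
#' @export
enumerateWindows <- function(blocks) {
    if (is.list(blocks))
        return(do.call(rbind, lapply(blocks, enumerateWindows)))
    stopifnot(is(blocks, "GenomicBlocks"))
    seqs <- as.character(blocks@sequences)
    labs <- blocks@regionLabels
    out <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        Lb <- nchar(seqs[i])
        if (Lb < 5L) {
            message("block ", names(seqs)[i], " of gene ", blocks@geneId,
                    " is shorter than 5 nt; no windows enumerated")
            next
        }
        starts <- seq_len(Lb - 4L)
        mid <- starts + 2L
        km <- substring(seqs[i], starts, starts + 4L)
        out[[i]] <- data.frame(
            gene_id = blocks@geneId,
            block_id = as.integer(names(seqs)[i]),
            middle_pos = mid,
            source_pos = blocks@sourceOffsets[i] + mid - 1L,
            forward_kmer = km,
            region_label = as.character(labs[[i]])[mid],
            stringsAsFactors = FALSE
        )
    }
    win <- do.call(rbind, out)
    if (is.null(win))
        return(data.frame(gene_id = character(), block_id = integer(),
                          middle_pos = integer(), source_pos = integer(),
                          forward_kmer = character(), canonical = character(),
                          orientation = character(),
                          region_label = character()))
    cm <- canonicalMotif(win$forward_kmer)
    win$canonical <- cm$canonical
    win$orientation <- cm$orientation
    win[, c("gene_id", "block_id", "middle_pos", "source_pos",
            "forward_kmer", "canonical", "orientation", "region_label")]
}

#' Read gene sequences, exon annotation and padding parameters
#'
#' Reads one FASTA record per gene, a BED file of exon intervals (0-based
#' half-open, converted to 1-based internally; the BED chrom field is the
#' gene id) and a tab-separated parameter file with columns
#' \code{gene_id}, \code{flank_length}, \code{utr_pad}, then assembles the
#' analyzed blocks of every gene.
#'
#' @param fastaPath path to a FASTA file of gene source sequences.
#' @param bedPath path to a BED file of exon intervals.
#' @param paramsPath path to the per-gene parameter TSV; alternatively a
#'   data.frame with the same columns.
#' @return named list of \linkS4class{GenomicBlocks}, one per gene.
#' @export
readGeneInputs <- function(fastaPath, bedPath, paramsPath) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    bed <- rtracklayer::import(bedPath, format = "BED")
    if (is.data.frame(paramsPath)) {
        par <- paramsPath
    } else {
        par <- utils::read.table(paramsPath, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    }
    need <- c("gene_id", "flank_length", "utr_pad")
    if (!all(need %in% colnames(par)))
        stop("parameter table must have columns: ",
             paste(need, collapse = ", "))
    out <- list()
    for (g in names(seqs)) {
        hit <- as.vector(GenomicRanges::seqnames(bed)) == g
        if (!any(hit))
            stop("no exon intervals for gene '", g, "' in BED input")
        row <- par[par$gene_id == g, , drop = FALSE]
        if (nrow(row) != 1L)
            stop("expected exactly one parameter row for gene '", g, "'")
        gr <- bed[hit]
        o <- order(BiocGenerics::start(gr))
        gs <- GeneStructure(
            g,
            IRanges(start = BiocGenerics::start(gr)[o],
                    end = BiocGenerics::end(gr)[o]),
            flankLength = row$flank_length,
            utrPad = row$utr_pad)
        out[[g]] <- assembleBlocks(gs, as.character(seqs[[g]]))
    }
    out
}

#' Export a window table as TSV
#'
#' @param windows data.frame from [enumerateWindows()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
exportWindows <- function(windows, path) {
    utils::write.table(windows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
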