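#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom Biostrings DNAStringSet
NULL

.VALID_REGION_LABELS <- c("utr_pad", "exon", "intron_flank")
.MOTIF_CLASSES <- c("coldspot", "hotspot", "neutral")

#' GeneStructure: exon layout and padding rules for one gene
#'
#' Describes how the analyzed sequence of a gene is assembled from its
#' source sequence: the exon intervals, the number of intronic nucleotides
#' retained on each side of every exon (\code{flankLength}), and the number
#' of untranslated nucleotides kept before the first and after the last
#' codon (\code{utrPad}, default 2 so that the first and last coding bases
#' can occupy window middle positions).
#'
#' @slot geneId single gene identifier.
#' @slot exons \linkS4class{IRanges} of exon intervals, 1-based inclusive
#'   coordinates in the source sequence, sorted and non-overlapping.
#' @slot flankLength non-negative integer, intron nucleotides kept on each
#'   side of internal exon boundaries.
#' @slot utrPad non-negative integer, nucleotides kept outside the first and
#'   last exon in place of the intron flank.
#'
#' @seealso [GeneStructure()], [assembleBlocks()]
#' @exportClass GeneStructure
setClass("GeneStructure",
    representation(
        geneId = "character",
        exons = "IRanges",
        flankLength = "integer",
        utrPad = "integer"
    )
)

setValidity("GeneStructure", function(object) {
    msg <- character()
    if (length(object@geneId) != 1L || is.na(object@geneId) ||
        !nzchar(object@geneId))
        msg <- c(msg, "'geneId' must be a single non-empty string")
    if (length(object@flankLength) != 1L || is.na(object@flankLength) ||
        object@flankLength < 0L)
        msg <- c(msg, "'flankLength' must be a single non-negative integer")
    if (length(object@utrPad) != 1L || is.na(object@utrPad) ||
        object@utrPad < 0L)
        msg <- c(msg, "'utrPad' must be a single non-negative integer")
    ex <- object@exons
    if (length(ex) == 0L) {
        msg <- c(msg, "at least one exon is required")
    } else {
        st <- BiocGenerics::start(ex)
        en <- BiocGenerics::end(ex)
        if (is.unsorted(st, strictly = TRUE))
            msg <- c(msg, "exons must be sorted by start")
        if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
        if (any(st < 1L))
            msg <- c(msg, "exon coordinates must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' GenomicBlocks: assembled contiguous analyzed stretches of one gene
#'
#' Each block is one contiguous padded stretch (UTR pad + exon + intron
#' flanks, with overlapping or abutting padded exon intervals merged), the
#' unit over which 5-nt windows are enumerated. Windows never span two
#' blocks.
#'
#' @slot geneId single gene identifier.
#' @slot sequences \linkS4class{DNAStringSet} of block sequences
#'   (uppercase ACGT), one per block, named by block id.
#' @slot regionLabels \linkS4class{CharacterList} parallel to
#'   \code{sequences}: per-position label in \code{utr_pad}, \code{exon},
#'   \code{intron_flank}.
#' @slot sourceOffsets integer vector, 1-based source coordinate of each
#'   block's first base; blocks are disjoint and sorted.
#'
#' @seealso [assembleBlocks()], [enumerateWindows()]
#' @exportClass GenomicBlocks
setClass("GenomicBlocks",
    representation(
        geneId = "character",
        sequences = "DNAStringSet",
        regionLabels = "CharacterList",
        sourceOffsets = "integer"
    )
)

setValidity("GenomicBlocks", function(object) {
    msg <- character()
    n <- length(object@sequences)
    if (length(object@geneId) != 1L)
        msg <- c(msg, "'geneId' must be a single string")
    if (length(object@regionLabels) != n || length(object@sourceOffsets) != n)
        msg <- c(msg, "'regionLabels' and 'sourceOffsets' must parallel 'sequences'")
    if (n > 0L) {
        freq <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
        if (any(freq[, "other"] > 0L))
            msg <- c(msg, "block sequences must contain only A, C, G, T")
        if (length(object@regionLabels) == n) {
            if (!identical(unname(lengths(object@regionLabels)),
                           unname(BiocGenerics::width(object@sequences))))
                msg <- c(msg, "each label vector must match its block length")
            if (!all(unlist(object@regionLabels) %in% .VALID_REGION_LABELS))
                msg <- c(msg, "region labels must be utr_pad/exon/intron_flank")
        }
        if (length(object@sourceOffsets) == n && n > 1L) {
            ends <- object@sourceOffsets +
                BiocGenerics::width(object@sequences) - 1L
            if (any(object@sourceOffsets[-1L] <= ends[-n]))
                msg <- c(msg, "blocks must be disjoint and sorted in source coordinates")
        }
    }
    if (length(msg)) msg else TRUE
})

#' MotifTallies: per-motif, per-gene, per-orientation window tallies
#'
#' A \linkS4class{SummarizedExperiment} whose rows are canonical 5-nt
#' motifs and whose columns are (gene, orientation) units. Assays:
#' \describe{
#'   \item{nOcc}{number of windows (occurrences) whose forward 5-mer maps
#'     to the motif with that orientation,}
#'   \item{nMut}{occurrences whose middle position carries at least one
#'     recorded substitution (several substitutions at one position count
#'     as one mutation),}
#'   \item{nSub}{total distinct substitutions summed over occurrences
#'     (each position can carry 0-3).}
#' }
#'
#' @seealso [tallyCounts()], [combineMotifs()]
#' @exportClass MotifTallies
setClass("MotifTallies", contains = "SummarizedExperiment")

setValidity("MotifTallies", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("nOcc", "nMut", "nSub") %in% an))
        return("assays 'nOcc', 'nMut', 'nSub' are required")
    occ <- SummarizedExperiment::assay(object, "nOcc")
    mut <- SummarizedExperiment::assay(object, "nMut")
    sub <- SummarizedExperiment::assay(object, "nSub")
    if (any(mut > occ) || any(mut < 0L))
        msg <- c(msg, "0 <= nMut <= nOcc violated")
    if (any(sub < mut) || any(sub > 3L * occ))
        msg <- c(msg, "nMut <= nSub <= 3*nOcc violated")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("geneId", "orientation") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'geneId' and 'orientation'")
    else if (!all(cd$orientation %in% c("forward", "reverse")))
        msg <- c(msg, "orientation must be 'forward' or 'reverse'")
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (canonical motifs) are required")
    if (length(msg)) msg else TRUE
})

#' MotifResults: Fisher-combined per-motif test results
#'
#' Holds one row per canonical motif with the Fisher chi-square statistics,
#' degrees of freedom, combined coldspot and hotspot p-values, pooled
#' tallies and the classification at the significance threshold
#' \code{alpha} (\code{coldspot}, \code{hotspot} or \code{neutral}).
#'
#' @slot results a \linkS4class{DataFrame}, one row per motif.
#' @slot alpha significance threshold used for classification.
#' @slot mode counting mode: \code{collapsed} (several substitutions at a
#'   position count as one mutation) or \code{all_substitutions}
#'   (denominator 3 x occurrences).
#' @slot method proportion-test method used (\code{exact_binomial} or
#'   \code{chisq_cc}).
#'
#' @seealso [combineMotifs()], [rankTop()], [motifClassMap()]
#' @exportClass MotifResults
setClass("MotifResults",
    representation(
        results = "DataFrame",
        alpha = "numeric",
        mode = "character",
        method = "character"
    )
)

setValidity("MotifResults", function(object) {
    msg <- character()
    need <- c("canonical", "n_units", "n_occ", "n_mut", "n_sub",
              "stat_cold", "stat_hot", "df", "p_cold", "p_hot",
              "classification")
    if (!all(need %in% colnames(object@results)))
        msg <- c(msg, paste("results must have columns:",
                            paste(need, collapse = ", ")))
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "'alpha' must be in (0, 1)")
    if (!object@mode %in% c("collapsed", "all_substitutions"))
        msg <- c(msg, "unknown mode")
    if ("classification" %in% colnames(object@results) &&
        !all(object@results$classification %in%
             c(.MOTIF_CLASSES, "not_observed")))
        msg <- c(msg, "invalid classification value")
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic mutation-landscape generator
#'
#' Defaults are the generator's reference study conditions: five genes,
#' planted coldspots mutating at per-occurrence probability 0.02, planted
#' hotspots at 0.75, background motifs at 0.2, at least 30 planted
#' occurrences per motif per gene, and a 4:1 transition:transversion odds
#' for alternate-allele sampling.
#'
#' @slot nGenes number of genes to simulate.
#' @slot exonsPerGene exons per gene.
#' @slot exonLengthRange integer length-2, min and max exon length (nt).
#' @slot flankLength intron nucleotides retained on each exon side.
#' @slot utrPad UTR nucleotides at the gene ends (default 2).
#' @slot plantedColdspots,plantedHotspots canonical 5-mers planted with the
#'   coldspot and hotspot mutation probabilities; disjoint lists.
#' @slot pCold,pHot,pBackground per-occurrence middle-position mutation
#'   probabilities by motif class; 0 <= pCold < pBackground < pHot <= 1.
#' @slot tsTvRatio transition:transversion odds for alternate-base sampling.
#' @slot minPlantedPerGene guaranteed minimum occurrences of each planted
#'   motif per gene (inserted at non-overlapping interior exon positions,
#'   alternating strand orientation).
#' @slot gcContent background G+C fraction of simulated sequence.
#' @slot seed integer seed making the simulation fully reproducible.
#'
#' @seealso [SimConfig()], [simulateGenes()]
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nGenes = "integer",
        exonsPerGene = "integer",
        exonLengthRange = "integer",
        flankLength = "integer",
        utrPad = "integer",
        plantedColdspots = "character",
        plantedHotspots = "character",
        pCold = "numeric",
        pHot = "numeric",
        pBackground = "numeric",
        tsTvRatio = "numeric",
        minPlantedPerGene = "integer",
        gcContent = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@exonsPerGene < 1L)
        msg <- c(msg, "'nGenes' and 'exonsPerGene' must be >= 1")
    if (length(object@exonLengthRange) != 2L ||
        any(object@exonLengthRange < 20L) ||
        object@exonLengthRange[1L] > object@exonLengthRange[2L])
        msg <- c(msg, "'exonLengthRange' must be an increasing pair >= 20")
    if (object@flankLength < 0L || object@utrPad < 0L)
        msg <- c(msg, "pads must be non-negative")
    planted <- c(object@plantedColdspots, object@plantedHotspots)
    if (length(planted)) {
        if (any(nchar(planted) != 5L) ||
            !all(strsplit(paste(planted, collapse = ""), "")[[1L]] %in%
                 c("A", "C", "G", "T")))
            msg <- c(msg, "planted motifs must be 5-nt ACGT strings")
        if (anyDuplicated(planted))
            msg <- c(msg, "planted coldspot and hotspot lists must be disjoint")
    }
    if (!(object@pCold >= 0 && object@pCold <= object@pBackground &&
          object@pBackground < object@pHot && object@pHot <= 1))
        msg <- c(msg, "need 0 <= pCold <= pBackground < pHot <= 1")
    if (object@tsTvRatio <= 0)
        msg <- c(msg, "'tsTvRatio' must be positive")
    if (object@gcContent <= 0 || object@gcContent >= 1)
        msg <- c(msg, "'gcContent' must be in (0, 1)")
    if (object@minPlantedPerGene < 0L)
        msg <- c(msg, "'minPlantedPerGene' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' MotifSimulation: a generated mutation landscape with known truth
#'
#' Bundle of the emitted gene sequences, exon annotation, per-gene padding
#' parameters, mutation table, and the planted truth (motif to class and
#' mutation-probability map plus the full mutation ledger), all derived
#' reproducibly from the seed in \code{config}.
#'
#' @slot sequences \linkS4class{DNAStringSet}, one source sequence per gene.
#' @slot exons \linkS4class{GRanges} of exon intervals (seqnames = gene id).
#' @slot geneParams data.frame with columns gene_id, flank_length, utr_pad.
#' @slot mutations data.frame with columns gene_id, position (1-based source
#'   coordinate), ref, alt, mclass.
#' @slot truth \linkS4class{DataFrame}: canonical motif, class, mutation
#'   probability for every planted motif plus the background rule.
#' @slot config the \linkS4class{SimConfig} used.
#'
#' @seealso [simulateGenes()], [recoveryReport()]
#' @exportClass MotifSimulation
setClass("MotifSimulation",
    representation(
        sequences = "DNAStringSet",
        exons = "GRanges",
        geneParams = "data.frame",
        mutations = "data.frame",
        truth = "DataFrame",
        config = "SimConfig"
    )
)
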