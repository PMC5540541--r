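#' @include AllClasses.R
NULL

#' Accessors for pentaspot classes
#'
#' Small accessor generics: \code{geneId} returns the gene identifier of a
#' \linkS4class{GeneStructure} or \linkS4class{GenomicBlocks};
#' \code{blockSequences}, \code{regionLabels} and \code{sourceOffsets}
#' return the per-block slots of \linkS4class{GenomicBlocks}; \code{nOcc},
#' \code{nMut} and \code{nSub} return the tally matrices of a
#' \linkS4class{MotifTallies}; \code{resultTable} the per-motif table of a
#' \linkS4class{MotifResults}; \code{simSequences}, \code{simExons},
#' \code{simGeneParams}, \code{simMutations}, \code{simTruth} and
#' \code{simConfig} the components of a \linkS4class{MotifSimulation}.
#'
#' @param x an object of the documented class.
#' @return the slot contents (see above).
#' @name accessors
#' @aliases geneId blockSequences regionLabels sourceOffsets nOcc nMut nSub
#'   resultTable simSequences simExons simGeneParams simMutations simTruth
#'   simConfig
#' @examples
#' gs <- GeneStructure("g", exons = cbind(start = 3, end = 12),
#'                     flankLength = 0, utrPad = 2)
#' geneId(gs)
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("blockSequences", function(x) standardGeneric("blockSequences"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("sourceOffsets", function(x) standardGeneric("sourceOffsets"))
#' @rdname accessors
#' @export
setGeneric("nOcc", function(x) standardGeneric("nOcc"))
#' @rdname accessors
#' @export
setGeneric("nMut", function(x) standardGeneric("nMut"))
#' @rdname accessors
#' @export
setGeneric("nSub", function(x) standardGeneric("nSub"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setGeneric("simSequences", function(x) standardGeneric("simSequences"))
#' @rdname accessors
#' @export
setGeneric("simExons", function(x) standardGeneric("simExons"))
#' @rdname accessors
#' @export
setGeneric("simGeneParams", function(x) standardGeneric("simGeneParams"))
#' @rdname accessors
#' @export
setGeneric("simMutations", function(x) standardGeneric("simMutations"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

setMethod("geneId", "GeneStructure", function(x) x@geneId)
setMethod("geneId", "GenomicBlocks", function(x) x@geneId)
setMethod("blockSequences", "GenomicBlocks", function(x) x@sequences)
setMethod("regionLabels", "GenomicBlocks", function(x) x@regionLabels)
setMethod("sourceOffsets", "GenomicBlocks", function(x) x@sourceOffsets)

setMethod("nOcc", "MotifTallies",
    function(x) SummarizedExperiment::assay(x, "nOcc"))
setMethod("nMut", "MotifTallies",
    function(x) SummarizedExperiment::assay(x, "nMut"))
setMethod("nSub", "MotifTallies",
    function(x) SummarizedExperiment::assay(x, "nSub"))

setMethod("resultTable", "MotifResults", function(x) x@results)

setMethod("simSequences", "MotifSimulation", function(x) x@sequences)
setMethod("simExons", "MotifSimulation", function(x) x@exons)
setMethod("simGeneParams", "MotifSimulation", function(x) x@geneParams)
setMethod("simMutations", "MotifSimulation", function(x) x@mutations)
setMethod("simTruth", "MotifSimulation", function(x) x@truth)
setMethod("simConfig", "MotifSimulation", function(x) x@config)

setMethod("show", "GeneStructure", function(object) {
    cat("GeneStructure for gene", object@geneId, "\n")
    cat(" ", length(object@exons), "exon(s), flankLength =",
        object@flankLength, ", utrPad =", object@utrPad, "\n")
})

setMethod("show", "GenomicBlocks", function(object) {
    w <- BiocGenerics::width(object@sequences)
    cat("GenomicBlocks for gene", object@geneId, "\n")
    cat(" ", length(w), "block(s), total length", sum(w), "nt\n")
})

setMethod("show", "MotifTallies", function(object) {
    cat("MotifTallies:", nrow(object), "canonical motifs x",
        ncol(object), "(gene, orientation) units\n")
    cat("  total occurrences:", sum(nOcc(object)),
        "| mutated:", sum(nMut(object)),
        "| substitutions:", sum(nSub(object)), "\n")
})

setMethod("show", "MotifResults", function(object) {
    tab <- object@results
    cat("MotifResults (mode =", object@mode, ", method =", object@method,
        ", alpha =", object@alpha, ")\n")
    cat(" ", nrow(tab), "motifs:",
        sum(tab$classification == "coldspot"), "coldspot,",
        sum(tab$classification == "hotspot"), "hotspot,",
        sum(tab$classification == "neutral"), "neutral\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x", object@exonsPerGene,
        "exons, seed", object@seed, "\n")
    cat("  p(cold/background/hot) =", object@pCold, "/",
        object@pBackground, "/", object@pHot, "\n")
    cat("  planted:", length(object@plantedColdspots), "coldspot(s),",
        length(object@plantedHotspots), "hotspot(s), >=",
        object@minPlantedPerGene, "occurrences per gene\n")
})

setMethod("show", "MotifSimulation", function(object) {
    cat("MotifSimulation:", length(object@sequences), "genes,",
        nrow(object@mutations), "mutations, seed",
        object@config@seed, "\n")
})
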