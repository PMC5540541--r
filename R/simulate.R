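#' @include validation.R
NULL

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig}. The defaults are the
#' generator's reference study conditions: 5 genes of 3 exons (300-400 nt
#' each) with 6-nt intron flanks and 2-nt UTR pads, two planted coldspots
#' mutating at per-occurrence probability 0.02 and two planted hotspots at
#' 0.75 against a background of 0.2, at least 30 planted occurrences per
#' motif per gene, uniform base composition, and 4:1
#' transition:transversion odds.
#'
#' @param nGenes,exonsPerGene,exonLengthRange,flankLength,utrPad gene
#'   geometry; see \linkS4class{SimConfig}.
#' @param plantedColdspots,plantedHotspots canonical 5-mers to plant.
#' @param pCold,pHot,pBackground per-occurrence middle-position mutation
#'   probabilities by motif class.
#' @param tsTvRatio transition:transversion odds for alternate-base
#'   sampling.
#' @param minPlantedPerGene guaranteed planted occurrences per motif per
#'   gene.
#' @param gcContent background G+C fraction.
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' SimConfig(seed = 7)
#' @export
SimConfig <- function(nGenes = 5L, exonsPerGene = 3L,
                      exonLengthRange = c(300L, 400L),
                      flankLength = 6L, utrPad = 2L,
                      plantedColdspots = c("AAAGA", "AAGAA"),
                      plantedHotspots = c("AGGTA", "TGGAA"),
                      pCold = 0.02, pHot = 0.75, pBackground = 0.2,
                      tsTvRatio = 4, minPlantedPerGene = 30L,
                      gcContent = 0.5, seed = 1L) {
    planted <- c(plantedColdspots, plantedHotspots)
    if (length(planted)) {
        cm <- canonicalMotif(planted)
        if (!all(cm$orientation == "forward"))
            stop("planted motifs must be given as canonical 5-mers; ",
                 "non-canonical: ",
                 paste(planted[cm$orientation != "forward"],
                       collapse = ", "))
    }
    new("SimConfig",
        nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene),
        exonLengthRange = as.integer(exonLengthRange),
        flankLength = as.integer(flankLength),
        utrPad = as.integer(utrPad),
        plantedColdspots = as.character(plantedColdspots),
        plantedHotspots = as.character(plantedHotspots),
        pCold = pCold, pHot = pHot, pBackground = pBackground,
        tsTvRatio = tsTvRatio,
        minPlantedPerGene = as.integer(minPlantedPerGene),
        gcContent = gcContent,
        seed = as.integer(seed))
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

## Sample alternate bases for reference bases with transition odds ts:1.
.sampleAlt <- function(ref, tsTvRatio) {
    pTs <- tsTvRatio / (tsTvRatio + 1)
    isTs <- stats::runif(length(ref)) < pTs
    alt <- character(length(ref))
    alt[isTs] <- .TRANSITION[ref[isTs]]
    if (any(!isTs)) {
        pick <- stats::runif(sum(!isTs)) < 0.5
        tv <- vapply(ref[!isTs], function(b) .TRANSVERSIONS[[b]][1L], "")
        tv2 <- vapply(ref[!isTs], function(b) .TRANSVERSIONS[[b]][2L], "")
        alt[!isTs] <- ifelse(pick, tv, tv2)
    }
    alt
}

#' Generate a synthetic mutation landscape with planted motif classes
#'
#' Simulates genes segmented into exon blocks with fixed-length intron
#' flanks and UTR padding, plants the configured coldspot and hotspot
#' motifs at non-overlapping interior exon positions (alternating strand
#' orientation to exercise reverse-complement collapsing), and mutates
#' every window middle position independently with the per-occurrence
#' probability of its canonical motif class: planted coldspots low,
#' planted hotspots high, everything else the background rate. Chance
#' occurrences of a planted 5-mer inherit the planted probability, so the
#' generative rule is purely motif-determined. Alternate alleles are
#' drawn with the configured transition:transversion odds. The whole
#' landscape is a deterministic function of the seed in \code{config}
#' (the RNG seed is set internally).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{MotifSimulation}.
#' @examples
#' sim <- simulateGenes(SimConfig(nGenes = 2, minPlantedPerGene = 5,
#'                                exonLengthRange = c(100L, 120L)))
#' sim
#' @export
simulateGenes <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    baseProb <- c(A = (1 - config@gcContent) / 2,
                  C = config@gcContent / 2,
                  G = config@gcContent / 2,
                  T = (1 - config@gcContent) / 2)
    planted <- c(config@plantedColdspots, config@plantedHotspots)
    plantedRC <- if (length(planted))
        stats::setNames(revComp(planted), planted) else character()
    geneIds <- sprintf("gene%02d", seq_len(config@nGenes))

    seqs <- character(config@nGenes)
    exonList <- vector("list", config@nGenes)
    for (gi in seq_len(config@nGenes)) {
        exLen <- sample(seq.int(config@exonLengthRange[1L],
                                config@exonLengthRange[2L]),
                        config@exonsPerGene, replace = TRUE)
        # introns long enough that padded exons never merge, plus margin
        intronLen <- 2L * config@flankLength +
            sample(10:40, max(config@exonsPerGene - 1L, 1L),
                   replace = TRUE)
        lead <- config@utrPad + 10L
        starts <- integer(config@exonsPerGene)
        pos <- lead + 1L
        for (e in seq_len(config@exonsPerGene)) {
            starts[e] <- pos
            pos <- pos + exLen[e]
            if (e < config@exonsPerGene)
                pos <- pos + intronLen[e]
        }
        total <- pos - 1L + config@utrPad + 10L
        chars <- sample(.BASES, total, replace = TRUE, prob = baseProb)
        ends <- starts + exLen - 1L
        if (length(planted)) {
            slots <- unlist(lapply(seq_len(config@exonsPerGene),
                function(e) seq.int(starts[e], ends[e] - 4L, by = 6L)))
            need <- length(planted) * config@minPlantedPerGene
            if (need > length(slots))
                stop("planted motifs cannot reach the minimum occupancy ",
                     "of ", config@minPlantedPerGene,
                     " per gene within the configured exon lengths")
            slots <- sample(slots)
            si <- 0L
            for (mot in planted) {
                for (i in seq_len(config@minPlantedPerGene)) {
                    si <- si + 1L
                    ins <- if (i %% 2L == 1L) mot else plantedRC[[mot]]
                    chars[slots[si] + 0:4] <- strsplit(ins, "")[[1L]]
                }
            }
        }
        seqs[gi] <- paste(chars, collapse = "")
        exonList[[gi]] <- data.frame(gene_id = geneIds[gi],
                                     start = starts, end = ends)
    }
    exonDf <- do.call(rbind, exonList)
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- geneIds
    exons <- GenomicRanges::GRanges(
        seqnames = exonDf$gene_id,
        ranges = IRanges(start = exonDf$start, end = exonDf$end))
    geneParams <- data.frame(gene_id = geneIds,
                             flank_length = config@flankLength,
                             utr_pad = config@utrPad,
                             stringsAsFactors = FALSE)

    probMap <- c(
        stats::setNames(rep(config@pCold,
                            length(config@plantedColdspots)),
                        config@plantedColdspots),
        stats::setNames(rep(config@pHot, length(config@plantedHotspots)),
                        config@plantedHotspots))

    mutList <- vector("list", config@nGenes)
    for (gi in seq_len(config@nGenes)) {
        g <- geneIds[gi]
        ex <- exonDf[exonDf$gene_id == g, , drop = FALSE]
        gs <- GeneStructure(g, cbind(ex$start, ex$end),
                            flankLength = config@flankLength,
                            utrPad = config@utrPad)
        blocks <- assembleBlocks(gs, seqs[gi])
        win <- enumerateWindows(blocks)
        p <- probMap[win$canonical]
        p[is.na(p)] <- config@pBackground
        hit <- stats::runif(nrow(win)) < p
        if (!any(hit)) next
        ref <- substr(win$forward_kmer[hit], 3L, 3L)
        alt <- .sampleAlt(ref, config@tsTvRatio)
        mutList[[gi]] <- data.frame(
            gene_id = g,
            position = win$source_pos[hit],
            ref = ref,
            alt = alt,
            mclass = "missense_nonsense",
            canonical = win$canonical[hit],
            orientation = win$orientation[hit],
            stringsAsFactors = FALSE)
    }
    mutations <- do.call(rbind, mutList)
    if (is.null(mutations))
        mutations <- data.frame(gene_id = character(),
                                position = integer(), ref = character(),
                                alt = character(), mclass = character(),
                                canonical = character(),
                                orientation = character(),
                                stringsAsFactors = FALSE)

    truth <- S4Vectors::DataFrame(
        canonical = c(config@plantedColdspots, config@plantedHotspots),
        class = c(rep("coldspot", length(config@plantedColdspots)),
                  rep("hotspot", length(config@plantedHotspots))),
        prob = c(rep(config@pCold, length(config@plantedColdspots)),
                 rep(config@pHot, length(config@plantedHotspots))))
    S4Vectors::metadata(truth) <- list(p_background = config@pBackground)

    new("MotifSimulation", sequences = sequences, exons = exons,
        geneParams = geneParams, mutations = mutations, truth = truth,
        config = config)
}

#' Assemble the analyzed blocks of a simulated landscape
#'
#' @param sim a \linkS4class{MotifSimulation}.
#' @return named list of \linkS4class{GenomicBlocks}, one per gene.
#' @export
simulationBlocks <- function(sim) {
    stopifnot(is(sim, "MotifSimulation"))
    out <- list()
    for (g in names(sim@sequences)) {
        gr <- sim@exons[as.vector(GenomicRanges::seqnames(sim@exons)) == g]
        par <- sim@geneParams[sim@geneParams$gene_id == g, ]
        gs <- GeneStructure(
            g, cbind(BiocGenerics::start(gr), BiocGenerics::end(gr)),
            flankLength = par$flank_length, utrPad = par$utr_pad)
        out[[g]] <- assembleBlocks(gs, as.character(sim@sequences[[g]]))
    }
    out
}

#' Write a simulated landscape to FASTA/BED/TSV files
#'
#' Emits exactly the dialects the scan pipeline consumes: a FASTA of gene
#' source sequences, a BED of exon intervals (0-based half-open), the
#' mutation TSV (1-based positions; standard columns only, provenance
#' columns are dropped) and the per-gene parameter TSV.
#'
#' @param sim a \linkS4class{MotifSimulation}.
#' @param dir output directory (created if missing).
#' @return named list of file paths (fasta, bed, mutations, params).
#' @export
writeSimulation <- function(sim, dir) {
    stopifnot(is(sim, "MotifSimulation"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genes.fasta"),
                  bed = file.path(dir, "exons.bed"),
                  mutations = file.path(dir, "mutations.tsv"),
                  params = file.path(dir, "gene_params.tsv"))
    Biostrings::writeXStringSet(sim@sequences, paths$fasta)
    rtracklayer::export(sim@exons, paths$bed, format = "BED")
    utils::write.table(
        sim@mutations[, c("gene_id", "position", "ref", "alt", "mclass")],
        paths$mutations, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim@geneParams, paths$params, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths
}

#' Run the full motif scan on assembled blocks
#'
#' Convenience pipeline: enumerate windows, validate mutation records,
#' tally, test and combine.
#'
#' @param blocks named list of \linkS4class{GenomicBlocks}.
#' @param mutations mutation table path or data.frame (see
#'   [readMutationTable()]).
#' @param ... passed to [combineMotifs()] (mode, method, alpha, ...).
#' @return list with elements \code{windows}, \code{records} (the
#'   accepted/rejected split), \code{tallies} and \code{results}.
#' @export
scanMotifs <- function(blocks, mutations, ...) {
    windows <- enumerateWindows(blocks)
    records <- readMutationTable(mutations, blocks)
    tallies <- tallyCounts(windows, records$accepted)
    results <- combineMotifs(tallies, ...)
    list(windows = windows, records = records, tallies = tallies,
         results = results)
}

#' Run the full motif scan on a simulated landscape
#'
#' @param sim a \linkS4class{MotifSimulation}.
#' @param ... passed to [combineMotifs()].
#' @return as [scanMotifs()].
#' @export
analyzeSimulation <- function(sim, ...) {
    scanMotifs(simulationBlocks(sim),
               sim@mutations[, c("gene_id", "position", "ref", "alt",
                                 "mclass")], ...)
}

#' Planted-motif recovery report
#'
#' Compares pipeline classifications against the planted truth of a
#' simulation: per planted class, how many planted motifs were recovered
#' (recall) and what fraction of all motifs called in that class are
#' planted ones (precision). With no planted motifs of a class, recall is
#' undefined (NA).
#'
#' @param results a \linkS4class{MotifResults} from the pipeline run on
#'   the simulated data.
#' @param truth the \code{simTruth} \linkS4class{DataFrame} of the
#'   simulation.
#' @return data.frame with columns \code{class}, \code{n_planted},
#'   \code{n_recovered}, \code{recall}, \code{n_called},
#'   \code{precision}, \code{full_recovery}.
#' @export
recoveryReport <- function(results, truth) {
    stopifnot(is(results, "MotifResults"))
    cmap <- motifClassMap(results)
    out <- lapply(c("coldspot", "hotspot"), function(cc) {
        planted <- truth$canonical[truth$class == cc]
        called <- names(cmap)[cmap == cc]
        rec <- sum(planted %in% called)
        data.frame(
            class = cc,
            n_planted = length(planted),
            n_recovered = rec,
            recall = if (length(planted)) rec / length(planted) else
                NA_real_,
            n_called = length(called),
            precision = if (length(called))
                sum(called %in% planted) / length(called) else NA_real_,
            full_recovery = length(planted) > 0L &&
                rec == length(planted),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
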