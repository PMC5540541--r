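# Shared builders for small in-code fixtures.

# Blocks of a single-gene toy sequence.
makeBlocks <- function(seq, exons, flank = 0L, utr = 2L, gene = "g1") {
    gs <- GeneStructure(gene, exons, flankLength = flank, utrPad = utr)
    assembleBlocks(gs, seq)
}

# A MotifTallies with hand-specified counts. Each of occ/mut/sub is a
# motif x unit matrix; units alternate forward/reverse per gene.
makeTallies <- function(occ, mut = occ * 0L, sub = mut, genes = "gA") {
    units <- expand.grid(orientation = c("forward", "reverse"),
                         geneId = genes, stringsAsFactors = FALSE)
    units <- units[, c("geneId", "orientation")]
    stopifnot(ncol(occ) == nrow(units))
    key <- paste(units$geneId, units$orientation, sep = "|")
    dimnames(occ) <- dimnames(mut) <- dimnames(sub) <-
        list(rownames(occ), key)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(nOcc = occ, nMut = mut, nSub = sub),
        rowData = S4Vectors::DataFrame(canonical = rownames(occ),
                                       row.names = rownames(occ)),
        colData = S4Vectors::DataFrame(geneId = units$geneId,
                                       orientation = units$orientation,
                                       row.names = key))
    new("MotifTallies", se)
}

# Random ACGT string.
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# Independent brute-force binomial tail: sum of pmf terms computed from
# log-binomial coefficients, no pbinom/dbinom.
bruteTail <- function(x, n, p0, side) {
    pmf <- function(k) exp(lchoose(n, k) + k * log(p0) +
                           (n - k) * log1p(-p0))
    ks <- switch(side, less = 0:x, greater = x:n)
    sum(vapply(ks, pmf, numeric(1)))
}

# Small simulation used by several tests.
quickSim <- function(seed, ...) {
    simulateGenes(SimConfig(seed = seed, ...))
}
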