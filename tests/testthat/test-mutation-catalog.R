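test_that("mutation records are validated and mapped to window middles", {
    #          123456789012345678
    seq <- "TTACGTACGTACGTACGT"
    b <- makeBlocks(seq, cbind(3, 16), flank = 0L, utr = 2L)
    tab <- data.frame(
        gene_id = "g1",
        position = c(8L, 8L, 2L, 8L, 30L, 8L, 9L),
        ref = c("C", "T", "T", "C", "A", "C", "G"),
        alt = c("T", "A", "A", "T", "C", "C", "A"),
        mclass = c("missense_nonsense", "missense_nonsense",
                   "missense_nonsense", "missense_nonsense",
                   "missense_nonsense", "missense_nonsense", "other"),
        stringsAsFactors = FALSE)
    out <- readMutationTable(tab, b)
    # row 1 accepted at middle 8; row 2 ref mismatch; row 3 non-middle
    # (1 nt inside the block edge); row 4 duplicate of row 1; row 5
    # outside any block; row 6 ref == alt; row 7 filtered by class
    expect_identical(nrow(out$accepted), 1L)
    expect_identical(out$accepted$block_id, 1L)
    expect_identical(out$accepted$middle_pos, 8L)
    expect_setequal(out$rejected$reason,
                    c("ref_mismatch", "non_middle", "duplicate",
                      "out_of_block", "bad_alleles", "class_filtered"))
    # the non-middle reason is attached to the edge record
    expect_identical(out$rejected$reason[out$rejected$position == 2L],
                    "non_middle")
    # unknown gene
    out2 <- readMutationTable(
        data.frame(gene_id = "nope", position = 5L, ref = "A", alt = "C"),
        b)
    expect_identical(out2$rejected$reason, "unknown_gene")
    expect_error(
        readMutationTable(data.frame(gene_id = "g1", position = "x",
                                     ref = "A", alt = "C"), b),
        "malformed")
})

test_that("tallies count occurrences, mutations and substitutions", {
    seq <- "TTACGTACGTACGTACGT"
    b <- makeBlocks(seq, cbind(3, 16), flank = 0L, utr = 2L)
    w <- enumerateWindows(b)
    # two substitutions at one middle: one mutation, two substitutions
    tab <- data.frame(gene_id = "g1", position = c(8L, 8L),
                      ref = "C", alt = c("T", "A"),
                      stringsAsFactors = FALSE)
    rec <- readMutationTable(tab, b)$accepted
    expect_identical(nrow(rec), 2L)
    tal <- tallyCounts(w, rec)
    expect_identical(sum(nOcc(tal)), nrow(w))
    expect_identical(sum(nMut(tal)), 1L)
    expect_identical(sum(nSub(tal)), 2L)
    # the mutated window's motif carries the counts
    mot <- w$canonical[w$middle_pos == 8L]
    expect_identical(sum(nMut(tal)[mot, ]), 1L)

    # no mutations at all -> all-zero mutation tallies
    tal0 <- tallyCounts(w, NULL)
    expect_true(all(nMut(tal0) == 0L) && all(nSub(tal0) == 0L))
})

test_that("per-gene mutation totals are conserved", {
    sim <- quickSim(99, nGenes = 3L, exonsPerGene = 2L,
                    exonLengthRange = c(120L, 150L),
                    minPlantedPerGene = 5L)
    blocks <- simulationBlocks(sim)
    w <- enumerateWindows(blocks)
    rec <- readMutationTable(
        simMutations(sim)[, c("gene_id", "position", "ref", "alt",
                              "mclass")], blocks)
    expect_identical(nrow(rec$rejected), 0L)
    tal <- tallyCounts(w, rec$accepted)
    cd <- SummarizedExperiment::colData(tal)
    for (g in unique(cd$geneId)) {
        distinctPos <- length(unique(
            rec$accepted$position[rec$accepted$gene_id == g]))
        expect_identical(
            sum(nMut(tal)[, cd$geneId == g]), distinctPos)
    }
    # substitutions conserve distinct (position, alt) pairs
    expect_identical(sum(nSub(tal)), nrow(rec$accepted))
})

test_that("strand relabeling swaps orientations but conserves totals", {
    sim <- quickSim(17, nGenes = 1L, exonsPerGene = 2L,
                    exonLengthRange = c(100L, 120L),
                    minPlantedPerGene = 4L)
    blocks <- simulationBlocks(sim)
    w <- enumerateWindows(blocks)
    mut <- simMutations(sim)
    rec <- readMutationTable(
        mut[, c("gene_id", "position", "ref", "alt", "mclass")],
        blocks)$accepted
    tal <- tallyCounts(w, rec)

    # relabel: reverse complement the source, flip exon coordinates,
    # complement ref/alt and mirror positions
    g <- "gene01"
    seq <- as.character(simSequences(sim)[[g]])
    L <- nchar(seq)
    gr <- simExons(sim)
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    flipped <- GeneStructure(g, cbind(rev(L - en + 1L), rev(L - st + 1L)),
                             flankLength = simGeneParams(sim)$flank_length,
                             utrPad = simGeneParams(sim)$utr_pad)
    bFlip <- assembleBlocks(flipped, revComp(seq))
    wFlip <- enumerateWindows(bFlip)
    mutFlip <- data.frame(
        gene_id = g,
        position = L - mut$position + 1L,
        ref = chartr("ACGT", "TGCA", mut$ref),
        alt = chartr("ACGT", "TGCA", mut$alt),
        mclass = mut$mclass, stringsAsFactors = FALSE)
    recFlip <- readMutationTable(mutFlip, bFlip)$accepted
    talFlip <- tallyCounts(wFlip, recFlip)

    expect_identical(sort(rownames(tal)), sort(rownames(talFlip)))
    m <- rownames(tal)
    for (a in c("nOcc", "nMut", "nSub")) {
        tot <- rowSums(SummarizedExperiment::assay(tal, a))
        totF <- rowSums(SummarizedExperiment::assay(talFlip, a))[m]
        expect_identical(unname(tot), unname(totF))
    }
    # orientation columns are swapped
    cd <- SummarizedExperiment::colData(tal)
    cdF <- SummarizedExperiment::colData(talFlip)
    expect_identical(
        unname(nOcc(tal)[m, cd$orientation == "forward"]),
        unname(nOcc(talFlip)[m, cdF$orientation == "reverse"]))
})

test_that("the minimal VCF reader agrees with the TSV route", {
    skip_if_not_installed("VariantAnnotation")
    seq <- "TTACGTACGTACGTACGT"
    b <- makeBlocks(seq, cbind(3, 16), flank = 0L, utr = 2L)
    vcf <- c("##fileformat=VCFv4.2",
             "##contig=<ID=g1,length=18>",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             "g1\t8\t.\tC\tT,A\t.\tPASS\t.",
             "g1\t9\t.\tG\tC\t.\tPASS\t.")
    vf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, vf)
    out <- readMutationVCF(vf, b)
    tsv <- readMutationTable(
        data.frame(gene_id = "g1", position = c(8L, 8L, 9L),
                   ref = c("C", "C", "G"), alt = c("T", "A", "C")), b)
    expect_identical(out$accepted[, c("position", "ref", "alt")],
                     tsv$accepted[, c("position", "ref", "alt")])
})
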