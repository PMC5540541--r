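test_that("simulation is a deterministic function of the seed", {
    a <- quickSim(123, nGenes = 2L, exonsPerGene = 2L,
                  exonLengthRange = c(150L, 180L), minPlantedPerGene = 6L)
    b <- quickSim(123, nGenes = 2L, exonsPerGene = 2L,
                  exonLengthRange = c(150L, 180L), minPlantedPerGene = 6L)
    expect_identical(as.character(simSequences(a)),
                     as.character(simSequences(b)))
    expect_identical(simMutations(a), simMutations(b))
    d <- quickSim(124, nGenes = 2L, exonsPerGene = 2L,
                  exonLengthRange = c(150L, 180L), minPlantedPerGene = 6L)
    expect_false(identical(as.character(simSequences(a)),
                           as.character(simSequences(d))))
})

test_that("written files agree byte-for-byte with the in-memory ledger", {
    sim <- quickSim(9, nGenes = 2L, exonsPerGene = 2L,
                    exonLengthRange = c(120L, 150L), minPlantedPerGene = 5L)
    dir <- withr::local_tempdir()
    paths <- writeSimulation(sim, dir)
    reread <- read.table(paths$mutations, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer",
                                        "character", "character",
                                        "character"))
    expect_identical(
        reread,
        simMutations(sim)[, c("gene_id", "position", "ref", "alt",
                              "mclass")])
    # every emitted mutation's ref matches the emitted sequence
    fasta <- Biostrings::readDNAStringSet(paths$fasta)
    for (i in seq_len(nrow(reread))) {
        expect_identical(
            substr(as.character(fasta[[reread$gene_id[i]]]),
                   reread$position[i], reread$position[i]),
            reread$ref[i])
    }
})

test_that("degenerate configurations behave as specified", {
    # zero mutation probability everywhere -> empty mutation table
    s0 <- quickSim(3, nGenes = 1L, exonsPerGene = 2L,
                   exonLengthRange = c(100L, 120L),
                   plantedColdspots = character(),
                   plantedHotspots = character(),
                   pCold = 0, pBackground = 0, pHot = 0.5,
                   minPlantedPerGene = 0L)
    expect_identical(nrow(simMutations(s0)), 0L)
    # planted motifs that cannot fit -> config error
    expect_error(
        quickSim(3, nGenes = 1L, exonsPerGene = 1L,
                 exonLengthRange = c(30L, 30L), minPlantedPerGene = 50L),
        "minimum occupancy")
    # invalid probability ordering rejected
    expect_error(SimConfig(pCold = 0.5, pBackground = 0.2),
                 "pCold <= pBackground")
    # non-canonical planted motif rejected
    expect_error(SimConfig(plantedHotspots = "TCTTT"), "canonical")
})

test_that("planted motifs reach their guaranteed occupancy", {
    sim <- quickSim(21, nGenes = 2L, exonsPerGene = 3L,
                    exonLengthRange = c(250L, 300L),
                    minPlantedPerGene = 12L)
    w <- enumerateWindows(simulationBlocks(sim))
    truth <- simTruth(sim)
    for (g in unique(w$gene_id)) {
        cnt <- table(w$canonical[w$gene_id == g])
        for (mot in truth$canonical)
            expect_gte(cnt[[mot]], 12L)
    }
    # alternating insertion exercises both strands
    expect_setequal(
        unique(w$orientation[w$canonical %in% truth$canonical]),
        c("forward", "reverse"))
})

test_that("planted mutation rates match their class probabilities", {
    # planted hotspot at p = 0.8 with >= 50 occurrences: the observed
    # mutated fraction lies in the exact binomial 99% interval
    sim <- quickSim(31, nGenes = 1L, exonsPerGene = 3L,
                    exonLengthRange = c(350L, 400L),
                    plantedColdspots = character(),
                    plantedHotspots = "AGGTA",
                    pHot = 0.8, pBackground = 0.2,
                    minPlantedPerGene = 50L)
    blocks <- simulationBlocks(sim)
    w <- enumerateWindows(blocks)
    rec <- readMutationTable(
        simMutations(sim)[, c("gene_id", "position", "ref", "alt",
                              "mclass")], blocks)$accepted
    pm <- perMotifAssociation(w, rec, "AGGTA")
    expect_gte(pm$n_occ, 50L)
    ci <- binom.test(pm$n_mut, pm$n_occ, p = 0.8,
                     conf.level = 0.99)$conf.int
    expect_gte(0.8, ci[1])
    expect_lte(0.8, ci[2])
})

test_that("recovery report computes precision and recall against truth", {
    sim <- quickSim(77, exonLengthRange = c(250L, 300L),
                    minPlantedPerGene = 25L)
    res <- analyzeSimulation(sim)$results
    rep <- recoveryReport(res, simTruth(sim))
    expect_identical(rep$class, c("coldspot", "hotspot"))
    expect_identical(rep$n_planted, c(2L, 2L))
    # coldspots at 0.02 against an expected 0.25 are essentially always
    # recovered in full
    cold <- rep[rep$class == "coldspot", ]
    expect_identical(cold$n_recovered, 2L)
    expect_true(cold$full_recovery)
    expect_equal(cold$precision, 1)
    # no planted motifs -> recall undefined
    empty <- S4Vectors::DataFrame(canonical = character(),
                                  class = character(), prob = numeric())
    rep0 <- recoveryReport(res, empty)
    expect_true(all(is.na(rep0$recall)))
})

test_that("hotspot recall does not decrease as the planted rate rises", {
    recallAt <- function(pHot, seeds = c(1201, 1202, 1203)) {
        mean(vapply(seeds, function(s) {
            sim <- quickSim(s, plantedColdspots = character(),
                            plantedHotspots = "AGGTA", pHot = pHot,
                            exonLengthRange = c(250L, 300L),
                            minPlantedPerGene = 20L)
            rep <- recoveryReport(analyzeSimulation(sim)$results,
                                  simTruth(sim))
            rep$recall[rep$class == "hotspot"]
        }, numeric(1)))
    }
    r <- vapply(c(0.78, 0.88, 0.98), recallAt, numeric(1))
    expect_true(all(diff(r) >= 0))  # non-strict monotone
    expect_equal(r[3], 1)           # saturates at a near-certain rate
})
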