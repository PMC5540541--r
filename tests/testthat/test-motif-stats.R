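test_that("exact binomial tails match brute-force enumeration", {
    # spot values
    expect_equal(proportionTest(0, 1, 0.25, "less"), 0.75)
    expect_equal(proportionTest(1, 1, 0.75, "greater"), 0.75)
    expect_equal(proportionTest(0, 10, 0.25, "less"), 0.75^10,
                 tolerance = 1e-12)
    expect_equal(proportionTest(0, 10, 0.25, "less"), 0.0563135,
                 tolerance = 1e-6)
    # full sweep against the log-binomial-coefficient oracle, n <= 25
    for (p0 in c(0.25, 0.75)) {
        for (n in c(1:10, 15, 20, 25)) {
            x <- 0:n
            expect_equal(proportionTest(x, n, p0, "less"),
                         vapply(x, bruteTail, numeric(1), n = n, p0 = p0,
                                side = "less"),
                         tolerance = 1e-10)
            expect_equal(proportionTest(x, n, p0, "greater"),
                         vapply(x, bruteTail, numeric(1), n = n, p0 = p0,
                                side = "greater"),
                         tolerance = 1e-10)
        }
    }
})

test_that("proportion test handles sides, vectors, and degenerate input", {
    # monotonicity in x
    pl <- proportionTest(0:20, 20, 0.25, "less")
    pg <- proportionTest(0:20, 20, 0.25, "greater")
    expect_true(all(diff(pl) >= 0))
    expect_true(all(diff(pg) <= 0))
    # n = 0: no test
    expect_true(is.na(proportionTest(0, 0, 0.25, "less")))
    expect_error(proportionTest(1, 2, 0), "p0")
    expect_error(proportionTest(3, 2, 0.5), "x <= n")
    # continuity-corrected chi-square option agrees with prop.test
    expect_equal(proportionTest(3, 10, 0.25, "two_sided", "chisq_cc"),
                 suppressWarnings(
                     prop.test(3, 10, p = 0.25, correct = TRUE)$p.value))
    expect_equal(proportionTest(1, 8, 0.25, "less", "chisq_cc"),
                 suppressWarnings(
                     prop.test(1, 8, p = 0.25, alternative = "less",
                               correct = TRUE)$p.value))
})

test_that("Fisher combination matches the chi-square tail oracle", {
    # k = 1 identity
    expect_equal(fisherCombine(0.05)$p, 0.05, tolerance = 1e-12)
    # k = 2 frozen values, cross-checked by numeric integration
    fc <- fisherCombine(c(0.1, 0.1))
    expect_equal(fc$statistic, 9.21034, tolerance = 1e-5)
    expect_identical(fc$df, 4L)
    expect_equal(fc$p, 0.0560517, tolerance = 1e-6)
    oracle <- stats::integrate(function(z) stats::dchisq(z, df = 4),
                               fc$statistic, Inf)$value
    expect_equal(fc$p, oracle, tolerance = 1e-6)
    # degenerate ends
    expect_equal(fisherCombine(c(1, 1))$statistic, 0)
    expect_equal(fisherCombine(c(1, 1))$p, 1)
    # permutation invariance
    p <- c(0.9, 0.02, 0.4, 0.07)
    expect_equal(fisherCombine(p)$p, fisherCombine(rev(p))$p)
    expect_error(fisherCombine(numeric()), "no p-values")
    expect_warning(fisherCombine(c(0, 0.5)), "clipped")
})

test_that("per-motif combination pools units and classifies at alpha", {
    # motif present in one unit only: combined p equals the unit p
    occ <- matrix(c(10L, 0L), nrow = 1,
                  dimnames = list("AAAAA", NULL))
    mut <- matrix(c(0L, 0L), nrow = 1)
    tal <- makeTallies(occ, mut)
    res <- resultTable(combineMotifs(tal))
    expect_equal(res$p_cold, pbinom(0, 10, 0.25), tolerance = 1e-12)
    expect_identical(res$df, 2L)
    expect_identical(res$classification, "coldspot")  # 0.0563 < 0.1

    # clear hotspot: all occurrences mutated in both orientations
    occ2 <- matrix(c(8L, 8L), nrow = 1, dimnames = list("ACCTG", NULL))
    mut2 <- matrix(c(8L, 8L), nrow = 1)
    tal2 <- makeTallies(occ2, mut2, sub = mut2)
    res2 <- resultTable(combineMotifs(tal2))
    expect_identical(res2$classification, "hotspot")
    expect_equal(res2$p_hot,
                 fisherCombine(rep(pbinom(7, 8, 0.75, lower.tail = FALSE),
                                   2))$p,
                 tolerance = 1e-12)

    # neutral when both combined p >= alpha
    occ3 <- matrix(c(4L, 4L), nrow = 1, dimnames = list("ACGTA", NULL))
    mut3 <- matrix(c(1L, 1L), nrow = 1)
    res3 <- resultTable(combineMotifs(makeTallies(occ3, mut3, mut3)))
    expect_identical(res3$classification, "neutral")

    # motif with zero occurrences everywhere: not observed, never classified
    occ4 <- rbind(AAAAA = c(10L, 0L), CCCCC = c(0L, 0L))
    mut4 <- occ4 * 0L
    res4 <- resultTable(combineMotifs(makeTallies(occ4, mut4)))
    expect_identical(res4["CCCCC", "classification"], "not_observed")
    expect_true(is.na(res4["CCCCC", "p_cold"]))
})

test_that("all-substitutions mode uses the 3n denominator", {
    occ <- matrix(c(6L, 0L), nrow = 1, dimnames = list("AAAAA", NULL))
    mut <- matrix(c(2L, 0L), nrow = 1)
    sub <- matrix(c(5L, 0L), nrow = 1)
    res <- resultTable(combineMotifs(makeTallies(occ, mut, sub),
                                     mode = "all_substitutions"))
    expect_equal(res$p_cold, pbinom(5, 18, 0.25), tolerance = 1e-12)
    expect_equal(res$p_hot, pbinom(4, 18, 0.75, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("an added mutated occurrence never strengthens coldspot evidence", {
    for (n in 1:10) {
        for (x in 0:n) {
            expect_gte(proportionTest(x + 1, n + 1, 0.25, "less"),
                       proportionTest(x, n, 0.25, "less"))
        }
    }
})

test_that("ranking is by ascending p with lexicographic tie-break", {
    occ <- rbind(GGGGG = c(10L, 0L), AAAAA = c(10L, 0L),
                 CCCCC = c(2L, 0L))
    mut <- occ * 0L
    res <- combineMotifs(makeTallies(occ, mut))
    top <- rankTop(res, "cold", m = 10)
    # identical p for AAAAA/GGGGG -> lexicographically smaller first
    expect_identical(top$canonical[1:2], c("AAAAA", "GGGGG"))
    expect_identical(nrow(top), 3L)  # m larger than motif count
})

test_that("a strongly mutable planted motif ranks first on the hotspot side", {
    sim <- quickSim(2024, plantedColdspots = character(),
                    plantedHotspots = "AGGTA",
                    pCold = 0.01, pHot = 0.9, pBackground = 0.15,
                    minPlantedPerGene = 20L,
                    exonLengthRange = c(200L, 250L))
    res <- analyzeSimulation(sim)$results
    top <- rankTop(res, "hot", m = 5)
    expect_identical(top$canonical[1], "AGGTA")
})
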