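# pentaspot

Detection of pentanucleotide mutation **coldspots** and **hotspots** —
5-nt DNA sequence contexts that are rarely or frequently associated with
single-nucleotide mutations — in genes with dense germline mutation
catalogues. The package is aimed at analysts of inherited-disease
mutation data who want sequence-context effects (purine tracts, CpG
mutability) separated from population-driven mutation spectra: because a
curated mutation database records each mutation once, the per-context
mutation frequency is not inflated by founder effects.

## The method

A gene's analyzed sequence is assembled from its exons, a fixed number
of intronic nucleotides on each side of every exon boundary, and 2 nt of
UTR before the first and after the last codon (so terminal coding bases
can sit at window centers). Each contiguous block is segmented into
overlapping 5-nt windows; a window's 5-mer and its reverse complement
are collapsed into one *canonical motif*, reducing the 1024 possible
5-mers to 512 double-stranded motifs.

For a motif with `n` occurrences in a gene (one strand orientation) of
which `x` have a mutation recorded at the middle position, two
one-sample proportion tests are computed against fixed reference
expectations:

- coldspot evidence: `P(X <= x)` with `X ~ Binomial(n, 0.25)`
- hotspot evidence: `P(X >= x)` with `X ~ Binomial(n, 0.75)`

Per-motif p-values from every (gene, strand) unit are pooled with
Fisher's method, `S = -2 * sum(log p_i) ~ chi-square(2k)`, and motifs
with a combined p-value below `alpha = 0.1` on a side are classified
coldspot or hotspot; everything else is neutral. A second counting mode
treats each of the up-to-3 distinct substitutions per position as a
separate success out of `3n` trials. Selected motifs are characterized
by purine tracts (runs of ≥ 4 A/G on either strand), CpG dinucleotides
overlapping the middle base, position frequency matrices on the
purine-middle strand, and substitution spectra; classes can be validated
on a held-out gene. A synthetic-landscape simulator with planted motif
classes makes every stage testable without any external database.

## Worked example

Simulate five genes under the reference conditions (two planted
coldspots at per-occurrence mutation probability 0.02, two planted
hotspots at 0.75, background 0.2) and run the full scan:

```r
library(pentaspot)
sim  <- simulateGenes(SimConfig(seed = 42))
scan <- analyzeSimulation(sim)
scan$results
#> MotifResults (mode = collapsed , method = exact_binomial , alpha = 0.1 )
#>   500 motifs: 2 coldspot, 0 hotspot, 498 neutral

rankTop(scan$results, "cold", m = 3)[, c("canonical", "n_occ", "n_mut", "p_cold")]
#>       canonical n_occ n_mut       p_cold
#> AAGAA     AAGAA   203     3 2.159948e-13
#> AAAGA     AAAGA   192     3 2.480443e-12
#> CTTTA     CTTTA    63     8 3.469088e-01

recoveryReport(scan$results, simTruth(sim))
#>      class n_planted n_recovered recall n_called precision full_recovery
#> 1 coldspot         2           2      1        2         1          TRUE
#> 2  hotspot         2           0      0        0        NA         FALSE
```

The two planted coldspots (AAGAA, AAAGA — ~200 occurrences each, 3
mutated) head the coldspot ranking with combined p-values near 1e-12 and
are the only motifs classified. The planted hotspots mutate at exactly
the 0.75 reference expectation, so the one-sided hotspot test has no
power against them — rates must exceed 0.75 to be called (see the
methods vignette). Feature flags behave as the coldspot biology
predicts:

```r
hasPurineTract(c("AAGAA", "AAAGA"))   # TRUE TRUE
cpgMiddle(c("AAGAA", "TCGCA"))        # FALSE TRUE
```

The packaged top-20 motif lists from the two database snapshots are
available via `topMotifs(side, dataset)` for feature and overlap
analyses.

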