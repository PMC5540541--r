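---
title: "Detecting pentanucleotide mutation coldspots and hotspots"
author: "pentaspot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pentanucleotide mutation coldspots and hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentaspot)
```

## The model

Certain DNA sequence contexts mutate more or less often than chance.
`pentaspot` quantifies this at the 5-mer scale: every position of an
analyzed gene sequence is the middle of a 5-nt window, and a window's
5-mer together with its reverse complement — the same physical context
read from the two strands — forms one *canonical motif*. Collapsing the
1024 5-mers by reverse complement yields exactly 512 motifs (no
odd-length 5-mer is its own reverse complement). A motif is a
**coldspot** when its middle positions carry significantly fewer
recorded mutations than a reference expectation, and a **hotspot** when
they carry significantly more.

The statistical unit is a (gene, strand-orientation) pair. For a motif
occurring $n$ times in a unit with $x$ mutated middles, the coldspot
p-value is the lower binomial tail $P(X \le x)$ under
$X \sim \mathrm{Bin}(n, p_0^{cold})$ with $p_0^{cold} = 0.25$, and the
hotspot p-value is the upper tail under $p_0^{hot} = 0.75$. Unit
p-values are pooled with Fisher's method,
$S = -2\sum_i \ln p_i \sim \chi^2_{2k}$, and the motif is classified at
a fixed threshold $\alpha = 0.1$: coldspot if the combined coldspot
p-value is below $\alpha$, hotspot if the hotspot side is, neutral
otherwise. The 25%/75% expectations are fixed reference benchmarks, not
estimates of the genome-wide mutation rate; they encode how strongly a
context must deviate before it is called.

Two counting modes exist. In the default *collapsed* mode, any number of
distinct substitutions at one middle position counts as one mutation
($x \le n$). In *all-substitutions* mode each position can contribute up
to three distinct alternate bases, and the test uses $x = $ substitution
count against $3n$ trials. The collapsed mode is the primary analysis;
the all-substitutions mode becomes informative only when catalogues are
dense enough that repeated, different substitutions at one site are
common.

### Sidedness

The classification tests are deliberately one-sided. A two-sided test
against 0.75 would flag motifs with *low* mutation frequency as
"significant hotspots", inverting the intended meaning; one-sided tails
make small p-values on each side mean exactly one thing. The
continuity-corrected chi-square approximation
(`method = "chisq_cc"`, the default flavor of `prop.test` in base R) is
provided for parity experiments with workflows built on that test, but
the exact binomial tail is the default: per-unit counts are routinely
below 10, where the chi-square approximation is poor.

A consequence worth stating explicitly: a one-sided test has no power at
its own null. A context whose true per-occurrence mutation probability
is exactly 0.75 yields uniform-ish hotspot p-values, and no amount of
data classifies it as a hotspot; only rates above 0.75 are detectable,
with power growing in the excess and in occurrence counts. The
simulator's reference hotspot probability sits at exactly 0.75, so
hotspot recovery under the reference conditions measures this boundary
behavior (coldspots, planted at 0.02 against an expectation of 0.25, are
recovered essentially always). `recoveryReport()` makes both outcomes
visible rather than papering over them.

## Sequence assembly choices

Analyzed sequence is assembled per gene from exons padded with
`flankLength` intronic nucleotides on each side — mutation catalogues
cover intron edges to varying depth, so the retained flank is a per-gene
parameter — and `utrPad = 2` untranslated nucleotides at the two gene
ends, so the first and last coding bases can occupy window middles.
Padded intervals that overlap or abut are merged before windowing;
otherwise short introns would be counted twice. Windows are enumerated
within contiguous blocks only: concatenating blocks would manufacture
junction 5-mers that do not exist in the genome. Mutations within 2 nt
of a block edge can never be window middles; they are reported with a
reason tag, not tallied. Source coordinates are 1-based internally; BED
input (0-based, half-open) is converted on import by `rtracklayer`, and
records failing reference-base validation are collected per record
rather than aborting the run.

The canonical representative of a motif pair is the lexicographically
smaller string under A < C < G < T. Any fixed convention gives
identical statistics; fixing one makes outputs joinable across runs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `flankLength` | per gene (sim: 6) | intron nt retained per exon side |
| `utrPad` | 2 | nt outside first/last codon |
| `p0Cold`, `p0Hot` | 0.25, 0.75 | reference expectations (probability) |
| `alpha` | 0.1 | classification threshold |
| `mode` | collapsed | mutation counting mode |
| `method` | exact_binomial | proportion-test flavor |

P-values are floored at 1e-300 before logs so Fisher's statistic stays
finite; the floor is documented and triggers a warning when hit. Ties in
`rankTop()` break lexicographically, making rankings deterministic.
Motifs never observed in any gene are reported `not_observed`, never
classified — even long genes do not contain all 512 motifs, and absence
of evidence is not evidence of coldness.

## The synthetic landscape generator

`simulateGenes()` emulates the statistical structure the tests assume,
nothing more. Genes are i.i.d. uniform ACGT (GC content adjustable);
exon/flank geometry matches the assembly model; planted coldspot and
hotspot motifs are written into exon interiors at non-overlapping
positions with alternating strand orientation (exercising the
reverse-complement collapsing); every window middle then mutates
independently with the probability of its canonical motif class —
planted coldspots 0.02, planted hotspots 0.75, background 0.2 by
default, with at least 30 planted occurrences per motif per gene across
5 genes. Chance occurrences of a planted 5-mer inherit the planted
probability, keeping the generative rule purely motif-determined.
Alternate bases are drawn with 4:1 transition:transversion odds. The
whole landscape is a deterministic function of one seed.

What the generator does **not** emulate: real base composition and
repeat structure, mutational signatures (APOBEC, UV), CpG-methylation
chemistry, replication-strand asymmetry, and correlated mutation
processes. Passing recovery tests therefore demonstrates that the
pipeline's bookkeeping and statistics behave as designed under the
assumed independence model — not that the biological findings of any
particular gene set replicate.

## Validation on a held-out gene

`classAssociation()` applies trained motif classes to a gene excluded
from training and pools middle-position occurrences per class; the
pooled percentage is the occurrence-weighted mean of per-motif rates,
which is how a single per-class figure arises from motifs of very
different frequencies. On synthetic data the expected ordering —
coldspot% < neutral% < hotspot% — is reproduced qualitatively; exact
percentages depend on the full trained motif table of the training
genes. Display rounding is to whole percent; raw fractions are always
retained.

## Problem sizes and test design

The test suite and acceptance script size simulations to keep full runs
in the low minutes on one CPU: recovery uses the reference 5-gene
configuration over 10 seeds; the empirical null study uses 200 compact
two-gene genomes with all motifs at exactly the coldspot expectation
0.25, where the observed non-neutral classification fraction stays well
below the nominal $\alpha = 0.1$ because exact one-sided tests are
conservative at per-unit counts of 1–10. Oracles are independent of the
code paths they check: binomial tails are re-derived from log-binomial
coefficients, the Fisher tail from numeric integration of the
chi-square density, and block assembly from brute-force coordinate
unions.

## Known limitations

- Expectations of 25%/75% are convention, not estimated rates; absolute
  classifications shift with catalogue density, which is why two
  database snapshots are compared by list overlap rather than p-value.
- No multiple-testing correction is applied beyond the fixed $\alpha$;
  the ranking, not the absolute significance, is the primary output.
- Insertion/deletion events, population frequencies, and splice-site
  semantics beyond fixed-length flanks are out of scope.
- Hotspot classification is blind to contexts mutating at or below the
  0.75 expectation (see *Sidedness*).
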