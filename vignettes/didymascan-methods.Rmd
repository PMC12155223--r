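---
title: "Methods: detecting didyma and quantifying APOBEC/carcinogen co-mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting didyma and quantifying APOBEC/carcinogen co-mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological model

APOBEC3B (A3B) is a cytidine deaminase that converts cytosine to uracil in
single-stranded DNA, with a strong preference for TC dinucleotides followed
by A or T (the TCW motif). Its fixed mutational footprint is C>T (SBS2-like)
and C>G (SBS13-like) substitutions in TCW. Bulky-adduct carcinogens such as
4-nitroquinoline 1-oxide (NQO, a tobacco surrogate) damage guanines and
leave G>T and G>C mutations (an SBS4-like spectrum). These two processes
interact: removal of a bulky guanine adduct by nucleotide excision repair
(NER) transiently exposes a 24–32 nt single-stranded tract, which is exactly
the substrate A3B requires. Two deaminations of the same tract, immortalised
by gap-filling synthesis, produce a *didymos*: a pair of strand-coordinated
APOBEC-context mutations separated by at most 32 nt, with near-identical
variant allele fractions because both arise in one cell. *Didyma* (the
plural) are distinct from *omikli* (2–3 clustered mutations, mismatch-repair
associated) and *kataegis* (4 or more, break/R-loop associated).

This package implements the full analysis chain needed to detect and
quantify these events in somatic SNV catalogs, and a synthetic-data
generator that emulates the co-mutagenesis model so every stage can be
validated against planted truth.

## Catalog ingestion and somatic confidence

Catalogs are plain data frames of single-base substitutions (1-based
coordinates, VCF convention) read from TSV or VCF. The somatic confidence
filter retains records with at least 3 alt-supporting reads, at least 10
reads of depth, VAF strictly over 0.05, and support from at least 2
callers. The VAF comparison is strict because the rule is phrased as an
exceedance; records exactly at 0.05 are removed. Setting a threshold to 0
disables that criterion, which also lets catalogs without read-support
columns pass through. Filtering is idempotent, monotone in each threshold,
and never reorders records.

## Context classification

Every substitution is strand-normalised before classification: records with
a purine reference are reverse-complemented so channels are expressed on
the pyrimidine strand (for SBS96 and APOBEC calls) or on the guanine strand
(for adduct calls).

* **APOBEC context**: C>T or C>G with upstream T and downstream A or T
  after pyrimidine-strand normalisation (T[C>T/G]W).
* **NQO context**: G>T in any context, and G>C except when the guanine is
  followed by A on its own strand. The GA exclusion removes exactly the
  class that reads as an opposite-strand T[C>G] APOBEC event, so no
  mutation can be counted in both the didyma class and the adduct-pair
  class. We apply the exclusion for every downstream-A guanine regardless
  of the upstream base, because the definition carries no upstream
  condition.

Records whose context window leaves the contig or contains N are excluded
from context-dependent operations with a logged tally but retained in the
catalog. Pentanucleotide spectra divide each (5-mer, alt) count by the
genome-wide occurrence count of that 5-mer; genome-wide counts are
strand-collapsed (forward plus reverse occurrences), which keeps the
normaliser symmetric with the strand-normalised mutation counts.

## Cluster detection and taxonomy

Intermutation distance (IMD) between two mutations is the difference of
their positions: the two cytosines of TCC are 1 apart, those of TCTC are
2 apart. No IMD crosses a sample or chromosome boundary. For per-mutation
decisions we use the nearest-neighbour IMD.

The sample-dependent IMD threshold is estimated against simulated
backgrounds (next section): scanning candidate cutoffs c, the observed
number of mutations with nearest IMD ≤ c is compared with the simulated
mean count, which defines a Poisson null for the upper-tail probability
P(X ≥ observed). These probabilities are Benjamini-Hochberg adjusted
across the scanned grid, and the returned threshold is the largest c with
adjusted probability below 0.01 for which chance accounts for at most 10%
of the observed sub-threshold mutations (the 90% capture condition). We
chose the Poisson tail over the raw empirical tail because an empirical
probability over k iterations cannot fall below 1/(k+1); at the default
100 iterations that floor (≈0.0099) survives no multiplicity adjustment
across a grid, so the empirical variant can never satisfy q < 0.01. The
candidate grid is graded — 1 nt steps to 100 nt, 10 nt steps to 1 kb,
100 nt steps to 10 kb — matching the resolution at which the estimate is
scientifically meaningful. When no cutoff qualifies the sample has no
detectable excess clustering and the estimator returns NA; didyma
extraction does not depend on it (the 32 nt window is fixed by mechanism,
not by sample).

A regional correction guards against density artefacts: each mutation is
evaluated in the 1 Mb window centred nearest to it (centres advance in
0.5 Mb steps), and where the window's observed count exceeds the simulated
mean, the local cutoff is the global threshold divided by that ratio.
Ratios below 1 never loosen the cutoff. We rescale the cutoff rather than
re-test per-window counts because the cutoff form composes naturally with
the event-building step; this is one of two defensible readings of a
sliding-window correction and is flagged as a design choice.

Events are maximal runs of consecutive mutations whose successive IMDs sit
below the (locally corrected) threshold; runs are split wherever two
successive members differ in VAF by more than 0.1 (co-occurrence in one
cell), and events of size ≥ 2 survive. Strand-coordinated, all-APOBEC
events are labelled *omikli* (size 2–3, at least one IMD > 1) or
*kataegis* (size ≥ 4, at least one IMD > 1); a size-2 event within 32 nt
additionally carries the didyma mark. A pair at IMD exactly 1 fails the
omikli clause and is labelled didyma outright — it is tallied as didyma
only, never as omikli, which keeps the subtraction arithmetic
(omikli − didyma) exact.

Didyma extraction scans *all* same-sample, same-chromosome pairs of
APOBEC-context mutations within 32 nt (not only consecutive ones),
requiring a shared pyrimidine strand and ΔVAF ≤ 0.1. Qualifying pairs that
chain into runs of three or more mutations are not decomposed into
multiple didyma: the run belongs to the omikli/kataegis taxonomy and no
pair is emitted from it. Run membership is resolved by connected
components of the qualifying-pair graph, a deterministic operationalisation
of "mutually clustered". Both behaviours (with and without run
decomposition) are available, and extraction can optionally be restricted
to clustered-flagged mutations; the default scans all mutations because
the didyma definition is a fixed-window one.

## Background simulation and enrichment

Simulated catalogs preserve, for every mutation: chromosome, forward-strand
trinucleotide (which fixes both the SBS96 channel and the reference strand
of the mutated base), and genic/intergenic location when gene models are
supplied. Candidate positions are pre-indexed per (chromosome,
trinucleotide, region) stratum, and each iteration draws positions without
replacement within a stratum whenever enough candidate sites exist, so
per-stratum counts are conserved exactly; a stratum with no candidate in
its region class falls back to the whole chromosome with a logged tally.
VAFs and alleles are carried over. All randomness flows from a single
seed and reruns are bit-identical.

Pair enrichment compares, at each exact IMD from 1 to 100 nt, the observed
number of qualifying pairs with the arithmetic mean of the same count over
(by default) 100 simulated catalogs: enrichment = observed / simulated
mean, per the four pair classes (APOBEC or adduct context, same or
opposite strand). We read the observed/simulated division as a division of
*pair* counts per IMD — a mutation-level division is ill-defined within an
IMD bin. Bins with zero simulated mean are reported as undefined (NA),
never as 0 or infinity, and cohort averaging takes the per-IMD mean of
per-sample enrichment ratios, skipping undefined entries and recording the
number of contributing samples.

## Genomic attribution

Genic space is the union of gene spans (exons plus introns, merged so
overlapping genes are not double-counted); defaults for mouse territory
are 1,139 Mb genic and 1,584 Mb intergenic, overridable or recomputable
from supplied models. A didymos is assigned one region and gene by its
first member's position — at ≤ 32 nt, pairs essentially never straddle a
boundary, and a deterministic rule beats double counting. For a gene
transcribed from sense strand S, a pair whose pyrimidine strand equals S
carries its lesions on the coding (non-transcribed) strand; pairs in genes
overlapping on opposite strands are NA because the template is ambiguous.
Expression bins are the quartiles of the positive-expression distribution
(nearest-rank boundaries, ties share a bin) plus a fifth bin for zero or
missing expression.

## The synthetic generator

The generator emulates the study conditions end to end: an i.i.d. random
genome at GC 0.42 (mouse-like), non-overlapping genes with zero-inflated
log-normal expression (20% zeros; log-mean 2, log-sd 1 — an arbitrary but
realistic dispersion for normalised counts), dispersed APOBEC mutations
uniform over TCW sites (70% C>T), dispersed adduct mutations over guanine
sites with a 3× weight for guanines followed by another guanine (the
observed +1 guanine bias) and 75% G>T, and didyma planted by choosing a
strand, a 24–32 nt tract (length uniform), and two TCW cytosines inside
it, each mutated to T or G with probability one half. Pair members share a
clone VAF (truncated normal, mean 0.35, sd 0.1 on [0.1, 0.6]) plus small
within-pair noise (sd 0.02), so true pairs respect the 0.1 ΔVAF bound.
Read support is drawn to satisfy the somatic filters (depth ≈ 30×, floor
12; alt reads ≥ 3; 2–4 callers). Genic tract placement is weighted by
1 + expression, giving the transcription-associated bias a simple linear
form.

Three configuration profiles are canonical:

* **default** (`synthetic_config()`): 1 Mb genome, 50 didyma pairs, 200
  dispersed APOBEC + 400 dispersed adduct mutations. Background mutations
  are rejected within 100 nt of a planted tract and tracts sit at least
  200 nt apart, so recovery scoring against truth is unambiguous.
* **null** (`synthetic_config_null()`): 2 Mb, 50,000 dispersed APOBEC
  mutations, nothing planted. The count is sized so each IMD bin of the
  same-strand APOBEC profile carries ≥ 500 expected pairs, keeping the
  Monte-Carlo noise of the ratio within a few percent — the power needed
  to test the null value of 1 bin by bin.
* **enrichment** (`synthetic_config_enrichment()`): 2 Mb, 500 pairs over
  5,000 + 2,000 dispersed mutations with the truth-isolation constraints
  off. Those constraints deliberately deplete observed pairs near planted
  tracts; they are right for recovery scoring and wrong for an enrichment
  profile, whose 33–100 nt band must behave like the null.

What the generator does **not** emulate: sequencing noise and mapping
artefacts, copy-number and clonal structure beyond a single clone VAF per
event, replication timing, chromatin-dependent mutation rates, and the
full 96-channel spectra of real signatures (context classes are simplified
to their defining motifs; signature refitting is tested against its own
explicit profile fixtures instead). Tests passing on synthetic data
therefore validate the algorithmic chain, not robustness to real-data
artefacts.

## Signature refitting

SBS96 catalogs are refit against known signature profiles by two-pass
non-negative least squares: pass 1 solves min‖counts − S·x‖₂ with x ≥ 0
over all signatures; signatures whose exposure share x_i/Σx falls strictly
below the cutoff (default 0.015) are removed; pass 2 re-solves over the
retained set. Shares exactly at the cutoff are retained (with a 1e-9
guard for solver round-off). Pruning can worsen the fit, so no residual
monotonicity is assumed — instead the pass-2 solution is checked optimal
over the retained columns. Fitting operates on raw counts; NNLS is
scale-equivariant, so counts versus frequencies only rescales exposures.
If every signature is pruned the best pass-1 signature is kept and the
result flagged. Burdens normalise per megabase with 2,723 Mb (mouse WGS),
2,800 Mb (human WGS) or 30 Mb (human WES). A small built-in matrix of five
synthetic profiles shaped after familiar signature classes supports tests
and examples without any download; the loader accepts the standard
COSMIC-style TSV.

## Problem sizes and numerics

The validation suite runs at desk scale: recovery experiments use the
default 1 Mb / 700-mutation profile over 10 seeded replicates; null and
enrichment calibrations use the 2 Mb profiles with 100 simulation
iterations; oracle-equivalence checks sweep 50 random catalogs of up to
2,000 mutations against full O(n²) enumerations. Sweep pair enumeration
uses sorted positions with `findInterval` windows; simulation indexes
candidate positions once per genome. All stochastic stages consume one
integer seed; derived stage seeds stay below 2³¹.

## Known limitations

The regional correction's rescaling form, the connected-component reading
of "mutually within 32 nt", and the strand-collapsed pentanucleotide
normaliser are documented choices among defensible alternatives; each is
isolated behind its own function so sensitivity analyses can swap them.
The sample-dependent threshold reconstruction matches the published
capture/q-value constraints but not necessarily the reference tool's
internals. Expression handling consumes pre-normalised values and treats
missing genes as non-expressed.
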