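---
title: "Comparing two transcriptomes: orthology, Ka/Ks, GO profiling and marker mining"
author: "compara authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two transcriptomes: orthology, Ka/Ks, GO profiling and marker mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compara)
```

# The analysis

`compara` implements the standard desk analysis for comparing two de novo
transcriptome assemblies of related species — the kind of study performed
for non-model organisms such as bivalves, where EST collections exist but
reference genomes do not. The pipeline answers three questions:

1. **Which transcripts are 1:1 orthologs?** Bidirectional best hits (BBH)
   between the two transcript sets, followed by two paralog-exclusion
   filters: both members must best-match the *same* protein accession in a
   reference protein database, and the annotated gene name must occur only
   once within each transcriptome (multi-gene families confound pairwise
   Ka/Ks, so they are excluded wholesale).
2. **Which orthologs evolve fast or under constraint?** Pairwise Ka/Ks
   (dN/dS) on the aligned coding sequences, with a Fisher exact test of
   ω ≠ 1 and a three-way classification (constrained / neutral /
   fast-evolving), plus hypergeometric GO enrichment of the constrained and
   fast-evolving sets.
3. **Which markers can be mined from the assemblies?** Bi-allelic SNPs and
   indels from read pileups under joint depth and minor-allele-frequency
   thresholds, and perfect microsatellites (SSRs) of 2–6 bp motifs.

Every stage is also exercisable against a synthetic dual-transcriptome
generator with known ground truth, which is what the test suite and the
acceptance script use.

# Ortholog identification

`best_hits()` takes, per query, the subject with the maximal bitscore among
hits with E-value ≤ 10⁻⁶ (the conventional cutoff for cross-species EST
searches). What "best" means is ambiguous in much of the
literature; bitscore is the standard reading, with ties broken by lower
E-value and then lexicographic subject id so results are reproducible.
`reciprocal_best_hits()` keeps (a, b) iff each is the other's best.

The same-protein filter compares protein *accessions*, not gene names —
the unambiguous notion of "the same protein". Pairs with an unannotated
member cannot satisfy the criterion and are dropped (not errored), mirroring
how such screens are run in practice. The unique-name filter counts gene
names over each **full** annotation table, case-insensitively after
whitespace normalisation, because BLAST-derived names vary in case.

`funnel_report()` asserts the invariant that stage counts are monotone
non-increasing.

# Ka/Ks estimation

## Codon alignment

CDS intervals come from the transcript-vs-protein search (highest-bitscore
HSP; reverse-strand hits are reverse-complemented; the 3' end is trimmed to
a codon multiple). CDSs with an internal stop codon are removed; a terminal
stop is stripped. Alignment is protein-guided: the translations are
globally aligned (BLOSUM62, gap open 10, gap extend 0.5 — ordinary protein
alignment defaults) and codons are threaded back through the protein
alignment. Columns containing a gap or an ambiguity codon are discarded and
counted in QC fields.

## NG86

The Nei–Gojobori (1986) method counts synonymous sites per codon as the
fraction of the nine single-nucleotide changes that are synonymous (changes
into stop codons count as nonsynonymous), averaged over the two sequences;
differences are averaged over all shortest mutational pathways with equal
weights, excluding pathways through stop codons. Proportions receive the
Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4 leaves the
distance undefined (`saturated` flag) rather than raising an error. NG86 is
deliberately simple and serves as the cross-check for YN00: the test suite
verifies its per-codon site counts and all 61×61 pairwise difference counts
against an independent brute-force pathway-enumeration oracle.

## YN00

The Yang–Nielsen (2000) approximate method corrects NG86's two main biases:
transition/transversion bias and unequal codon usage.

* **Codon frequencies** are estimated from the pair by F3×4 (positional
  nucleotide frequencies multiplied across codon positions, stops zeroed,
  renormalised). A pseudocount of 0.1 per base per position keeps observed
  codons from getting zero weight on very short alignments; at realistic
  lengths its effect is negligible.
* **κ** is estimated from fourfold-degenerate third positions and
  nondegenerate positions, each K80-corrected, combining the transitional
  and transversional distance components weighted by the class site counts.
  Only positions whose codons agree at the other two positions are used, so
  each difference is unambiguously attributable. When neither class yields
  a valid estimate (tiny alignments), κ falls back to 2 and the result is
  flagged `kappa_default`.
* **Site counting** weights each possible mutation by π(target codon) ×
  κ^transition (mutations into stops excluded) and scales to 3 sites per
  codon, so S + N = 3L exactly.
* **Difference counting** averages over mutational pathways with weights
  proportional to the product over steps of π(target) × κ^transition ×
  ω^nonsynonymous. Because the weights depend on ω, counts and distances
  are iterated to convergence (change < 10⁻⁶, at most 100 iterations,
  `not_converged` flag otherwise). Each differing codon pair is counted in
  both directions at half weight, which makes the estimate exactly
  symmetric in the two sequences.
* **Distances**: the transitional/transversional difference proportions per
  site class receive the K80 correction; Ka and Ks are the corrected
  distances and ω = Ka/Ks (undefined with a flag when Ks = 0 or a class is
  saturated).

The generator (below) implements the matching GY94-style model, so
parameter recovery is a fair end-to-end check: at 2,000 codons, κ = 2,
t = 0.4, the mean ω̂ over 200 replicate pairs is within a few percent of
the truth across ω ∈ {0.1, 0.5, 1, 2}, and the acceptance suite requires
agreement within 10% plus strict monotonicity.

One convention difference is worth knowing: in the no-bias limit (κ = 1,
uniform frequencies) YN00 does not reduce *exactly* to NG86, because NG86
counts mutations into stop codons as nonsynonymous while YN00's
mutation-weighted site counting excludes them. This leaves a systematic
~5% offset in ω at these settings; the regression test brackets the ratio
at 8%.

## Significance and classification

The screening question "does ω deviate from 1?" is answered with a
two-sided Fisher exact test on the 2×2 table
[[round(Sd), round(Nd)], [round(S−Sd), round(N−Nd)]] — the convention of
the KaKs_Calculator family of tools. Corrected counts can occasionally
exceed sites; negative rounded cells are clamped to zero and flagged. No
multiple-testing correction is applied by default (the per-pair p < 0.05
reading used in comparable studies); `p_adjust = TRUE` enables
Benjamini–Hochberg for users who want it. Labels: `fast_evolving` iff
ω > 1 and p < α, `constrained` iff ω < 1 and p < α, otherwise `neutral`
(`undefined` when ω cannot be computed; such pairs are reported with their
flags rather than silently dropped).

Fisher's exact test is conservative on discrete tables, so under a neutral
simulation the empirical rejection rate at α = 0.05 sits slightly below
the nominal level (≈ 0.04–0.05 at 500-codon pairs); the acceptance band is
0.05 ± 0.02 over 1,000 replicates.

# GO tools

The minimal OBO reader accepts `[Term]` stanzas with `id`, `name`,
`namespace` and `is_a` lines only; `part_of` and other relationships are
deliberately ignored (the conservative reading for rollup and enrichment),
obsolete terms are skipped, and cycles are a hard error. "Level 3" is
defined as shortest-path depth with the namespace root at level 1 — the
convention of the Blast2GO-style tooling this analysis emulates; the
longest-path alternative was rejected because it is unstable under DAG
edits. Rollup propagates each annotation to all of its level-k ancestors; a
gene counts once per level-k term, and because the ontology is a DAG, a
gene can legitimately count towards several terms, so per-namespace
fractions may sum to more than 1.

Enrichment is the upper-tail hypergeometric probability
p = Σᵢ₌ₖ C(K,i)·C(N−K,n−i)/C(N,n) with annotations propagated to all
ancestors before counting; the test suite checks it against a direct
combinatorial oracle for N ≤ 60. The population is always explicit — the
caller decides whether it is "all analysed pairs" or "all annotated genes",
since published analyses are frequently ambiguous on this point.

# Markers

**SNPs.** A site is called iff the two most frequent alleles each have ≥ 8
reads and the minor allele frequency is ≥ 25%, both thresholds inclusive
(the screening rule used for 454 EST assemblies). The MAF denominator is
the top-two-allele depth, not the total: the vendor tools this emulates
emit bi-allelic variants. The alternative (total depth) is exposed as
`maf_denominator = "total"`. Third alleles are ignored for the call but
reported in a QC column. A↔G and C↔T are transitions, other base pairs
transversions, deletion/insertion alleles indels. The summary reports the
frequency as "one per X bp" with X = round(total bp / number of calls).

**SSRs.** Perfect tandem repeats only, motif lengths 2–6 (mononucleotide
runs are excluded by construction), reported iff total length ≥ 15 bp AND
≥ 3 repeats — jointly, so the length constraint binds for 2–4-mers and the
repeat constraint for 5–6-mers. Mismatch-tolerant detection is out of
scope: tools' "default" mismatch models are under-documented, and the
perfect-repeat mode is exactly reproducible. A trailing partial repeat
extends the tract (fractional repeat count); `count_partial = FALSE`
disables this. When a region qualifies under several motif lengths the
shortest period wins (an AT run is never reported as ATAT); remaining
overlaps are resolved left-to-right, longest first. The canonical class of
a motif is the lexicographic minimum over its rotations and the rotations
of its reverse complement (so TA → AT, GAT → ATC), which is how summary
tables in the field group motifs.

# The synthetic generator

`simulate_ortholog_pairs()` draws an ancestral codon sequence from the
configured codon frequencies (stops excluded) and evolves two independent
lineages, each for t/2 expected substitutions per codon, under a GY94-style
continuous-time Markov process: single-nucleotide changes only, rate
proportional to the target-codon frequency, × κ for transitions, × ω for
nonsynonymous changes, rates into stop codons zero. The matrix is scaled so
one unit of t is one expected substitution per codon at stationarity, hence
the pairwise divergence of a pair is t. Evolution uses uniformisation
(Poisson number of candidate jump events per site, applied in vectorised
rounds), which is exactly distributed and fast. Each operation takes one
integer seed and uses a single RNG stream with a fixed draw order, so fixed
seed ⇒ byte-identical FASTA.

Defaults are chosen once for a realistic EST study: 500 codons per CDS
(a typical annotated transcript), κ = 2 (the usual vertebrate/invertebrate
transition bias), t = 0.4 (congeneric-species divergence at which Ka/Ks is
informative but far from saturation), uniform codon frequencies (the
neutral baseline; any 61-vector can be supplied). The ω grid used in tests
{0.1, 0.5, 1, 2} spans constraint to positive selection for estimator
characterisation, not empirical realism.

`simulate_hit_tables()` fabricates the similarity-search tables so every
true pair is a mutual best hit sharing a protein accession and a unique
gene name; planted decoys each violate exactly one filter (non-reciprocal
best hit; reciprocal pair best-matching different proteins; reciprocal pair
with a gene name duplicated within transcriptome A) and are recorded per
type, so funnel tests have per-filter ground truth. Bitscores are monotone
in simulated identity; the exact formula is arbitrary and only needs to
rank hits. `simulate_pileup()` draws per-read alleles binomially around the
planted fractions and then applies substitution errors. `plant_ssrs()`
inserts tracts at recorded coordinates and regenerates any random
background in which the detector would find anything other than exactly the
qualifying planted tracts, so truth tables are exhaustive.
`simulate_go_annotations()` builds a toy two-level ontology with one term
enriched in a designated study set.

What the generator does *not* emulate: 454 homopolymer error profiles,
assembly artefacts, isoform structure, indels within orthologous CDSs
(alignments of simulated pairs are trivially column-paired; the
protein-guided aligner is separately tested on constructed indel cases),
and realistic codon-usage skew unless supplied. Passing tests therefore
demonstrate correctness of the estimators and filters under their model
assumptions, not robustness to assembly noise in real EST data.

# Numerical choices and degenerate inputs

* Convergence: YN00 iterates to 10⁻⁶ or 100 iterations; non-convergence is
  flagged, never silent.
* Identical sequences: Ka = Ks = 0, ω undefined with `no_differences`.
* Saturation (JC p ≥ 3/4, or K80 log arguments ≤ 0): distances are NA with
  `saturated`, and such pairs are counted separately in reports.
* Ties: best-hit ties break by E-value then subject id; SNP allele-count
  ties by the fixed allele order A, C, G, T, del, ins; SSR major-motif ties
  lexicographically with a flag.
* Empty inputs: empty hit tables give empty maps and an all-zero funnel;
  an empty study set gives an empty enrichment table; zero SNP calls give
  an NA frequency, not a division error.

# Problem sizes in the shipped checks

The test-suite and acceptance-script problem sizes are the package's own
choices for a thorough-but-quick verification: estimator recovery uses 200
replicate pairs of 2,000 codons per ω in the test suite and 40 pairs of
1,000 codons in the acceptance script; null calibration uses 1,000 and 300
neutral replicates of 500-codon pairs respectively; funnel, SNP, SSR and
enrichment checks use tens of items because they are exact (precision and
recall 1 on error-free fixtures), where more replication adds nothing.

# Limitations

* Pairwise, 1:1 orthologs only; no many-to-many orthology, no ML codon
  models (codeml-style branch/site models are out of scope).
* The Fisher test on rounded site/difference counts is an approximation
  inherited from the tool convention it mirrors; it is well calibrated in
  the tested regime but counts are not integers by nature.
* Perfect SSRs only; compound/interrupted repeats are reported as separate
  adjacent tracts.
* The SNP caller starts from allele counts; read mapping is out of scope,
  so mapping artefacts are invisible to it.
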