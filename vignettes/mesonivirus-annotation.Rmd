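---
title: "Annotating mesonivirus genomes and demarcating species by pairwise evolutionary distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating mesonivirus genomes and demarcating species by pairwise evolutionary distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoniv)
```

## The problem

Mesoniviruses are mosquito-specific positive-sense single-stranded RNA
viruses (family *Mesoniviridae*, order *Nidovirales*) with ~20-kb
polyadenylated genomes. Their genomes share a rigid plan: a long 5' UTR
(~360 nt), a replicase region of two long overlapping ORFs (ORF1a and ORF1b)
expressed as a single pp1ab polyprotein through a programmed -1 ribosomal
frameshift at a slippery heptamer (GGAUUUU), a spike ORF (ORF2a) whose 5'
region also carries a nested nucleoprotein ORF (ORF2b) in an alternative
frame, two small overlapping ORFs (ORF3a/ORF3b, with a putative CACUUUU
slippery site), a short conserved ORF4, and a long 3' terminal region
(~1790 nt) before the poly-A tail. Subgenomic mRNA synthesis is directed by
conserved transcription-regulatory sequences (TRS) in the 5' UTR and in the
regions preceding ORF2a and ORF3a.

This package implements the two analyses that genome descriptions of new
mesonivirus isolates rest on:

1. **rule-based annotation** of that canonical architecture from a bare
   genome sequence (ORF mapping, TRS and slippery-heptamer scans, conceptual
   frameshift translation, spike cleavage-site motifs, nucleoprotein
   features, block-insertion detection against a reference), and
2. **species demarcation** by maximum-likelihood pairwise evolutionary
   distances (PED) between the conserved replicase domains (3CLpro, RdRp,
   ZnHel1) under the WAG amino-acid model, with taxa clustered at the
   proposed cutoff of 0.032 substitutions/site.

Because real genomes must be fetched from a sequence database, the package
also ships a synthetic-genome generator with a complete truth table, so that
every stage of the pipeline is testable offline and every claim in the test
suite is checked against planted ground truth.

## The annotation rule set

The literature gives the genome *plan* but no assignment algorithm, so the
rules are a design of this package (all thresholds sit in `meso_config()`
and travel with every report):

* **ORF1a** — first ATG-initiated ORF of at least 3000 nt.
* **ORF1b** — the maximal stop-to-stop open segment in frame
  `(frame(ORF1a) + 2) mod 3` that spans the 3' boundary of ORF1a. No start
  codon is required: ORF1b is expressed only by read-through. The segment
  through that boundary is unique per frame, so the choice is deterministic.
* **ORF2a** — next ATG ORF of at least 2000 nt starting *after the end of
  ORF1b*. An earlier draft used "after ORF1a", but that rule is structurally
  wrong: ORF1b's open segment always contains a long internal ATG-to-stop
  ORF in its own frame (its first internal ATG), which would usurp the spike
  ORF. The genome plan is sequential, so ORF2a is sought after the replicase
  region.
* **ORF2b** — longest alternative-frame ORF that starts in the 5' third of
  ORF2a and is contained in it (the nucleoprotein gene sits in the region
  encoding the variable N-terminal product of the spike polyprotein).
* **ORF3a** — next ATG ORF of at least 500 nt after ORF2a;
  **ORF3b** — longest different-frame ORF overlapping ORF3a's 3' half.
* **ORF4** — first ORF of 120-200 nt after ORF3b; it is allowed to be
  absent, as in some described mesoniviruses.
* 5' UTR = `[0, start(ORF1a))`; 3' terminal region = `[end(last ORF), end)`.
  Unassigned ORFs of more than 180 nt (60 aa) are reported as alternative
  small ORFs.

Coordinates are 0-based half-open everywhere inside the package (protein
positions included); GFF3 output converts to 1-based inclusive, strand
always `+` (these are (+)ssRNA genomes and only the forward strand is
scanned).

## Frameshift translation

The -1 frameshift is modeled as one nucleotide read twice: the fused coding
sequence is `genome[start1a, j) + genome[j-1, end1b)`, where `j` is the
smallest ORF1a codon boundary at least 7 nt past the slippery heptamer and
at most 16 nt past it, chosen as the first such boundary that yields a
stop-free fusion. The constraint window plus the no-internal-stop condition
make the join unambiguous; translation uses the standard genetic code and
the terminal stop is dropped. The same machinery produces the putative p3ab
read-through product at the CACUUUU site; whether ORF3b is actually
expressed that way is unsettled, so the package emits both the ORF3b
product and p3ab.

## Motifs and protein features

TRS elements are matched with a small degenerate-pattern language (exact
bases, `x` for any base, a parenthesized symbol for an optional base; the
longest match at a position wins, overlapping hits are all reported). The
two patterns used by default are `AUxxUACUACUACUA` and `AGAx(x)ACUCUCCCA`,
stored in the DNA alphabet (U = T). Only `x` is treated as a wildcard; any
other emphasis the patterns may carry in print is ignored.

Spike cleavage sites are pure sequence-motif scans: signalase cleavage after
a C or S immediately followed by `[L/A/S]TRIDL`, and the S1-S2 site after an
R followed by `WDSSYV`. Signal-peptide and transmembrane predictions are out
of scope.

Protein molecular weights use average (not monoisotopic) residue masses with
one water, reported in kDa and rounded only at report time. Isoelectric
points are found by bisection of the net-charge function on pH (0, 14) to
|charge| < 1e-4 with an EMBOSS-style pKa table (N-terminus 8.6, C-terminus
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1). The table is an
argument of `protein_pi()`; the biological claim the pipeline relies on
("nucleoproteins are highly basic, pI > 10") is robust to the table choice.
N-glycosylation sequons follow N-X-S/T with X not proline.

## Pairwise alignment

Global alignment is an affine-gap Needleman-Wunsch (Gotoh) implemented in
C++, with a gap of length *k* costing `gap_open + k * gap_extend` (defaults
5/-4/10/0.5, the common EDNAFULL-style values; protein mode uses BLOSUM62).
Tie-breaking is deterministic: diagonal over gap-in-b over gap-in-a. A
banded mode (default half-width 2000, widened by the length difference)
keeps 20-kb genome pairs affordable; on homologous pairs the banded result
equals the full matrix, and the test suite checks both against exhaustive
enumeration of all alignments of tiny pairs.

Substitutions are counted as mismatching gap-free columns, and one indel
event is one maximal gap run, matching how isolate differences are usually
phrased ("68 substitutions and two indels of 3 and 6 nt"). Whether published
counts exclude gap-adjacent columns is not stated anywhere; this package
counts gap-free mismatch columns only.

Block insertions are maximal reference-row gap runs of at least 30 nt, after
aligning a query region to the homologous reference region (the reference
window is extended past the query window so a genuine insertion does not
force compensating end gaps; terminal gap runs are window artifacts and are
never reported as blocks). Regions whose column identity (matches over all
alignment columns) falls below 0.30 are refused as non-homologous rather
than mined for gap runs — note that for nucleotide sequences the random
baseline of this statistic is ~0.42, so the floor only rejects grossly
non-alignable inputs. In-frame blocks are annotated with imperfect repeats
of an SKRKGK-like seed (Hamming distance at most 2 by default). Insertion
boundaries can wobble by a few nucleotides when flanking bases make the gap
placement ambiguous; block *lengths* are exact.

## Distances, demarcation, divergence profiles

`wag_ml_distance()` maximizes the likelihood
\(\prod_i \pi_{a_i} P_{a_i b_i}(d)\) over \(d \in [10^{-9}, 10]\) (tolerance
1e-7), where \(P(d) = e^{Qd}\) comes from the eigendecomposition of the
reversible rate matrix built from the published WAG exchangeabilities and
equilibrium frequencies, normalized to one expected substitution per site.
Gap and ambiguous columns are dropped pairwise; fewer than 50 comparable
sites is an error, and estimates at the upper bound are flagged as
saturated. A Poisson mode (uniform exchangeabilities and frequencies) exists
mainly as an analytic cross-check: its ML estimate must equal
\(-(19/20)\,\ln(1 - (20/19)\,\hat p)\), and the test suite holds it to that
within 1e-6. No rate heterogeneity is applied by default — the source
methods name only "the WAG model" — and demarcation output labels the model
accordingly.

Domains are located by local alignment (BLOSUM62, gap open 10, extend 0.5)
of reference domain sequences against pp1ab; hits are extrapolated to the
full reference span so that boundary residues trimmed by the local
alignment do not shift the reported coordinates, and a hit scoring below
25% of the reference self-score is a missing domain. The packaged reference
set (`reference_domains()`) is **synthetic** — built deterministically from
the canonical default-spec genome — because curated mesonivirus domain
sequences cannot be shipped here; analyses of real genomes should pass a
curated reference FASTA instead. Concatenation order is fixed: 3CLpro,
RdRp, ZnHel1.

Species are demarcated by agglomerative clustering of the PED matrix cut at
t = 0.032. Single linkage is the default because the published criterion
compares pairs to the cutoff, which single linkage operationalizes exactly
(any pair at or below t shares a species); complete linkage is available
for sensitivity analysis. Sliding-window divergence uses windows of 100
residues stepped by 25 (the original analysis names its software but not
its parameters; both are configurable), excludes gaps pairwise, and records
windows with no comparable sites as missing rather than zero.

## What the generator emulates — and what it does not

`make_genome()` constructs the full canonical plan with known coordinates:
planted leader/body TRS instances, a stop-free -1-frame ORF1b overlap with
its heptamer, the nested K/R-enriched (hence pI > 10) nucleoprotein ORF,
overlapping ORF3a/3b, ORF4, an optional in-frame ORF1a block insertion
(typical lengths 0/180/573/588 nt, ~940 nt into ORF1a, i.e. ~1300 nt from
the 5' terminus) carrying imperfect terminal repeats, a 3' region and a
poly-A tail. Default segment lengths give a ~19.9-kb body. ORF filler is
sampled codon-wise excluding stops; dual-frame regions are repaired by
resampling free codons until both frames are open; guard stop codons are
planted immediately upstream of each ORF start (and of the nested ORF2b and
overlapping ORF3b starts) so the planted ORF is exactly what the assignment
rules find. After construction, independent string scans re-verify every
uniqueness assumption (no competitor ORFs, single heptamer per overlap, no
spurious TRS hits); in the rare case a random filler region violates one,
the genome is regenerated from a derived seed. Generation is deterministic
given the spec.

`evolve_sequence()` applies i.i.d. site evolution (Jukes-Cantor for
nucleotides, WAG for amino acids); `make_isolate_set()` plants exact,
disjoint substitution counts (avoiding planted motifs, starts and stops, and
never creating a stop in a planted frame) plus optional 3'-region deletions;
`make_species_set()` evolves only the three replicase domains (single-frame
regions) and re-encodes them, leaving the architecture intact.

None of this models codon-usage or dinucleotide bias, recombination, rate
heterogeneity across sites, or sequencing error. Passing tests therefore
demonstrate that the *algorithms* are correct on genomes obeying the
canonical plan at controlled divergences — not that the rule set is robust
to every oddity of real field isolates.

## Numerical and size choices

* Poly-A trimming requires a run of at least 5 A (tail delimitation is not
  specified anywhere authoritative); the generator ends genome bodies with
  a non-A base so the planted tail length is recoverable exactly.
* Ambiguity codes are rejected by default (`allow_ambiguous = FALSE`); when
  allowed they score as mismatches everywhere and never match motifs.
* Ties among equal-length candidate ORFs break toward the smaller start.
* The test suite and the acceptance script use 100 randomized synthetic
  genomes for architecture/frameshift recovery, 10,000 sites for distance
  recovery (within 5% at d between 0.05 and 1.0), 200 tiny pairs plus
  exhaustive length-2 pairs against the alignment enumeration oracle, and
  20 random matrices for the clustering properties.

## Known limitations

* The assignment rules are calibrated to the canonical plan; a genome with
  a genuinely missing element fails loudly (by design) rather than being
  annotated partially.
* PED values depend on the domain reference used for extraction; with the
  synthetic packaged reference, only genomes descended from the same
  simulated base are meaningfully comparable. Real analyses need a curated
  reference set.
* Banded alignment equals the full matrix only when the optimal path stays
  within the band — guaranteed for near-identical 20-kb isolates with the
  default band of 2000, but not for arbitrary unrelated inputs (use
  `band = NULL` for the exact full matrix).
* The stimulating RNA structure of the frameshift (pseudoknot/stem-loop) is
  explicitly not modeled; only the heptamer and the conceptual translation
  are.
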