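---
title: "Methods: cross-kingdom sRNA discovery, target prediction and validation design"
author: "ckRNAi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-kingdom sRNA discovery, target prediction and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Arbuscular mycorrhizal (AM) fungi such as *Rhizophagus irregularis* can
deliver small RNAs (sRNAs) into root cells of their host plant, where the
fungal sRNAs load into the host's Argonaute 1 (AGO1) and silence host mRNAs
— cross-kingdom RNA interference (ckRNAi). The experimental design this
package analyses is an AGO1 co-immunoprecipitation: sRNA libraries are
sequenced from mock-inoculated and fungus-colonized (AM) roots, so every
read is a candidate AGO1 cargo. The computational task is to find the rare
fungal sRNA species among an overwhelming host background, predict which
host transcripts they silence, and design the downstream validation
reagents (short tandem target mimics and scrambled controls) and readouts
(colonization indices, qPCR fold changes).

`ckRNAi` implements that pipeline as reusable, tested functions, and ships
a synthetic-data generator with a machine-readable ground-truth manifest
so that every stage can be validated end to end without any external
downloads.

## Subtractive read classification

Reads are adapter-clipped (exact match of the first 8 nt of the 3' adapter;
inserts outside 15–34 nt rejected — no quality filtering is used anywhere),
collapsed to unique sequences with counts, and mapped by **perfect
full-length matching on both strands** to the host and fungal genomes.
Perfect-match-only mapping is deliberate: the inclusion logic of the study
design is "did not perfectly match the host reference", and an exact
contract is testable against a brute-force substring oracle, which the test
suite does on every run. All loci of multi-mapping reads are retained; no
best-hit capping is applied.

Classification is a partition of unique reads:

* **host** — at least one perfect host locus;
* **fungal** — no host locus, at least one fungal locus;
* **ambiguous** — perfect loci in both genomes (excluded from candidacy
  rather than assigned to either organism);
* **unassigned** — no perfect locus anywhere.

Internally the package uses a Biostrings `PDict` with a trusted band over
the first 15 nt to match all query widths in one pass; the oracle tests
pin this optimisation to the naive scan.

## Candidate selection

A sequence is a cross-kingdom candidate when all four filters hold:

1. length 21–24 nt (`sizes`),
2. more than 25 reads per million in **every** AM library, where RPM is
   normalized on the library's total fungus-mapped reads (`min_rpm`,
   strictly greater than),
3. zero raw reads in every mock library (`max_mock_count = 0`; the
   threshold is configurable because "absence" in sequencing data is
   depth-dependent),
4. fungus-exclusive origin.

The boundary semantics matter and are tested: exactly 25.0 RPM fails, one
mock read disqualifies. Near-identical sequences (single-nucleotide
variants) are deliberately kept as distinct candidates. Per-sample
fungus-derived percentages are reported against the post-preprocessing
read total, which is the package's reading of the corresponding per-sample
percentage range; the denominator is a config choice because raw versus
clipped totals differ by the junk-read fraction.

Size/5'-nucleotide profiles are RPM matrices over lengths 15–34 and 5'
A/C/G/U, normalized within the profiled subset (host-mapped or
fungus-mapped), so each profile sums to 1e6 RPM — an identity the tests
assert to 1e-6 relative tolerance. Feature-class assignment of
fungus-mapped reads uses the priority order rRNA > tRNA > snRNA > snoRNA >
repeat > mRNA > intergenic with one shared base counting as overlap,
ignoring strand.

## Target prediction

Plant AGO1 slicing requires extensive complementarity. The scorer follows
the plant-miRNA target-prediction convention: the sRNA (5'→3') is aligned
antiparallel to a site given in transcript sense orientation; per sRNA
position a Watson–Crick pair costs 0, a G:U wobble 0.5, a mismatch 1 and a
gap 2, each **doubled at positions 2–12**. At most one gap is allowed
(either an unpaired sRNA base or a single bulged site base), matching
plant-target practice and keeping the exhaustive enumeration oracle
tractable; ties are broken toward fewer gaps, then the leftmost gap. A
bulged site base between sRNA positions *p* and *p+1* takes the positional
multiplier of *p* (clamped to the sRNA range).

Hits must pass two cutoffs, `score <= 4.5` and `energy_ratio >= 0.7`. The
score boundary is implemented as inclusive (`<=`) and configurable, since
only the cutoff value itself is fixed by convention. The free-energy ratio
is the hybridization energy of the observed duplex divided by that of the
perfect-complement duplex of the same sRNA, clamped to [0, 1]. Energies
come from an embedded nearest-neighbour RNA/RNA Watson–Crick stack table
(Turner-style 37 °C values, symmetric under reverse complement); stacks
containing a G:U pair contribute a fixed weak term (−0.5 kcal/mol), and
mismatches, gaps and bulges interrupt stacking. The duplex initiation term
defaults to 0: the ratio compares two duplexes of the same sRNA, so a
common additive offset cancels in intent, and omitting it keeps every
partially paired duplex non-positive. Because the published analysis used
an external hybridization engine whose parameterisation is not restated,
absolute energies here are a documented package convention; the *ratio*
and the score cutoffs carry the biological contract, and all acceptance
checks are formulated on planted synthetic truth rather than on absolute
energies.

Every transcript window within ±1 nt of the sRNA length is scanned with a
vectorised implementation of the same enumeration (tested for exact
agreement with `align_duplex`), overlapping windows are clustered and only
the best hit (lowest score, then highest ratio) per cluster is reported.

**Cleavability.** AGO-mediated slicing occurs between the target bases
opposite sRNA positions 10 and 11; a G:U wobble there blocks cleavage even
though the duplex still passes the prediction cutoffs. `call_cleavage()`
therefore requires Watson–Crick pairs at positions 10 and 11 (configurable
to 9–11) and no bulge between them.

**STTM design.** A short tandem target mimic sequesters an sRNA by binding
without being sliced: each mimic is the reverse complement of its sRNA
with a 3-nt "CTA" bulge inserted between the bases opposite positions 10
and 11; mimics are joined by the canonical 48-nt spacer of the STTM
literature. The quadruple construct mirrors the validation design of the
study system (four sRNAs sequestered simultaneously). Each mimic is
validated by the package's own calls: non-cleavable, yet binding-competent.
`scramble_site()` produces the composition-matched negative controls:
seeded uniform permutations, redrawn (bounded retries) until the permuted
site no longer passes the score cutoff against its cognate sRNA —
mononucleotide runs therefore fail loudly rather than silently.

## Downstream quantification

`trouvelot_indices()` computes the standard root-length colonization
indices from per-fragment ordinal scores with the conventional weights
(intensity classes 0,1,5,30,70,95; arbuscule/vesicle classes 0,10,50,100):
F% (frequency), M%/m% (intensity in the whole system / colonized
fragments), a%/A% (arbuscule abundance) and v%/V% (vesicles). The indices
are invariant under fragment reordering and table duplication, and A% can
never exceed M% — both are asserted as properties. Group statistics
(ANOVA/Tukey) are left to standard R routines on the tidy per-sample
tables the package emits. `ddct_fold_change()` implements plain ΔΔCt
(fold = 2^−ΔΔCt) without efficiency correction; the reference gene is an
explicit input because it is an experimental choice, not a constant.

## What the synthetic data emulates — and what it does not

`sim_config()` defaults *are* the study conditions at desk scale:

* 5 AM + 3 mock libraries of 1e6 reads each (`background_reads_per_library`);
* planted cross-kingdom sRNAs: 12 species (the number surviving all
  filters in the motivating study), 21–24 nt, 5'-U with probability 0.8,
  planted at 30–120 reads per million of library total so every species
  clears the >25 RPM filter with margin; two species are encoded by a
  tandem-repeat family present at exactly four dispersed identical copies
  (the multi-locus case), the rest by single intergenic loci;
* per-AM-library fungus-derived read fraction drawn from 1.0–3.5%, inside
  the per-sample range observed in the study system;
* fungal background reads drawn from annotated loci with a repeat-dominated
  class mix (repeats 45%, mRNA 25%, the remainder across rRNA/tRNA/sn(o)RNA
  and intergenic), so the feature-composition pie is exercised;
* host background: 30 miRNA-like loci (21-nt, 5'-U-biased mature reads)
  plus genome fragments, all perfect host substrings, so host subtraction
  is non-vacuous;
* a minor 17-nt peak in the size distribution (a feature of AGO co-IP
  libraries with no assigned truth label);
* one decoy per candidate filter, each violating exactly its named filter;
* target sites at four graded designs per planted sRNA (perfect,
  sub-cutoff, position-10 wobble, non-target), verified against the
  package's own scorer at build time;
* adapter-ligated 50-nt reads on disk, including ~1% junk raw reads that
  fail preprocessing; sequencing errors default to 0 (perfect-match
  mapping makes errored copies useless by construction; an optional error
  rate exists to test that they never rescue a failed filter).

Three generator choices deserve emphasis because they define what a
passing test does and does not show about real data:

* **Background is library-private.** Each AM library samples its fungal
  background fragments from a disjoint partition of the annotated loci
  (and only one copy of the four-copy repeat family is sampled). On a
  desk-scale genome, unrestricted sampling would make stochastic
  background recur in all five libraries and pass the reproducibility
  filter — something that is vanishingly unlikely on a ~150 Mb genome but
  near-certain on 100 kb. The partition models the biological rationale of
  the "present in all five libraries" filter: genuine AGO-loaded species
  recur across independent experiments, degradation noise does not.
  Consequently the planted-truth recovery result (precision = recall = 1)
  certifies the filter logic, not the false-positive rate expected on a
  real genome.
* **The abundance decoy is absent from one AM library** rather than
  present below 25 RPM everywhere: at realistic fungus-mapped totals
  (~1–3.5% of 1e6 reads) a single read already exceeds 25 RPM on the
  fungal denominator, so a "present but sub-threshold in all five"
  species is not representable with integer counts.
* **Repeat annotations are intervals, not sequence structure.** Only the
  four-copy family has genuinely repeated sequence; transposon and
  inverted/tandem repeat features annotate otherwise random sequence.
  Multi-mapping behaviour is exercised through the four-copy family.

Determinism: the same seed yields byte-identical FASTA/GFF3/FASTQ/manifest
output; seeds for the genome, transcriptome and library stages are derived
as `seed`, `seed + 1`, `seed + 2`.

## Numerical and statistical choices

* Internal coordinates are 0-based half-open; GFF3 and all reports are
  1-based inclusive; the conversion is an involution and is tested.
* RNA input (U) is folded to DNA (T) internally; candidate tables print
  sRNA sequences in the RNA alphabet.
* The 5'-U acceptance check uses the read-weighted U fraction of
  fungus-mapped reads against a 3-standard-deviation band that combines
  per-read binomial variance of background reads with the species-level
  variance of the planted/decoy species (whose 5' nucleotide is drawn once
  at genome-build time). The fraction over *unique* sequences is a biased
  estimator on small genomes, because 5'-U fragments draw from a ~4x
  smaller start-position pool and therefore collide more often.
* Scores are compared with a 1e-9 slack where floating-point sums are
  involved; alignment tie-breaks are deterministic (fewest gaps, leftmost
  gap), as is hit ordering (score, then ratio, then coordinates).
* Problem sizes in the test suite: unit tests run on 60–100 kb genomes
  and 10–20 k read libraries; the acceptance suite runs the full default
  configuration (1e6 reads per library) across 20 seeds for the recovery
  check, 500 random queries for the mapping oracle and 200 random pairs
  for the alignment oracle.

## Known limitations

* Mismatch-tolerant alignment is out of scope by design; reads from
  polymorphic or erroneous positions are simply unassigned.
* Translational-inhibition targets are not predicted; cleavability is a
  pairing rule at positions 10–11, not a thermodynamic model of slicing.
* Absolute duplex energies follow the embedded convention described above
  and should not be compared with other engines' absolute values.
* The generator does not model quality scores, PCR duplicates or
  chromosome-scale genome organisation.
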