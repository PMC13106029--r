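# ckRNAi

Discovery and target analysis of cross-kingdom small RNAs in arbuscular
mycorrhizal symbiosis.

Arbuscular mycorrhizal fungi deliver small RNAs (sRNAs) into the root cells
of their host plant; these load into the host's Argonaute 1 and silence
host mRNAs (cross-kingdom RNA interference). Starting from AGO1
co-immunoprecipitation sRNA libraries of mock and fungus-colonized roots,
`ckRNAi` finds the fungal sRNA species hidden in the host background,
predicts their host transcript targets, calls whether each target can be
sliced, designs the sequestration reagents used to validate them, and
computes the downstream quantitative readouts.

## What the pipeline does

1. **Preprocess** — 3' adapter clipping (exact 8-nt seed, inserts 15–34 nt)
   and collapsing to unique sequences with counts.
2. **Subtractive classification** — perfect full-length matching of every
   unique read against the host and fungal genomes, on both strands, with
   all loci of multi-mapping reads retained. Reads that match the host
   anywhere are host; reads matching only the fungus are fungal; reads
   matching both are ambiguous and excluded from candidacy.
3. **Profiling** — size (15–34 nt) by 5'-nucleotide RPM matrices per mapped
   subset, the fungal subset normalized on total fungus-mapped reads per
   million, plus the feature-class composition of fungal reads (priority
   rRNA > tRNA > snRNA > snoRNA > repeat > mRNA > intergenic).
4. **Candidate selection** — fungus-exclusive sequences of 21–24 nt with
   more than 25 RPM (fungal denominator) in *every* colonized library and
   zero reads in every mock library.
5. **Target prediction** — plant-miRNA-style duplex scoring (mismatch 1,
   G:U wobble 0.5, gap 2, doubled at sRNA positions 2–12, at most one gap)
   with cutoffs score ≤ 4.5 and hybridization free-energy ratio ≥ 0.7
   against the perfect-complement duplex; cleavability requires
   Watson–Crick pairing at sRNA positions 10–11 (a wobble there blocks
   slicing).
6. **Validation design** — short tandem target mimics (reverse complement
   of the sRNA with a CTA bulge between positions 10/11, joined by 48-nt
   spacers) and composition-preserving scrambled control sites.
7. **Quantification** — Trouvelot root-length colonization indices (F%,
   M%, m%, a%, A%, v%, V%) and ΔΔCt qPCR fold changes.

A first-class synthetic-data module (`sim_config()`, `simulate_dataset()`)
generates toy host/fungus genomes, annotations, transcriptomes with planted
target sites, and mock/AM read libraries with a machine-readable
ground-truth manifest, so the whole pipeline is testable end to end with
planted truth — including one decoy per candidate filter, each violating
exactly that filter.

## Worked example

```r
library(ckRNAi)

cfg <- sim_config(seed = 42, background_reads_per_library = 50000,
                  n_unique_host_fragments = 800)
sim <- simulate_dataset(cfg, "demo")            # writes FASTA/GFF3/FASTQ/manifest

report <- run_pipeline(run_config(
  host_genome = sim$paths$host_genome, fungus_genome = sim$paths$fungus_genome,
  host_gff = sim$paths$host_gff, fungus_gff = sim$paths$fungus_gff,
  sample_sheet = sim$paths$sample_sheet, cds = sim$paths$cds,
  adapter = cfg$adapter, out_dir = "demo/run", seed = 42))

report$samples[, c("sample_id", "condition", "total_after_preprocess",
                   "fungal", "fungal_pct")]
#>   sample_id condition total_after_preprocess fungal fungal_pct
#> 1     mock1      mock                  50000      1      0.002
#> 2     mock2      mock                  50000      0      0.000
#> 3     mock3      mock                  50000      0      0.000
#> 4       AM1        AM                  50000   1283      2.566
#> 5       AM2        AM                  50000    799      1.598
#> ...
```

Only a small percentage of reads in colonized libraries is fungus-derived
(the single mock fungal read is a planted decoy that the mock filter then
rejects). The selected candidates are exactly the planted cross-kingdom
sRNAs, reported in the RNA alphabet with their loci and feature classes:

```r
head(report$candidates, 4)
#>                 sequence length n_fungal_loci feature_class min_am_rpm
#> 1 UCAUAUAGUUCCUCCUAUUGUU     22             1    intergenic   2503.129
#> 2  UACUGUACAGCCUAGGAAGAA     21             4        repeat   2392.344
#> 3  UGGUAUAUAGGCUGCAGGAUU     21             4        repeat   2338.270
#> 4  UUGUCUAUGUGUGGAUUCUCU     21             1    intergenic   1794.258
```

`min_am_rpm` is the lowest per-library abundance (reads per million of
fungus-mapped reads) across the five colonized libraries — all far above
the >25 filter. Two candidates are encoded by a repeat family at four
genomic loci; the others by single intergenic loci. Their predicted host
targets, with cleavage calls:

```r
head(read.delim("demo/run/target_hits.tsv"), 4)[
  , c("srna_id", "transcript_id", "site_start", "score", "energy_ratio", "cleavable")]
#>   srna_id transcript_id site_start score energy_ratio cleavable
#> 1  cand01        TX0025        464     0            1      TRUE
#> 2  cand02        TX0001        177     0            1      TRUE
#> 3  cand03        TX0005         78     0            1      TRUE
#> 4  cand04        TX0037        397     0            1      TRUE
```

Score 0 with ratio 1 is a perfectly complementary site; sites with a G:U
wobble opposite sRNA position 10 still pass both cutoffs but are called
non-cleavable. Individual duplexes can be inspected directly:

```r
align_duplex("UCAUAUAGUUCCUCCUAUUGUU", "AACAAUAGGAGGAACUAUAUGA")
#> sRNA 5'-UCAUAUAGUUCCUCCUAUUGUU-3'
#>        ||||||||||||||||||||||
#> site   AACAAUAGGAGGAACUAUAUGA (sense 5'->3')
```

A quadruple sequestration construct and its controls:

```r
sttm <- design_sttm(setNames(chartr("U", "T", report$candidates$sequence[1:4]),
                             paste0("cand", 1:4)))
sttm
#> STTM construct: 4 mimic site(s), 48-nt spacer, 242 nt total
#>   all non-cleavable: TRUE; all binding-competent: TRUE
```

Downstream readouts:

```r
trouvelot_indices(data.frame(intensity = 5, arbuscule = "A3", vesicle = "V0"))
#> Trouvelot indices (n = 1 fragments):
#>   F% = 100.0  M% = 95.00  m% = 95.00
#>   a% = 100.00  A% = 95.00  v% = 0.00  V% = 0.00
```

A command-line front end wrapping the same functions is installed as
`exec/ckrna` (`ckrna simulate|run|targets|design-sttm|trouvelot|ddct`).

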