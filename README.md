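# rdnaunit

Recovery, annotation and repeat analysis of ribosomal DNA repeat units.

## What this is for

The 18S–5.8S–28S ribosomal RNA gene cluster is tandemly repeated at
nucleolar organizer regions. One repeat unit is the transcribed block
(5'-ETS, 18S, ITS1, 5.8S, ITS2, 28S, 3'-ETS) plus the intergenic spacer
(IGS) carrying the RNA polymerase I promoter, the transcription terminator
and dense internal repeats. Avian rDNA units are so GC-rich (spacers above
70% GC) that they are chronically missing from genome assemblies; the
workflow that works is targeted — fish rDNA-bearing long reads out of a
whole-genome pool with a conserved query, polish gene regions with
accurate short reads, transfer boundaries from an annotated reference
unit, call the transcription start site (TSS) from RNA-seq coverage, and
characterise the spacers' repeat and composition landscape.

`rdnaunit` implements that workflow for R users working on rDNA locus
reconstruction:

* **Read recovery** — `kmer_fish()` classifies reads by canonical k-mer
  containment against a conserved query; `polish_consensus()` applies
  strict-majority pileup correction.
* **Annotation** — `transfer_boundaries()` lifts the eight canonical
  region boundaries from a reference unit via 40-bp anchor alignments;
  `find_tss()` calls the coverage onset (plateau = median of the top
  decile; TSS = first position sustaining ≥ 10% of plateau for 50 bases);
  `find_terminator()` finds the poly-T + inverted-repeat terminator;
  `locate_promoter()` scans for the 19-nt Pol I promoter motif by Hamming
  distance.
* **Composition & repeats** — `gc_content()`, `cpg_islands()` (stretches
  > 200 bp, GC > 50%, CpG observed/expected
  `oe = N_CpG * L / (N_C * N_G)` > 0.6), `find_microsatellites()`
  (maximal perfect tandem runs of primitive 2–6 bp units, all phases),
  `count_motif_and_complement()`, `find_pur_pyr_tracts()` (bendable
  H-DNA-prone tracts), `find_g4_motifs()` (four G-runs, loops 1–7).
* **Comparison** — `pairwise_identity()` (global alignment +1/−1/−2;
  identity = matches / alignment columns), `promoter_distance()`,
  `build_report()` for a two-unit region/gene/promoter/CpG summary.
* **Synthetic truth** — `coturnix_preset()` + `generate_unit()` build a
  deterministic 21166-bp unit with planted repeats, promoter, terminator,
  plus `generate_reads()` (tandem-context long reads) and
  `generate_coverage()` (TSS onset, attenuation at the 28S border).

Every coordinate in the package is 0-based half-open; GFF3 output is
1-based inclusive. FASTA, GFF3 and WIG/bedGraph I/O are included, and
`exec/rdnaunit` exposes the pipeline as a shell tool
(`simulate`, `fish`, `polish`, `annotate`, `features`, `compare`,
`convert`).

## Worked example

```r
library(rdnaunit)

truth <- generate_unit(coturnix_preset(seed = 1))
truth
#> <planted_truth> synthetic_unit_seed1: 21166 bp, 24 features (seed 1)

cov <- generate_coverage(truth, depth = 100, noise_sd = 10, seed = 2)
feats <- annotate_unit(truth$unit, truth$unit,
                       truth$features[truth$features$type %in% region_order(), ],
                       track = cov, promoter_motif = PROMOTER_MOTIF)
feats[feats$type %in% c(region_order(), "TSS", "TERMINATOR", "PROMOTER"),
      c("type", "start", "end")]
#>        type start   end
#>        ETS5     0  1779
#>        R18S  1779  3602
#>        ITS1  3602  5649
#>       R5_8S  5649  5806
#>        ITS2  5806  6464
#>        R28S  6464 10649
#>        ETS3 10649 11288
#>         IGS 11288 21166
#>         TSS     0     1
#>  TERMINATOR 11259 11288
#>    PROMOTER 21147 21166
```

The eight canonical regions tile the unit exactly as planted; the TSS is
called at the coverage onset (position 0), the terminator's poly-T +
inverted repeat is found at the 3' end of the 3'-ETS, and the promoter
motif sits in the last 19 bases of the IGS — immediately 5' of the next
repeat's start in the tandem array.

```r
s <- truth$unit$seq
gc_content(substr(s, 3603, 5649))      # ITS1
#> [1] 76.3
head(find_microsatellites(s, max_unit = 10), 4)
#>      kind motif copies start end
#>  MICROSAT    GA      3    31  37
#>  MICROSAT    AG      3    32  38
#>  MICROSAT    CG      3   427 433
#>  MICROSAT    GC      3   456 462
cpg_island_coverage(cpg_islands(s), nchar(s))
#> [1] 100
pairwise_identity("ACGT", "ACGA")
#> [1] 75
```

ITS1 GC lands on its 0.768 target; the repeat scan reports every maximal
perfect tandem run (background di-nucleotide runs included — the planted
repeats are among them at their exact planted coordinates); a uniformly
GC-rich unit is wall-to-wall CpG island under the
Gardiner-Garden/Frommer criterion, hence 100% coverage.

## The methods vignette

`vignettes/rdna-unit-annotation.Rmd` documents the model behind each
stage, every tunable threshold with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
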