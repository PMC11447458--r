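---
title: "Annotating an rDNA repeat unit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating an rDNA repeat unit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaunit)
```

## The problem

The ribosomal RNA gene cluster (18S, 5.8S, 28S) is tandemly repeated at
nucleolar organizer regions. One repeat unit consists of a transcribed block
— 5'-ETS, 18S, ITS1, 5.8S, ITS2, 28S, 3'-ETS — followed by a long,
non-transcribed intergenic spacer (IGS) that carries the RNA polymerase I
promoter, the transcription terminator, and a dense load of internal
repeats. In birds these units are extremely GC-rich (spacers above 70% GC),
which makes them nearly invisible to standard short-read assembly: rDNA is
systematically under-represented and fragmented in avian genome assemblies.
The practical workflow that succeeds is targeted: *fish* the rare
rDNA-bearing long reads out of a whole-genome pool with a conserved query,
assemble or pick a unit-spanning read, *polish* the gene regions with
accurate short reads, then *annotate* the unit — transfer gene and spacer
boundaries from the one fully annotated reference unit available (chicken),
call the transcription start site (TSS) from RNA-seq coverage, and locate
the promoter and terminator. The spacers are then characterised by their
composition: GC content, CpG islands, microsatellites, dispersed
motif/complement repeats, polypurine/polypyrimidine "bendable" tracts and
G-quadruplex motifs.

`rdnaunit` implements that workflow as composable, deterministic functions,
with a synthetic-data generator that plants known truth so that every stage
is testable offline.

## Coordinates and containers

All internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive and the conversion is exercised by round-trip tests against an
independent GFF3 parser. Sequences are plain uppercase `A,C,G,T,N` strings
in `seq_record` objects; `N` is accepted in reads but rejected by the
composition statistics (GC, islands, tracts), where any imputation would
silently bias the result. Units are stored promoter-to-terminator on the
sense strand; no minus-strand features exist in this locus model.

## The synthetic generator and what it does (not) emulate

`unit_spec()`/`generate_unit()` build a unit from per-region backgrounds at
fixed GC targets, then overwrite planted features at recorded offsets. The
defaults of `coturnix_preset()` are the study conditions for a galliform
unit: region lengths 1779 / 1823 / 2047 / 157 / 658 / 4185 / 639 / 9878 bp
(21166 bp in total), spacer GC targets 0.741 (5'-ETS), 0.768 (ITS1), 0.780
(ITS2), 0.721 (3'-ETS), 0.663 (IGS) and 0.55 for the three genes; a 19-nt
Pol I promoter motif (`TTGCTCCGCAGGAGCGAGC`); a terminator of a 7-base
T-run plus an 8-bp inverted repeat with a 6-bp spacer at the 3' end of the
3'-ETS; and planted microsatellites, a dispersed CGG block, bendable
tracts and a `(GAGGGG)`-type G4 motif of the repeat classes reported for
galliform spacers.

Design choices worth knowing:

* **Background composition.** Backgrounds use exact-composition sampling: a
  region of length $n$ at GC target $g$ contains exactly
  $\mathrm{round}(ng)$ G/C bases, randomly permuted. A per-base i.i.d. draw
  has binomial sd $\sqrt{g(1-g)/n}\approx 0.9\%$ at 2 kb, which would
  violate the generator's own guarantee that realised region GC stays
  within 0.02 of target; exact composition keeps the guarantee while the
  sequence remains exchangeable, so the CpG observed/expected ratio is ~1
  and island behaviour is controlled by planted islands.
* **Re-detectability.** Plants are flanked by guard bases chosen to break
  run or phase extension into the background (a microsatellite cannot
  accidentally gain a copy, a tract cannot extend), and accidental T-runs
  of 5+ upstream of the planted terminator within its search window are
  broken. This is what makes "every planted feature is recovered at exact
  coordinates" a property of the generator, not luck.
* **Tandem context.** Reads are sampled from a two-copy head-to-tail
  concatenation of the unit, because the locus is tandemly repeated and
  junction-spanning reads are precisely what makes IGS reconstruction
  possible. Lengths are log-normal (sd(log) = 0.5) clipped to
  [200, unit length]; strands are sampled equally; errors are i.i.d.
  substitutions only. No homopolymer or signal-level error model is
  attempted: the generator emulates the *selection* problem (is this read
  from the locus?) and the *consensus* problem (majority vote), not
  nanopore chemistry, so passing tests say nothing about indel-dominated
  error profiles.
* **Coverage.** The RNA-seq track is `depth` from the TSS to the 28S 3'
  end, a linear attenuation ramp across the 3'-ETS (transcription
  attenuates at the 28S border; the 3'-ETS end is where the terminator
  sits), and 0 over the IGS, with truncated Gaussian noise floored at 0.
  The real signal is burstier; the model is the minimal one with a
  detectable onset and attenuation.
* **CpG islands.** A GC-rich exchangeable background is itself one giant
  CpG island under the Gardiner-Garden/Frommer criterion, as real
  galliform rDNA largely is — so island detection in *both* directions is
  tested on dedicated constructed sequences (AT-rich backgrounds with
  planted CG-rich stretches), not on the preset unit. A `CPG_ISLAND` plant
  boosts CpG dinucleotide frequency to 1.5x the i.i.d. expectation.

## Method formalisations

**Read fishing** (`kmer_fish`). Similarity-search selection is replaced by
a deterministic containment statistic: the fraction of a read's distinct
canonical k-mers (k = 15) present in the query's set. The default
threshold 0.10 leaves ample margin for long-read error: at 5% substitution
a 15-mer survives with probability $0.95^{15}\approx0.46$, so true reads
score ~0.46 and random 1 kb reads score below 0.01 (collision probability
per k-mer is about $|Q|/4^{15}$). Canonicalisation over the reverse
complement makes strand irrelevant.

**Polishing** (`polish_consensus`). Short-read correction is a pileup
majority vote on substitution-aligned placements: a position is edited only
when covered by at least `min_depth` (3) read bases and one base holds a
strict majority (more than half the votes). Ties and pluralities keep the
draft base — corrections are deliberately conservative, and the operation
is idempotent. Indels are out of scope by construction (placements are
gap-free), which keeps the expected behaviour exactly checkable.

**Boundary transfer** (`transfer_boundaries`). Each of the seven internal
region boundaries of the reference is represented by a 40-bp anchor
centred on the boundary; anchors are locally aligned (match +1, mismatch
-1, gap -2) to the target and the boundary maps to the target position
aligned with the anchor centre. 40 bp is long enough to be unique in a
~21 kb unit and short enough to stay within the conserved gene ends that
flank each boundary. An anchor matching fewer than 60% of its bases is
declared `UNMAPPED` — the floor stops anchors from being dragged into the
divergent spacer — and its coordinate is interpolated between the nearest
mapped boundaries at the reference's relative spacing, with the status
recorded in the attributes of both adjacent regions.

**TSS calling** (`find_tss`). Reading a coverage onset off a browser track
is formalised as: plateau = median of the top decile of per-base depths;
TSS = first position where depth holds at or above `frac` (0.1) of the
plateau for `sustain` (50) consecutive bases. Both knobs are exposed; the
sustain requirement rejects isolated noise blips.

**Terminator** (`find_terminator`). The pattern is a poly-T run (>= 5)
followed within 30 bases by an inverted repeat: a 6-bp arm whose reverse
complement recurs within 20 bases downstream, searched in an 800-bp window
past the 28S 3' end. The published descriptions give the pattern but not
the lengths; these defaults are configurable and every hit records the
parameters and arm in its attributes. The 5'-most qualifying site wins,
and the search uses the minimal qualifying arm with the earliest second
arm, so results are deterministic.

**Promoter** (`locate_promoter`). A Hamming scan of the motif over a
window (sense strand only), results ordered by mismatches then position.
In the tandem context the Pol I promoter lies immediately 5' of the next
unit's TSS, i.e. at the 3' end of the IGS of the recorded unit — which is
where the generator plants it and where `annotate_unit()` searches.

**CpG islands** (`cpg_islands`). The criterion — length > 200 bp,
GC > 50%, observed/expected CpG ratio > 0.6 with
$\mathrm{oe} = N_{CpG} \cdot L / (N_C \cdot N_G)$ — defines a property of
stretches, not a search algorithm. The search returns maximal qualifying
stretches greedily (longest first, leftmost on ties, non-overlapping):
exactly, by an $O(n^2)$ prefix-sum scan, for sequences up to 6 kb; longer
sequences are first reduced to candidate neighbourhoods by a step-1 scan
of 200-bp qualifying windows (expanded by 400 bp and merged), inside which
the exact search runs, with a fast path for intervals that qualify whole
and a midpoint split above 6 kb. The exact path is validated against a
brute-force all-substrings oracle on a mixed corpus up to 2 kb.

**Microsatellites** (`find_microsatellites`). Maximal perfect tandem runs
of a primitive 2-6 bp unit with >= 3 copies, found by lag-u equality runs.
When phases of one run each reach whole copies (`ACCCG` / `CCCGA` /
`CCGAC`), every phase is reported — matching how spacer catalogues list
such repeats. Homopolymers are excluded (the poly-T logic of the
terminator handles those). A single-IUPAC-position degenerate search
(e.g. `(CAGM)5`) is available behind `degenerate = TRUE`, default off;
repeats with a 10-bp unit such as `(GACCTGACCC)3` are reachable through
`max_unit`.

**Dispersed repeats** (`count_motif_and_complement`). Catalogues of
dispersed spacer repeats pair each motif with its base-by-base complement
— CGG with GCC, GCGA with CGCT — not its reverse complement; the function
follows that convention and counts overlapping occurrences by default.
Published per-motif counts do not state their counting convention, so they
are treated as qualitative validation, not targets.

**Identity** (`pairwise_identity`). Global alignment with match +1,
mismatch -1, linear gap -2; identity = matches / alignment columns, the
only definition under which identity(a, a) = 100 and indels penalise both
sequences symmetrically. Among co-optimal alignments the one maximising
matched columns is used — both objectives are additive, so a single DP
over a combined value is exact — making the reported value well defined
rather than an artefact of traceback order. The optimal score is
cross-checked against `Biostrings::pairwiseAlignment` in tests, and the
identity against an independent brute-force DP oracle.

## Degenerate inputs and numerical conventions

Empty sequences, all-zero coverage, windows shorter than the motif,
placements off the draft, overlapping islands and missing canonical
regions are all hard errors naming the offending quantity; nothing is
silently skipped. Reads shorter than k are the one exception — they are
skipped with a warning, since discarding undersized reads is the intended
behaviour mid-pipeline. Percentages are reported to 0.1 throughout
(matching the precision such values are conventionally printed at), which
means a concatenation's GC and the length-weighted mean of rounded
per-region values may differ by up to ~0.1.

## Problem sizes used in tests

The test suite and the reproduction script run entirely on synthetic data:
one 21166-bp unit per scenario, 2000 reads (200 rDNA at 5% substitutions
against 1800 random) for classification, a 10x tiling pileup over the
1823-bp 18S for polishing, and oracle corpora of 200 sequences per
operation (up to 2 kb for islands, 500 bp for microsatellites, 200 bp for
alignment). These sizes keep a full run in the low minutes while leaving
every statistic far from its decision boundary.

## Known limitations

* Substitution-only error and polishing models; no indels, no assembly.
* The terminator and promoter searches are pattern-based, not
  thermodynamic or PWM-based; G4 detection is the standard four-G-run
  regex, not a stability score.
* Boundary transfer assumes collinearity between target and reference
  units; a structural rearrangement would surface as an ordering error,
  not be resolved.
* "CpG island retention" is interpreted as the percentage of unit length
  covered by islands (`cpg_island_coverage`); on uniformly GC-rich
  synthetic units that figure is near 100 by construction.
* The repeat-content percentages sometimes quoted for spacers (e.g. 28.4%
  for a 5'-ETS) do not correspond to any single counting convention we
  could reproduce from printed per-motif counts; the tools report counts
  under their documented conventions instead.
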