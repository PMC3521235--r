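---
title: "Methods: homology-based plant miRNA discovery and target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based plant miRNA discovery and target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmir)
```

## Overview

plantmir implements two connected pipelines for plant small-RNA analysis.
The **miRNA identification pipeline** takes a collection of nucleotide
sequences (cDNA, EST or GSS assemblies), finds sequences carrying
near-exact copies of known mature miRNAs, folds those sequences, excises
the stem-loop precursor around each homolog, and validates the excised
hairpin against the structural criteria of plant miRNA biogenesis. The
**target identification pipeline** scans transcripts for sites
complementary to mature miRNAs under a weighted binding score and refines
the hits by miRNA:site duplex hybridization. Both pipelines are
deterministic given their configuration.

The approach is homology-based: it can only recover members of families
already represented in the mature-miRNA reference. This is the standard
trade-off for EST/GSS surveys of species without deep small-RNA
sequencing, where expression evidence is unavailable but family
conservation is strong.

## Sequence validation

Input FASTA records are upper-cased and checked against the alphabet
A/C/G/T/U/N. Records longer than the pipeline cap (3,000 nt for miRNA
identification, 20,000 nt for targets), records with other characters,
empty records and duplicated identifiers (first kept) are excluded, and
every exclusion is reported with a reason rather than raised as an
error. U and T are treated as equivalent in every comparison downstream,
because cDNA inputs (T) are routinely scanned with miRBase queries (U);
records keep their original letters. N is tolerated by validation but
never matches anything in a scan, so it behaves as a guaranteed
mismatch.

## Homolog search

The scan reports every ungapped window of an input sequence whose
Hamming distance to a mature miRNA is at most `max_mismatch` (default
4, the conventional cap for miRNA homology surveys). Two implementations
share one contract:

* `scan_exhaustive()` — per-offset counting, complete by construction;
* `scan_seeded()` — pigeonhole acceleration: the query is split into
  `max_mismatch + 1` contiguous seeds, and any window within budget must
  contain at least one exact seed, so verifying seed-anchored offsets is
  lossless.

The seeded scan is proven equal to the exhaustive scan property-wise in
the test suite (and both against a naive character-level oracle). We
deliberately do not use a word-seeded heuristic search here: heuristic
seeding with a fixed word size can miss matches whose mismatches are
spread across every word, whereas the pigeonhole split cannot. A
consequence is that no E-value is computed — the mismatch count is the
sole criterion. The default is plus-strand-only scanning, matching how
such surveys are usually run on oriented cDNA; `strands = "both"` maps
reverse-strand hits back to forward coordinates.

## Secondary structure

Structure prediction sits behind one contract with two engines.

* `engine = "thermo"` calls ViennaRNA (`RNAfold` for single sequences,
  `RNAduplex` for hybridization) and reports thermodynamic free energies
  in kcal/mol at the configured temperature (default 37 °C, also used
  for duplexes; exposed in `fold_params()`).
* `engine = "builtin"` (the default) is a deterministic Nussinov
  base-pair maximization with minimum hairpin loop 3 and pairs
  AU/GC/GU. Its energy is a proxy: −1 per pair for folding, and
  GC −3 / AU −2 / GU −1 summed over the best ungapped antiparallel
  offset for duplexes (ties to the smaller absolute offset). Traceback
  ties prefer leaving a base unpaired, then the smallest partner index,
  so identical input always yields identical structure text.

The proxies exist so the entire pipeline, its tests and its fixtures run
with no external software, and they are never compared against kcal/mol
thresholds from the literature. MFEI filtering (below) is
scale-dependent; the default threshold is calibrated for hairpin-quality
screening and behaves sensibly under both engines because MFEI
normalizes by length and GC content. Suboptimal ensembles, partition
functions and pseudoknots are out of scope.

## Precursor excision and validation

For each homolog hit the source sequence is folded, and Auto-mode
cleavage runs from the start of the mature hit to the end of its miRNA*
partner, read off the pair table: the star spans the partners of the
outermost paired mature positions, extended by two nucleotides at its 3'
end — the signature overhang of Dicer-processed duplexes — and clamped
at the sequence ends. The same partner-span rule is applied for mature
sequences on either arm. Manual mode accepts explicit cleavage
positions. The excised precursor is then refolded and all validation
statistics are computed on the second-pass structure; the first-pass
structure is used only for excision. Note the star end is anchored at
the partner of the mature 5' end plus two; the mature strand itself is
taken exactly as found by the homolog scan.

Validation statistics per candidate:

* **GC%, AMFE, MFEI** — AMFE is MFE normalized per 100 nt; MFEI is
  AMFE divided by GC percentage. Candidates with zero GC are rejected
  outright (MFEI undefined).
* **multi-loop** — a precursor whose structure holds more than one
  terminal loop is rejected, always.
* **one-arm rule** — every position of the mature span must sit outside
  the terminal loop with all its partners across the loop; violating
  candidates are rejected, always.
* **duplex statistics** — walking the mature span: opposed unpaired
  positions flanked by pairs count as duplex mismatches; unpaired runs
  on one strand only are bulges (count and maximum size recorded). Where
  an interior loop is asymmetric (r vs g unpaired), `min(r, g)` counts
  as mismatches and the excess as one bulge of size `|r − g|`; unpaired
  runs at the span ends belong to overhangs and are not counted. G:U is
  a pair here, not a mismatch — the structural convention — while target
  scoring below half-penalizes G:U; the two conventions are deliberately
  different.
* **2-nt 3' overhangs** — a duplex end is counted (0, 1 or 2) only when
  the 3' strand protrudes exactly two nucleotides over a flush opposing
  5' end. Truncated ESTs can destroy an overhang through clamping, so
  the default filter reports overhangs without requiring them.

Default thresholds (`precursor_filters()`): |MFEI| ≥ 0.85, at most 4
duplex mismatches, at most 2 bulges of at most 2 nt. These are the
conventional plant-precursor screening values; every knob is exposed.

## Target scanning

Scanning uses the reverse complement of each miRNA as the query. A
candidate window is classified position by position from the miRNA 5'
end against the antiparallel site: Watson–Crick match, G:U wobble, or
mismatch. The binding score is the weighted sum — mismatch 1.0, G:U
0.5, gap 2.0 — and sites above `max_score` (default 4.0) are dropped.
The mismatch budget handed to the seeded scanner is
`floor(max_score / min positive weight)`, which cannot miss a qualifying
window because every non-Watson-Crick opposition costs at least the
minimum weight. Positional rules are applied by default and can be
disabled: at most one mismatch in positions 1–9, none at positions 10
or 11 (the cleavage-site region), and no three consecutive mismatches;
G:U and gaps do not count as mismatches for these rules. The score
cutoff is checked before the positional rules; the first violated rule
is recorded.

Gapped alignment is limited to one single-nucleotide gap (either
strand) and is attempted only where the ungapped window fails.
Candidates for gapped evaluation are seeded from the two query halves:
with one gap and a total score within `max_score`, one half is gap-free
and within its own mismatch budget, so the pigeonhole argument extends
to gapped sites.

`refine_with_duplex()` annotates each surviving site with the duplex
hybridization energy and the fraction of the scanned span covered by
pairing positions; it never removes sites, because post-refinement
filtering is a user decision.

## Pipelines, reports, hooks

Each pipeline writes per-step artifacts (TSV tables, FASTA, Vienna
structure files, JSON reports) into its output directory and returns
chained step reports (`n_in == n_out + n_excluded`, consecutive steps
connect). External database screening (protein-coding and non-miRNA
ncRNA removal) is a hook: a function from records to per-sequence
verdicts that a user can back with any search tool; with no hook
configured the pipelines simply omit those removal steps.
`parallel_map()` distributes pure per-sequence steps over forked workers
and restores input order, so any thread count produces byte-identical
outputs. Accepted precursors from a miRNA-pipeline run can be passed
directly as the miRNA source of a target run; their mature sequences are
reused as queries, equivalent to supplying them via FASTA.

## Synthetic fixtures

The generators in `make_hairpin()`, `make_decoy()` and
`make_target_transcript()` provide planted ground truth so every stage
is testable offline; each is a pure function of its seed and spec.

A planted hairpin is `flank5 + mature + loop + star + flank3` (arms
swapped for 3p), with the star arm the reverse complement of the mature
sequence carrying engineered symmetric mismatches or bulges. Three
composition choices make the designed stem the unique base-pair-maximal
structure, so the recorded truth is exact rather than approximate: the
loop is all-C and the flanks poly-A (neither can pair internally or with
each other), the three stem bases flanking the loop avoid the letters
that could pair into the loop, and the three outer stem bases avoid the
letters that could pair into the flanks. Auto-sampled mature sequences
are AU-rich (5–7 GC in 21 nt), reflecting the base composition typical
of plant mature miRNAs and keeping planted precursors clear of the MFEI
gate under the builtin energy proxy; the generator rejection-samples (up
to 50 draws) until the built-in fold reproduces the designed pair map
exactly. What these fixtures do **not** emulate: natural flank
composition, imperfect loops, multi-branch pri-miRNA contexts, genomic
repeats, or sequencing error — so passing fixture tests demonstrates
algorithmic correctness on clean structures, not recall on real ESTs.

Decoys are uniform random sequences or dinucleotide shuffles
(Altschul–Erikson Eulerian-path construction, preserving all 16
dinucleotide counts). The expected homolog-scan false-hit rate on
uniform decoys has the closed form `P(Binom(m, 3/4) ≤ k)` per window,
which the tests check to within three standard deviations.

Planted target sites embed the reverse complement of a miRNA in a
uniform background with controlled mismatch/G:U/gap edits, recording the
implied binding score in advance.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, the miRBase/GFF
  convention; spans are reported on the forward strand.
* Scores and energies are doubles; AMFE and MFEI stored on candidates
  agree with recomputation from (MFE, length, GC) to 1e-9 relative
  tolerance.
* Degenerate inputs: a mature region that is entirely unpaired cannot
  anchor a star (`no_duplex` rejection); zero-GC precursors are
  rejected (`zero_gc`); validation never raises on content.
* Problem sizes in the shipped tests (100 planted hairpins, 50 planted
  sites, 500 scanner equivalence cases, 200 folding-optimality cases,
  all ≤ 3-mismatch positional patterns of a 21-mer) were chosen so the
  whole suite exercises every contract in well under a minute of
  desk-scale compute while keeping the statistical checks meaningful.
* The external TAIR10/miRBase/Rfam benchmark of the original system
  requires database downloads and screening hooks; the package ships
  the arithmetic and the pipeline, not the databases.

## Worked example

```{r example, eval = FALSE}
hp <- make_hairpin(seed = 42)
mir <- mirna_table("ath-miR9999", chartr("T", "U", hp$truth$mature_seq))
hits <- run_homolog_search(hp$record, mir, max_mismatch = 0)
cands <- hairpin_candidates(hp$record, hits)
filter_precursors(cands)$accepted
```

On this fixture the precursor spans source positions 11–62 (52 nt), the
star arm sits at 40–62 with one exact 2-nt 3' overhang, and the builtin
proxy gives MFEI −0.95 — comfortably past the 0.85 gate.

## Known limitations

Homology-only discovery cannot find novel families; the builtin engine
ranks structures by pair count, not thermodynamics (use the ViennaRNA
engine where installed for energy-faithful results); gapped target
alignment is capped at one gap; E-value statistics and external
database screening are intentionally not modeled; no GUI or project
persistence.
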