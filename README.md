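# plantmir

Homology-based identification of plant miRNA genes and their targets in
nucleotide sequence collections (cDNA/EST/GSS), as a tested R package
with a thin command-line front end.

Plant miRNA surveys in species without deep small-RNA sequencing lean on
two facts: mature miRNAs are strongly conserved within families, and
plant miRNAs bind their targets with near-perfect complementarity.
plantmir turns both into scriptable pipelines:

* **miRNA identification** — validate sequences (≤ 3,000 nt,
  A/C/G/T/U/N), scan them for homologs of known mature miRNAs with a
  lossless mismatch-tolerant seeded search (Hamming distance ≤ 4 by
  default), fold candidate primary transcripts, excise the stem-loop
  precursor from the mature hit to its miRNA* partner with the 2-nt 3'
  overhang, refold, and validate: single terminal loop, mature confined
  to one arm, |MFEI| ≥ 0.85, ≤ 4 miRNA:miRNA* mismatches, ≤ 2 bulges of
  ≤ 2 nt. MFEI = (MFE / length × 100) / GC%, the classical index that
  separates miRNA precursors from other RNAs.
* **target identification** — validate transcripts (≤ 20,000 nt), scan
  with the reverse complement of each miRNA under a weighted binding
  score (mismatch 1, G:U wobble 0.5, gap 2; keep score ≤ 4), apply the
  plant positional rules (≤ 1 mismatch at positions 1–9, none at 10–11,
  no 3 consecutive), and annotate surviving sites with miRNA:site
  duplex hybridization energy and pairing overlap.

Secondary structure comes from a pluggable engine: ViennaRNA
(`RNAfold`/`RNAduplex`) when available, or a built-in deterministic
base-pair-maximization fallback with documented proxy energies, so the
whole package runs and tests with no external software. Seeded fixture
generators plant hairpins and target sites with exact recorded truth,
making every pipeline stage verifiable offline.

## Worked example

```r
library(plantmir)

hp  <- make_hairpin(seed = 42)                 # planted pri-miRNA fixture
mir <- mirna_table("ath-miR9999", chartr("T", "U", hp$truth$mature_seq))
hits  <- run_homolog_search(hp$record, mir, max_mismatch = 0)
cands <- hairpin_candidates(hp$record, hits)
subset(filter_precursors(cands)$accepted,
       select = c(pre_start, pre_end, star_start, star_end,
                  mfei, n_overhang2, duplex_mismatches))
#>   pre_start pre_end star_start star_end       mfei n_overhang2 duplex_mismatches
#> 1        11      62         30       52 -0.9545455           1                 0
```

The 70-nt fixture holds a 21-nt mature miRNA at positions 11–31; the
pipeline excises the precursor from the mature start to the star end
with its 2-nt 3' overhang (source span 11–62, 52 nt), finds the star at
precursor positions 30–52, one exact overhang, a perfect duplex (0
mismatches), and MFEI −0.95 — past the 0.85 acceptance gate.

The same flows are available from a shell:

```sh
Rscript inst/cli/plantmir.R fixtures --outdir fx --n-hairpins 3 --seed 5
Rscript inst/cli/plantmir.R mirna  --input fx/hairpins.fasta \
        --mirnas fx/hairpin_mirnas.fasta --outdir out_mirna
#> sequence_loading   in=3 out=3 excluded=0
#> homolog_search     in=3 out=3 excluded=0
#> primary_folding    in=3 out=3 excluded=0
#> precursor_folding  in=3 out=3 excluded=0
#> accepted 3 precursor(s): 3 family(ies), 3 member(s)
Rscript inst/cli/plantmir.R target --input fx/targets.fasta \
        --mirnas fx/target_mirnas.fasta --outdir out_target
```

Each run writes per-step TSV/FASTA/Vienna artifacts and a JSON report
whose step counts chain (`n_in = n_out + n_excluded`).

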