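# mitoallo

Comparative genomics and transcriptomics of **alloplasmic plant
mitochondrial genomes** — lines that combine the nuclear genome of a crop
with the cytoplasm (and hence the mitochondria) of a wild relative. Such
lines are the classic source of cytoplasmic male sterility (CMS), and the
genomic signals that matter for CMS gene hunting are exactly the ones this
package computes:

* **Repeat landscape** — dispersed repeats by seeded genome
  self-comparison on both strands (direct/inverted orientation, size
  classes large ≥ 1 kb, medium 100–1000 bp, small < 100 bp), and tandem
  repeats by a wraparound dynamic-programming detector (match/mismatch/
  indel weights 2/7/7, minimum alignment score 80).
* **Mitotype-specific sequences (MSS)** — 100-bp windows every 50 bp
  scanned against a reference mitotype panel; a window "aligns" when a
  seeded local alignment reaches ≥ 80 % identity over ≥ 60 % of the
  window, and runs of ≥ 2 consecutive non-aligning windows are merged
  into MSS intervals. MSSs are where wild-donor material — including
  candidate CMS ORFs — resides.
* **Promiscuous sequence** — chloroplast- or transposon-derived segments
  found by whole-genome scanning against an organelle/TE panel (merged
  hits ≥ 40 bp at ≥ 80 % identity), reported as intervals and as percent
  of the genome.
* **C-to-U RNA editing** — chloroplast-derived regions are N-masked, then
  sites are called from per-replicate pileup columns when the variant
  frequency is ≥ 20 % in ≥ 2 independent replicates at depth ≥ 10
  (C→T on the forward strand, G→A on the reverse). Each site is annotated
  with region, codon position, reference/edited codon and amino acid,
  effect (synonymous, nonsynonymous, stop gained, start gained for
  ACG→ATG first codons) and the Kyte–Doolittle hydropathy class of the
  edited residue, and aggregated into a per-genome editing profile.
* **Expression and ORFs** — TPM from per-feature counts
  (`tpm_i = 10^6 · (c_i/l_i) / Σ_j c_j/l_j`), six-frame ORF discovery
  (≥ 300 nt including the stop, starts ATG/GTG/TTG), and expressed-ORF
  flagging from a coverage track (mean ≥ 5× and ≥ 2× the intergenic
  median).
* **Feature accounting** — per genome: length, GC, the coding/intron/
  intergenic partition (which sums to 100 % by construction), and repeat/
  chloroplast/TE coverage rates.
* **Synthetic-data generator** — builds an ancestral mitogenome with gene
  models, derives an alloplasmic genome with planted MSS segments
  (carrying intact CMS-candidate ORF cassettes), chloroplast insertions,
  repeat duplications and SNP background, and simulates replicate pileups
  with editing at known fractions, so every stage has a recovery test
  against exact planted truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, run from
the repository root; each stage reads the files written by the earlier
ones into `results/`:

```sh
Rscript analysis/01_simulate_study.R    # generate the synthetic study
Rscript analysis/02_genome_report.R     # Table-1-style accounting
Rscript analysis/03_repeats.R           # dispersed + tandem repeats
Rscript analysis/04_mss_promiscuous.R   # MSS + chloroplast-derived scan
Rscript analysis/05_editing.R           # C-to-U editing sites + profile
Rscript analysis/06_expression_orfs.R   # TPM + ORF screening
```

With the default seed the run prints:

```
study written to results/study: derived genome 113895 bp, 5 MSS,
  3 cp insertions, 50 editing sites planted
4 dispersed pairs (large 2, medium 2); 2 tandem arrays; planted
  duplications recovered 2/2; repeat coverage 4.95%
182/2277 windows non-aligning; 5 MSS called totalling 9150 bp; planted
  recovered 5/5 (max boundary error 59 bp)
3 chloroplast-derived intervals, 2.26% of the genome; planted recovered 3/3
sensitivity 100% (50/50), false positives 0; codon-position profile 12:24:4
TPM sum 1e+06; max relative error vs truth 2.63%
40 ORFs >= 300 nt; 23 flagged expressed; planted MSS cassettes
  found+expressed 5/5
```

Reading the numbers: all five planted donor segments come back as MSS
calls with boundaries within ~one window step of truth; every planted
editing site is recovered with no false calls, and the called sites
reproduce the planted 3:6:1 codon-position shape (12:24:4 over 40 coding
sites); the CMS-candidate ORF cassettes planted inside MSS segments are
found at exact coordinates and flagged as transcribed.

The same machinery is exposed as ordinary functions
(`find_dispersed_repeats()`, `scan_genome()` + `call_mss()`,
`find_promiscuous()`, `call_sites()` + `annotate_sites()` +
`editing_profile()`, `compute_tpm()`, `find_orfs()`, `run_pipeline()`),
so external FASTA/GFF3/pileup inputs can be analysed directly; see the
vignette for the model and parameter discussion.

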