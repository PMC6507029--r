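---
title: "Methods: comparative analysis of alloplasmic mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of alloplasmic mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and coordinate conventions

`mitoallo` analyses alloplasmic plant mitochondrial genomes: repeat
discovery, mitotype-specific-sequence (MSS) detection, promiscuous
(chloroplast/TE-derived) sequence scanning, C-to-U RNA-editing calling
and profiling, TPM quantification and ORF screening, plus a generator
that builds synthetic studies with exact planted truth.

All in-memory coordinates are 0-based half-open; GFF3 (1-based
inclusive) and BED (0-based half-open) conventions are honored on disk
and converted in exactly one place each. A genome is a plain uppercase
string over `A,C,G,T,N`; `U` and ambiguity codes are rejected at parse
time with the offending position named, because every downstream
operation assumes the four-letter alphabet. Features spanning the
circular origin are not representable: circular genomes are analysed on
the linearized sequence (the ORF finder scans the doubled sequence and
deduplicates modulo length; the repeat seeder appends a k−1 overlap;
origin-crossing repeat copies are truncated at the origin). This loses
at most a window's worth of signal at one locus per genome and keeps
every interval type simple.

# Dispersed repeats

`find_dispersed_repeats()` self-compares the genome with exact 15-mer
seeds between distinct positions, on both strands (inverted copies are
found by comparing against the reverse complement). Seeds sharing a
diagonal within 200 bp are chained and extended **gap-free** with an
x-drop rule (match +1, mismatch −2, stop when the running score falls 20
below its maximum); the final block's identity is recomputed by direct
base comparison. Calls are filtered by explicit thresholds, default
30 bp at 90 % identity, both exposed. Contained pairs collapse to their
maximal representative; pairs are canonical (copy1 has the smaller
start); the self-diagonal is excluded.

Two deliberate choices here. First, explicit length/identity thresholds
replace a BLAST-style e-value cutoff: e-values are scorer-specific and
irreproducible across implementations, whereas 30 bp at 90 % identity is
a stricter filter than e ≤ 1e−5 at mitogenome scale and is directly
testable. Second, the extension is gap-free because the operation's
defining oracle — the exhaustive comparison of all same-length substring
pairs — is itself gap-free, and the generator plants
substitution-diverged copies only. A gapped extension would change calls
only for indel-diverged repeats, which this version does not model.
The boundary case length = 1000 bp is classed **large** ("≥ 1 kb" wins
over "100–1000 bp" where the two size-class labels touch).

The test suite holds the finder to the brute-force oracle on 2-kb
genomes. The oracle enumerates every qualifying same-length substring
pair per diagonal; its qualifying windows form a staircase of
overlapping near-duplicates around each true block, because identity
stays above 90 % while chance matches (25 % rate) accrue in the flanks
for a few tens of bases. The comparison therefore folds oracle windows
into per-diagonal clusters and requires one call per cluster, contained
in the cluster span and covering ≥ 70 % of it. In the genome-versus-
reverse-complement comparison both copies of an inverted pair fall on
the *same* diagonal (two segments), which the tests account for.

# Tandem repeats

`find_tandem_repeats()` proposes candidate periods from recurring 5-mer
spacings (a 5-mer recurring at spacing p suggests period p ≤ 500),
derives a majority-rule consensus per phase, and scores each candidate
region (plus one period of flank on each side, for maximal extent) by
wraparound dynamic programming against the circular consensus: +2 for a
match, −7 for a mismatch, −7 per indel, local alignment with a zero
floor, wraparound handled by two left-propagation passes per row. Arrays
scoring ≥ 80 are reported with period, copy number and extent. A perfect
array of length L scores exactly 2L, which pins the threshold to
interpretable units: the minimum reportable perfect array is 40 bp
(e.g. eight copies of a 5-mer), and a 30-bp perfect array (score 60)
is correctly rejected. Same-extent harmonic calls (period 2p, 3p, …)
collapse to the smallest period among the top-scoring ones; genuinely
different overlapping periods are all reported. This detector keeps the
published scoring contract (2, 7, 7, 80) without re-implementing the
full probabilistic tandem-repeat model (composition-corrected P-values,
consensus realignment), which the rest of the pipeline never consumes.

# Sliding-window homology and MSS calling

The scan places 100-bp windows every 50 bp (`ceil((L−w)/s)+1` windows;
the final window is clipped, and clipped windows shorter than 20 bp are
dropped). A window **aligns** when a seeded (11-mer, both strands)
gap-free local alignment against *any* panel member reaches ≥ 80 %
identity over ≥ 60 % of the window; union-over-panel semantics because
the reference is a panel of mitotypes. "Could not align" had to be
operationalized — the choice of 80 %/60 % cleanly separates
within-crop-lineage homology (> 95 % identity in practice) from
wild-donor material diverged well below the threshold, and both knobs
are exposed. Runs of ≥ 2 consecutive non-aligning windows merge into one
MSS interval spanning first-window start to last-window end; isolated
non-aligning windows are discarded as unreliable at this resolution.
MSS boundaries are therefore window-quantized: against planted truth
the observed boundary error is ≤ ~60 bp, about one step plus the
flank a window may still align with.

`find_promiscuous()` reuses the same seeding genome-wide: per-diagonal
chains are x-drop extended, segments below 80 % identity are dropped,
colinear segments (diagonals within 20 bp, genome gaps ≤ 10 bp) are
chained, and a chain qualifies when it covers ≥ 40 bp **and** carries at
least one single-diagonal alignment of ≥ 25 bp. The second condition is
a low-complexity guard: inside simple repeats, short chance extensions
on period-spaced diagonals can otherwise pool their lengths into a
spurious hit (the standard pipelines solve this with DUST masking; the
chain test is the equivalent local remedy). Qualifying chains merge
across ≤ 10 bp gaps into maximal intervals, reported with the percent of
the genome covered.

# C-to-U editing

Chloroplast-derived intervals are replaced by the same number of `N`s
(`mask_cp()`, length-preserving) before calling, so reads of chloroplast
transcripts cannot produce fake mitochondrial editing evidence; masked
positions are never called. A site is called when the genome base is `C`
with T-fraction ≥ 20 % (or `G` with A-fraction ≥ 20 %, the
reverse-strand case) at depth ≥ 10 in at least 2 replicates
independently — "present in two experiments" is read as the full
frequency condition holding twice, not merely nonzero evidence twice.
The frequency denominator is the whole column depth, matching
variant-frequency semantics of standard callers. The depth floor is this
package's addition: a 20 % frequency on fewer than ten reads is
statistically meaningless, and the threshold is exposed.

Annotation maps each called site through the gene models: region by the
coding > intron > intergenic precedence of the feature partition; for
protein-CDS positions, the strand-aware, phase-corrected CDS offset o
gives codon position (o mod 3) + 1, the reference codon is read from the
spliced CDS and the edited codon substitutes the single base (C→T on
the coding strand; a site on the strand opposite its gene appears as
G→A in the coding frame and is annotated accordingly). Effects follow
the standard genetic code: synonymous, nonsynonymous, stop gained, and
start gained for an ACG first codon edited to ATG (the known mechanism
by which some mitochondrial genes acquire their initiator). tRNA/rRNA
exonic sites are region "gene" with effect "noncoding" — their
editability is an empirical question, not a rule. For nonsynonymous
sites the *edited* (product) residue's Kyte–Doolittle sign assigns
hydrophobic (> 0) or hydrophilic; this product-class convention is one
reading of the usual profile tables (whose hydropathy rows do not sum to
the nonsynonymous count), so the profile also keeps stop-gains separate
and the unclassified remainder implicit. The profile is a plain count
aggregation and is tested against an independent recount and the
bookkeeping identities (codon-position counts sum to the CDS-site count;
synonymous + nonsynonymous + stop-gain likewise).

# Expression and ORFs

TPM is the length-normalized rate `c_i/l_i` scaled to sum to 10^6; all
zero counts yield all-zero TPM rather than NaN. ORFs are scanned in all
six frames: within each inter-stop segment the earliest in-frame start
(ATG, GTG or TTG — the conventional alternative-start set, exposed as a
parameter) opens the ORF, which runs to the first stop; the span
including the stop must be ≥ 300 nt ("longer than 300 nucleotides" and
"larger than 100 codons" reconcile as ≥ 300). Nested ORFs sharing a stop
report only the longest. An ORF is flagged *expressed* when its mean
per-base coverage is ≥ 5× and ≥ 2× the median intergenic coverage —
an explicit, reproducible stand-in for the visual browser inspection a
human would do; both thresholds are parameters.

# The synthetic generator

`make_reference()` builds an i.i.d. background at GC 0.45 (the
composition of real crucifer mitogenomes) with 12 non-overlapping
protein genes (alternating single- and two-exon, 101–301 codons, valid
start/stop, no internal stops, introns 80–200 bp), 3 tRNA and 1 rRNA
models, and 2 perfect tandem arrays (unit 4–12 bp, 15–30 copies).
`make_alloplasmic()` then inserts, at intergenic points ≥ 600 bp apart:
5 MSS segments of 300–3000 bp (fresh donor sequence diverged to 70 %
identity of its donor original, each segment rejection-checked so that
*no* window aligns to the reference panel — detectability is constructed,
not hoped for — and, when ≥ 450 bp, carrying an intact ORF cassette
anchored behind an in-frame stop so the reported ORF coincides exactly
with the cassette); 3 chloroplast segments of 42–2186 bp copied verbatim
from a generated chloroplast panel; and 2 repeat duplications (direct
and inverted) of reference background. Background substitutions at rate
0.002 are applied outside planted features, so planted coordinates
re-extract their sequences exactly. Placement carves each feature (plus
spacing) out of the remaining free intergenic space, sampling gaps
weighted by capacity, and errors out when a feature no longer fits.

These defaults are the study conditions: mitogenome-scale sequence
(100 kb keeps every stage CPU-cheap while being large enough for
realistic seed statistics), MSS and chloroplast segment sizes spanning
the ranges reported for real alloplasmic lines, editing at 50 sites with
fractions 0.3–0.9 over 3 replicates at depth 50 and 0.5 % sequencing
error. Editing sites are planted on coding-strand `C`s of protein CDS
with codon positions in the canonical 3:6:1 ratio (plus intergenic
sites), avoiding chloroplast intervals because those are masked before
calling. Under these conditions the binomial tails make the caller's
behavior essentially deterministic: a 30 % site at depth 50 fails the
20 % threshold in ≥ 2 of 3 replicates with probability ~5×10⁻³, and a
sequencing-error column reaches 20 % with probability ~10⁻¹⁷, which is
why the acceptance checks demand ≥ 95 % sensitivity and exactly zero
false positives.

What the generator does *not* emulate: indels (the caller is
substitution-only, so pileups carry none), structural rearrangement
between mitotypes, read-level artifacts (mapping bias, strand bias,
duplicates), partial editing gradients along transcripts, and
origin-spanning features. Passing tests therefore demonstrate the
correctness of the window logic, the calling thresholds and the
annotation arithmetic — not robustness to alignment artifacts in real
BAM-derived pileups, which enter this pipeline only through the
pileup TSV contract.

# Numerical and degenerate-input choices

* GC content excludes `N` from numerator and denominator and errors on
  all-`N` input; report percentages round to 2 decimals.
* The feature partition is computed by interval algebra (IRanges) and
  asserts `coding + intron + intergenic = L` exactly, as integers.
* Only cis (within-model) inter-exon gaps count as intron; trans-spliced
  arrangements are out of scope.
* Wraparound DP breaks score ties toward the longer alignment (smallest
  start row); the x-drop extension breaks ties toward the score peak
  reached first.
* `call_sites()` treats a declared-but-absent replicate as
  non-supporting everywhere (with a warning); an empty panel is a
  configuration error, not an empty result.
* Truth sets serialize to JSON and reload losslessly, with integer
  coordinate columns re-coerced on read.
* Test problem sizes: the oracle comparisons run on 2-kb genomes
  (dispersed repeats), 20 windows against a 20-kb panel
  (Smith–Waterman flag oracle via `pairwiseAlignment`), and 200 planted
  CDS sites on a 60-kb genome (full-CDS retranslation); recovery tests
  run on a shared 30-kb study, and the acceptance checks on the full
  100-kb study conditions. These sizes make every brute-force oracle
  exact rather than sampled while keeping the default run lightweight.

# Known limitations

Origin-spanning features are truncated or dropped rather than wrapped;
repeat counts enumerate maximal *pairs*, not repeat families, so they
are not directly comparable to family-collapsed counts; the MSS
boundaries are window-quantized rather than alignment-breakpoint exact;
the promiscuous scanner has no composition-adjusted significance model,
only the length/identity/low-complexity rules above; and the editing
caller neither models strand-specific libraries nor quantifies partial
editing beyond the per-replicate frequencies it stores.
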