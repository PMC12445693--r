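---
title: "Reconstructing multipartite dsRNA virus genomes from FLDS data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multipartite dsRNA virus genomes from FLDS data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fldseg` turns FLDS libraries — dsRNA physically fragmented to ~1.5 kb with
an adaptor ligated to every fragment 3′ end — into complete multipartite
virus genomes and their characterization. This vignette explains the models
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the method left room.

## 1. Terminal completeness from adaptor junctions

Every fragment 3′ end in an FLDS library carries the adaptor, on both
strands of the duplex. After mapping, a read crossing a fragment 3′
junction shows the adaptor as soft-clipped sequence: as a clipped *suffix*
beginning with the adaptor when the junction is on the plus strand
(evidence for a 3′ terminus at `ref_end − 1`), or as a clipped *prefix*
ending with the reverse-complemented adaptor (evidence for a 5′ terminus at
`ref_start`; dsRNA symmetry means a minus-strand 3′ end marks the
plus-strand 5′ terminus). `detect_adaptor_junctions()` accumulates these
events into per-position arrays `j5`/`j3` plus a coverage track.

`call_completeness()` reduces each terminus to a three-way status:

* terminal count `n` = junction events in the first/last `window` nt
  (default 50 nt — wide enough to absorb a few bases of assembly overshoot,
  narrow relative to the ~1.5 kb breakpoint spacing);
* background `b` = junction events in the central half of the contig per
  window-sized bin, floored at the equivalent of one event spread over the
  central half (so an event-free centre cannot produce infinite
  enrichment);
* **complete** if `n ≥ min_events` (default 3) and `n ≥ enrich·b`
  (default 5); **ambiguous** if only the count is reached; **incomplete**
  otherwise.

The defaults are deliberate: at 50× coverage with ~1.5 kb fragments, a
50-nt internal window collects on the order of 2 junction events by chance,
so a count threshold of 3 with 5× enrichment keeps internal breakpoints
from masquerading as termini up to very high coverage, while a true
terminus — where *every* covering fragment ends — accumulates tens of
events. The peak position is the argmax inside the terminal window, ties
broken toward the contig extremity because assemblers occasionally extend a
few bases past the true terminus. In validation we score a terminus call as
correct when it classifies complete vs not-complete: a truncated end that
comes back *ambiguous* (some internal junction events, no enrichment) is a
correct rejection, not an error.

## 2. Genome grouping by conserved termini

Cognate segments of one multipartite genome share their terminal sequences;
unrelated genomes agree only at the random ~25% level. `group_segments()`
builds the graph of segment pairs whose 5′ *and* 3′ 30-nt terminal windows
both reach 0.8 best-offset ungapped identity (offsets ±5 nt absorb ragged
assembly ends; overhangs are excluded from the denominator) and takes
connected components (single linkage, matching the population-level reading
of a virus and its variants). Monte-Carlo calibration: random 30-mers score
0.25 on average and their best-of-eleven-offsets maximum stays below 0.65
in 10,000 trials, so 0.8 cannot link unrelated genomes by chance, while
error-free cognate termini score 1.0 and 0.2%-error copies ≥ 0.93. The AND
over both termini prevents chance 5′-only matches. Raising `min_id` can
only refine the partition, never merge sets.

## 3. Annotation

`find_orfs()` is a deterministic six-frame stop-to-stop scanner: within
each frame, each inter-stop interval contributes at most one ORF, reported
from its most upstream permitted start codon (ATG/GTG/TTG, genetic code
11), with a 60-aa default minimum — below the smallest protein expected in
these genomes, so nothing real is missed. Reverse-strand ORFs are reported
in forward coordinates (0-based half-open throughout the package; 1-based
only at the GFF3 boundary).

`detect_sd()` scans the coding strand upstream window
`[start − (15 + 6), start − 3)` for the longest contiguous match (≥4 nt) to
the canonical AGGAGG, preferring matches whose spacer is closest to the
8-nt optimum. Those parameters are standard prokaryotic practice; the SD
presence upstream of viral ORFs is evidence of a bacterial host.

`hydropathy_tm_scan()` flags candidate transmembrane segments as maximal
runs of 19-aa windows with mean Kyte–Doolittle hydropathy ≥1.6. It is a
hydropathy surrogate, *not* an HMM topology predictor, and every output row
carries `tm_method = "hydropathy_surrogate"` so downstream users cannot
conflate the two.

## 4. UTR coding-potential diagnostics

A genuinely noncoding region shows (a) stop codons in all six frames at
near-random density — `stop_codon_map()` reports all six frames on forward
coordinates for single-axis plotting — and (b) a trinucleotide composition
unlike any coding region. `trinuc_profile()` uses overlapping 3-mer
frequencies (64-vector, N-containing windows excluded) and
`composition_distance()` the Euclidean metric on those vectors: simple,
symmetric, and sufficient to separate codon-driven from
Markov-chain-driven composition by a wide margin. Conserved blocks between
UTRs are found by ungapped fixed-window comparison (100 nt every 10 nt,
identity > 0.68, diagonal-merged); ungapped windows keep the search
deterministic and O(n·m/step²), at the cost of missing indel-containing
homology — acceptable for closely related UTRs.

## 5. Abundance

Mapped reads pass the `identity ≥ 0.97`, `indels ≤ 3` filter; identity is
`matched / (aligned read bases including insertions)` from the NM tag (MD
fallback), with N counting as mismatch. Fragments (read pairs, or single
reads in single-end data) count once; multi-mapped fragments go to the
best-identity hit, ties to the longest representative — the simplest
deterministic rule, chosen over fractional allocation and documented so it
is not mistaken for any particular mapper's ambiguity handling.
`greedy_cluster()` reimplements CD-HIT-style incremental clustering:
length-sorted, k-mer prefiltered, ends-free pairwise alignment, identity =
matches over the shorter length with ≥80% coverage of the shorter sequence
(the coverage term stops short fragments from being absorbed into long
contigs). `FPKM = fragments / (kb × M cleaned reads)`; shares are
FPKM-normalized, and taxa below 2% pool into "other dsRNA"/"other ssRNA",
with unclassified contigs reported as "others".

## 6. Consensus expansion and column trimming

Family alignments are condensed to per-column majority consensi (ties
alphabetical); columns that are majority-gap (>0.5) become sentinels and
are excluded from the consensus sent to the master aligner. After the
consensi are aligned (externally — master alignment construction is out of
scope), `expand_master()` replaces each consensus residue with its full
family column and each master gap with all-gap columns, giving one complete
alignment whose per-family slices reproduce the originals exactly
(a property test asserts the round trip and residue conservation).

Column filtering removes a column when `gap_fraction > 0.67` **or**
`homogeneity < 0.05`. Two decisions are worth flagging. First, homogeneity
is implemented as the mean pairwise identity among the column's non-gap
residues (`Σ C(n_a,2)/C(n,2)`; fewer than two residues ⇒ 1.0, never
removed); several column-conservation scores are in circulation, and mean
pairwise identity at 0.05 cleanly removes near-random columns (uniform
20-letter columns score ≈0.05) while keeping any real conservation. A
substitution-matrix-based similarity could be slotted in as an
alternative. Second, the two thresholds act as independent
removal filters (OR) rather than a conjunction: removing only columns that
are *both* gappy and heterogeneous would retain near-random low-gap
columns, defeating the purpose of the trim.
 Trimming is idempotent.
`select_diverse()` picks up to 40 representatives per family by greedy
maxi-min selection under pairwise aligned identity, seeded with the least
similar pair — deterministic with row-order tie-breaks.

## 7. The synthetic-data generator

`simulate_genomes()` builds bisegmented genomes: each genome draws
independent 30-nt 5′/3′ terminal sequences shared by its two segments; RNA1
carries one long RdRP-like ORF behind a 1.5-kb noncoding 5′UTR (on 60% of
genomes by default), RNA2 carries 1–4 ORFs; 90% of ORFs get an AGGAGG SD
motif 8 nt upstream. Coding sequence is codon-sampled from a fixed
nonuniform usage table; noncoding sequence comes from an order-2 Markov
chain targeting an AT-rich, stop-enriched trinucleotide bias — this
produces the coding/noncoding composition contrast and six-frame stop
density without modeling real genes. Segment lengths are drawn from
2.5–6.5 kb.

Two constructional details make ground truth exact. Each ORF is preceded by
an in-frame stop directly at `start − 3`, so the scanner's most-upstream
start is the true start. And a repair pass inserts stop codons into any
*spurious* ORF (≥60 aa, either strand) that codon sampling produced by
chance, under a local safety rule — a mutation may not destroy an existing
stop or create a start codon in any frame of either strand, and may not
touch terminals, SD windows, or true start/stop codons — which guarantees
the repair monotonically shrinks spurious open reading and converges.
Truth proteins are re-translated from the final sequence. The recovered
annotation therefore equals the generator's truth exactly at zero error
rate, which the tests assert.

`simulate_flds_reads()` fragments both strands at Normal(1500, 300)
breakpoints (truncated at 200 nt — "~1.5 kb" is all the protocol
specifies), ligates the adaptor to every fragment 3′ end, and samples
300-nt single-end reads from both fragment ends, so junction-crossing reads
carry genomic suffix + adaptor prefix; substitution errors are applied at
0.2%. Single-end simulation is the default because terminal analysis
consumes junctions, which single-end reads carry equally well. The adaptor
default is an arbitrary fixed 20-mer: the real laboratory adaptor is not
public, and the analysis depends only on "an adaptor at fragment 3′ ends".
`truth_alignments()` projects the reads onto (possibly truncated) contigs
with perfect knowledge of provenance — a simulation component standing in
for an external mapper, with soft-clips, identities and strand handled
exactly as a SAM-reporting aligner would.

What the generator does *not* emulate: assembly errors and chimeras, RT/PCR
coverage bias, quality-score structure, indel sequencing errors,
reverse-complemented assembly orientations, and between-sample variation.
Passing tests therefore demonstrate the pipeline's logic and its behaviour
under substitution noise and truncation — not robustness to assembly
artefacts, which must be judged on real libraries.

## 8. Problem sizes and numerical choices

The validation suite runs the recovery study at the generator's study
conditions: 10 bipartite genomes, 50× coverage, 0.2% substitution error,
100 seeded replicates (≈4,000 terminus calls), with five RNA1 segments
truncated by 200 nt per run as negative controls; smaller 2–4-genome
simulations back the per-module tests. Column-statistic checks compare
1,000 random columns against a brute-force pair-enumeration oracle.
Enrichment ratios are capped at 10⁶ for reporting (a zero background would
otherwise print infinity); completeness calling refuses contigs shorter
than four windows (termini and background would overlap); `trinuc_profile`
requires ≥3 nt; consensus ties break alphabetically and selection ties by
row order so every result is reproducible bit for bit under a fixed seed.

## 9. Known limitations

* Terminal calling assumes adaptor sequences survive in soft-clips; a
  mapper that trims adaptors before alignment erases the signal.
* Grouping assumes segments are assembled in a consistent orientation;
  reverse-complement resolution is limited to orientation-consistent
  inputs.
* The hydropathy TM scan over-calls hydrophobic globular stretches
  relative to HMM predictors; treat flags as candidates.
* The conserved-link search is ungapped; indels within a conserved block
  split links.
* The 2% pooling and taxon labels assume an external taxonomic assignment;
  the package only consumes the contig→taxon map.
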