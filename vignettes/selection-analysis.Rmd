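---
title: "Analyzing phage display selections from NGS data with phagerank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing phage display selections from NGS data with phagerank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phage display (and its mirror-image variant) enriches peptide binders against
a target over successive rounds of binding, washing, elution and
amplification. Next-generation sequencing of each round replaces the handful
of Sanger clones of the classical workflow with millions of reads, but only a
short randomized region of each read is informative: the insert encoding the
displayed peptide, flanked by constant vector sequence. Two confounds make
raw round-3 abundance a poor ranking signal. First, some phages amplify
faster than others regardless of binding; second, some peptides bind
surfaces (plastic, beads) rather than the target. Control selections expose
both: the naive **library** gives each sequence's pre-selection baseline, an
**empty selection** (run entirely without target) enriches exactly the
target-independent sequences, and a **direct control** (a target selection
continued one round without target) probes round-to-round carryover.

`phagerank` implements this workflow end to end: anchored insert extraction
from FASTQ, reading-frame triage, translation, DNA-level counting with
parts-per-million (ppm) normalization, control-aware scoring, SQLite
persistence, and a fully specified campaign simulator that makes every stage
testable without sequencing data.

## Insert extraction

The user supplies the two framing anchors; conceptually the search pattern is
the regular expression `LEFT(.+?)RIGHT` with non-greedy, first-match
semantics. The implementation locates the first occurrence of the left
anchor, then the nearest occurrence of the right anchor starting immediately
after it (so overlapping anchors can never match), and returns the
intervening insert — at most one per read. Matching is exact and
case-insensitive (reads are uppercased on ingest); a read whose anchors
carry a point mutation is counted as a miss. Anchors directly adjacent yield
the empty insert, which is frame-valid (length 0) and translates to the
empty peptide; it is retained rather than silently dropped so that read
accounting stays exhaustive.

Every matched insert is frame-checked: a length not divisible by 3 indicates
a frame-breaking indel, and such inserts are set aside as *frame failures*
rather than translated. Extraction therefore partitions each round exactly:
`inserts + frame_failures + misses == total reads`, and the frequency of
incomplete sequences is reported per round.

Missed reads are not necessarily lost. `enumerate_anchor_variants()`
generates every pattern obtained by substituting exactly one base of exactly
one anchor (`3 * (len(left) + len(right))` patterns) and `cmd_variants()`
re-searches the missed reads with them, crediting each read to one variant.
Recovered inserts are reported separately and never merged into the stored
round tables, because they were found under a relaxed pattern.

## Translation

Four modes cover the possible orientations of the insert relative to the
sequencing primer: `forward` (as read), `forward_complement` (base
complement in place), `reverse` (character-reversed), and
`reverse_complement`. Translation uses the standard genetic code (NCBI
table 1). Stop codons are rendered `*` and kept — the pipeline's only
read-discarding rule is the frame check, and a `drop_stop` flag is available
for users who want stop-containing peptides removed. Codons containing a
non-ACGT symbol (an `N` base call, say) render `X` for the same reason: no
additional silent loss.

Counting is at the DNA level, keyed on the insert *as extracted*
(pre-transform), so synonymous sequences remain distinct rows and count
tables are comparable across translation modes. For mirror-image campaigns
the selected L-peptides correspond to D-peptide binders of the natural
target; the sequence arithmetic is identical and needs no special handling
here.

## Normalization and scoring

Raw counts are normalized to parts-per-million: `ppm = count / total * 1e6`,
where the denominator is the round's total of successfully extracted,
frame-valid inserts — exactly the sequences that appear as rows. This
convention makes the ppm column of every round sum to one million and makes
rounds of different sequencing depth directly comparable; it is a documented
choice (total reads or total matches would be alternatives, but then the
stored rows would not account for their own denominator).

Two ratios are computed per sequence present in the final target round, both
on ppm values:

- **enrichment score** = frequency in final target round / frequency in
  library — how strongly selection amplified the sequence over its baseline;
- **empty score** = frequency in final target round / frequency in the final
  empty round — how much better the sequence did *with* the target than
  without it.

The table is ordered by empty score, the primary key: a sticky or
amplification-advantaged sequence enriches in the empty selection too and
lands near an empty score of 1, while a genuine binder's empty-round
frequency stays at baseline. Ties break by enrichment score, then
final-target ppm, then lexicographic DNA, making the ranking a deterministic
total order independent of input read order.

A sequence absent from a control round has a zero denominator. Rather than
dropping such "never seen in control" sequences — which are exactly the most
interesting ones — the denominator is floored at a configurable ppm value,
default 0.5 ppm: half the smallest observable frequency at the 10^6 scale,
i.e. the value conventionally assigned to "present below one count". The
floor caps, but preserves, their ranking. The direct control is reported as
a ratio column (`direct_ppm / max(target_ppm, floor)`) with an *optional*
maximum-ratio filter that is never applied by default: no published hard
rule exists for it, so the package exposes the quantity instead of inventing
a cutoff. All filters (minimum target ppm, minimum enrichment, maximum
direct ratio) run after scoring, so they remove rows without changing any
score.

When fewer than three target rounds are provided, "final round" means the
last one given; earlier target rounds appear as context ppm columns.

## Storage

One SQLite file holds the campaign: one table per provided selection round
(columns `selection_name`, `user`, `dna`, `peptide`, `raw_count`, `ppm`,
`processed_date`), a `rounds_meta` table with per-round totals, a
`search_patterns` table for reusable anchor pairs, and an `evaluation` table
once scoring has run. Table names derive from the selection name by mapping
non-alphanumerics to `_`. Evaluation never mutates round tables — the
original extracted counts remain the reference if a scoring configuration is
revisited. Dates are stored as ISO-8601 text for portability.

## The campaign simulator

`generate_campaign()` produces FASTQ files plus a ground-truth manifest. It
emulates:

- a naive library of distinct inserts with Zipf-distributed abundances
  (default exponent 1.1) — the heavy skew a display library acquires through
  amplification; a log-normal law is available;
- panning-with-amplification as multinomial resampling: target round *r*
  draws reads from the background law with each planted binder's weight
  multiplied by `factor^r`; empty rounds resample the background without the
  advantage; the direct control applies the advantage through round *k−1*
  and then one neutral round;
- reads of the form `pad + left anchor + insert + right anchor + pad` with
  random pad lengths (5–15 nt);
- two corruption processes: a fraction of reads receives one anchor point
  mutation (unfindable by exact matching), another fraction a 1-nt deletion
  in the insert (a frame failure).

Library inserts are generated anchor-free, and every assembled read is
verified to produce its intended extraction outcome (clean reads extract to
exactly their insert, mutated reads to nothing, frameshifted reads to a
frame-invalid insert); pads — and for stubborn reads the planted mutation —
are redrawn until the layout is conflict-free. This rejection step is what
makes the manifest *exact* ground truth rather than an expectation, so tests
can assert equality instead of tolerances. A fixed seed yields byte-identical
FASTQ output.

What the simulator deliberately does not model: position-dependent
sequencing error profiles, quality-score structure (qualities are a constant
`I`), paired-end reads, PCR chimeras, or biophysical binding kinetics.
Passing tests on simulated campaigns therefore demonstrate the correctness
of the bookkeeping — extraction, counting, normalization, scoring, storage —
under a known generative model, not robustness to every artifact of real
sequencing chemistry.

## Default parameters and problem sizes

| Parameter | Default | Why |
|---|---|---|
| ppm floor | 0.5 ppm | half the smallest observable frequency at 10^6 scale |
| insert length | 27 nt | a 9-mer peptide, typical of display libraries |
| anchors | `GATTCCAGG` / `TACGACCCG` | 9-nt framing regions used as the canonical example pair |
| library size | 1,000 sequences | simulated campaign default |
| planted binders | 5 at 10× per round | well-separated recovery benchmark |
| reads per round | 50,000 | deep enough that a binder's empty-round baseline is observable |
| Zipf exponent | 1.1 | realistic naive-library skew |

The test suite exercises small campaigns (hundreds of sequences, 10^4 reads)
for module checks and full 50,000-read campaigns at three seeds for the
end-to-end binder-recovery property; the same sizes are used by
`scripts/acceptance.R`. At these sizes a full simulate–extract–score cycle
takes seconds on one CPU; the pipeline is vectorized and scales linearly in
read count, so million-read rounds are practical.

## Numerical and degenerate-input choices

- ppm values are stored at full double precision; rounding is left to
  display.
- A round with zero extractable reads is an error ("no extractable reads in
  round"), not an empty table: every stored round must satisfy
  Σppm = 10^6.
- Score sorting compares exact floating-point values; the tie-break chain
  ends in a lexicographic key, so the order is total and
  platform-independent.
- Reads are searched on the given strand only. If a campaign's inserts were
  sequenced in the opposite orientation, the user selects the matching
  translation mode; no reverse-complement anchor search is attempted, which
  is a known divergence risk for mixed-orientation data.
- Wrapped (multi-line) FASTQ is rejected rather than guessed at; quality
  strings are validated for length and otherwise ignored.

## Known limitations

Anchor matching is exact: systematic anchor-region sequencing errors reduce
yield, and the single-mutation variant re-search is a reporting tool, not a
fuzzy aligner. Scoring uses the final-round ratios only — no per-round
trajectory statistics or significance testing — and clustering of related
peptides (one mutational family split across synonymous DNA rows) is out of
scope: the DNA-level rows are deliberately left unmerged.
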