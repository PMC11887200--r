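---
title: "Targeted polishing of draft assemblies with per-target Bloom filters"
author: "TargetPolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted polishing of draft assemblies with per-target Bloom filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-read assemblers often leave regions with concentrated base errors in
otherwise accurate drafts: gap fills made of raw, unpolished read
sequence, terminal overlaps of fragmented contigs, and similar artefacts.
Pipelines that produce such regions commonly mark them by soft-masking
(lowercase bases). Re-polishing the whole assembly to repair a fraction
of a percent of it is wasteful, and global polishing can even degrade the
already-accurate majority. TargetPolish instead excises exactly the
suspect regions, polishes them with read evidence local to each region,
and splices the corrected sequence back.

The workflow has five stages, mirroring common targeted-polishing
practice:

1. long reads are mapped to the draft (externally; any PAF-producing
   mapper works — minimap2 defaults, or ntLink `pair` with its k=88,
   w=1000 minimizer defaults);
2. target regions are identified from soft-masking (or a user BED),
   extended by 64 bp flanks, merged, excised and renamed
   `"{contig}.{index}.{start}-{end}"` (0-based, half-open);
3. the PAF is lifted into target coordinates and reads touching no
   target are discarded;
4. each target is polished independently by a Bloom-filter k-mer edit
   engine built only from the reads assigned to it;
5. polished targets are spliced back using the coordinates encoded in
   their names; replacements are applied per contig in descending start
   order, so indel-induced length changes never invalidate the
   remaining coordinates.

## The edit engine

For each target and each k-mer size `k` in a descending schedule
(default 32, 28, 24, 20), the engine builds a Bloom filter over the
canonical (strand-neutral) k-mers of the assigned reads, sized from the
exact k-mer count at a configured false-positive rate (default 1%).
Bloom filters answer only membership — no false negatives, a tunable
false-positive rate, no counts — which is what makes per-target filters
cheap enough to build by the thousand.

The target is scanned left to right. A position whose canonical k-mer is
absent from the filter implies an error at the first base not covered by
the preceding supported window (`pos + k - 1`). Candidate repairs are
enumerated there: the three substitutions (greedily extensible into a
substitution run of up to `maxSubRun` = 16 bases, because a run of
adjacent substitution errors cannot be repaired one base at a time);
deletions of 1..`maxIndel` bases; and insertions of 1..`maxIndel` bases,
bases beyond the first chosen greedily by read support (`maxIndel` = 5;
the generator injects 1 bp indels, but raw gap-fill sequence can carry
longer ones). A candidate is accepted only if *all* of the following
hold:

* **anchor gate** — the k-mer spanning the verified left context and the
  first edited base is present in the filter: the edit must be directly
  read-backed, not merely an improvement;
* **quorum** — that anchor region is also supported by both halves of
  the read set (below);
* **ratchet** — support over the `verifyWindow` = 6 windows at the scan
  anchor strictly exceeds the unedited support, so repeated edits at one
  anchor make monotone progress and the scan terminates;
* **junction** — support over the 6 windows spanning the candidate's
  rightmost edited base plus downstream context exceeds
  `acceptFraction` = 0.3: the edit must reconnect the sequence to the
  right. Scoring insertions at the plain anchor instead would credit
  windows that end inside the inserted bases, and the engine would
  happily "tunnel" — endlessly inserting read-supported sequence at any
  site it cannot repair.

After an accepted edit the scan rewinds `k - 1` bases so the new
junction k-mers are themselves verified. Edits are allowed in the
flanks: flank sequence is read-supported, so the fixed-point property
protects it, and the per-edit log keeps flank edits auditable. The
engine contains no randomness; identical inputs give byte-identical
outputs regardless of a `threads` setting.

### Why the acceptance fraction is low

The verification span of a candidate covers about `verifyWindow + k`
bases downstream. In exactly the regions this tool exists for, errors
sit a few tens of bases apart, so a high acceptance fraction vetoes
correct repairs whose verification span happens to contain the *next*
error. With the anchor gate and quorum carrying the burden of rejecting
unsupported edits (a chance acceptance needs correlated false positives
in up to three filters at once, below 1e-4 per candidate), the fraction
threshold can be as low as 0.3 — tolerating a following error ~2 bp past
the junction — without admitting junk. This is why the defaults are
`verifyWindow = 6`, `acceptFraction = 0.3` rather than a long window
with a high fraction.

### Site probing and the two-read quorum

Membership filters cannot distinguish a k-mer seen in one read from one
seen in thirty. Two consequences matter at realistic read error rates
(~1%):

* *masked anchors*: a read whose own sequencing error matches the
  draft's error (expected at roughly `coverage × error/4 / 3` ≈ 7% of
  substitution sites at 30× and 1% read error) makes windows containing
  the draft error appear supported, so the first absent window — and
  with it the implied edit site — lands off the true error. The scan
  therefore probes sites a few bases either side of the implied site
  (`anchorBacktrack` = 4) and keeps the best candidate, breaking ties by
  support over *all* k windows containing the edit: a single colluding
  read rarely stays error-free across that whole span, while the
  bulk-read frame does.
* *single-read frames*: an edit can be fully "supported" by one
  erroneous read. To screen these out without counting structures, the
  read set is split into two deterministic halves (alternating input
  order) and per-k filters are built for each half alongside the main
  filter. A candidate must have at least one scored window present in
  both halves — i.e. be backed by at least two reads with high
  probability. The quorum is skipped whenever either half is empty, so
  single-read workflows behave exactly as the plain filter dictates.

## The synthetic study system

`simulateFixture()` generates the conditions the package is tested
against: a uniform-random truth genome (200 kb in 2 contigs), a draft
that is identical to the truth except inside 10 non-overlapping 2 kb
windows carrying 2% substitutions and 0.5% single-base indels (the
windows are rendered lowercase, emulating soft-masked raw gap fills), an
event-exact error ledger, and 30× reads of lognormal length (mean 10 kb,
sdlog 0.25) with 1% uniformly scattered errors (3/4 substitutions, 1/8
insertions, 1/8 deletions), plus a PAF of true read origins projected
onto draft coordinates so no external mapper is needed. All randomness
is R's Mersenne–Twister, seeded explicitly per stage (`seed`,
`seed + 1`, `seed + 2` for truth/draft/reads), making every artefact
reproducible from the configuration alone. Contig count and read-length
distribution are not dictated by the study conditions; they were fixed
once at ONT-scale values and left alone.

What the fixture does *not* emulate: homopolymer-biased ONT error
profiles, base qualities, chimeric or ambiguously-mapping reads, and —
importantly — repeat structure. Passing tests on this fixture show the
engine recovers concentrated errors from clean-ish long reads with
unique mappings; they do not demonstrate robustness to repeats or
mapping ambiguity on real genomes.

`evaluatePolish()` scores a polished assembly against the truth with a
banded unit-cost global alignment per contig (band half-width 256,
auto-widened to the contig length difference; traceback classifies every
residual difference by truth coordinate as in-window, in-flank or
off-target). On the standard conditions the suite requires at least 80%
of in-window errors removed and zero off-target changes; across the
seeds exercised during development the engine removed 81–87%. The
residual floor is dominated by two intrinsic ambiguities of
membership-only evidence: error sites confirmed by a colluding read, and
clusters so tight that no junction ever verifies.

## Targeted versus whole-assembly filters, at desk scale

The package's premise is that per-target filters beat one whole-assembly
filter. On this fixture that contrast is structurally invisible: reads
map uniquely, so the reads covering a target are the same in both arms;
a whole-assembly filter adds only k-mers from other loci, which at
k ≥ 20 on a uniform-random 200 kb genome essentially never collide with
local candidate windows, and both filters are sized to the same
false-positive rate. The advantage of targeting materialises with
repeat-rich genomes and the much larger, noisier filters of real-scale
data. The test suite nevertheless states the strict comparison — and is
expected to fail it on this fixture — so the limitation is measured, not
hidden; the acceptance script reports both residual counts.

## Numerical and degenerate-input choices

* k is limited to 2..32 (canonical k-mers are packed 2 bits/base into a
  64-bit word).
* Filter sizing: `m = ceil(-n ln p / ln(2)^2)`, `h = round(m/n · ln 2)`,
  with `n` the exact total k-mer count of the assigned reads.
* Windows containing non-ACGT characters are never "present"; an
  uppercase `N` inside a target can therefore be removed or replaced
  only by an edit that eliminates it from every verified window.
* Targets shorter than the smallest k are returned unchanged; each k
  skips targets shorter than itself.
* Book-ended (touching) flank-extended targets merge, so reinsertion
  never sees zero-length inter-target slices.
* BED targets are authoritative (mask scanning is skipped entirely) and
  are flank-extended like mask-derived targets — the polisher needs
  anchoring context either way.
* Lifted PAF query coordinates are clipped proportionally (no CIGAR is
  consulted; for `-` strand records from the opposite query end);
  `nmatch`/`blocklen` scale by the kept fraction, floored at 1. The PAF
  drives read-to-target assignment only — filters are populated from
  full read sequences, so clipping inaccuracies cannot starve a target
  of edge k-mers.
* Reinserted targets are uppercased by default (lowercase = unpolished
  downstream); `keepCase`/`uppercase = FALSE` preserves case, which
  makes excise-then-reinsert an exact round trip.
* Zero targets is a valid state: the pipeline warns, copies input to
  output and exits cleanly.

## Known limitations

* Membership-only evidence cannot resolve a draft error that some read
  confirms; a counting structure could, but is out of scope here.
* Mixed clusters (substitution and indel errors within one k-mer span)
  lack compound candidates and may survive polishing.
* The engine is serial per target; `threads` is accepted for interface
  compatibility and never changes results.
* External pointers back the Bloom filters, so `BloomFilterSet` objects
  do not survive `saveRDS()`; rebuild them from reads instead.
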