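---
title: "Junction resolution in Bionano hybrid scaffolds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction resolution in Bionano hybrid scaffolds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafmend)
```

## The model

A hybrid-scaffolding run aligns contig label maps (in-silico digests of
the assembled contigs) to anchor maps built from imaged DNA molecules.
`scafmend` takes the resulting bundle as ground truth for contig order
and orientation and re-decides only what happens *between* anchor-adjacent
contigs. Three mutually exclusive outcomes are possible per junction, in
this order of evidence strength:

* **Fusion at a shared label.** If both contig maps align to at least one
  common anchor label, the two contigs physically overlap through that
  label site. We take the shared label with the greatest anchor position
  (the one closest to the junction, which maximizes retained left-contig
  sequence), read its position on each contig from the contig's own CMAP
  — positions on contig maps carry no sizing noise, because contig maps
  are digests of known sequence — and cut: the left contig is kept
  through the label base, the right contig from the base after it. The
  duplicated region appears exactly once in the output.
* **Gap re-estimation, with alignment rescue.** Without shared labels the
  junction gap is estimated from map coordinates: the anchor distance
  between the facing alignment ends, minus the unaligned contig tails
  (`g = (Sa_n − Ea_k) − (Size_k − Em_k) − Sm_n`). The estimate is exact
  on noiseless data and inherits only the anchor's sizing noise over the
  spanned interval. When `g ≤ 1000` bp the junction may still be an
  overlap whose labels failed to align; the facing 30 kb windows are
  locally aligned and a score above 5 000 triggers a fusion at the
  alignment start on each side. Otherwise `g` Ns are emitted.
* **Containment.** A contig whose anchor span lies inside another's is
  not a linear neighbour. Between the outermost shared labels, whichever
  contig has more of its own labels aligned wins the region: if the
  contained contig wins it replaces the host's segment between the two
  label positions; otherwise the host stays intact and the contained
  contig is emitted as a singleton. Ties conservatively keep the host.
  Containment is resolved before the adjacent-pair walk so a contained
  contig never participates in pair arithmetic.

All cut arithmetic happens in *anchor orientation*: a reverse-aligned
contig is conceptually reverse-complemented first, and a label at native
position `p` moves to `L − p + 1`. Every orientation combination is
supported and fixture-tested.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gap_merge_threshold` | 1 000 bp | gap estimates at or below this trigger alignment rescue |
| `min_align_score` | 5 000 | minimal rescue score for a fusion |
| `window` | 30 000 bp | contig-end window length aligned at rescue |
| `min_gap` | 13 N | sentinel floor for emitted gaps |
| `seed_k` | 11 | exact seed length of the aligner |
| `band_pad` / `band_max` | 64 / 2048 | diagonals around / within the seed cluster |

The first four defaults are the upstream tool-chain's published operating
points; the 13-N sentinel in particular is the fixed gap the Bionano
scaffolder itself inserts, so unresolved junctions remain recognizable.
AGP requires positive gap lengths, so negative or sub-sentinel estimates
emit 13 Ns while the decision report keeps the raw estimate.

## The alignment score

The rescue threshold of 5 000 originates from BLAT's PSL score
(`matches − mismatches − gap opens`). That expression cannot be used
directly as a dynamic-programming objective: with any-length gaps costing
1, the optimum for two *unrelated* 30 kb windows chains thousands of
spurious micro-matches and easily exceeds 5 000 (we measured ~9 000 on
random sequence). Purely per-base gap costs (−1 per base, no opening
charge) are also still in the linear-growth phase for DNA and reach
~3 000 on random 30 kb pairs. `scafmend` therefore scores match +1,
mismatch −1, gap open −1 plus −1 per gapped base (a gap of length L costs
1 + L). This keeps every anchored property: an exact overlap of L bases
scores exactly L (so the 5 000 threshold means "≥ ~5 kb of real
overlap"), a single mismatch costs 2, and random-window scores stay in
the logarithmic regime (tens). The aligner runs full Smith–Waterman below
2 kb — and is tested for exact equality against an independent
dynamic-programming implementation there — and seed-and-extend (exact
11-mers vote for diagonals; banded DP around the densest diagonal
cluster) above it. Ns never match, so gap-adjacent sequence cannot fake
an overlap. An adapter for an external `blat` executable with the PSL
score is provided for users who want decisions taken by BLAT itself.

## The synthetic fixture generator

`simulate_fixture()` emulates the inputs the tool consumes, with full
ground truth:

* a uniform random genome (default 5 Mb — a desk-scale stand-in for a
  human chromosome arm) fragmented left to right into contigs separated
  by gap junctions (default 8, 3.4–100 kb) and overlap junctions
  (default 8);
* overlaps fall into three sub-populations mirroring the outcome classes
  seen on real data: `labelled` (the overlap contains a shared label —
  resolvable by fusion), `alignable` (≥ 6 kb of overlap but the right
  contig's labels in the overlap are unaligned — resolvable only by
  rescue; capped at 25 kb so the 30 kb rescue window can see the whole
  overlap), and `tiny` (≤ 200 bp — below anything a score-5 000 rescue
  can certify, so correctly left unresolved);
* contained contigs are exact interior subsequences of large hosts,
  placed away from junction-overlap regions; half are "label-rich" (the
  host's labels are thinned in the region, as when a fragile or
  repetitive region resolves poorly in the host map) and must be
  reinserted, half are "label-poor" and must come out as singletons;
* a quarter of contigs are embedded reverse-complemented;
* labelling uses the real recognition motifs (DLE-1 `CTTAAG`, BspQI
  `GCTCTTC`), one channel per enzyme, with label-site coordinates
  recorded strand-aware (start of a forward occurrence, end of a
  reverse-complement one) so both strands report the same physical base;
* the anchor map carries *interval-multiplicative* Gaussian sizing noise
  (default sd 0.3%): inter-label distances are perturbed and re-summed,
  because optical-map sizing error grows with distance — perturbing
  absolute coordinates instead would make errors scale with chromosome
  position, which is not how the measurement works. False-negative and
  false-positive label rates (defaults 2% / 1%) model unresolved and
  spurious labels.

What the generator does **not** emulate: molecule-level noise and map
assembly, chimeric joins and their conflict cuts (only the resulting
`_subseq_` key naming is exercised), non-uniform base composition, and
genomic repeats. Passing tests therefore demonstrate the correctness of
the junction arithmetic and file handling, not robustness to misassembled
input.

## Numerical choices and degenerate inputs

* Map coordinates stay exactly as printed (1-based bp, possibly
  fractional); rounding (half away from zero) happens once, where
  sequence indices are needed.
* Reverse-orientation XMAP rows are normalized at parse time (ascending
  query span + explicit flag).
* Palindromic motifs such as `CTTAAG` match both strands on the same
  6-bp footprint; no single-base coordinate can represent the site
  consistently from both strands, so cuts and gap estimates touching a
  *reverse*-oriented contig on a palindromic channel carry a bounded
  error of at most motif length − 1 (5 bp). Non-palindromic channels are
  exact in every orientation, which is why the byte-exactness tests run
  on the BspQI channel.
* Multi-channel arbitration: when both enzymes provide shared labels for
  a pair, the channel whose last shared label sits furthest along the
  anchor wins (the cut closest to the junction), ties going to the
  channel with more shared labels. For containment the channel with the
  most shared labels is used.
* A contig aligned to several anchors keeps only its highest-confidence
  alignment (preventing sequence duplication across scaffolds); ties
  break by file entry order.
* If a label-derived cut would empty a contig entirely (label at the
  extreme end), the fusion is abandoned and the junction falls through to
  gap estimation — no junction resolution ever discards a contig, and
  every input contig remains reachable from the AGP.
* Aligner backend failure at a junction degrades to a sized gap with a
  warning; the junction is preserved, never dropped.
* The scaffolder itself is deterministic; all randomness lives in the
  seeded generator.

## Bookkeeping invariants

Every run maintains an exact base ledger: total output length equals
total component length minus bases removed at fusions and containment
insertions plus emitted gap bases; the N count of the output equals the
sum of emitted gap lengths; and the AGP, re-expanded against the input
FASTA by an independent reader, reproduces the emitted scaffold FASTA
byte for byte. The test suite asserts all three on every fixture, plus
byte-identity of fused scaffolds against the source genome on noiseless
fixtures.

## Problem sizes

The shipped tests simulate 1–4 Mb genomes with 4–10 junctions per case;
the quantitative gap-size experiment uses a 10 Mb genome with 50 gap
junctions drawn uniformly from 3.4–100 kb under 0.3% sizing noise, the
scale at which the mean scaled absolute error of the estimator is
measured (see `scripts/acceptance.R`). These sizes keep a full test run
in the one-minute range on a laptop while every code path — all three
junction cases, all orientation combinations, both enzymes, containment
both ways — is exercised.

## Known limitations

* Unlabelled overlaps longer than the 30 kb rescue window cannot be
  certified and are (correctly, but unhelpfully) emitted as sentinel
  gaps; the window is kept at 30 kb per the upstream convention.
* The label-count criterion for containment uses aligned-label counts
  only; no sequence-level check of the replaced host segment is made.
* Scaffold-level conflict detection (chimera cutting) is out of scope;
  the tool trusts the upstream scaffolder's `_subseq_` cuts.
* After fusing duplicated regions, one copy's polishing state wins; a
  final round of short-read polishing on the output is advisable when
  the input copies were polished independently.
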