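# scafmend

Contiguity repair for Bionano hybrid scaffolds.

## The problem

Hybrid scaffolding with Bionano optical maps orders and orients long-read
contigs along chromosome-scale anchor maps, but the upstream scaffolder is
deliberately conservative at contig junctions. When two adjacent contigs
actually share sequence — typically an allelic duplication that the
assembler failed to merge — it still emits both contigs in full, separated
by a fixed 13-N sentinel gap, duplicating the shared region (sometimes by
hundreds of kilobases). Contigs whose alignment span falls inside another
contig are dropped entirely. Both behaviors hurt downstream analyses such
as copy-number work.

`scafmend` post-processes the file bundle such a run leaves behind — the
key file (map id ↔ contig name), CMAPs (label-site positions per map) and
XMAPs (contig-to-anchor alignments with explicit site pairs) — together
with the draft assembly FASTA, and resolves every junction between
anchor-adjacent contigs:

1. **Shared-label fusion.** If the two contig maps share at least one
   aligned anchor label, the label closest to the junction is taken; its
   position `P` on each contig is read from that contig's own CMAP; the
   left contig is kept through `P`, the right contig from just after it,
   and the gap disappears.
2. **Gap re-estimation with alignment rescue.** Otherwise the gap is
   re-sized from map coordinates:
   `n = Sa_n − Ea_k`, `d_k = Size_k − Em_k`, `d_n = Sm_n`,
   `g = n − d_k − d_n`, where `Sm/Em` and `Sa/Ea` are the alignment spans
   on the contig map and anchor. If `g ≤ 1000`, the last 30 kb of the
   left contig is locally aligned against the first 30 kb of the right
   one; a score above 5 000 (unit scoring: match +1, mismatch −1, gap of
   length L costs 1+L) fuses the contigs at the alignment start without
   duplicating a base. Otherwise `g` Ns are emitted (a 13-N sentinel
   floor applies when `g` is small or negative).
3. **Contained-contig reinsertion.** A contig whose anchor span lies
   inside another contig's span is reinserted between the outermost
   shared labels when it has more aligned labels there than its host;
   otherwise it is emitted as a singleton instead of being discarded.

Outputs are a scaffold FASTA, an AGP v2.1 file describing the new
organization of the input contigs, and a per-junction decision report.
Reverse-oriented contigs are handled in all combinations by mirroring map
coordinates into anchor orientation.

The package also ships a synthetic-fixture simulator (`simulate_fixture`)
that fragments a random genome into contigs with known gaps, overlaps and
contained contigs, labels it in silico at motif occurrences (DLE-1
`CTTAAG`, BspQI `GCTCTTC` by default), and emits the same key/CMAP/XMAP
bundle with a ground-truth manifest — so the whole pipeline is testable
without proprietary tools — plus contiguity metrics (NX/LX, auN =
ΣL²/ΣL, scaffold-to-contig splitting at N runs).

## Worked example

```r
library(scafmend)

spec <- fixture_spec(genome_length = 3e6, seed = 11,
                     n_gap_junctions = 4, n_overlap_junctions = 4,
                     overlap_classes = c(labelled = .5, alignable = .5, tiny = 0),
                     n_contained = 2, motifs = "GCTCTTC",
                     label_noise_sd = 0, label_fn_rate = 0, label_fp_rate = 0,
                     reverse_fraction = 0.4)
fx  <- simulate_fixture(spec)
res <- build_scaffolds(fx$contigs, fx$key, fx$contig_maps,
                       fx$anchor_maps, fx$alignments)
table(res$report$kind)
#>    containment_insert containment_singleton         fuse_at_label
#>                     1                     1                     2
#>     fuse_by_alignment             sized_gap
#>                     2                     4
res$ledger
#> $input_bases
#> [1] 3067562
#> $removed_bases
#> [1] 198223
#> $gap_bases
#> [1] 211774
#> $expected_output
#> [1] 3081113
```

All four planted overlap junctions were fused (two at shared labels, two
by alignment rescue), one contained contig was reinserted, one label-poor
one became a singleton, and the four true gaps were re-sized — none of
them closed. The ledger balances exactly against the emitted FASTA, and
on this zero-noise fixture the fused scaffold is byte-identical to the
source genome with the true gaps N-masked.

From the shell, the same pipeline is available as a tool:

```sh
inst/scripts/scafmend simulate --out-dir fixture --seed 11
inst/scripts/scafmend scaffold --fasta fixture/contigs.fasta \
    --key fixture/components.key \
    --contig-cmap fixture/contigs_ch1.cmap,fixture/contigs_ch2.cmap \
    --anchor-cmap fixture/anchor_ch1.cmap,fixture/anchor_ch2.cmap \
    --xmap fixture/alignments_ch1.xmap,fixture/alignments_ch2.xmap \
    --out-dir out
inst/scripts/scafmend stats --fasta out/scaffolds.fasta --report out/decisions.tsv
```

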