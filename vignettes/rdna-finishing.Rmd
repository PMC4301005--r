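---
title: "Planning bacterial genome finishing around rDNA operons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning bacterial genome finishing around rDNA operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnafinish)
```

## The problem

Short-read assemblies of bacterial genomes almost never close. The dominant
culprit is the ribosomal RNA (rDNA) operon — the 16S–ITS–23S(–5S) cluster —
present in many near-identical copies of roughly 5–6 kb each, longer than
any short-read insert. Assemblers cannot decide which reads belong to which
copy, so they break contigs at every operon, emit short chimeric
"rRNA-isoform" contigs assembled from reads of several copies at once, and
leave runs of ambiguous `N` bases wherever mate pairs link regions without
internal coverage. Finishing such a draft traditionally means blind primer
walking across every gap: each Sanger read extends the known sequence by
750–1000 bp, and each next primer must wait for the previous read.

`rdnafinish` implements the planning and analysis side of an
operon-aware finishing strategy. The key observation is that most gaps in
such drafts *contain* an rDNA operon, and the conserved gene bodies inside
the gap are already known — only the flanks and the internal transcribed
spacer (ITS) are not. Universal primers that anneal inside the conserved
16S and 23S genes can therefore prime reads *outward* from the middle of
the gap at the same time as the gap primers read inward. Six reactions
run in parallel — the two gap primers plus U1/U2 at the 16S boundaries and
U3/U4 at the 23S boundaries — tile the two flanks and the ITS in one round,
the equivalent of three serial walking stages, identically for every rDNA
gap in the genome. Wet-lab PCR and sequencing are replaced here by
in-silico PCR and a read-span model, so the whole strategy can be planned,
audited and tested computationally.

## The workflow

`run_finishing_plan()` chains the stages; each is also exposed on its own.

1. **rDNA scan and masking** (`scan_contigs()`, `mask_rrna_contigs()`).
   Consensus 16S/23S/5S genes are located on every contig by seeded local
   alignment (exact k-mer seeds, k = 13 every 10 bp, refined by local
   pairwise alignment clipped to the seed-supported span). A contig is
   masked out of the working set when it is shorter than 2 kb *and* at
   least 80% covered by rDNA hits. The identity floor is 90% with a 100 bp
   minimum fragment: operon copies are highly similar but not identical,
   so the floor must tolerate several percent of inter-copy divergence
   while rejecting chance matches; 0.8 coverage absorbs alignment edge
   effects at contig termini. Contigs at or above 2 kb are never masked,
   whatever their rDNA content.
2. **End annotation** (`annotate_contig_ends()`). An end is annotated when
   a hit starts or ends within 200 bp of the terminus. On repeat-broken
   drafts nearly half the contig ends carry such fragments — the
   diagnostic signature that operons, not random coverage gaps, broke the
   assembly.
3. **Ambiguous stretches** (`find_n_stretches()`,
   `design_n_flanking_primers()`). Maximal `N` runs of three or more bases
   are treated as short, pre-located gaps: a primer pair flanking each run
   (searched within 350 bp of the boundary, mirroring the gap-primer
   offset convention) amplifies it for direct sequencing.
4. **Small-contig placement** (`place_small_contigs()`). Assemblers often
   emit the sequence missing from an N run as a separate small contig
   whose ends overlap the run's flanks. Both ends of each sub-kilobase
   contig are aligned (free end gaps, ≥95% identity, 300 bp flank window)
   against the flanks of every stretch; an unambiguous best match merges
   the contig into the host, replacing the Ns. The replacement may differ
   from the run length by up to ±50% — assemblers only estimate run
   lengths from insert sizes. Ambiguous matches are reported, never
   merged.
5. **Scaffolding** (`anchor_contigs()`, `order_and_orient()`,
   `estimate_gap_sizes()`). Contigs are ordered and oriented against a
   finished related genome using maximal exact matches seeded from 21-mers
   unique in both the reference and the contig set; anchors under 42 bp
   are discarded. Orientation is the majority strand by anchored bases
   (ties break to `+` with a warning); the start estimate is the median
   anchor projection. Because uniqueness excludes repeats, rDNA regions
   anchor poorly by design — exactly the regions one should not trust for
   ordering. Gap sizes are reference distances between projected inward
   contig ends; negative estimates are flagged as putative overlaps.
6. **Gap classification and walk plans** (`design_gap_primers()`,
   `classify_gap_rdna()`, `plan_rdna_walk()`,
   `plan_traditional_walk()`). Gap primers are placed with their 5' base
   250–350 bp inside each flanking contig's inward end. The in-silico gap
   amplicon is then re-amplified with the universal pairs: a 16S call
   requires an 8F/1492R product of 1200–1700 bp, a 23S call a 127F/2241R
   product of 1800–2400 bp — windows bracketing the canonical bacterial
   gene sizes, standing in for the gel bands a bench scientist would
   read. 5S, for which no universal pair exists, is assessed by a direct
   consensus scan. Gaps with a complete operon get the six-reaction
   parallel plan; all others get a serial plan of
   `ceiling(gap / (2 x 750))` bidirectional stages. Predicted read tiling
   uses the conservative 750 bp span; the optimistic 1000 bp figure is
   carried in the plan as the best case. Any unknown interval the six
   reads cannot reach (for example a pathologically long ITS) is reported
   as uncovered rather than silently absorbed.
7. **Rearrangement detection** (`window_map()`,
   `call_rearrangements()`, `design_junction_primers()`). The
   layout-ordered draft is tiled with 10 kb windows every 5 kb and each
   window placed at its unique-anchor-supported reference position.
   Breakpoints are jumps of at least 50 kb (or strand flips) between
   adjacent placed windows — judged locally, so the slow coordinate drift
   that unsequenced gaps accumulate never triggers a call. An interior
   segment is an inversion when its strand differs from both flanks, and
   a relocation when excising it leaves the flanks reference-continuous;
   when one event is visible from both sides as two complementary
   segments, the smaller is reported (parsimony) and the larger noted.
   Call edges are refined from window to anchor resolution, and calls
   abutting an N stretch are typed `insertion-at-N`. Junction primers
   within 1 kb of each breakpoint give sub-kilobase verification
   products; windows are clipped at N runs and pushed beyond a run that
   contains the breakpoint.
8. **Validation** (`verify_draft_coverage()`). Every original draft
   contig — including masked rRNA contigs — must align to the finished
   sequence at ≥99% identity over ≥99% of its informative (non-N) bases.
   Placement is by anchor chaining with inter-anchor segments verified by
   direct comparison; coverage may split across chains, so a contig
   spanning a corrected rearrangement still validates. N positions are
   excluded from both denominators (they encode absence of information),
   and circular genomes are virtually doubled so origin-spanning contigs
   are found.

## The synthetic study conditions

`generate_genome()` and `corrupt_to_draft()` build a fully seeded model of
the finishing problem, with complete ground truth, so that every stage is
testable without any external data. The defaults encode the package's
reference scenario, a defect load typical of a repeat-broken
*Paenibacillus*-scale draft: a 6 Mb
genome at GC 0.45 with 12 operon copies at 2% inter-copy divergence and
400–600 bp ITS jitter; a draft of 38 contigs — 18 backbone contigs broken
120–200 bp inside the operon margins (so 24 of the 56 working-set contig
ends carry rDNA fragments), 10 sub-2-kb rRNA-isoform contigs sliced from
gene bodies, and 10 sub-kilobase placeable contigs excised and replaced by
N runs of ±20%-jittered length; 198 ambiguous stretches of 9–769 bp in
total; 18 inter-contig gaps of which 12 contain an operon; and one 200 kb
segmental relocation inserted next to an N stretch inside the largest
contig. Operon sequences are synthesized de novo around fixed universal
primer footprints (kept mutation-free, since these primers are universal
precisely because their sites are conserved) rather than copied from any
real rRNA, keeping the package self-contained. Every contig is emitted in
a random orientation and renamed in descending length order, the
convention draft assemblies follow.

Two deliberate idealisations matter when reading test results. First, the
background genome is i.i.d. random sequence: it contains no tandem
repeats, IS elements, prophages or skewed composition, so anchoring and
primer uniqueness are easier than on real genomes. Second, corruption is
substitution- and excision-only: there are no small indels, chimeric
junctions inside backbone contigs, or base-calling errors. Passing the
planted-truth suites therefore demonstrates the logic of every stage and
its bookkeeping — not that the thresholds are optimal for any particular
real genome; the thresholds remain user-visible parameters throughout.

The generator's self-consistency is itself an invariant under test:
`reconstruct_genome()` inverts every corruption operator (orientation,
relocation splice, N-run restoration, gap interleaving) and must
reproduce the genome byte for byte for any seed.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally and in BED/JSON
  outputs; human-readable TSVs carry companion `*_1based` columns.
* Melting temperatures use unified nearest-neighbor thermodynamics with
  an entropic salt correction, at 50 mM monovalent salt and 500 nM oligo.
  Degenerate positions are resolved to their weakest-annealing expansion
  (a conservative estimate, preferring A, then T, C, G); the Wallace
  counting rule is kept as an independent cross-check.
* Hybridization requires ≤2 mismatches with the primer's 3'-terminal
  3 bases matching exactly — 3' mismatches block polymerase extension.
  IUPAC codes expand on the primer side only; an ambiguous template base
  (including N) never confirms hybridization.
* Primer design scores candidates by `-|Tm - 60|`, breaking ties by
  `|GC - 50|` and then leftmost position — fully deterministic. The
  specificity check counts mismatch-tolerant occurrences across the whole
  working contig set and accepts exactly one.
* In-silico PCR treats the two primers as interchangeable and caps
  products at 15 kb (double the expected mean gap size of ~7.5 kb).
* `n50()` returns the contig length at which the cumulative sum first
  reaches half the total (`>=` comparison), so a tie at exactly half
  returns the crossing contig.
* Consensus building drops majority-gap columns and emits the covering
  IUPAC code on ties; length-discordant copies are aligned to the longest
  copy first (match +1, mismatch −1, gap −2 per base).
* Empty assemblies, zero-length genomes, empty gene sets, and all-N
  contigs raise errors or are flagged (`"no informative bases"`) rather
  than silently passing.

## Problem sizes used in the test suite

Module tests run on an 800 kb genome with 4 operons and proportionally
scaled defect counts; the acceptance suite runs the full 6 Mb, 38-contig
conditions once end to end, checks the statistical primitives against
brute-force oracles on a thousand random instances each, and verifies
generator reversibility across twenty seeds at 500 kb. These sizes were
chosen so the complete planted structure (every defect class present,
several operons on each strand) is exercised while the suite stays
comfortably interactive.

## Limitations

The scaffolder is a deliberate simplification of collinear-block
alignment: it orders one draft against one reference and will not
reconcile rearrangements across several references. Rearrangement calls
are window/anchor-resolution, not base-precise, and use no read-level
evidence. The primer engine screens neither hairpins nor primer dimers
and ranks off-targets only by mismatch count. None of the wet-lab
realities — polymerase processivity, gel interpretation, chromatogram
quality — are modelled beyond the read-span abstraction.
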