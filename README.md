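# rdnafinish

Planning toolkit for finishing fragmented bacterial draft genomes whose
assembly is broken by repetitive ribosomal RNA (rDNA) operons.

## The problem

Bacterial genomes carry many near-identical copies of the ~5–6 kb
16S–ITS–23S(–5S) rDNA operon — longer than any short-read insert, so
short-read assemblers break contigs at every copy. The resulting drafts
show a characteristic defect signature: rDNA fragments at a large share of
contig ends, short chimeric rRNA-isoform contigs, runs of ambiguous `N`
bases, small orphan contigs that actually belong inside those runs, and
occasional large misassemblies. Closing such a draft by blind primer
walking costs one Sanger read (~750–1000 bp) per serial stage, per gap.

`rdnafinish` plans the finishing campaign around the repeats instead.
Because the conserved 16S/23S gene bodies inside a gap are already known,
universal primers annealing at their boundaries (8F/1492R, 127F/2241R for
gap typing; U1–U4 for walking) can prime reads *outward* from the middle
of the gap while the gap primers read inward. For every gap that contains
a complete operon the package emits the same six-reaction parallel plan —
equivalent to three serial walking stages but performed in one round:

```
  gap_fwd >>>                U1 <<<   >>> U2        U3 <<<   >>> U4                <<< gap_rev
  ----------[left flank]--[16S...........]--[ITS]--[23S......................]--[right flank]----------
```

All wet-lab steps are replaced by in-silico PCR (IUPAC-aware
hybridization with a mismatch budget and exact 3'-terminal matching) and
a read-span model. The package also: masks rRNA-only contigs (<2 kb,
≥80% rDNA), annotates contig ends, finds and flanks N-stretches, places
small contigs into stretches, orders contigs against a finished related
genome by unique-21-mer anchoring, estimates gap sizes, detects large
relocations/inversions by windowed draft-vs-reference placement, designs
junction-verification primers, and validates a finished sequence against
the original draft (≥99% identity over ≥99% of non-N bases per contig).
A fully seeded synthetic genome/draft simulator with complete ground
truth (`generate_genome()`, `corrupt_to_draft()`) makes every stage
testable offline.

## Worked example

Simulate the package's default study conditions — a 6 Mb genome with 12
divergent rDNA operons corrupted into a 38-contig draft — and run the
whole workflow against the source genome as reference:

```r
library(rdnafinish)

gt <- generate_genome(seed = 42)            # 6 Mb, 12 operons, 2% divergence
dt <- corrupt_to_draft(gt, cr1_profile(), seed = 43)

rep <- run_finishing_plan(
  dt$contigs, gt$genes,
  reference        = as_contigs("ref", gt$genome),
  genomic_template = as_contigs("gdna", gt$genome),  # in-silico PCR template
  final_assembly   = gt$genome)
rep
#> <finishing_report>
#>   contigs: 38 -> 28 (masking) -> 18 (placement)
#>   ends annotated with rDNA: 24 of 56
#>   ambiguous stretches: 198; small contigs placed: 10
#>   gaps: 18 (12 rDNA-positive)
#>   rearrangement calls: 1
#>   draft coverage validation: PASS
```

Reading the report: ten sub-2-kb contigs were pure rRNA isoforms and were
masked (38 → 28); ten sub-kilobase contigs matched the flanks of ten
N-stretches and were merged into their hosts (28 → 18); 24 of the 56
remaining contig ends carry rDNA fragments — the operons sit in the gaps.
Of the 18 inter-contig gaps, 12 test rDNA-positive with the universal
pairs and receive the six-reaction parallel plan
(`glance(rep$plans[[i]])` shows 6 reactions, stage equivalent 3); the
other six fall back to serial walking. One 200,000 bp relocation is
called (`rep$rearrangements`, typed `insertion-at-N` because the planted
block lands beside an ambiguous stretch), and every one of the original
38 draft contigs — masked ones included — is recovered in the finished
sequence, so validation passes.

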