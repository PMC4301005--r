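make_gap_fixture <- function(seed = 900) {
  set.seed(seed)
  g <- random_dna(30000, gc = 0.5)
  left <- substr(g, 1, 10000)
  right <- substr(g, 15001, 25000)
  contigs <- as_contigs(c("L", "R"), c(left, right))
  layout <- structure(list(
    placements = tibble::tibble(contig_id = c("L", "R"),
                                orientation = "+",
                                ref_start_est = c(0, 15000),
                                n_anchors = 1L, anchored_bp = 10000L),
    unplaced = character(0)), class = "scaffold_layout")
  gap <- tibble::tibble(gap_id = "L|R", left_contig = "L", left_end = "3p",
                        right_contig = "R", right_end = "5p",
                        size = 5000, overlap = FALSE, rdna = "unknown")
  list(genome = g, contigs = contigs, layout = layout, gap = gap)
}

test_that("gap primers sit 250-350 bp inside the inward contig ends", {
  fx <- make_gap_fixture()
  gp <- design_gap_primers(fx$gap, fx$layout, fx$contigs)
  expect_true(all(gp$status == "ok"))
  left <- gp[gp$side == "left", ]
  # forward primer 5' base within [len-350, len-250] of the left contig
  expect_gte(left$start, 10000 - 350)
  expect_lte(left$start, 10000 - 250)
  expect_equal(left$strand, "+")
  right <- gp[gp$side == "right", ]
  expect_gte(right$end, 250)
  expect_lte(right$end, 350)
  expect_equal(right$strand, "-")
  # the pair amplifies across the gap on the genome
  amp <- simulate_pcr(fx$genome, gp$seq[1], gp$seq[2])
  expect_equal(nrow(amp), 1)
  expect_gte(amp$length, 5000)
})

test_that("a too-short flanking contig is undesignable", {
  fx <- make_gap_fixture()
  contigs <- fx$contigs
  contigs$seq[1] <- substr(contigs$seq[1], 1, 200)
  contigs$length[1] <- 200L
  gp <- design_gap_primers(fx$gap, fx$layout, contigs)
  expect_equal(gp$status[gp$side == "left"], "undesignable")
})

test_that("rDNA-repeat contig ends push or defeat the primer search", {
  gt <- small_truth()
  fx <- make_gap_fixture()
  contigs <- fx$contigs
  # replace the left contig's inward 400 bp with 16S sequence that also
  # occurs on the right contig (a repeat within the uniqueness scope)
  g16 <- substr(gt$genes$seq[gt$genes$gene == "16S"], 1, 400)
  contigs$seq[1] <- paste0(substr(contigs$seq[1], 1, 9600), g16)
  contigs$seq[2] <- paste0(g16, substr(contigs$seq[2], 401, 10000))
  gp <- design_gap_primers(fx$gap, fx$layout, contigs)
  left <- gp[gp$side == "left", ]
  # offset window [len-350, len-250] is fully repeat-covered: undesignable
  expect_equal(left$status, "undesignable")
})

test_that("gap classification follows the universal product windows", {
  amp <- operon_amplicon()
  gt <- small_truth()
  cls <- classify_gap_rdna(amp, consensus_5s = gt$genes$seq[
    gt$genes$gene == "5S"])
  expect_true(cls$has_16s)
  expect_true(cls$has_23s)
  expect_true(cls$has_5s)
  expect_equal(cls$rdna, "present")
  expect_gte(cls$len_16s, 1200)
  expect_lte(cls$len_16s, 1700)
  expect_gte(cls$len_23s, 1800)
  expect_lte(cls$len_23s, 2400)

  # a unique-sequence amplicon tests negative on all counts
  set.seed(901)
  neg <- classify_gap_rdna(random_dna(6000),
                           consensus_5s = gt$genes$seq[3])
  expect_false(neg$has_16s)
  expect_false(neg$has_23s)
  expect_equal(neg$rdna, "absent")

  # 16S without 23S: partial operon
  ops <- gt$operons[gt$operons$strand == "+", ][1, ]
  only16 <- paste0(substr(gt$genome, ops$s16_start - 200 + 1,
                          ops$s16_end + 200))
  p <- classify_gap_rdna(only16)
  expect_true(p$has_16s)
  expect_false(p$has_23s)
})

test_that("the parallel walk emits six reactions worth three stages", {
  amp <- operon_amplicon()
  # gap primers at the amplicon ends
  fwd <- design_primer(amp, window = c(0, 280))
  rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                       direction = "rev")
  plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
  expect_s3_class(plan, "walk_plan")
  expect_equal(plan$strategy, "rdna-parallel")
  expect_equal(nrow(plan$reactions), 6)
  expect_equal(plan$stage_equivalent, 3L)
  expect_equal(nrow(plan$uncovered), 0)
  expect_equal(nrow(plan$degraded), 0)
  expect_setequal(plan$reactions$primer,
                  c("gap_fwd", "U1", "U2", "U3", "U4", "gap_rev"))
  # parallel contract: no reaction depends on another
  expect_false("depends_on" %in% names(plan$reactions))
})

test_that("the walk plan handles a reverse-orientation operon", {
  amp <- revcomp(operon_amplicon())
  fwd <- design_primer(amp, window = c(0, 280))
  rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                       direction = "rev")
  plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
  expect_equal(nrow(plan$reactions), 6)
  expect_equal(plan$template_orientation, "-")
  expect_equal(nrow(plan$uncovered), 0)
})

test_that("a pathological 2.5 kb spacer leaves an uncovered interval", {
  gt <- small_truth()
  genes <- gt$genes
  set.seed(902)
  op <- paste0(genes$seq[genes$gene == "16S"], random_dna(2500),
               genes$seq[genes$gene == "23S"], random_dna(30),
               genes$seq[genes$gene == "5S"])
  amp <- paste0(random_dna(300, 0.5), op, random_dna(300, 0.5))
  fwd <- design_primer(amp, window = c(0, 280))
  rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                       direction = "rev")
  plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
  # two 750 bp reads from U2/U3 cannot tile 2.5 kb of spacer
  expect_gt(sum(plan$uncovered$length), 0)
  its_lo <- 300 + 1550
  its_hi <- 300 + 1550 + 2500
  expect_true(all(plan$uncovered$start >= its_lo &
                    plan$uncovered$end <= its_hi))
})

test_that("a knocked-out U2 site degrades that segment to walking", {
  amp <- operon_amplicon()
  up <- universal_primers()
  u2 <- up$sequence[up$name == "U2"]
  at <- as.integer(regexpr(u2, amp, fixed = TRUE))
  expect_gt(at, 0)
  mut <- u2
  substr(mut, 3, 3) <- "A"
  substr(mut, 8, 8) <- "C"
  substr(mut, 13, 13) <- "A"
  substr(mut, 18, 18) <- "C"
  substr(amp, at, at + nchar(u2) - 1) <- mut
  fwd <- design_primer(amp, window = c(0, 280))
  rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                       direction = "rev")
  plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
  expect_equal(nrow(plan$reactions), 5)
  expect_equal(plan$degraded$primer, "U2")
  expect_match(plan$degraded$segment, "intragenic")
})

test_that("traditional walking is serial with ceiling-based stages", {
  p1 <- plan_traditional_walk(1500)
  expect_equal(p1$stage_equivalent, 1L)
  expect_equal(nrow(p1$reactions), 2)

  # the documented average 7.5 kb gap needs five serial stages
  p5 <- plan_traditional_walk(7500)
  expect_equal(p5$stage_equivalent, 5L)
  expect_equal(nrow(p5$reactions), 10)

  p0 <- plan_traditional_walk(600)
  expect_equal(p0$stage_equivalent, 1L)
  expect_error(plan_traditional_walk(0), "positive")

  # serial contract: every stage after the first depends on its parent
  deps <- p5$reactions$depends_on[p5$reactions$stage > 1]
  expect_false(any(is.na(deps)))
  expect_true(all(deps %in% p5$reactions$reaction))
  # full coverage by construction
  expect_equal(nrow(p5$uncovered), 0)
})

test_that("empty uncovered set implies the reads tile the unknowns", {
  amp <- operon_amplicon()
  fwd <- design_primer(amp, window = c(0, 280))
  rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                       direction = "rev")
  plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
  expect_equal(nrow(plan$uncovered), 0)
  # reconstruct coverage independently: reads + primer footprints + gene
  # bodies must cover [0, template_length)
  rx <- plan$reactions
  iv <- IRanges::reduce(c(
    IRanges::IRanges(rx$read_start + 1L, rx$read_end),
    IRanges::IRanges(rx$primer_start + 1L, rx$primer_end)))
  gaps_left <- IRanges::setdiff(
    IRanges::IRanges(1L, plan$template_length), iv)
  # anything left must lie inside the 16S/23S bodies (known sequence)
  gt <- small_truth()
  expect_true(all(BiocGenerics::width(gaps_left) <= 2900))
})

test_that("stage equivalent stays three whatever the amplicon flanks", {
  for (flank in c(300, 500)) {
    amp <- operon_amplicon(flank = flank)
    fwd <- design_primer(amp, window = c(0, 280))
    rev <- design_primer(amp, window = c(nchar(amp) - 280, nchar(amp)),
                         direction = "rev")
    plan <- plan_rdna_walk(amp, fwd$seq, rev$seq)
    if (nrow(plan$uncovered) == 0) {
      expect_equal(plan$stage_equivalent, 3L)
    }
  }
})
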