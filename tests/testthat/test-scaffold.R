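test_that("anchoring recovers exact and reverse-complement slices", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  slice <- substr(gt$genome, 100001, 110000)
  a <- anchor_contigs(as_contigs("s", slice), ref)
  expect_equal(nrow(a), 1)
  expect_equal(a$strand, "+")
  expect_equal(a$contig_start, 0L)
  expect_equal(a$contig_end, 10000L)
  expect_equal(a$ref_start, 100000L)

  arc <- anchor_contigs(as_contigs("s", revcomp(slice)), ref)
  expect_equal(arc$strand, "-")
  expect_equal(arc$ref_start, 100000L)

  set.seed(800)
  expect_equal(nrow(anchor_contigs(as_contigs("r", random_dna(5000)), ref)),
               0)
})

test_that("layout recovers the order and orientation of shuffled slices", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  cuts <- c(0, 250000, 500000, nchar(gt$genome))
  slices <- vapply(1:3, function(i) {
    substr(gt$genome, cuts[i] + 1, cuts[i + 1])
  }, "")
  contigs <- as_contigs(c("mid", "last", "first"),
                        c(slices[2], slices[3], slices[1]))
  anchors <- anchor_contigs(contigs, ref)
  layout <- order_and_orient(contigs, anchors)
  expect_equal(layout$placements$contig_id, c("first", "mid", "last"))
  expect_true(all(layout$placements$orientation == "+"))
  expect_equal(length(layout$unplaced), 0)

  # one slice reverse-complemented flips only its orientation
  contigs2 <- contigs
  contigs2$seq[contigs2$id == "mid"] <- revcomp(slices[2])
  layout2 <- order_and_orient(contigs2, anchor_contigs(contigs2, ref))
  expect_equal(layout2$placements$contig_id, c("first", "mid", "last"))
  expect_equal(
    layout2$placements$orientation[layout2$placements$contig_id == "mid"],
    "-")
})

test_that("a layout is a permutation of the input contigs", {
  gt <- small_truth()
  dt <- small_draft()
  anchors <- anchor_contigs(dt$contigs, as_contigs("ref", gt$genome))
  layout <- order_and_orient(dt$contigs, anchors)
  expect_setequal(c(layout$placements$contig_id, layout$unplaced),
                  dt$contigs$id)
  expect_equal(nrow(layout$placements) + length(layout$unplaced),
               nrow(dt$contigs))
  # backbone contigs recover their true genomic order
  bb <- dt$backbone[order(dt$backbone$index), ]
  placed_bb <- layout$placements$contig_id[
    layout$placements$contig_id %in% bb$contig_id]
  expect_equal(placed_bb, bb$contig_id)
})

test_that("reordering an already-ordered set is the identity", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  cuts <- seq(0, nchar(gt$genome), length.out = 5) |> round()
  contigs <- as_contigs(paste0("c", 1:4), vapply(1:4, function(i) {
    substr(gt$genome, cuts[i] + 1, cuts[i + 1])
  }, ""))
  l1 <- order_and_orient(contigs, anchor_contigs(contigs, ref))
  ordered <- contigs[match(l1$placements$contig_id, contigs$id), ]
  l2 <- order_and_orient(ordered, anchor_contigs(ordered, ref))
  expect_equal(l2$placements$contig_id, l1$placements$contig_id)
  expect_equal(l2$placements$orientation, l1$placements$orientation)
})

test_that("gap sizes equal reference distances between projected ends", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  g <- gt$genome
  contigs <- as_contigs(c("a", "b"),
                        c(substr(g, 1, 100000),
                          substr(g, 103001, 200000)))
  anchors <- anchor_contigs(contigs, ref)
  layout <- order_and_orient(contigs, anchors)
  gaps <- estimate_gap_sizes(layout, anchors, contigs, ref)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$size, 3000, tolerance = 0.01)
  expect_false(gaps$overlap)

  # abutting slices give a zero gap
  contigs0 <- as_contigs(c("a", "b"),
                         c(substr(g, 1, 100000),
                           substr(g, 100001, 200000)))
  anchors0 <- anchor_contigs(contigs0, ref)
  gaps0 <- estimate_gap_sizes(order_and_orient(contigs0, anchors0),
                              anchors0, contigs0, ref)
  expect_equal(gaps0$size, 0, tolerance = 1e-9)

  # overlapping slices give a negative, flagged gap
  contigsv <- as_contigs(c("a", "b"),
                         c(substr(g, 1, 101000),
                           substr(g, 100001, 200000)))
  anchorsv <- anchor_contigs(contigsv, ref)
  gapsv <- estimate_gap_sizes(order_and_orient(contigsv, anchorsv),
                              anchorsv, contigsv, ref)
  expect_equal(gapsv$size, -1000, tolerance = 0.01)
  expect_true(gapsv$overlap)
})

test_that("gap estimates on the fixture match the planted gap lengths", {
  gt <- small_truth()
  dt <- small_draft()
  ref <- as_contigs("ref", gt$genome)
  bb_ids <- dt$backbone$contig_id
  contigs <- dt$contigs[dt$contigs$id %in% bb_ids, ]
  anchors <- anchor_contigs(contigs, ref)
  layout <- order_and_orient(contigs, anchors)
  gaps <- estimate_gap_sizes(layout, anchors, contigs, ref,
                             circular = TRUE)
  expect_equal(nrow(gaps), nrow(dt$gaps))
  truth <- dt$gaps
  for (i in seq_len(nrow(gaps))) {
    want <- truth[truth$left_contig == gaps$left_contig[i] &
                    truth$right_contig == gaps$right_contig[i], ]
    expect_equal(nrow(want), 1)
    planted <- want$end - want$start
    expect_lt(abs(gaps$size[i] - planted), 0.1 * planted + 50)
  }
})

test_that("a rearranged reference changes order but not the placed set", {
  gt <- small_truth()
  dt <- small_draft()
  contigs <- dt$contigs[dt$contigs$id %in% dt$backbone$contig_id, ]
  ref1 <- as_contigs("ref", gt$genome)
  # emulate scaffolding against a related genome with a large inversion
  g <- gt$genome
  inv <- paste0(substr(g, 1, 200000),
                revcomp(substr(g, 200001, 500000)),
                substr(g, 500001, nchar(g)))
  ref2 <- as_contigs("ref2", inv)
  l1 <- order_and_orient(contigs, anchor_contigs(contigs, ref1))
  l2 <- order_and_orient(contigs, anchor_contigs(contigs, ref2))
  expect_setequal(l1$placements$contig_id, l2$placements$contig_id)
})
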