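# Manual rearrangement fixtures: slices of the small-fixture genome with a
# block moved or inverted, checked against the unmodified genome.

splice_relocation <- function(g, a, b, d) {
  # move [a, b) (0-based) to insert before position d (d > b)
  paste0(substr(g, 1, a), substr(g, b + 1, d), substr(g, a + 1, b),
         substr(g, d + 1, nchar(g)))
}

invert_block <- function(g, a, b) {
  paste0(substr(g, 1, a), revcomp(substr(g, a + 1, b)),
         substr(g, b + 1, nchar(g)))
}

test_that("window placements are collinear on an identical draft", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  wm <- window_map(substr(gt$genome, 1, 300000), ref)
  pl <- wm$placements[wm$placements$placed, ]
  expect_gt(nrow(pl), 50)
  expect_true(all(pl$strand == "+"))
  expect_true(all(diff(pl$ref_start) > 0)) # monotone
  expect_equal(pl$ref_start, pl$draft_start, tolerance = 1e-9)
  expect_equal(nrow(call_rearrangements(wm)), 0) # no false positives
})

test_that("a reverse-complement draft maps entirely to the minus strand", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  wm <- window_map(revcomp(substr(gt$genome, 1, 200000)), ref)
  pl <- wm$placements[wm$placements$placed, ]
  expect_true(all(pl$strand == "-"))
})

test_that("windows of pure ambiguity are unplaced", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  draft <- paste0(substr(gt$genome, 1, 100000), strrep("N", 15000),
                  substr(gt$genome, 100001, 200000))
  wm <- window_map(draft, ref)
  pl <- wm$placements
  mid <- pl[pl$draft_start >= 100000 & pl$draft_end <= 115000, ]
  expect_true(any(!pl$placed))
  expect_true(all(!mid$placed))
})

test_that("a planted relocation is called once at the planted size", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  g <- substr(gt$genome, 1, 760000)
  draft <- splice_relocation(g, 100000, 150000, 400000)
  wm <- window_map(draft, ref)
  calls <- call_rearrangements(wm)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "relocation")
  expect_lt(abs(calls$block_size - 50000), 5000)
  # draft position of the moved block: just before the insertion point
  expect_lt(abs(calls$draft_start - (400000 - 50000)), 5000)
})

test_that("relocation sizes 30-80 kb are recovered within a window step", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  set.seed(1000)
  for (i in 1:6) {
    L <- sample(30000:80000, 1)
    a <- sample(50000:150000, 1)
    d <- a + L + sample((L + 60000):300000, 1)
    draft <- splice_relocation(gt$genome, a, a + L, d)
    calls <- call_rearrangements(window_map(draft, ref))
    expect_equal(nrow(calls), 1)
    expect_lte(abs(calls$block_size - L), 5000)
  }
})

test_that("an inverted block yields one inversion call, symmetrically", {
  gt <- small_truth()
  g <- substr(gt$genome, 1, 700000)
  ref <- as_contigs("ref", g)
  draft <- invert_block(g, 200000, 300000)
  calls <- call_rearrangements(window_map(draft, ref))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "inversion")
  expect_lt(abs(calls$block_size - 100000), 5000)

  # strand symmetry: inverting the block in the reference instead
  calls2 <- call_rearrangements(window_map(g, as_contigs("r2", draft)))
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$type, "inversion")
  expect_lt(abs(calls2$block_size - 100000), 5000)
})

test_that("a relocation landing at an N-stretch is typed insertion-at-N", {
  gt <- small_truth()
  g <- substr(gt$genome, 1, 700000)
  ref <- as_contigs("ref", g)
  with_n <- paste0(substr(g, 1, 400000), strrep("N", 200),
                   substr(g, 400001, nchar(g)))
  draft <- splice_relocation(with_n, 100000, 150000, 400200)
  st <- find_n_stretches(draft)
  calls <- call_rearrangements(window_map(draft, ref), n_stretches = st)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "insertion-at-N")
})

test_that("junction primers span both breakpoints of a call", {
  gt <- small_truth()
  ref <- as_contigs("ref", gt$genome)
  g <- substr(gt$genome, 1, 760000)
  draft <- splice_relocation(g, 100000, 150000, 400000)
  calls <- call_rearrangements(window_map(draft, ref))
  jp <- design_junction_primers(calls[1, ], draft)
  expect_equal(nrow(jp), 2)
  expect_true(all(jp$status == "ok"))
  for (i in 1:2) {
    expect_lte(jp$left_start[i], jp$breakpoint[i])
    expect_gte(jp$right_end[i], jp$breakpoint[i])
    amp <- simulate_pcr(draft, jp$left_seq[i], jp$right_seq[i],
                        max_product = 3000)
    expect_gte(nrow(amp), 1)
    expect_lte(amp$start[1], jp$breakpoint[i])
    expect_gte(amp$end[1], jp$breakpoint[i])
  }
})

test_that("a breakpoint at the draft edge is undesignable on that side", {
  gt <- small_truth()
  draft <- substr(gt$genome, 1, 5000)
  call <- tibble::tibble(call_id = 1L, draft_start = 50L,
                         draft_end = 3000L, block_size = 2950L,
                         type = "relocation", ref_start = 0L, ref_end = 0L,
                         offset = 0, windows = "", note = "")
  jp <- design_junction_primers(call, draft)
  expect_equal(jp$status[jp$junction == "start"], "undesignable")
})

test_that("a junction inside an N-stretch pushes primers past the Ns", {
  set.seed(1001)
  g <- random_dna(20000, gc = 0.5)
  draft <- paste0(substr(g, 1, 10000), strrep("N", 300),
                  substr(g, 10301, 20000))
  call <- tibble::tibble(call_id = 1L, draft_start = 10150L,
                         draft_end = 18000L, block_size = 7850L,
                         type = "insertion-at-N", ref_start = 0L,
                         ref_end = 0L, offset = 0, windows = "", note = "")
  jp <- design_junction_primers(call, draft)
  start_j <- jp[jp$junction == "start", ]
  expect_equal(start_j$status, "ok")
  expect_lte(start_j$left_start, 10000) # placed before the N run
  expect_gte(start_j$right_end, 10300) # and beyond it
})
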