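test_that("find_n_stretches reports maximal runs above the minimum", {
  st <- find_n_stretches("ACGTNNNNACGT")
  expect_equal(nrow(st), 1)
  expect_equal(st$start, 4L)
  expect_equal(st$end, 8L)
  expect_equal(st$length, 4L)

  expect_equal(nrow(find_n_stretches("ACNNA", min_length = 3)), 0)
  expect_equal(nrow(find_n_stretches("ACGTACGT")), 0)
})

test_that("stretches plus sub-minimum runs partition all N bases", {
  set.seed(700)
  for (i in 1:20) {
    seq <- random_dna(500)
    for (j in 1:8) {
      at <- sample(1:(500 - 12), 1)
      len <- sample(1:10, 1)
      substr(seq, at, at + len - 1) <- strrep("N", len)
    }
    all_runs <- find_n_stretches(seq, min_length = 1)
    n_total <- sum(strsplit(seq, NULL)[[1]] == "N")
    expect_equal(sum(all_runs$length), n_total)
    # runs are maximal: neighbours outside each run are not N
    chars <- strsplit(seq, NULL)[[1]]
    for (r in seq_len(nrow(all_runs))) {
      if (all_runs$start[r] > 0) {
        expect_false(chars[all_runs$start[r]] == "N")
      }
      if (all_runs$end[r] < 500) {
        expect_false(chars[all_runs$end[r] + 1] == "N")
      }
    }
  }
})

test_that("the small-fixture draft yields exactly the planted stretches", {
  dt <- small_draft()
  st <- find_n_stretches(dt$contigs)
  expect_equal(nrow(st), nrow(dt$n_runs))
  got <- dplyr::arrange(st[, c("contig_id", "start", "length")],
                        .data$contig_id, .data$start)
  want <- dplyr::arrange(
    tibble::tibble(contig_id = dt$n_runs$contig_id,
                   start = as.integer(dt$n_runs$start),
                   length = as.integer(dt$n_runs$length)),
    .data$contig_id, .data$start)
  expect_equal(got, want)
})

test_that("flanking primers read across their stretch", {
  set.seed(701)
  contig <- as_contigs("c", {
    s <- random_dna(5000, gc = 0.5)
    substr(s, 1001, 1100) <- strrep("N", 100)
    s
  })
  st <- find_n_stretches(contig)
  des <- design_n_flanking_primers(contig, st)
  expect_equal(nrow(des), 2)
  expect_true(all(des$status == "ok"))
  amp <- simulate_pcr(contig, des$seq[1], des$seq[2])
  expect_equal(nrow(amp), 1)
  expect_lte(amp$start, 1000)
  expect_gte(amp$end, 1100)
})

test_that("a stretch at the contig terminus is undesignable", {
  set.seed(702)
  s <- paste0(strrep("N", 40), random_dna(800))
  contig <- as_contigs("c", paste0(substr(s, 1, 10 + 40), random_dna(750)))
  contig <- as_contigs("c", paste0(random_dna(10), strrep("N", 40),
                                   random_dna(800)))
  st <- find_n_stretches(contig)
  des <- design_n_flanking_primers(contig, st)
  fwd <- des[des$side == "fwd", ]
  expect_equal(fwd$status, "undesignable") # only 10 bp of upstream room
})

test_that("repetitive flanks defeat the uniqueness rule", {
  set.seed(703)
  rep_unit <- random_dna(400)
  s <- paste0(paste(rep(rep_unit, 3), collapse = ""), strrep("N", 50),
              paste(rep(rep_unit, 3), collapse = ""))
  contig <- as_contigs("c", s)
  st <- find_n_stretches(contig)
  des <- design_n_flanking_primers(contig, st)
  expect_true(all(des$status == "undesignable"))
})

test_that("planted small contigs place exactly, Ns replaced", {
  set.seed(704)
  host <- random_dna(3000)
  novel <- random_dna(400)
  true_host <- paste0(substr(host, 1, 1500), novel,
                      substr(host, 1501, 3000))
  small_seq <- paste0(substr(host, 1201, 1500), novel,
                      substr(host, 1501, 1800))
  host_n <- paste0(substr(host, 1, 1500), strrep("N", 400),
                   substr(host, 1501, 3000))
  hosts <- as_contigs("host", host_n)
  smalls <- as_contigs("small", small_seq)
  st <- find_n_stretches(hosts)
  res <- place_small_contigs(smalls, hosts, st)
  expect_equal(nrow(res$placements), 1)
  expect_equal(res$placements$orientation, "+")
  merged <- res$contigs$seq[res$contigs$id == "host"]
  expect_identical(merged, true_host)
  expect_equal(nrow(res$contigs), 1) # small consumed

  # reverse-complemented small places with orientation '-'
  smalls_rc <- as_contigs("small", revcomp(small_seq))
  res_rc <- place_small_contigs(smalls_rc, hosts, st)
  expect_equal(res_rc$placements$orientation, "-")
  expect_identical(res_rc$contigs$seq[res_rc$contigs$id == "host"],
                   true_host)
})

test_that("merging never changes a non-N host base", {
  dt <- small_draft()
  hosts <- dt$contigs[dt$contigs$length >= 1000, ]
  smalls <- dt$contigs[dt$contigs$id %in% dt$smalls$contig_id, ]
  st <- find_n_stretches(hosts)
  res <- place_small_contigs(smalls, hosts, st)
  expect_equal(nrow(res$placements), nrow(smalls))
  for (hid in unique(res$placements$host_id)) {
    before <- strsplit(hosts$seq[hosts$id == hid], NULL)[[1]]
    after <- res$contigs$seq[res$contigs$id == hid]
    # every non-N prefix/suffix region outside stretches is untouched:
    # compare around each placement
    ph <- res$placements[res$placements$host_id == hid, ]
    ph <- ph[order(ph$stretch_start), ]
    expect_identical(substr(paste(before, collapse = ""), 1,
                            min(ph$stretch_start)),
                     substr(after, 1, min(ph$stretch_start)))
  }
})

test_that("a contig matching two stretches equally is reported ambiguous", {
  set.seed(705)
  flank_a <- random_dna(300)
  flank_b <- random_dna(300)
  novel <- random_dna(200)
  host <- paste0(flank_a, strrep("N", 200), flank_b,
                 random_dna(500),
                 flank_a, strrep("N", 200), flank_b)
  hosts <- as_contigs("host", host)
  smalls <- as_contigs("sm", paste0(flank_a, novel, flank_b))
  st <- find_n_stretches(hosts)
  res <- place_small_contigs(smalls, hosts, st)
  expect_equal(nrow(res$placements), 0)
  expect_equal(nrow(res$unplaced), 1)
  expect_match(res$unplaced$reason, "ambiguous")
  expect_match(res$unplaced$candidates, ";") # both candidates listed
})
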